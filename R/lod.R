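# LOD profiles, support intervals and explained variances for a fitted
# MT-MIM model.

# log10 likelihood-ratio of the full model against the model without QTL r
# (the QTL's active pattern removed, other QTLs fixed).
lodOfQtl <- function(model, Y, X, r) {
  idx <- model@qtls$index
  act <- model@active
  full <- fitJointModel(Y, X[, idx, drop = FALSE], act)
  red <- fitJointModel(Y, X[, idx[-r], drop = FALSE], act[-r, , drop = FALSE])
  (full$logLik - red$logLik) / log(10)
}

#' LOD profile and LOD-1.5 support interval for one QTL
#'
#' The profile LOD at each grid position p of the focal QTL's linkage group
#' is log10 L(model with the focal QTL moved to p) minus log10 L(model
#' without the focal QTL), all other QTLs held fixed. The ~95% support
#' interval is the widest contiguous region around the peak with
#' LOD >= peak - drop (default drop 1.5), clipped to the group ends.
#'
#' @param model a pruned \linkS4class{QTLModel}.
#' @param Y,X scan inputs.
#' @param positions the candidate-grid data.frame the model was searched on.
#' @param qtlIndex which QTL of the model (row of \code{model@qtls}).
#' @param drop LOD drop defining the interval (default 1.5).
#' @return list(profile = data.frame(cM, lod), peakLod, peakCM,
#'   interval = c(lo, hi) in cM).
#' @export
lodSupport <- function(model, Y, X, positions, qtlIndex, drop = 1.5) {
  R <- nrow(model@qtls)
  stopIfNot(qtlIndex >= 1 && qtlIndex <= R, "qtlIndex out of range")
  grp <- model@qtls$group[qtlIndex]
  gridIdx <- which(positions$group == grp)
  idx <- model@qtls$index
  act <- model@active
  red <- fitJointModel(Y, X[, idx[-qtlIndex], drop = FALSE],
                       act[-qtlIndex, , drop = FALSE])
  lod <- vapply(gridIdx, function(p) {
    ix <- idx; ix[qtlIndex] <- p
    f <- tryCatch(fitJointModel(Y, X[, ix, drop = FALSE], act),
                  error = function(e) NULL)
    if (is.null(f)) return(NA_real_)
    (f$logLik - red$logLik) / log(10)
  }, 0)
  cm <- positions$cM[gridIdx]
  ok <- !is.na(lod)
  peakAt <- which.max(lod)
  peak <- lod[peakAt]
  inSupp <- !is.na(lod) & lod >= peak - drop
  lo <- peakAt; hi <- peakAt
  while (lo > 1 && inSupp[lo - 1]) lo <- lo - 1
  while (hi < length(lod) && inSupp[hi + 1]) hi <- hi + 1
  list(profile = data.frame(cM = cm, lod = lod),
       peakLod = peak, peakCM = cm[peakAt],
       interval = c(cm[lo], cm[hi]))
}

#' Percent phenotypic variance explained per QTL and environment
#'
#' PVE_er = 100 a_er^2 Var_i(x_r) / Var_i(y_e) using sample variances over
#' individuals; inactive ("sur") effects get NA.
#'
#' @param model a pruned \linkS4class{QTLModel}.
#' @param Y,X scan inputs.
#' @return R x E matrix of PVE percentages (NA where inactive).
#' @export
computePve <- function(model, Y, X) {
  Y <- as.matrix(Y)
  R <- nrow(model@qtls); E <- ncol(Y)
  vy <- apply(Y, 2, var)
  if (any(vy < 1e-12))
    stop("zero-variance trait column: PVE undefined", call. = FALSE)
  pve <- matrix(NA_real_, R, E)
  if (R == 0) return(pve)
  vx <- apply(X[, model@qtls$index, drop = FALSE], 2, var)
  for (r in seq_len(R)) for (e in seq_len(E))
    if (model@active[r, e])
      pve[r, e] <- 100 * model@effects[r, e]^2 * vx[r] / vy[e]
  colnames(pve) <- model@envNames
  pve
}
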