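#' Forward-backward MT-MIM model search with score-statistic thresholds
#'
#' Forward selection: at each round the score statistic is computed at every
#' eligible position (outside the exclusion window of all QTLs in the model)
#' under the current model, a genome-wide threshold at
#' \code{settings$alphaForward} is obtained by multiplier resampling, and the
#' argmax position enters the model if its statistic exceeds the threshold.
#' Backward elimination: each QTL is re-tested by removing it and comparing
#' its score statistic under the reduced model against the genome-wide
#' \code{settings$alphaBackward} threshold; failures are dropped (refitting
#' after every change) until all survive. With one environment this is
#' univariate MIM.
#'
#' @param Y individuals x environments adjusted means (complete cases).
#' @param X individuals x P genotype scores at all candidate positions
#'   (expected scores in genetic-map mode, observed scores in physical mode).
#' @param positions data.frame describing the candidate grid: columns
#'   \code{group}, \code{cM} (genetic mode) and/or \code{chrom}, \code{bp}.
#' @param settings list from \code{\link{scanSettings}}.
#' @return A \linkS4class{QTLModel} (all effects active; apply
#'   \code{\link{surPrune}} for environment-specific pruning).
#' @export
modelSearch <- function(Y, X, positions, settings = scanSettings()) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  stopIfNot(nrow(Y) == nrow(X), "Y and X must cover the same individuals")
  stopIfNot(ncol(X) == nrow(positions), "X columns must match positions rows")
  modelIdx <- integer(0)
  round <- 0L
  repeat {
    round <- round + 1L
    elig <- eligiblePositions(positions, modelIdx, settings)
    if (!length(elig)) break
    D <- cbind(1, X[, modelIdx, drop = FALSE])
    sc <- scoreScan(Y, X[, elig, drop = FALSE], D)
    thr <- resampleThreshold(sc, settings$alphaForward, settings$nResamples,
                             seed = subSeed(settings$seed, paste0("fwd", round)))
    best <- which.max(sc$stat)
    if (length(best) && !is.na(sc$stat[best]) && sc$stat[best] > thr)
      modelIdx <- c(modelIdx, elig[best])
    else break
  }
  # backward elimination at the stricter genome-wide level
  repeat {
    dropped <- FALSE
    for (r in seq_along(modelIdx)) {
      keep <- modelIdx[-r]
      elig <- eligiblePositions(positions, keep, settings)
      if (!modelIdx[r] %in% elig) elig <- sort(c(elig, modelIdx[r]))
      D <- cbind(1, X[, keep, drop = FALSE])
      sc <- scoreScan(Y, X[, elig, drop = FALSE], D)
      thr <- resampleThreshold(sc, settings$alphaBackward, settings$nResamples,
                               seed = subSeed(settings$seed,
                                              paste0("bwd", r, "-", length(modelIdx))))
      statR <- sc$stat[match(modelIdx[r], elig)]
      if (is.na(statR) || statR <= thr) {
        modelIdx <- keep
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  newQTLModel(Y, X, positions, modelIdx, settings)
}

# assemble a QTLModel from grid indices (all effects active)
newQTLModel <- function(Y, X, positions, modelIdx, settings,
                        active = NULL) {
  E <- ncol(as.matrix(Y))
  R <- length(modelIdx)
  if (is.null(active)) active <- matrix(TRUE, R, E)
  fit <- fitJointModel(Y, X[, modelIdx, drop = FALSE], active)
  qt <- positions[modelIdx, , drop = FALSE]
  qt <- as.data.frame(qt)
  qt$index <- modelIdx
  rownames(qt) <- NULL
  envN <- colnames(as.matrix(Y))
  if (is.null(envN)) envN <- paste0("T", seq_len(E))
  methods::new("QTLModel", qtls = qt, effects = fit$effects,
               active = active, mu = fit$mu, sigmaE = fit$sigmaE,
               logLik = fit$logLik, envNames = envN, settings = settings)
}

#' Prune nonsignificant environment-specific effects (sur)
#'
#' Iteratively removes the least significant per-environment QTL effect whose
#' Wald p-value exceeds \code{surAlpha}, refitting with unequal regressor
#' sets (seemingly unrelated regressions) after each removal, until every
#' retained effect is significant. Removed effects are flagged inactive
#' ("sur"); a QTL losing all its effects is dropped from the model entirely.
#'
#' @param model a \linkS4class{QTLModel} from \code{\link{modelSearch}}.
#' @param Y,X the inputs the model was built on.
#' @param surAlpha per-effect Wald level (default \code{model@settings$surAlpha}).
#' @return the pruned \linkS4class{QTLModel}.
#' @export
surPrune <- function(model, Y, X, surAlpha = NULL) {
  if (is.null(surAlpha)) surAlpha <- model@settings$surAlpha
  if (is.null(surAlpha)) surAlpha <- 0.05
  modelIdx <- model@qtls$index
  active <- model@active
  repeat {
    if (!length(modelIdx)) break
    fit <- fitJointModel(Y, X[, modelIdx, drop = FALSE], active)
    w <- jointWald(fit)
    w <- w[!is.na(w$p), , drop = FALSE]
    if (!nrow(w) || max(w$p) <= surAlpha) break
    worst <- w[which.max(w$p), ]
    active[worst$qtl, worst$env] <- FALSE
    dead <- rowSums(active) == 0
    if (any(dead)) {
      modelIdx <- modelIdx[!dead]
      active <- active[!dead, , drop = FALSE]
    }
  }
  fit <- fitJointModel(Y, X[, modelIdx, drop = FALSE], active)
  qt <- model@qtls[match(modelIdx, model@qtls$index), , drop = FALSE]
  rownames(qt) <- NULL
  methods::new("QTLModel", qtls = qt, effects = fit$effects, active = active,
               mu = fit$mu, sigmaE = fit$sigmaE, logLik = fit$logLik,
               envNames = model@envNames, settings = model@settings)
}
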