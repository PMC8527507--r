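# Multivariate score statistics for a putative QTL effect, plus
# multiplier-resampling genome-wide thresholds.

#' Scan settings
#'
#' Bundles the tuning constants of the model search: grid step (cM), the
#' exclusion window around QTLs already in the model (10 cM in genetic-map
#' mode; 100 or 200 kb in physical-map mode), genome-wide significance
#' levels for forward selection (0.05) and backward elimination (0.01), the
#' number of multiplier resamples for the threshold (1000), the Wald level of
#' the seemingly-unrelated-regression pruning (0.05), and the seed.
#'
#' @param step grid step in cM.
#' @param window exclusion window; interpreted in \code{windowUnit}.
#' @param windowUnit "cM" or "bp".
#' @param alphaForward,alphaBackward genome-wide significance levels.
#' @param nResamples multiplier resamples for thresholds.
#' @param surAlpha per-effect Wald level of sur pruning.
#' @param seed integer seed.
#' @return list of settings.
#' @export
scanSettings <- function(step = 1, window = 10, windowUnit = c("cM", "bp"),
                         alphaForward = 0.05, alphaBackward = 0.01,
                         nResamples = 1000L, surAlpha = 0.05, seed = 1L) {
  windowUnit <- match.arg(windowUnit)
  stopIfNot(alphaForward > 0 && alphaForward < 1 &&
            alphaBackward > 0 && alphaBackward < 1, "alphas must be in (0,1)")
  stopIfNot(window > 0, "window must be > 0")
  list(step = step, window = window, windowUnit = windowUnit,
       alphaForward = alphaForward, alphaBackward = alphaBackward,
       nResamples = as.integer(nResamples), surAlpha = surAlpha,
       seed = as.integer(seed))
}

# positions eligible for a new QTL: outside `window` of every model position
eligiblePositions <- function(positions, modelIdx, settings) {
  if (!length(modelIdx)) return(seq_len(nrow(positions)))
  keep <- rep(TRUE, nrow(positions))
  for (m in modelIdx) {
    if (settings$windowUnit == "cM") {
      keep <- keep & !(positions$group == positions$group[m] &
                       abs(positions$cM - positions$cM[m]) < settings$window)
    } else {
      keep <- keep & !(positions$chrom == positions$chrom[m] &
                       abs(positions$bp - positions$bp[m]) < settings$window)
    }
  }
  which(keep)
}

#' Multivariate score statistics for putative QTL effects
#'
#' At each candidate position, tests H0: a_e = 0 for all environments, given
#' the current model (design shared across environments). With xt the
#' candidate scores residualized against the current design and e the null
#' residuals, U_e = xt' e_e and the statistic is
#' U' (SigmaHat (x) xt'xt)^-1 U = U' SigmaHat^-1 U / (xt'xt), asymptotically
#' chi-square(E) under H0. Per-individual contributions are retained for the
#' multiplier resampling of \code{\link{resampleThreshold}}.
#'
#' @param Y individuals x environments adjusted means.
#' @param Xcand individuals x P candidate score columns (already restricted
#'   to eligible positions).
#' @param design current model design (default intercept only); one column
#'   per fitted term, shared across environments.
#' @return list with \code{stat} (length P), \code{Xres}, \code{resid},
#'   \code{sigmaInv}, \code{s2} and \code{n}.
#' @export
scoreScan <- function(Y, Xcand, design = NULL) {
  Y <- as.matrix(Y)
  I <- nrow(Y)
  if (is.null(design)) design <- matrix(1, I, 1)
  Xcand <- as.matrix(Xcand)
  stopIfNot(ncol(Xcand) > 0, "no eligible positions")
  DtD <- crossprod(design)
  H <- solve(DtD, crossprod(design, cbind(Xcand, Y)))
  P <- ncol(Xcand)
  Xres <- Xcand - design %*% H[, seq_len(P), drop = FALSE]
  Eres <- Y - design %*% H[, P + seq_len(ncol(Y)), drop = FALSE]
  sigma <- crossprod(Eres) / I
  sigmaInv <- solve(sigma)
  s2 <- colSums(Xres^2)
  s2[s2 < 1e-12] <- NA_real_   # candidate collinear with the design
  U <- crossprod(Xres, Eres)               # P x E
  stat <- rowSums((U %*% sigmaInv) * U) / s2
  list(stat = stat, Xres = Xres, resid = Eres, sigmaInv = sigmaInv,
       s2 = s2, n = I)
}

#' Genome-wide score-statistic threshold by multiplier resampling
#'
#' Per resample, the per-individual score contributions are reweighted by
#' i.i.d. standard normal multipliers, the statistic is recomputed at every
#' eligible position and the genome-wide maximum recorded; the threshold is
#' the empirical (1 - alpha) quantile of the maxima.
#'
#' @param scan result of \code{\link{scoreScan}} over the eligible grid.
#' @param alpha genome-wide significance level.
#' @param nResamples number of resamples (>= 100 recommended; a warning is
#'   issued below that, and alpha * nResamples < 5 is an error).
#' @param seed integer seed.
#' @return the threshold (numeric scalar) with attribute \code{"maxima"}.
#' @export
resampleThreshold <- function(scan, alpha, nResamples = 1000L, seed = 1L) {
  if (nResamples < 100L)
    warning("fewer than 100 resamples: threshold quantile is unstable")
  if (alpha * nResamples < 5)
    stop("alpha * nResamples < 5: too few resamples for this alpha",
         call. = FALSE)
  I <- scan$n
  E <- ncol(scan$resid)
  maxima <- withSeed(seed, {
    W <- matrix(rnorm(I * nResamples), I, nResamples)
    M <- vector("list", E)
    for (e in seq_len(E))
      M[[e]] <- crossprod(scan$Xres, W * scan$resid[, e])  # P x B
    acc <- 0
    for (e in seq_len(E)) for (f in seq_len(E)) {
      w <- scan$sigmaInv[e, f]
      if (w != 0) acc <- acc + w * (M[[e]] * M[[f]])
    }
    acc <- acc / scan$s2
    acc[is.na(acc)] <- 0
    colMax(acc)
  })
  thr <- unname(quantile(maxima, 1 - alpha, names = FALSE))
  attr(thr, "maxima") <- maxima
  thr
}
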