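#' Expected genotype scores for Haley-Knott regression
#'
#' x = P(AA) - P(BB) in [-1, 1] at every grid position; +1 corresponds to the
#' Brandes-like homozygote and -1 to the Wray-like homozygote.
#'
#' @param gp a \linkS4class{GenotypeProbabilities}.
#' @return numeric matrix individuals x positions.
#' @export
expectedScores <- function(gp) {
  x <- gp@probs[, , 1] - gp@probs[, , 2]
  x <- matrix(x, nrow = dim(gp@probs)[1])
  dimnames(x) <- list(gp@individuals, NULL)
  x
}

#' Observed marker scores for physical-map-mode scans
#'
#' Uses the observed (typically imputed) calls directly as +1/-1 scores;
#' missing or heterozygous calls score 0 (uninformative).
#'
#' @param mm a \linkS4class{MarkerMatrix}.
#' @return numeric matrix individuals x markers.
#' @export
markerScores <- function(mm) {
  m <- t(calls(mm))
  m[is.na(m)] <- 0L
  storage.mode(m) <- "double"
  m
}
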