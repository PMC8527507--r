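#' Filter markers by missingness, redundancy and segregation distortion
#'
#' Three ordered stages, each with its count recorded:
#' \enumerate{
#'   \item drop markers with a missing-call fraction above \code{maxMissing};
#'   \item collapse redundancy: markers whose call vectors are identical on
#'     all individuals (including the positions of missing values) keep a
#'     single representative;
#'   \item drop markers failing a 1:1 chi-square goodness-of-fit test on the
#'     non-missing +1/-1 counts at the Bonferroni-corrected level
#'     \code{distortionAlpha / m3}, where m3 is the number of markers
#'     entering this stage.
#' }
#'
#' @param mm a \linkS4class{MarkerMatrix}.
#' @param maxMissing maximum tolerated missing fraction (default 0.25).
#' @param distortionAlpha nominal significance for the distortion test
#'   (default 0.05, Bonferroni corrected within stage 3).
#' @return list with \code{mm} (filtered matrix) and \code{counts}
#'   (data.frame: stage, n_in, n_dropped, n_out).
#' @export
filterMarkers <- function(mm, maxMissing = 0.25, distortionAlpha = 0.05) {
  m <- calls(mm)
  stopIfNot(nrow(m) > 0, "empty marker matrix")
  n0 <- nrow(m)

  missFrac <- rowMeans(is.na(m))
  keep1 <- missFrac <= maxMissing
  m1 <- m[keep1, , drop = FALSE]

  key <- apply(m1, 1L, function(x) paste(ifelse(is.na(x), ".", x), collapse = ""))
  keep2 <- !duplicated(key)
  m2 <- m1[keep2, , drop = FALSE]

  nA <- rowSums(m2 == 1L, na.rm = TRUE)
  nB <- rowSums(m2 == -1L, na.rm = TRUE)
  n <- nA + nB
  chi2 <- ifelse(n > 0, (nA - nB)^2 / n, 0)
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  keep3 <- p >= distortionAlpha / nrow(m2)

  counts <- data.frame(
    stage = c("missing", "redundancy", "distortion"),
    n_in = c(n0, sum(keep1), nrow(m2)),
    n_dropped = c(sum(!keep1), sum(!keep2), sum(!keep3)),
    n_out = c(sum(keep1), nrow(m2), sum(keep3)))

  keepNames <- rownames(m2)[keep3]
  out <- mm[match(keepNames, rownames(m)), ]
  out <- methods::as(out, "MarkerMatrix")
  list(mm = out, counts = counts)
}
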