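#' GGE biplot decomposition of a genotype x environment mean matrix
#'
#' Columns are centered (and by default scaled by their SD) and the matrix is
#' decomposed by SVD. Genotype scores and column loadings use symmetric
#' singular-value partitioning (both sides scaled by sqrt of the singular
#' values). At full rank, with scaling on, the cosine of the angle between
#' two column loading vectors equals the Pearson correlation of the columns.
#'
#' @param means numeric matrix (>= 2 genotypes x >= 2 columns). Rows with
#'   missing cells are dropped (complete-case reduction).
#' @param scale scale columns by their SD (default TRUE).
#' @return A \linkS4class{GGEResult}.
#' @export
ggeBiplot <- function(means, scale = TRUE) {
  means <- as.matrix(means)
  cc <- stats::complete.cases(means)
  means <- means[cc, , drop = FALSE]
  stopIfNot(nrow(means) >= 2 && ncol(means) >= 2,
            "need >= 2 genotypes and >= 2 columns after complete-case reduction")
  ctr <- sweep(means, 2, colMeans(means))
  if (scale) {
    sds <- apply(means, 2, sd)
    if (any(sds == 0))
      stop("constant column(s) with scaling on: ",
           paste(colnames(means)[sds == 0], collapse = ", "), call. = FALSE)
    ctr <- sweep(ctr, 2, sds, "/")
  }
  sv <- svd(ctr)
  d <- sv$d
  sq <- sqrt(d)
  scores <- sv$u %*% diag(sq, length(d))
  loadings <- sv$v %*% diag(sq, length(d))
  rownames(scores) <- rownames(means)
  rownames(loadings) <- colnames(means)
  pct <- 100 * d^2 / sum(d^2)
  methods::new("GGEResult", d = d, scores = scores, loadings = loadings,
               pctVar = pct, correlation = cor(means), scaled = scale)
}
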