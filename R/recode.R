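#' Recode raw HapMap calls against the parental lines
#'
#' Per marker, each parent's consensus is the unanimous non-missing call
#' among its replicate columns. Markers are dropped as noninformative when
#' either parental consensus is missing or the replicates disagree, when the
#' parents share the same allele (monomorphic), when a parental consensus is
#' heterozygous, or when population calls include a homozygous allele absent
#' in both parents (inconsistent). Surviving markers are recoded +1 for the
#' first-parent (Brandes) allele and -1 for the second-parent (Wray) allele;
#' heterozygous population calls are set to missing.
#'
#' @param raw list as returned by \code{\link{readHapMap}}.
#' @param parentA,parentB column ids of the replicate columns of each parent
#'   (parent A = Brandes-like, coded +1).
#' @return list with \code{mm} (a \linkS4class{MarkerMatrix} of the
#'   population columns) and \code{rejections} (data.frame marker/reason).
#' @export
recodeFromParents <- function(raw, parentA, parentB) {
  m <- raw$calls
  taxa <- colnames(m)
  stopIfNot(length(parentA) >= 1 && length(parentB) >= 1,
            "at least one replicate column per parent is required")
  unknown <- setdiff(c(parentA, parentB), taxa)
  if (length(unknown))
    stop("unknown parent column id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  popCols <- setdiff(taxa, c(parentA, parentB))
  consensus <- function(x) {
    u <- unique(x[!is.na(x)])
    if (length(u) == 1L) u else NA_character_
  }
  nM <- nrow(m)
  reason <- rep(NA_character_, nM)
  calls <- matrix(NA_integer_, nM, length(popCols),
                  dimnames = list(rownames(m), popCols))
  for (i in seq_len(nM)) {
    cA <- consensus(m[i, parentA])
    cB <- consensus(m[i, parentB])
    if (is.na(cA) || is.na(cB)) { reason[i] <- "noninformative-parent"; next }
    if (cA %in% IUPAC_HET || cB %in% IUPAC_HET) {
      reason[i] <- "heterozygous-parent"; next
    }
    if (cA == cB) { reason[i] <- "monomorphic-in-parents"; next }
    pop <- m[i, popCols]
    hom <- !is.na(pop) & !(pop %in% IUPAC_HET)
    if (any(hom & !(pop %in% c(cA, cB)))) {
      reason[i] <- "inconsistent-with-parents"; next
    }
    v <- rep(NA_integer_, length(pop))
    v[!is.na(pop) & pop == cA] <- 1L
    v[!is.na(pop) & pop == cB] <- -1L
    calls[i, ] <- v
  }
  keep <- which(is.na(reason))
  # drop markers with zero informative population calls as well
  allMissing <- keep[rowSums(!is.na(calls[keep, , drop = FALSE])) == 0]
  reason[allMissing] <- "no-informative-calls"
  keep <- which(is.na(reason))
  mm <- MarkerMatrix(calls[keep, , drop = FALSE],
                     chrom = raw$meta$chrom[keep], pos = raw$meta$pos[keep],
                     markerNames = raw$meta$rs[keep],
                     individualIds = popCols)
  rejections <- data.frame(marker = rownames(m)[!is.na(reason)],
                           reason = reason[!is.na(reason)],
                           stringsAsFactors = FALSE)
  list(mm = mm, rejections = rejections)
}
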