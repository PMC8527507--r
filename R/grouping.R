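#' Group markers by two-point linkage
#'
#' Markers are joined transitively (union-find) whenever their two-point
#' estimates satisfy rf < \code{maxRf} AND LOD > \code{minLod}. Within each
#' group the majority chromosome (from the markers' physical annotation) is
#' identified and minority-chromosome markers are removed as false positives;
#' a 50/50 tie discards the group entirely. Singleton groups are reported
#' unplaced.
#'
#' @param tp all-pairs result from \code{\link{pairwiseTwoPoint}}.
#' @param mm the \linkS4class{MarkerMatrix} the pairs were computed on
#'   (supplies chromosome annotation).
#' @param maxRf,minLod linkage thresholds (defaults 0.35 and 8).
#' @return list with \code{groups} (named list of marker-name vectors, ordered
#'   by bp within group), \code{removed} (data.frame marker/reason) and
#'   \code{unplaced} (character).
#' @export
groupMarkers <- function(tp, mm, maxRf = 0.35, minLod = 8) {
  rd <- SummarizedExperiment::rowData(mm)
  mnames <- rownames(tp$r)
  chrom <- setNames(as.character(rd$chrom), rownames(rd))[mnames]
  bp <- setNames(rd$pos, rownames(rd))[mnames]
  nM <- length(mnames)

  parent <- seq_len(nM)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  linked <- which(tp$r < maxRf & tp$lod > minLod & upper.tri(tp$r), arr.ind = TRUE)
  for (e in seq_len(nrow(linked))) {
    a <- find(linked[e, 1]); b <- find(linked[e, 2])
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_len(nM), find, 1L)

  groups <- list(); removed <- list(); unplaced <- character(0)
  for (cid in unique(comp)) {
    members <- mnames[comp == cid]
    if (length(members) == 1L) { unplaced <- c(unplaced, members); next }
    tab <- sort(table(chrom[members]), decreasing = TRUE)
    if (length(tab) > 1L && tab[1] == tab[2]) {
      removed[[length(removed) + 1L]] <- data.frame(
        marker = members, reason = "ambiguous-group-chromosome",
        stringsAsFactors = FALSE)
      next
    }
    major <- names(tab)[1]
    minority <- members[chrom[members] != major]
    if (length(minority))
      removed[[length(removed) + 1L]] <- data.frame(
        marker = minority, reason = "minority-chromosome",
        stringsAsFactors = FALSE)
    keep <- members[chrom[members] == major]
    keep <- keep[order(bp[keep])]
    groups[[major]] <- c(groups[[major]], list(keep))
  }
  # merge multiple components assigned to the same chromosome, bp-ordered
  groups <- lapply(groups, function(gl) {
    v <- unique(unlist(gl))
    v[order(bp[v])]
  })
  if (length(groups)) groups <- groups[order(names(groups))]
  removed <- if (length(removed)) do.call(rbind, removed)
             else data.frame(marker = character(0), reason = character(0))
  list(groups = groups, removed = removed, unplaced = unplaced)
}
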