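# HapMap-format readers/writers. The 11 standard header columns are
# rs#, alleles, chrom, pos, strand, assembly#, center, protLSID, assayLSID,
# panelLSID, QCcode, followed by one column per taxon with diploid
# single-letter IUPAC codes ('N' = missing). Coordinates are 1-based bp.

HAPMAP_COLS <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
                 "center", "protLSID", "assayLSID", "panelLSID", "QCcode")
IUPAC_OK <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "N")
IUPAC_HET <- c("R", "Y", "S", "W", "K", "M")
IUPAC_PAIR <- c(AG = "R", GA = "R", CT = "Y", TC = "Y", CG = "S", GC = "S",
                AT = "W", TA = "W", GT = "K", TG = "K", AC = "M", CA = "M")

#' Read a HapMap genotype file
#'
#' @param path path to a tab-separated HapMap file.
#' @return list with \code{meta} (data.frame: rs, alleles, chrom, pos, strand)
#'   and \code{calls} (character matrix markers x taxa, \code{NA} = missing).
#'   Heterozygote codes are preserved for \code{\link{recodeFromParents}} to
#'   mask. Row order is preserved.
#' @export
readHapMap <- function(path) {
  stopIfNot(file.exists(path), paste0("file not found: ", path))
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 12 || !identical(hdr[1:11], HAPMAP_COLS))
    stop("not a HapMap file: header must start with the 11 standard columns",
         call. = FALSE)
  tb <- read.delim(path, check.names = FALSE, colClasses = "character")
  taxa <- hdr[-(1:11)]
  m <- as.matrix(tb[, taxa, drop = FALSE])
  bad <- which(matrix(!(m %in% IUPAC_OK), nrow(m)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-IUPAC call '%s' at line %d (marker %s, taxon %s)",
                 m[bad[1, 1], bad[1, 2]], bad[1, 1] + 1L,
                 tb[["rs#"]][bad[1, 1]], taxa[bad[1, 2]]), call. = FALSE)
  pos <- as.integer(tb$pos)
  for (ch in unique(tb$chrom)) {
    p <- pos[tb$chrom == ch]
    if (any(diff(p) < 0)) {
      ln <- which(tb$chrom == ch)[which(diff(p) < 0)[1] + 1L] + 1L
      stop(sprintf("bp positions not monotone within chromosome %s at line %d",
                   ch, ln), call. = FALSE)
    }
  }
  m[m == "N"] <- NA_character_
  rownames(m) <- tb[["rs#"]]
  list(meta = data.frame(rs = tb[["rs#"]], alleles = tb$alleles,
                         chrom = tb$chrom, pos = pos, strand = tb$strand,
                         stringsAsFactors = FALSE),
       calls = m)
}

#' Write a MarkerMatrix to a HapMap file
#'
#' Marker alleles are assigned deterministically (cycling among transversion/
#' transition pairs), the first allele being the Brandes-like (+1) parental
#' allele. Three replicate columns per parent are appended so the file round
#' trips through \code{\link{recodeFromParents}}.
#'
#' @param mm a \linkS4class{MarkerMatrix}.
#' @param path output path.
#' @param parentReps replicate columns written per parent.
#' @return \code{path}, invisibly.
#' @export
writeHapMap <- function(mm, path, parentReps = 3L) {
  m <- calls(mm)
  rd <- SummarizedExperiment::rowData(mm)
  pairs <- c("A/C", "A/G", "C/T", "G/T")
  alleles <- pairs[(seq_len(nrow(m)) - 1L) %% length(pairs) + 1L]
  a1 <- substr(alleles, 1, 1)
  a2 <- substr(alleles, 3, 3)
  code <- function(x, i) {
    out <- rep("N", length(x))
    out[!is.na(x) & x == 1L] <- a1[i]
    out[!is.na(x) & x == -1L] <- a2[i]
    out[!is.na(x) & x == 0L] <- IUPAC_PAIR[paste0(a1[i], a2[i])]
    out
  }
  calls_chr <- matrix("N", nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) calls_chr[i, ] <- code(m[i, ], i)
  pA <- matrix(rep(a1, parentReps), nrow(m))
  pB <- matrix(rep(a2, parentReps), nrow(m))
  colnames(pA) <- paste0("BRANDES_", seq_len(parentReps))
  colnames(pB) <- paste0("WRAY_", seq_len(parentReps))
  tb <- data.frame(`rs#` = rownames(m), alleles = alleles,
                   chrom = rd$chrom, pos = rd$pos, strand = "+",
                   `assembly#` = "NA", center = "NA", protLSID = "NA",
                   assayLSID = "NA", panelLSID = "NA", QCcode = "NA",
                   check.names = FALSE, stringsAsFactors = FALSE)
  tb <- cbind(tb, pA, pB, calls_chr)
  write.table(tb, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
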