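# Phenotype CSV readers/writers. Plot-level schema: trial, rep, block,
# genotype, [role,] stand, <trait...>; means-level schema: genotype, trial,
# <trait...>.

#' Read a phenotype CSV
#'
#' Auto-detects the plot-level schema (columns trial, rep, block, genotype,
#' stand, traits) versus the adjusted-means schema (genotype, trial, traits).
#'
#' @param path CSV path.
#' @param genotypes optional character vector of genotype ids to cross-check
#'   against; mismatches are reported as an attribute \code{"unmatched"}.
#' @return For plot-level input, a data.frame of class "TrialData"; for
#'   means-level input, a list of genotype x trial matrices, one per trait.
#' @export
readPhenotypes <- function(path, genotypes = NULL) {
  stopIfNot(file.exists(path), paste0("file not found: ", path))
  tb <- read.csv(path, stringsAsFactors = FALSE)
  plotLevel <- all(c("trial", "rep", "block", "genotype", "stand") %in% names(tb))
  if (plotLevel) {
    key <- paste(tb$trial, tb$rep, tb$block, tb$genotype)
    if (anyDuplicated(key))
      stop("duplicated plot key: ", key[which(duplicated(key))[1]], call. = FALSE)
    traits <- setdiff(names(tb), c("trial", "rep", "block", "genotype",
                                   "role", "stand"))
    for (tr in traits) {
      bad <- which(!is.na(tb[[tr]]) & is.na(suppressWarnings(as.numeric(tb[[tr]]))))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' for trait %s at row %d",
                     tb[[tr]][bad[1]], tr, bad[1]), call. = FALSE)
      tb[[tr]] <- as.numeric(tb[[tr]])
    }
    if (!"role" %in% names(tb)) tb$role <- "line"
    out <- tb
    class(out) <- c("TrialData", "data.frame")
  } else {
    stopIfNot(all(c("genotype", "trial") %in% names(tb)),
              "phenotype file must follow the plot-level or means-level schema")
    traits <- setdiff(names(tb), c("genotype", "trial"))
    out <- lapply(traits, function(tr) {
      w <- tapply(as.numeric(tb[[tr]]), list(tb$genotype, tb$trial), mean)
      w
    })
    names(out) <- traits
  }
  if (!is.null(genotypes)) {
    ids <- if (is.data.frame(out)) unique(out$genotype) else rownames(out[[1]])
    attr(out, "unmatched") <- setdiff(ids, genotypes)
  }
  out
}

#' Write plot-level trial data to CSV
#'
#' @param trial data.frame with columns trial, rep, block, genotype, role,
#'   stand and one or more trait columns.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePhenotypes <- function(trial, path) {
  write.csv(trial, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
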