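# Table-2-style reporting of fitted QTL models, plus a parser and summaries
# for published tables of the same layout.

#' Report table for one fitted model
#'
#' @param model a pruned \linkS4class{QTLModel}.
#' @param Y,X scan inputs.
#' @param positions candidate-grid data.frame.
#' @param trait trait label.
#' @param analysis analysis label ("T1", "T2", "T3" or "MT").
#' @param supportIntervals compute LOD-1.5 support intervals (genetic mode).
#' @return data.frame, one row per QTL in genome order, named
#'   TRAIT-ANALYSIS.k, with LOD, per-environment effect/PVE columns ("sur"
#'   where pruned) and the support interval.
#' @export
qtlReport <- function(model, Y, X, positions, trait, analysis = "MT",
                      supportIntervals = TRUE) {
  R <- nrow(model@qtls)
  E <- length(model@mu)
  if (R == 0)
    return(data.frame(trait = character(0), qtl = character(0)))
  ord <- order(model@qtls$group, model@qtls$cM)
  pve <- computePve(model, Y, X)
  rows <- lapply(seq_along(ord), function(k) {
    r <- ord[k]
    lod <- lodOfQtl(model, Y, X, r)
    si <- c(NA_real_, NA_real_)
    if (supportIntervals) {
      s <- lodSupport(model, Y, X, positions, r)
      si <- s$interval
    }
    row <- data.frame(trait = trait, qtl = paste0(trait, "-", analysis, ".", k),
                      group = model@qtls$group[r], cM = model@qtls$cM[r],
                      bp = if ("bp" %in% colnames(model@qtls))
                             model@qtls$bp[r] else NA,
                      lod = lod, ci_lo = si[1], ci_hi = si[2],
                      stringsAsFactors = FALSE)
    for (e in seq_len(E)) {
      en <- model@envNames[e]
      row[[paste0("eff_", en)]] <- if (model@active[r, e])
        as.character(signif(model@effects[r, e], 4)) else "sur"
      row[[paste0("pve_", en)]] <- if (model@active[r, e])
        as.character(signif(pve[r, e], 4)) else "sur"
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stack per-trait reports and tally QTL consistency across trials
#'
#' @param reports list of data.frames from \code{\link{qtlReport}}.
#' @return data.frame with attribute \code{"summary"}: a list with
#'   \code{nQtl}, per-trait counts, \code{nAllTrials} (QTLs with numeric
#'   effects in every environment) and \code{nWithSur}.
#' @export
buildReport <- function(reports) {
  out <- do.call(rbind, reports)
  rownames(out) <- NULL
  effCols <- grep("^eff_", colnames(out), value = TRUE)
  isSur <- as.matrix(out[, effCols, drop = FALSE]) == "sur"
  attr(out, "summary") <- list(
    nQtl = nrow(out),
    perTrait = table(out$trait),
    nAllTrials = sum(rowSums(isSur) == 0),
    nWithSur = sum(rowSums(isSur) > 0))
  out
}

#' Read a published MT-MIM QTL table
#'
#' Parses a TSV with columns trait, qtl, chrom, pos_cM, marker_bp, lod and
#' per-trial effect/PVE pairs where pruned effects hold the literal token
#' "sur" (the layout used for multitrait QTL summaries of the Brandes x Wray
#' sweet sorghum trials).
#'
#' @param path TSV path.
#' @return data.frame; effect/PVE columns numeric with NA where "sur", plus
#'   logical \code{sur_<trial>} columns.
#' @export
readQtlTable <- function(path) {
  tb <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  vcols <- grep("^(eff|pve)_", names(tb), value = TRUE)
  trials <- unique(sub("^(eff|pve)_", "", vcols))
  for (tr in trials)
    tb[[paste0("sur_", tr)]] <- tb[[paste0("eff_", tr)]] == "sur"
  for (v in vcols)
    tb[[v]] <- suppressWarnings(as.numeric(tb[[v]]))
  tb
}

#' Summaries of a parsed QTL table
#'
#' @param tbl data.frame from \code{\link{readQtlTable}}.
#' @return list with \code{nQtl}, \code{nAllTrials} (numeric effects in every
#'   trial), \code{nWithSur}, and \code{pveSums}: summed PVE per
#'   (trait, chromosome) and trial.
#' @export
summarizeQtlTable <- function(tbl) {
  surCols <- grep("^sur_", names(tbl), value = TRUE)
  surMat <- as.matrix(tbl[, surCols, drop = FALSE])
  pveCols <- grep("^pve_", names(tbl), value = TRUE)
  agg <- stats::aggregate(tbl[, pveCols, drop = FALSE],
                          by = list(trait = tbl$trait, chrom = tbl$chrom),
                          FUN = function(x) sum(x, na.rm = TRUE))
  list(nQtl = nrow(tbl),
       nAllTrials = sum(rowSums(surMat) == 0),
       nWithSur = sum(rowSums(surMat) > 0),
       pveSums = agg)
}
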