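#' Multipoint genetic-map estimation with an error-tolerant HMM
#'
#' Per linkage group (ordered by physical position, as the chromosome-wise
#' ordering choice), per-interval recombination fractions are re-estimated by
#' EM over a two-state HMM whose transition probability across an interval
#' with gametic rf r is the selfed-RIL recombinant probability
#' R = 2r/(1+2r) and whose emissions tolerate a fixed genotyping error rate
#' (missing calls emit 1). Cumulative cM positions come from the estimated r
#' via the chosen map function. EM iterates until the log-likelihood changes
#' by less than 1e-6 or 1000 iterations.
#'
#' @param mm a \linkS4class{MarkerMatrix}.
#' @param groups named list of marker-name vectors as from
#'   \code{\link{groupMarkers}} (or any ordered grouping).
#' @param errorRate HMM emission error probability (default 0.01).
#' @param mapFunction \code{"kosambi"} (default) or \code{"haldane"}.
#' @param tol,maxit EM convergence controls.
#' @return A \linkS4class{GeneticMap}.
#' @export
estimateMap <- function(mm, groups, errorRate = 0.01,
                        mapFunction = c("kosambi", "haldane"),
                        tol = 1e-6, maxit = 1000L) {
  mapFunction <- match.arg(mapFunction)
  m <- calls(mm)
  rd <- SummarizedExperiment::rowData(mm)
  rows <- list(); rfs <- list()
  for (g in names(groups)) {
    mk <- groups[[g]]
    if (length(mk) < 2L) {
      warning("group ", g, " has fewer than 2 markers; skipped")
      next
    }
    bp <- rd[mk, "pos"]
    mk <- mk[order(bp)]
    obs <- m[mk, , drop = FALSE]
    M <- length(mk)
    # init from adjacent-pair observed fractions
    R <- vapply(seq_len(M - 1), function(i) {
      xi <- obs[i, ]; xj <- obs[i + 1, ]
      ok <- !is.na(xi) & !is.na(xj) & xi != 0L & xj != 0L
      if (!sum(ok)) return(0.1)
      min(sum(xi[ok] != xj[ok]) / sum(ok), 0.49)
    }, 0)
    ll0 <- -Inf
    for (it in seq_len(maxit)) {
      fb <- hmmForwardBackward(obs, R, errorRate, wantXi = TRUE)
      if (abs(fb$loglik - ll0) < tol) break
      ll0 <- fb$loglik
      R <- pmin(colMeans(fb$xi), 0.49999)
    }
    r <- rilRinv(R)
    cm <- c(0, cumsum(mapDistance(r, mapFunction)))
    rows[[g]] <- data.frame(marker = mk, group = g, cM = cm,
                            chrom = rd[mk, "chrom"], bp = rd[mk, "pos"],
                            stringsAsFactors = FALSE)
    rfs[[g]] <- r
  }
  stopIfNot(length(rows) > 0, "no group with >= 2 markers")
  tb <- do.call(rbind, rows)
  rownames(tb) <- NULL
  methods::new("GeneticMap", table = S4Vectors::DataFrame(tb), rf = rfs,
               mapFunction = mapFunction)
}

#' Conditional genotype probabilities on a cM grid
#'
#' Forward-backward smoothing over the same HMM used by
#' \code{\link{estimateMap}}, on a grid augmenting the mapped markers with
#' pseudomarkers every \code{step} cM (the grid always includes position 0
#' and the terminal marker position). The prior at the chain start is
#' (1/2, 1/2); pseudomarkers emit 1.
#'
#' @param mm a \linkS4class{MarkerMatrix} containing the mapped markers.
#' @param gmap a \linkS4class{GeneticMap}.
#' @param step pseudomarker spacing in cM (> 0, default 1).
#' @param errorRate HMM emission error probability (default 0.01).
#' @return A \linkS4class{GenotypeProbabilities}.
#' @export
calcGenoProb <- function(mm, gmap, step = 1, errorRate = 0.01) {
  stopIfNot(step > 0, "step must be > 0")
  m <- calls(mm)
  tb <- as.data.frame(gmap@table)
  stopIfNot(all(tb$marker %in% rownames(m)),
            "all mapped markers must be present in the marker matrix")
  n <- ncol(m)
  posList <- list(); probList <- list()
  for (g in unique(tb$group)) {
    sub <- tb[tb$group == g, ]
    maxCM <- max(sub$cM)
    grid <- sort(unique(c(sub$cM, seq(0, maxCM, by = step))))
    isMarker <- !is.na(match(round(grid, 9), round(sub$cM, 9)))
    mIdx <- match(round(grid, 9), round(sub$cM, 9))
    obs <- matrix(NA_integer_, length(grid), n)
    obs[isMarker, ] <- m[sub$marker[mIdx[isMarker]], , drop = FALSE]
    d <- diff(grid)
    R <- rilR(mapInverse(d, gmap@mapFunction))
    fb <- hmmForwardBackward(obs, R, errorRate)
    # nearest left marker bp for pseudomarkers
    leftMk <- findInterval(grid + 1e-9, sub$cM)
    leftMk[leftMk < 1] <- 1
    posList[[g]] <- data.frame(
      group = g, cM = grid, pseudo = !isMarker,
      bp = sub$bp[leftMk],
      marker = ifelse(isMarker, sub$marker[mIdx], sub$marker[leftMk]),
      stringsAsFactors = FALSE)
    probList[[g]] <- fb$post
  }
  pos <- do.call(rbind, posList)
  rownames(pos) <- NULL
  P <- nrow(pos)
  probs <- array(0, c(n, P, 2))
  off <- 0
  for (g in seq_along(probList)) {
    k <- dim(probList[[g]])[2]
    probs[, off + seq_len(k), ] <- probList[[g]]
    off <- off + k
  }
  methods::new("GenotypeProbabilities", positions = S4Vectors::DataFrame(pos),
               probs = probs, individuals = colnames(m))
}
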