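#' Two-point linkage between a pair of markers
#'
#' With n complete (both non-missing) pairs of which k are recombinant
#' (different parental alleles), the observed RIL recombinant fraction is
#' Rhat = k/n. The ML gametic recombination fraction for selfed RILs inverts
#' the Haldane-Waddington relation, rhat = Rhat / (2 (1 - Rhat)), clamped to
#' [0, 0.5]. The LOD is the base-10 binomial likelihood ratio against
#' R = 0.5: k log10(Rhat) + (n-k) log10(1-Rhat) - n log10(0.5), with
#' 0 log10(0) = 0.
#'
#' @param mm a \linkS4class{MarkerMatrix}.
#' @param markerI,markerJ marker names or row indices.
#' @return list(r_hat, lod, n_informative, R_hat).
#' @export
twoPoint <- function(mm, markerI, markerJ) {
  m <- calls(mm)
  xi <- m[markerI, ]
  xj <- m[markerJ, ]
  ok <- !is.na(xi) & !is.na(xj) & xi != 0L & xj != 0L
  n <- sum(ok)
  if (n == 0)
    stop("no informative pairs for markers ", markerI, " / ", markerJ,
         call. = FALSE)
  k <- sum(xi[ok] != xj[ok])
  Rhat <- k / n
  lod0 <- function(c, p) if (c == 0) 0 else c * log10(p)
  lod <- lod0(k, Rhat) + lod0(n - k, 1 - Rhat) - n * log10(0.5)
  if (Rhat >= 0.5) lod <- 0   # repulsion clamps to the null
  list(r_hat = rilRinv(Rhat), lod = max(lod, 0), n_informative = n, R_hat = Rhat)
}

#' All-pairs two-point linkage
#'
#' Matrix-algebra computation of the complete-pair counts, recombinant
#' fractions and LODs for every marker pair.
#'
#' @param mm a \linkS4class{MarkerMatrix}.
#' @return list of symmetric matrices \code{r} (gametic rf), \code{lod},
#'   \code{n} (informative pairs) and \code{R} (observed RIL fraction);
#'   pairs with no informative individuals have \code{NA} rf/lod.
#' @export
pairwiseTwoPoint <- function(mm) {
  m <- calls(mm)
  M <- m
  M[is.na(M)] <- 0L
  M[M == 0L] <- 0L
  Mi <- matrix(as.numeric(M != 0L), nrow(m))
  Md <- matrix(as.numeric(M), nrow(m))
  n <- tcrossprod(Mi)                 # complete pairs
  S <- tcrossprod(Md)                 # matches - mismatches
  k <- (n - S) / 2
  R <- ifelse(n > 0, k / n, NA_real_)
  safeLog <- function(c, p) ifelse(c > 0, c * log10(pmax(p, 1e-300)), 0)
  lod <- safeLog(k, R) + safeLog(n - k, 1 - R) - n * log10(0.5)
  lod[n == 0] <- NA_real_
  lod[!is.na(R) & R >= 0.5] <- 0
  lod <- pmax(lod, 0)
  r <- rilRinv(R)
  dimnames(r) <- dimnames(lod) <- dimnames(n) <- dimnames(R) <-
    list(rownames(m), rownames(m))
  list(r = r, lod = lod, n = n, R = R)
}
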