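#' Map functions: recombination fraction to cM and back
#'
#' \code{mapDistance} converts a gametic recombination fraction to a genetic
#' distance in cM; \code{mapInverse} is its inverse. Kosambi:
#' d = 25 ln((1+2r)/(1-2r)); Haldane: d = -50 ln(1-2r).
#'
#' @param r gametic recombination fraction(s) in [0, 0.5).
#' @param d genetic distance(s) in cM.
#' @param mapFunction \code{"kosambi"} or \code{"haldane"}.
#' @return numeric vector of distances (cM) or recombination fractions.
#' @examples
#' mapDistance(0.1, "kosambi")  # 10.14 cM
#' mapDistance(0.1, "haldane")  # 11.16 cM
#' mapInverse(mapDistance(0.2, "kosambi"), "kosambi")  # 0.2
#' @export
mapDistance <- function(r, mapFunction = c("kosambi", "haldane")) {
  mapFunction <- match.arg(mapFunction)
  stopIfNot(all(r >= 0 & r < 0.5), "r must be in [0, 0.5)")
  switch(mapFunction,
         kosambi = 25 * log((1 + 2 * r) / (1 - 2 * r)),
         haldane = -50 * log(1 - 2 * r))
}

#' @rdname mapDistance
#' @export
mapInverse <- function(d, mapFunction = c("kosambi", "haldane")) {
  mapFunction <- match.arg(mapFunction)
  stopIfNot(all(d >= 0), "d must be >= 0")
  switch(mapFunction,
         kosambi = tanh(d / 50) / 2,
         haldane = (1 - exp(-d / 50)) / 2)
}

#' Haldane-Waddington correction for selfed RILs
#'
#' For recombinant inbred lines derived by repeated selfing, the probability
#' \code{R} that two loci carry different parental alleles in the final
#' inbred genome relates to the gametic recombination fraction \code{r} by
#' R = 2r/(1+2r). \code{rilR} maps r to R; \code{rilRinv} inverts it
#' (clamped to [0, 0.5]).
#'
#' @param r gametic recombination fraction(s).
#' @param R observed RIL recombinant-pair fraction(s).
#' @return numeric vector.
#' @export
rilR <- function(r) 2 * r / (1 + 2 * r)

#' @rdname rilR
#' @export
rilRinv <- function(R) pmin(pmax(R / (2 * (1 - pmin(R, 1 - 1e-12))), 0), 0.5)
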