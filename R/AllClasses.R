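#' @import methods
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData "assay<-"
#' @importFrom stats pchisq pnorm qchisq quantile rnorm runif rpois rbinom
#'   setNames var cor sd nlminb optim model.matrix qnorm median ave aggregate
#' @importFrom utils read.delim write.table read.csv write.csv head tail
NULL

#' Marker genotype matrix for a biparental RIL population
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding
#' parental-recoded marker calls for a recombinant inbred line (RIL)
#' population. Rows are markers, columns individuals. The single assay,
#' \code{"calls"}, is an integer matrix coded \code{+1} for the first-parent
#' (Brandes-like, "A") homozygote, \code{-1} for the second-parent
#' (Wray-like, "B") homozygote, \code{0} for a residual heterozygote (only
#' present in truth matrices produced by the simulator before masking), and
#' \code{NA} for missing. \code{rowData} carries at least \code{chrom} and
#' \code{pos} (1-based bp); simulated matrices also carry \code{pos_cM}.
#'
#' @export
setClass("MarkerMatrix", contains = "SummarizedExperiment")

setValidity("MarkerMatrix", function(object) {
  msg <- NULL
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'calls' is required")
  else {
    m <- SummarizedExperiment::assay(object, "calls")
    bad <- !(m %in% c(-1L, 0L, 1L) | is.na(m))
    if (any(bad)) msg <- c(msg, "calls must be -1, 0, 1 or NA")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("chrom", "pos") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'chrom' and 'pos'")
  else if (nrow(rd) > 0 && any(rd$pos < 1, na.rm = TRUE))
    msg <- c(msg, "bp positions must be positive (1-based)")
  if (is.null(msg)) TRUE else msg
})

#' Construct a MarkerMatrix
#'
#' @param calls integer matrix, markers x individuals, coded
#'   \code{+1}/\code{-1}/\code{0}/\code{NA} (see \linkS4class{MarkerMatrix}).
#' @param chrom character vector of chromosome names per marker.
#' @param pos integer vector of 1-based bp positions per marker.
#' @param pos_cM optional numeric vector of cM positions (simulated data).
#' @param markerNames,individualIds optional dimnames; taken from
#'   \code{dimnames(calls)} when absent.
#' @return A \linkS4class{MarkerMatrix}.
#' @export
MarkerMatrix <- function(calls, chrom, pos, pos_cM = NULL,
                         markerNames = rownames(calls),
                         individualIds = colnames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(markerNames))
    markerNames <- paste0("M", seq_len(nrow(calls)))
  if (is.null(individualIds))
    individualIds <- paste0("RIL", seq_len(ncol(calls)))
  dimnames(calls) <- list(markerNames, individualIds)
  rd <- S4Vectors::DataFrame(chrom = as.character(chrom),
                             pos = as.integer(pos),
                             row.names = markerNames)
  if (!is.null(pos_cM)) rd$pos_cM <- as.numeric(pos_cM)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = calls), rowData = rd)
  methods::new("MarkerMatrix", se)
}

#' @describeIn MarkerMatrix accessor for the calls assay
#'   (markers x individuals).
#' @param x a MarkerMatrix.
#' @export
calls <- function(x) SummarizedExperiment::assay(x, "calls")

#' Simulated truth map
#'
#' Marker positions of a synthetic genome: per-chromosome lengths in cM and
#' marker positions on both the genetic (cM) and a linear physical (bp)
#' scale. The bp scale is a fixed synthetic convention
#' (\code{bpPerCM}, default 250000, i.e. 250 kb/cM).
#'
#' @slot markers DataFrame with columns \code{name}, \code{chrom},
#'   \code{pos_cM}, \code{pos_bp}.
#' @slot chromLen named numeric, chromosome lengths in cM.
#' @slot mapFunction \code{"kosambi"} or \code{"haldane"}.
#' @slot bpPerCM numeric scalar, synthetic bp-per-cM scale.
#' @export
setClass("SimMap", representation(markers = "DataFrame",
                                  chromLen = "numeric",
                                  mapFunction = "character",
                                  bpPerCM = "numeric"))

setValidity("SimMap", function(object) {
  msg <- NULL
  mk <- object@markers
  if (!all(c("name", "chrom", "pos_cM", "pos_bp") %in% colnames(mk)))
    msg <- c(msg, "markers needs name/chrom/pos_cM/pos_bp")
  else for (ch in unique(mk$chrom)) {
    p <- mk$pos_cM[mk$chrom == ch]
    b <- mk$pos_bp[mk$chrom == ch]
    if (any(diff(p) <= 0)) msg <- c(msg, paste0(ch, ": cM not strictly increasing"))
    if (any(diff(b) <= 0)) msg <- c(msg, paste0(ch, ": bp not strictly increasing"))
    if (any(p < 0) || any(p > object@chromLen[ch] + 1e-9))
      msg <- c(msg, paste0(ch, ": positions outside [0, length]"))
  }
  if (!object@mapFunction %in% c("kosambi", "haldane"))
    msg <- c(msg, "mapFunction must be 'kosambi' or 'haldane'")
  if (is.null(msg)) TRUE else msg
})

#' Generating parameters of a synthetic multi-environment QTL study
#'
#' @slot simMap the \linkS4class{SimMap} the QTLs live on.
#' @slot qtlChrom,qtlPos chromosome and cM position per QTL.
#' @slot qtlEffects R x E matrix of per-environment additive effects (trait
#'   units for the +1/-1 genotype score).
#' @slot qtlActive R x E logical; inactive effects are simulated as zero.
#' @slot mu per-environment intercepts.
#' @slot sigmaE E x E residual (individual-level) covariance across
#'   environments; must be symmetric positive definite.
#' @slot design list with \code{reps}, \code{blocks}, \code{sigma_b2},
#'   \code{sigma2}, \code{standCoef}, \code{standMean} describing the lattice
#'   trial layout.
#' @slot generations selfing generations (F2 start counts as 2).
#' @slot seed integer master seed; operation-specific sub-streams are derived
#'   from it.
#' @export
setClass("SimTruth", representation(simMap = "SimMap",
                                    qtlChrom = "character",
                                    qtlPos = "numeric",
                                    qtlEffects = "matrix",
                                    qtlActive = "matrix",
                                    mu = "numeric",
                                    sigmaE = "matrix",
                                    design = "list",
                                    generations = "integer",
                                    seed = "integer"))

setValidity("SimTruth", function(object) {
  msg <- NULL
  E <- length(object@mu)
  if (!isSymmetric(unname(object@sigmaE), tol = 1e-8))
    msg <- c(msg, "sigmaE must be symmetric")
  else if (any(eigen(object@sigmaE, symmetric = TRUE,
                     only.values = TRUE)$values <= 0))
    msg <- c(msg, "sigmaE must be positive definite")
  if (nrow(object@sigmaE) != E) msg <- c(msg, "sigmaE dimension != length(mu)")
  R <- length(object@qtlPos)
  if (length(object@qtlChrom) != R || nrow(object@qtlEffects) != R ||
      nrow(object@qtlActive) != R)
    msg <- c(msg, "QTL slots must agree in length")
  if (R > 0 && (ncol(object@qtlEffects) != E || ncol(object@qtlActive) != E))
    msg <- c(msg, "effects/active must have one column per environment")
  if (object@generations < 2L) msg <- c(msg, "generations must be >= 2")
  d <- object@design
  if (d$reps < 1 || d$blocks < 1) msg <- c(msg, "reps and blocks must be >= 1")
  mk <- object@simMap@markers
  if (R > 0) for (r in seq_len(R)) {
    ok <- object@qtlChrom[r] %in% mk$chrom &&
      object@qtlPos[r] >= 0 &&
      object@qtlPos[r] <= object@simMap@chromLen[object@qtlChrom[r]] + 1e-9
    if (!ok) msg <- c(msg, paste0("QTL ", r, " off-map"))
  }
  if (is.null(msg)) TRUE else msg
})

#' Estimated genetic map
#'
#' Ordered linkage groups with multipoint cM positions. \code{table} has one
#' row per marker: \code{marker}, \code{group}, \code{cM} (0-based cumulative
#' within group), \code{chrom}, \code{bp}. \code{rf} stores the estimated
#' per-interval gametic recombination fractions per group.
#'
#' @export
setClass("GeneticMap", representation(table = "DataFrame",
                                      rf = "list",
                                      mapFunction = "character"))

setValidity("GeneticMap", function(object) {
  msg <- NULL
  tb <- object@table
  for (g in unique(tb$group)) {
    cm <- tb$cM[tb$group == g]
    if (length(cm) && (cm[1] != 0 || any(diff(cm) < -1e-9)))
      msg <- c(msg, paste0("group ", g, ": cM must start at 0, nondecreasing"))
    bp <- tb$bp[tb$group == g]
    if (any(diff(bp) < 0)) msg <- c(msg, paste0("group ", g, ": bp order broken"))
  }
  if (is.null(msg)) TRUE else msg
})

#' Conditional genotype probabilities on a pseudomarker grid
#'
#' @slot positions DataFrame with \code{group}, \code{cM}, \code{pseudo}
#'   (logical), \code{bp} (nearest left marker for pseudomarkers) and
#'   \code{marker} name.
#' @slot probs numeric array individuals x positions x 2 with
#'   \code{P(AA)} in slice 1 and \code{P(BB)} in slice 2; each pair sums
#'   to 1.
#' @slot individuals character ids.
#' @export
setClass("GenotypeProbabilities", representation(positions = "DataFrame",
                                                 probs = "array",
                                                 individuals = "character"))

setValidity("GenotypeProbabilities", function(object) {
  p <- object@probs
  if (length(dim(p)) != 3 || dim(p)[3] != 2)
    return("probs must be individuals x positions x 2")
  if (any(p < -1e-12) || any(p > 1 + 1e-12)) return("probabilities outside [0,1]")
  s <- p[, , 1] + p[, , 2]
  if (any(abs(s - 1) > 1e-9)) return("probability pairs must sum to 1 (1e-9)")
  TRUE
})

#' REML mixed-model fit
#'
#' Result container for single- and multi-trial lattice analyses: variance
#' components, adjusted genotype means (BLUEs or BLUPs), the average pairwise
#' prediction-error variance of BLUP differences (\code{vbarBlup}, feeding the
#' Cullis generalized heritability), the restricted log-likelihood and
#' AIC/BIC. \code{details} keeps the fitted fixed effects, the structure
#' label, the residual-contrast sample size used by BIC, and the genotype
#' PEV block when genotypes are random.
#'
#' @export
setClass("MixedFit", representation(varcomp = "numeric",
                                    fixef = "numeric",
                                    means = "data.frame",
                                    vbarBlup = "numeric",
                                    logREML = "numeric",
                                    nVarParams = "integer",
                                    aic = "numeric",
                                    bic = "numeric",
                                    details = "list"))

setValidity("MixedFit", function(object) {
  msg <- NULL
  if (any(object@varcomp < -1e-8)) msg <- c(msg, "variance components must be >= 0")
  q <- object@nVarParams
  if (abs(object@aic - (-2 * object@logREML + 2 * q)) > 1e-6)
    msg <- c(msg, "AIC inconsistent with logREML and nVarParams")
  if (is.null(msg)) TRUE else msg
})

#' Fitted MT-MIM model state
#'
#' Positions and per-environment additive effects of the QTLs currently in
#' the model, the per-environment intercepts, the ML residual covariance
#' across environments, and the maximized log-likelihood. \code{active} marks
#' which environment-specific effects are in the design; effects pruned by
#' the seemingly-unrelated-regression step are inactive ("sur") and exactly
#' zero.
#'
#' @export
setClass("QTLModel", representation(qtls = "data.frame",
                                    effects = "matrix",
                                    active = "matrix",
                                    mu = "numeric",
                                    sigmaE = "matrix",
                                    logLik = "numeric",
                                    envNames = "character",
                                    settings = "list"))

setValidity("QTLModel", function(object) {
  msg <- NULL
  R <- nrow(object@qtls)
  if (R > 0) {
    if (nrow(object@effects) != R || nrow(object@active) != R)
      msg <- c(msg, "effects/active rows must match number of QTLs")
    if (any(object@effects[!object@active] != 0))
      msg <- c(msg, "inactive effects must be exactly zero")
  }
  if (nrow(object@sigmaE) != length(object@mu))
    msg <- c(msg, "sigmaE dimension must match mu")
  if (is.null(msg)) TRUE else msg
})

#' GGE biplot decomposition
#'
#' @slot d singular values of the centered (optionally SD-scaled) matrix.
#' @slot scores genotype scores under symmetric singular-value partitioning.
#' @slot loadings column (environment/trait) loadings.
#' @slot pctVar percent variance per component (sums to 100).
#' @slot correlation Pearson correlation matrix of the input columns.
#' @slot scaled logical, whether columns were SD-scaled.
#' @export
setClass("GGEResult", representation(d = "numeric", scores = "matrix",
                                     loadings = "matrix", pctVar = "numeric",
                                     correlation = "matrix",
                                     scaled = "logical"))

setMethod("show", "MarkerMatrix", function(object) {
  m <- calls(object)
  cat("MarkerMatrix:", nrow(m), "markers x", ncol(m), "individuals\n")
  cat("  chromosomes:",
      paste(unique(SummarizedExperiment::rowData(object)$chrom), collapse = " "), "\n")
  cat(sprintf("  missing: %.1f%%\n", 100 * mean(is.na(m))))
})

setMethod("show", "SimMap", function(object) {
  cat("SimMap:", length(object@chromLen), "chromosomes,",
      nrow(object@markers), "markers,",
      sprintf("%.1f cM total (%s)\n", sum(object@chromLen), object@mapFunction))
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", length(object@qtlPos), "QTLs,",
      length(object@mu), "environments, generations =", object@generations,
      ", seed =", object@seed, "\n")
})

setMethod("show", "GeneticMap", function(object) {
  tb <- object@table
  lens <- vapply(split(tb$cM, tb$group), max, 0)
  cat("GeneticMap:", nrow(tb), "markers in", length(lens), "groups,",
      sprintf("%.2f cM (%s)\n", sum(lens), object@mapFunction))
})

setMethod("show", "GenotypeProbabilities", function(object) {
  cat("GenotypeProbabilities:", dim(object@probs)[1], "individuals x",
      dim(object@probs)[2], "positions (",
      sum(object@positions$pseudo), "pseudomarkers )\n")
})

setMethod("show", "MixedFit", function(object) {
  cat("MixedFit (", object@details$label, ")\n", sep = "")
  cat("  logREML:", format(object@logREML), " AIC:", format(object@aic),
      " BIC:", format(object@bic), "\n")
  cat("  varcomp:", paste(names(object@varcomp),
                          signif(object@varcomp, 4), sep = "=", collapse = ", "), "\n")
})

setMethod("show", "QTLModel", function(object) {
  cat("QTLModel:", nrow(object@qtls), "QTLs,",
      length(object@mu), "environments, logLik =",
      format(object@logLik), "\n")
  if (nrow(object@qtls)) {
    df <- object@qtls
    df$active <- apply(object@active, 1, function(a)
      paste(ifelse(a, "+", "sur"), collapse = "/"))
    print(df)
  }
})

#' @describeIn MixedFit Akaike information criterion of the REML fit.
#' @param object a MixedFit.
#' @param ... ignored.
#' @param k ignored (kept for generic compatibility).
#' @export
setMethod("AIC", "MixedFit", function(object, ..., k = 2) object@aic)

#' @describeIn MixedFit Bayesian information criterion (residual-contrast
#'   sample size).
#' @export
setMethod("BIC", "MixedFit", function(object, ...) object@bic)

#' @describeIn MixedFit restricted log-likelihood.
#' @export
logREML <- function(object) object@logREML

#' @describeIn MixedFit named variance components.
#' @export
varComp <- function(object) object@varcomp

#' @describeIn MixedFit adjusted genotype means (BLUEs or BLUPs).
#' @export
adjustedMeans <- function(object) object@means
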