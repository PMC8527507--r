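#' REML analysis of multi-environment trials with a structured G_L
#'
#' Fits the multitrial lattice model with trial, replicate-in-trial, checks,
#' check-by-trial and the (within-trial centered) stand covariate fixed;
#' incomplete blocks random, nested in replicate-in-trial, with a separate
#' block variance per trial; RIL genotype effects random with covariance
#' G_L (x) I under the requested structure; and heterogeneous per-trial
#' residual variances. The G_L structures and their parameter counts for L
#' trials are ID (1), DIAG (L), CS (2), CSH (L+1) and US (L(L+1)/2).
#'
#' @param data plot-level data.frame spanning >= 2 trials (columns trial,
#'   rep, block, genotype, role, stand and the trait).
#' @param trait trait column name.
#' @param structure one of "ID", "DIAG", "CS", "CSH", "US".
#' @return A \linkS4class{MixedFit}; \code{details$GL} holds the fitted
#'   genetic variance-covariance matrix across trials.
#' @export
fitMultiTrial <- function(data, trait = "y",
                          structure = c("ID", "DIAG", "CS", "CSH", "US")) {
  structure <- match.arg(structure)
  trials <- sort(unique(data$trial))
  L <- length(trials)
  stopIfNot(L >= 2, "at least 2 trials required")
  y <- data[[trait]]
  keep <- !is.na(y)
  data <- data[keep, , drop = FALSE]; y <- y[keep]
  if (!"role" %in% names(data)) data$role <- "line"
  isLine <- data$role == "line"
  lines <- sort(unique(data$genotype[isLine]))
  ng <- length(lines)
  if (structure == "US" && ng < L + 2)
    stop("insufficient data: US structure with ", L, " trials needs at least ",
         L + 2, " genotypes", call. = FALSE)
  fTrial <- factor(data$trial, levels = trials)
  # stand centered within trial
  sc <- data$stand - ave(data$stand, data$trial)

  X <- model.matrix(~ fTrial)
  # replicate within trial: indicator for rep >= 2 in each trial
  for (l in trials) for (k in sort(unique(data$rep[data$trial == l]))[-1])
    X <- cbind(X, as.numeric(data$trial == l & data$rep == k))
  colnames(X)[(L + 1):ncol(X)] <- paste0("rep", seq_len(ncol(X) - L))
  if (any(abs(sc) > 1e-12)) X <- cbind(X, stand = sc)
  checks <- sort(unique(data$genotype[!isLine]))
  if (length(checks)) {
    for (cgen in checks) {
      X <- cbind(X, as.numeric(data$genotype == cgen))
      colnames(X)[ncol(X)] <- paste0("check_", cgen)
      for (l in trials[-1]) {
        X <- cbind(X, as.numeric(data$genotype == cgen & data$trial == l))
        colnames(X)[ncol(X)] <- paste0("check_", cgen, ":", l)
      }
    }
  }

  fBlock <- factor(paste(data$trial, data$rep, data$block, sep = ":"))
  Zb <- indMat(fBlock)
  blockTrial <- vapply(strsplit(colnames(Zb), ":", fixed = TRUE), `[`, "", 1L)
  qb <- ncol(Zb)
  # genotype-by-trial design, environment-major columns
  Zg <- matrix(0, length(y), ng * L)
  gi <- match(data$genotype, lines)
  li <- as.integer(fTrial)
  ok <- isLine
  Zg[cbind(which(ok), (li[ok] - 1L) * ng + gi[ok])] <- 1
  colnames(Zg) <- paste(rep(lines, L), rep(trials, each = ng), sep = "@")
  Z <- cbind(Zb, Zg)

  nStruct <- glNParams(structure, L)
  rGroup <- as.integer(fTrial)
  # genotype-block triplet skeleton (pairs l <= l')
  pairIdx <- which(upper.tri(diag(L), diag = TRUE), arr.ind = TRUE)
  gi0 <- qb + as.vector(outer(seq_len(ng), (pairIdx[, 1] - 1L) * ng, `+`))
  gj0 <- qb + as.vector(outer(seq_len(ng), (pairIdx[, 2] - 1L) * ng, `+`))
  buildG <- function(theta) {
    sb <- exp(theta[seq_len(L)])
    thG <- theta[L + seq_len(nStruct)]
    se <- exp(theta[L + nStruct + seq_len(L)])
    GL <- glMatrix(structure, thG, L)
    Gi <- tryCatch(solve(GL), error = function(e) NULL)
    if (is.null(Gi) || any(!is.finite(Gi)))
      return(list(GinvTriplets = list(i = 1L, j = 1L, x = Inf),
                  logdetG = Inf, Rvars = se))
    xg <- rep(Gi[pairIdx], each = ng)
    list(GinvTriplets = list(
           i = c(seq_len(qb), gi0), j = c(seq_len(qb), gj0),
           x = c(1 / sb[match(blockTrial, trials)], xg)),
         logdetG = sum(log(sb[match(blockTrial, trials)])) +
           ng * determinant(GL, logarithm = TRUE)$modulus[1],
         Rvars = se)
  }
  v0 <- var(y) / 3
  theta0 <- c(rep(log(v0), L), glInit(structure, L, v0), rep(log(v0), L))
  fit <- remlCore(y, X, Z, rGroup, buildG, theta0)
  sb <- exp(fit$theta[seq_len(L)])
  GL <- glMatrix(structure, fit$theta[L + seq_len(nStruct)], L)
  se <- exp(fit$theta[L + nStruct + seq_len(L)])
  dimnames(GL) <- list(trials, trials)
  ghat <- fit$u[qb + seq_len(ng * L)]
  Xb <- as.vector(X %*% fit$beta)
  muStar <- vapply(seq_len(L), function(l)
    mean(Xb[isLine & li == l]), 0)
  meansDf <- data.frame(genotype = rep(lines, L),
                        trial = rep(trials, each = ng),
                        mean = rep(muStar, each = ng) + unname(ghat),
                        stringsAsFactors = FALSE)
  q <- as.integer(2L * L + nStruct)
  ll <- fit$logREML
  vc <- c(setNames(sb, paste0("sigma_b2_", trials)),
          setNames(diag(GL), paste0("sigma_g2_", trials)),
          setNames(se, paste0("sigma2_", trials)))
  methods::new("MixedFit", varcomp = vc, fixef = fit$beta, means = meansDf,
               vbarBlup = NA_real_, logREML = ll, nVarParams = q,
               aic = -2 * ll + 2 * q,
               bic = -2 * ll + q * log(fit$N - fit$p),
               details = list(label = paste0("multitrial ", structure),
                              GL = GL, structure = structure,
                              nContrasts = fit$N - fit$p))
}

#' Rank G_L structures by information criteria
#'
#' @param fits list of \linkS4class{MixedFit} objects from
#'   \code{\link{fitMultiTrial}} on the same data and trait.
#' @return list with \code{table} (structure, logREML, params, AIC, BIC,
#'   sorted by BIC with ties broken toward fewer parameters),
#'   \code{selected} (argmin BIC), \code{selectedAIC} and \code{disagree}.
#' @export
selectStructure <- function(fits) {
  stopIfNot(length(fits) >= 2, "at least 2 fits required")
  tb <- data.frame(
    structure = vapply(fits, function(f) f@details$structure, ""),
    logREML = vapply(fits, logREML, 0),
    params = vapply(fits, function(f) f@nVarParams, 1L),
    AIC = vapply(fits, AIC, 0),
    BIC = vapply(fits, BIC, 0))
  tb <- tb[order(tb$BIC, tb$params), ]
  rownames(tb) <- NULL
  selAIC <- tb$structure[order(tb$AIC, tb$params)][1]
  list(table = tb, selected = tb$structure[1], selectedAIC = selAIC,
       disagree = !identical(tb$structure[1], selAIC))
}
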