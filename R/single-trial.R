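#' REML analysis of a single lattice trial
#'
#' Fits y = mu + rep_k + b_j(k) + t_i + s_i(jk) + e with replicates and the
#' (within-trial centered) stand covariate fixed and incomplete blocks nested
#' in replicates random. With \code{genotypeRole = "fixed"} all genotype
#' effects are fixed and adjusted means are BLUEs. With
#' \code{genotypeRole = "random"} (default) the genotype term is split into
#' random RIL effects g_i ~ N(0, sigma_g2) and fixed check effects, adjusted
#' means are BLUPs, and the fit carries sigma_g2 plus the average pairwise
#' prediction-error variance of BLUP differences (vbarBlup) from the exact
#' inverse of the mixed-model-equation coefficient matrix.
#'
#' @param data plot-level data.frame (columns trial, rep, block, genotype,
#'   role, stand and the trait).
#' @param trait trait column name (default "y").
#' @param genotypeRole "random" (RILs random, checks fixed) or "fixed".
#' @param trial which trial to analyse when \code{data} holds several.
#' @return A \linkS4class{MixedFit}.
#' @export
fitSingleTrial <- function(data, trait = "y",
                           genotypeRole = c("random", "fixed"),
                           trial = NULL) {
  genotypeRole <- match.arg(genotypeRole)
  if (!is.null(trial)) data <- data[data$trial == trial, , drop = FALSE]
  stopIfNot(length(unique(data$trial)) == 1,
            "data spans several trials; pass `trial=` or use fitMultiTrial")
  stopIfNot(length(unique(data$rep)) >= 2, "at least 2 replicates required")
  y <- data[[trait]]
  keep <- !is.na(y)
  data <- data[keep, , drop = FALSE]; y <- y[keep]
  if (!"role" %in% names(data)) data$role <- "line"
  sc <- data$stand - mean(data$stand)
  fRep <- factor(data$rep)
  fBlock <- factor(paste(data$rep, data$block, sep = ":"))
  fGeno <- factor(data$genotype)
  isLine <- data$role == "line"
  lines <- sort(unique(data$genotype[isLine]))
  checks <- sort(unique(data$genotype[!isLine]))

  if (genotypeRole == "fixed") {
    X <- model.matrix(~ fRep + fGeno)
    if (any(abs(sc) > 1e-12)) X <- cbind(X, stand = sc)
    Zb <- indMat(fBlock)
    buildG <- function(theta) {
      sb <- exp(theta[1]); se <- exp(theta[2])
      list(GinvTriplets = list(i = seq_len(ncol(Zb)), j = seq_len(ncol(Zb)),
                               x = rep(1 / sb, ncol(Zb))),
           logdetG = ncol(Zb) * log(sb),
           Rvars = se)
    }
    v0 <- var(y) / 2
    fit <- remlCore(y, X, Zb, rep(1L, length(y)), buildG,
                    theta0 = log(c(v0, v0)))
    sb <- exp(fit$theta[1]); se <- exp(fit$theta[2])
    # BLUE adjusted means: genotype effects at average replicate, stand at 0
    base <- colnames(X)
    gcols <- grep("^fGeno", base)
    xrow <- colMeans(X)
    xrow[gcols] <- 0
    if ("stand" %in% base) xrow["stand"] <- 0
    lev <- levels(fGeno)
    means <- vapply(lev, function(g) {
      xr <- xrow
      cn <- paste0("fGeno", g)
      if (cn %in% base) xr[cn] <- 1
      sum(xr * fit$beta)
    }, 0)
    meansDf <- data.frame(genotype = lev, mean = unname(means),
                          stringsAsFactors = FALSE)
    vc <- c(sigma_b2 = sb, sigma2 = se)
    q <- 2L
    details <- list(label = "single-trial BLUE", fixef = fit$beta,
                    nContrasts = fit$N - fit$p, trial = data$trial[1])
    vbar <- NA_real_
  } else {
    X <- model.matrix(~ fRep)
    if (any(abs(sc) > 1e-12)) X <- cbind(X, stand = sc)
    if (length(checks)) {
      fCheck <- factor(ifelse(isLine, ".line", data$genotype))
      Xc <- model.matrix(~ fCheck)[, -1, drop = FALSE]
      X <- cbind(X, Xc)
    }
    Zb <- indMat(fBlock)
    gfac <- factor(ifelse(isLine, data$genotype, NA), levels = lines)
    Zg <- matrix(0, length(y), length(lines),
                 dimnames = list(NULL, lines))
    ok <- !is.na(gfac)
    Zg[cbind(which(ok), as.integer(gfac[ok]))] <- 1
    Z <- cbind(Zb, Zg)
    qb <- ncol(Zb); qg <- ncol(Zg)
    buildG <- function(theta) {
      sb <- exp(theta[1]); sg <- exp(theta[2]); se <- exp(theta[3])
      list(GinvTriplets = list(i = seq_len(qb + qg), j = seq_len(qb + qg),
                               x = c(rep(1 / sb, qb), rep(1 / sg, qg))),
           logdetG = qb * log(sb) + qg * log(sg),
           Rvars = se)
    }
    v0 <- var(y) / 3
    fit <- remlCore(y, X, Z, rep(1L, length(y)), buildG,
                    theta0 = log(c(v0, v0, v0)))
    sb <- exp(fit$theta[1]); sg <- exp(fit$theta[2]); se <- exp(fit$theta[3])
    gidx <- fit$p + qb + seq_len(qg)
    Cg <- fit$Cinv[gidx, gidx]
    mg <- qg
    sdiag <- sum(diag(Cg)); stot <- sum(Cg)
    vbar <- 2 * (mg * sdiag - stot) / (mg * (mg - 1))
    ghat <- fit$u[qb + seq_len(qg)]
    lineRows <- which(isLine)
    muStar <- mean((X %*% fit$beta)[lineRows])
    meansDf <- data.frame(genotype = lines, mean = muStar + unname(ghat),
                          stringsAsFactors = FALSE)
    vc <- c(sigma_b2 = sb, sigma_g2 = sg, sigma2 = se)
    q <- 3L
    details <- list(label = "single-trial BLUP", fixef = fit$beta,
                    nContrasts = fit$N - fit$p, trial = data$trial[1],
                    pevG = Cg)
  }
  ll <- fit$logREML
  methods::new("MixedFit", varcomp = vc, fixef = fit$beta, means = meansDf,
               vbarBlup = vbar, logREML = ll, nVarParams = q,
               aic = -2 * ll + 2 * q,
               bic = -2 * ll + q * log(fit$N - fit$p),
               details = details)
}

#' Heritability and coefficient of variation of a trial fit
#'
#' CV = sqrt(sigma2) / ybar x 100 and the Cullis generalized heritability
#' h2 = 1 - vbarBlup / (2 sigma_g2), where vbarBlup is the average over all
#' RIL pairs of the prediction-error variance of a BLUP difference. h2 is
#' clamped to [0, 1] with a warning when outside; sigma_g2 = 0 returns
#' h2 = 0 with a flag.
#'
#' @param fit a \linkS4class{MixedFit} from \code{\link{fitSingleTrial}} with
#'   genotypes random.
#' @param traitMean phenotypic mean for the CV; defaults to the mean of the
#'   adjusted means.
#' @return list(h2, CV, flag).
#' @export
summarizeFit <- function(fit, traitMean = NULL) {
  vc <- varComp(fit)
  if (is.null(traitMean)) traitMean <- mean(fit@means$mean)
  stopIfNot(traitMean > 0, "traitMean must be > 0 for the CV")
  cv <- sqrt(vc[["sigma2"]]) / traitMean * 100
  flag <- NULL
  if (!"sigma_g2" %in% names(vc) || is.na(fit@vbarBlup)) {
    stop("h2 requires a fit with genotypes random", call. = FALSE)
  }
  sg <- vc[["sigma_g2"]]
  if (sg <= 1e-12) {
    h2 <- 0; flag <- "sigma_g2-zero"
  } else {
    h2 <- 1 - fit@vbarBlup / (2 * sg)
    if (h2 < 0 || h2 > 1) {
      warning("h2 outside [0,1]; clamped")
      flag <- "clamped"
      h2 <- min(max(h2, 0), 1)
    }
  }
  list(h2 = h2, CV = cv, flag = flag)
}
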