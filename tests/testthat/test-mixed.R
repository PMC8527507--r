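test_that("MME-based REML matches a direct V-matrix maximization oracle", {
  # tiny instance: 6 genotypes x 2 reps x 2 blocks
  set.seed(14)
  tr <- simLattice(ng = 6, J = 2, K = 2, sg = 2, sb = 0.5, se = 1, seed = 14)
  fit <- fitSingleTrial(tr, "y", "random")
  # independent oracle: optimize the V-based restricted likelihood directly
  y <- tr$y
  X <- model.matrix(~ factor(tr$rep))
  Zb <- mtmim:::indMat(factor(paste(tr$rep, tr$block)))
  Zg <- mtmim:::indMat(factor(tr$genotype))
  obj <- function(th) -vRemlLoglik(y, X, Zb, Zg, exp(th[1]), exp(th[2]),
                                   exp(th[3]))
  opt <- optim(log(c(0.5, 1, 1)), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  expect_equal(logREML(fit), -opt$value, tolerance = 1e-6)
  vc <- varComp(fit)
  expect_equal(unname(vc[c("sigma_b2", "sigma_g2", "sigma2")]),
               unname(exp(opt$par)), tolerance = 1e-4)
})

test_that("noise-free data give BLUEs equal to genotype means and zero
           variance components", {
  ng <- 8
  g <- seq_len(ng)
  tr <- do.call(rbind, lapply(1:2, function(k)
    data.frame(trial = "T1", rep = k, block = rep(1:2, each = ng / 2),
               genotype = sprintf("G%d", g), role = "line", stand = 10,
               y = 10 + g)))
  fit <- fitSingleTrial(tr, "y", "fixed")
  vc <- varComp(fit)
  expect_lt(vc[["sigma2"]], 1e-4)
  expect_lt(vc[["sigma_b2"]], 1e-4)
  mns <- adjustedMeans(fit)
  expect_equal(mns$mean[match(sprintf("G%d", g), mns$genotype)], 10 + g,
               tolerance = 1e-4)
})

test_that("REML estimates are invariant to adding a constant", {
  tr <- simLattice(ng = 20, J = 4, K = 2, seed = 3)
  f1 <- fitSingleTrial(tr, "y", "random")
  tr2 <- tr; tr2$y <- tr2$y + 100
  f2 <- fitSingleTrial(tr2, "y", "random")
  expect_equal(varComp(f1), varComp(f2), tolerance = 1e-4)
  expect_equal(adjustedMeans(f2)$mean - adjustedMeans(f1)$mean,
               rep(100, 20), tolerance = 1e-6)
})

test_that("Cullis h2 and CV follow their formulas and the PEV oracle", {
  # formula arithmetic via a hand-built fit object
  fit <- methods::new("MixedFit",
                      varcomp = c(sigma_b2 = 0, sigma_g2 = 1, sigma2 = 4),
                      fixef = c(int = 0),
                      means = data.frame(genotype = "g", mean = 100),
                      vbarBlup = 0, logREML = 0, nVarParams = 3L,
                      aic = 2 * 3, bic = 0, details = list(label = "x"))
  s <- summarizeFit(fit, traitMean = 100)
  expect_equal(s$CV, 2)            # sqrt(4)/100 * 100
  expect_equal(s$h2, 1)            # vbar = 0 limit
  fit@varcomp[["sigma_g2"]] <- 0
  s0 <- summarizeFit(fit, traitMean = 100)
  expect_equal(s0$h2, 0)
  expect_equal(s0$flag, "sigma_g2-zero")

  # PEV oracle on a small balanced design: vbar from the joint covariance
  # formula PEV = G - G Z' P Z G, independent of the MME inverse route
  tr <- simLattice(ng = 10, J = 2, K = 3, sg = 1, sb = 0.3, se = 1, seed = 8)
  f <- fitSingleTrial(tr, "y", "random")
  vc <- varComp(f)
  X <- model.matrix(~ factor(tr$rep))
  Zb <- mtmim:::indMat(factor(paste(tr$rep, tr$block)))
  Zg <- mtmim:::indMat(factor(tr$genotype))
  N <- nrow(tr)
  V <- vc[["sigma2"]] * diag(N) + vc[["sigma_b2"]] * tcrossprod(Zb) +
    vc[["sigma_g2"]] * tcrossprod(Zg)
  Vi <- solve(V)
  P <- Vi - Vi %*% X %*% solve(crossprod(X, Vi %*% X), crossprod(X, Vi))
  G <- vc[["sigma_g2"]] * diag(10)
  PEV <- G - G %*% crossprod(Zg, P %*% Zg) %*% G
  m <- 10
  vbar <- 2 * (m * sum(diag(PEV)) - sum(PEV)) / (m * (m - 1))
  expect_equal(f@vbarBlup, vbar, tolerance = 1e-6)
  s2 <- summarizeFit(f)
  expect_equal(s2$h2, 1 - vbar / (2 * vc[["sigma_g2"]]), tolerance = 1e-6)
  expect_true(s2$h2 >= 0 && s2$h2 <= 1)
})

test_that("balanced RCB simulations recover sigma_g2 on average", {
  # K=3 complete blocks (J=1): REML should match the ANOVA estimator closely
  ests <- vapply(1:25, function(s) {
    tr <- simLattice(ng = 60, J = 1, K = 3, sg = 4, sb = 0, se = 1, seed = 100 + s)
    varComp(fitSingleTrial(tr, "y", "random"))[["sigma_g2"]]
  }, 0)
  expect_lt(abs(mean(ests) - 4) / 4, 0.05)
})

test_that("multitrial structures nest correctly and selection penalizes
           parameters", {
  st <- simulateStudy(nInd = 60, nChrom = 2, chromLen = 80,
                      markersPerChrom = 8, engine = "markov", seed = 17)
  tr <- st$trial
  fits <- lapply(c("ID", "DIAG", "CS", "CSH", "US"), function(s)
    fitMultiTrial(tr, "y", s))
  ll <- vapply(fits, logREML, 0)
  names(ll) <- c("ID", "DIAG", "CS", "CSH", "US")
  # nested structures never beat their generalizations
  expect_gte(ll[["US"]] + 1e-4, ll[["CSH"]])
  expect_gte(ll[["CSH"]] + 1e-4, ll[["CS"]])
  expect_gte(ll[["CSH"]] + 1e-4, ll[["DIAG"]])
  expect_gte(ll[["CS"]] + 1e-4, ll[["ID"]])
  expect_gte(ll[["DIAG"]] + 1e-4, ll[["ID"]])
  sel <- selectStructure(fits)
  expect_true(sel$selected %in% c("ID", "DIAG", "CS", "CSH", "US"))
  expect_equal(sel$table$AIC, -2 * sel$table$logREML + 2 * sel$table$params)
  # equal logREML -> fewer parameters win both criteria
  f2 <- fits[[3]]; f5 <- fits[[5]]
  fEq <- f5
  fEq@logREML <- f2@logREML
  fEq@aic <- -2 * f2@logREML + 2 * f5@nVarParams
  fEq@bic <- -2 * f2@logREML + f5@nVarParams * log(f5@details$nContrasts)
  sel2 <- selectStructure(list(f2, fEq))
  expect_equal(sel2$selected, "CS")
  expect_false(sel2$disagree)
  expect_error(selectStructure(fits[1]), "at least 2")
})

test_that("US structure demands enough genotypes", {
  tr <- simLattice(ng = 4, J = 1, K = 2, seed = 5)
  tr2 <- tr; tr2$trial <- "T2"; tr3 <- tr; tr3$trial <- "T3"
  expect_error(fitMultiTrial(rbind(tr, tr2, tr3), "y", "US"),
               "insufficient data")
})

test_that("heterogeneous genetic variances are detected over ID", {
  # strong DIAG truth: per-trial genetic variances 1, 4, 16
  set.seed(77)
  ng <- 80
  ids <- sprintf("G%03d", seq_len(ng))
  rows <- list()
  for (l in 1:3) {
    g <- rnorm(ng, 0, sqrt(c(1, 4, 16)[l]))
    for (k in 1:2) {
      perm <- sample.int(ng)
      blk <- sort(rep(1:8, length.out = ng))[order(perm)]
      rows[[length(rows) + 1L]] <- data.frame(
        trial = paste0("T", l), rep = k, block = blk, genotype = ids,
        role = "line", stand = 10L,
        y = 50 + g + rnorm(ng))
    }
  }
  tr <- do.call(rbind, rows)
  fits <- lapply(c("ID", "DIAG"), function(s) fitMultiTrial(tr, "y", s))
  sel <- selectStructure(fits)
  expect_equal(sel$selected, "DIAG")
})
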