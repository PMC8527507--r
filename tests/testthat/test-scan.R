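test_that("expected scores follow the probability coding", {
  probs <- array(0, c(1, 3, 2))
  probs[1, , 1] <- c(1, 0.5, 0.9)
  probs[1, , 2] <- c(0, 0.5, 0.1)
  gp <- methods::new("GenotypeProbabilities",
                     positions = S4Vectors::DataFrame(
                       group = "g", cM = c(0, 1, 2), pseudo = FALSE,
                       bp = 1L, marker = "m"),
                     probs = probs, individuals = "i1")
  expect_equal(unname(expectedScores(gp)[1, ]), c(1, 0, 0.8))
})

test_that("score statistics are chi-square(E) calibrated under the null", {
  set.seed(10)
  pos <- mkGridPositions(2, 99, 1)
  stats <- unlist(lapply(1:10, function(s) {
    X <- simGridScores(223, pos, 100 + s)
    Y <- matrix(rnorm(223), 223, 1)
    scoreScan(Y, X)$stat
  }))
  # mean of chi2(1) = 1; SE of the mean over correlated positions is inflated,
  # use independent-ish chromosome count for a conservative bound
  expect_lt(abs(mean(stats) - 1), 0.15)
  # E = 3 case
  stats3 <- unlist(lapply(1:10, function(s) {
    X <- simGridScores(223, pos, 200 + s)
    Y <- matrix(rnorm(223 * 3), 223, 3)
    scoreScan(Y, X)$stat
  }))
  expect_lt(abs(mean(stats3) - 3), 0.3)
})

test_that("positions inside the window of a model QTL are ineligible", {
  pos <- mkGridPositions(2, 50, 1)
  ss <- scanSettings(window = 10)
  q <- which(pos$group == "chr1" & pos$cM == 25)
  el <- mtmim:::eligiblePositions(pos, q, ss)
  near <- which(pos$group == "chr1" & abs(pos$cM - 25) < 10)
  expect_length(intersect(el, near), 0)
  far <- which(pos$group == "chr1" & abs(pos$cM - 25) >= 10)
  expect_true(all(far %in% el))
  expect_true(all(which(pos$group == "chr2") %in% el))
})

test_that("a large-effect QTL is localized at the true position", {
  pos <- mkGridPositions(1, 100, 1)
  hits <- 0
  for (s in 1:20) {
    X <- simGridScores(223, pos, 300 + s)
    q <- which(pos$cM == 50)
    set.seed(400 + s)
    Y <- matrix(X[, q] + rnorm(223), 223, 1)
    sc <- scoreScan(Y, X)
    if (abs(pos$cM[which.max(sc$stat)] - 50) <= 2) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("thresholds are monotone in alpha and approach the pointwise
           chi-square quantile for a single position", {
  set.seed(11)
  X <- matrix(sample(c(-1, 1), 223, TRUE), 223, 1)
  Y <- matrix(rnorm(223 * 3), 223)
  sc <- scoreScan(Y, X)
  thr5 <- resampleThreshold(sc, 0.05, 4000L, seed = 1)
  thr1 <- resampleThreshold(sc, 0.01, 4000L, seed = 1)
  expect_gte(thr1, thr5)
  expect_lt(abs(thr5 - qchisq(0.95, 3)), 0.8)
  expect_error(resampleThreshold(sc, 0.001, 1000L), "too few")
  expect_warning(resampleThreshold(sc, 0.2, 50L), "unstable")
})

test_that("forward selection matches exhaustive single-addition enumeration
           on tiny instances", {
  for (s in 1:30) {
    set.seed(500 + s)
    n <- 30
    X <- matrix(sample(c(-1, 1), n * 3, TRUE), n, 3)
    E <- 1 + (s %% 2)
    Y <- matrix(rnorm(n * E) + 0.4 * X[, 1 + (s %% 3)], n, E)
    sc <- scoreScan(Y, X)
    ll <- vapply(1:3, function(j)
      fitJointModel(Y, X[, j, drop = FALSE])$logLik, 0)
    expect_equal(which.max(sc$stat), which.max(ll))
  }
})

test_that("model search finds planted QTLs and prunes honestly", {
  pos <- mkGridPositions(2, 100, 2)
  X <- simGridScores(223, pos, 42)
  q1 <- which(pos$group == "chr1" & pos$cM == 30)
  q2 <- which(pos$group == "chr2" & pos$cM == 60)
  set.seed(43)
  A <- rbind(c(1, 1, 1), c(0.8, 0.8, 0))   # second QTL inactive in env 3
  Y <- X[, c(q1, q2)] %*% A + matrix(rnorm(223 * 3), 223)
  ss <- scanSettings(step = 2, seed = 77, nResamples = 500L)
  mod <- modelSearch(Y, X, pos, ss)
  expect_equal(nrow(mod@qtls), 2)
  found <- paste(mod@qtls$group, mod@qtls$cM)
  expect_true(any(mod@qtls$group == "chr1" & abs(mod@qtls$cM - 30) <= 4))
  expect_true(any(mod@qtls$group == "chr2" & abs(mod@qtls$cM - 60) <= 4))
  # likelihood monotonicity: dropping a retained QTL lowers the likelihood
  red <- fitJointModel(Y, X[, mod@qtls$index[1], drop = FALSE])
  expect_gt(mod@logLik, red$logLik)
  pruned <- surPrune(mod, Y, X)
  o <- order(pruned@qtls$group)
  expect_true(all(pruned@active[o[1], ]))
  expect_false(pruned@active[o[2], 3])
  expect_true(all(pruned@effects[!pruned@active] == 0))
  # strongly significant effects survive pruning untouched
  Y2 <- X[, c(q1, q2)] %*% rbind(c(1, 1, 1), c(1, 1, 1)) +
    matrix(rnorm(223 * 3), 223)
  mod2 <- surPrune(mtmim:::newQTLModel(Y2, X, pos, c(q1, q2), ss), Y2, X)
  expect_true(all(mod2@active))
})

test_that("LOD profiles obey the Gaussian closed form and bracket the peak", {
  pos <- mkGridPositions(1, 60, 2)
  X <- simGridScores(150, pos, 55)
  q <- which(pos$cM == 30)
  set.seed(56)
  Y <- matrix(X[, q] * 0.8 + rnorm(150), 150, 1)
  ss <- scanSettings(step = 2, seed = 1)
  mod <- mtmim:::newQTLModel(Y, X, pos, q, ss)
  # E = 1: LOD = (n/2) log10(RSS_reduced / RSS_full)
  rssF <- sum(lm(Y[, 1] ~ X[, q])$residuals^2)
  rss0 <- sum((Y[, 1] - mean(Y[, 1]))^2)
  expect_equal(mtmim:::lodOfQtl(mod, Y, X, 1),
               150 / 2 * log10(rss0 / rssF), tolerance = 1e-9)
  ls <- lodSupport(mod, Y, X, pos, 1)
  expect_equal(ls$profile$lod[ls$profile$cM == 30], ls$peakLod)
  expect_true(ls$interval[1] <= ls$peakCM && ls$peakCM <= ls$interval[2])
  expect_true(all(ls$profile$lod[ls$profile$cM >= ls$interval[1] &
                                 ls$profile$cM <= ls$interval[2]] >=
                  ls$peakLod - 1.5))
  expect_error(lodSupport(mod, Y, X, pos, 5), "out of range")

  # zero-effect focal QTL: flat profile spanning the whole group
  set.seed(57)
  Y0 <- matrix(rnorm(150), 150, 1)
  mod0 <- mtmim:::newQTLModel(Y0, X, pos, q, ss)
  ls0 <- lodSupport(mod0, Y0, X, pos, 1)
  expect_lt(ls0$peakLod, 1.5)
  expect_equal(ls0$interval, c(0, 60))
})

test_that("PVE follows the variance-ratio formula", {
  n <- 200
  x <- rep(c(1, -1), n / 2)            # balanced: Var(x) = 1 (about)
  a <- 1
  set.seed(60)
  noise <- rnorm(n)
  noise <- (noise - mean(noise)) / sd(noise) * sqrt(3)
  y <- a * x + noise                    # Var(y) ~= 4
  pos <- data.frame(group = "chr1", cM = 0, chrom = "chr1", bp = 1L)
  mod <- mtmim:::newQTLModel(cbind(y), cbind(x), pos, 1, scanSettings())
  pve <- computePve(mod, cbind(y), cbind(x))
  expect_equal(unname(pve[1, 1]),
               100 * mod@effects[1, 1]^2 * var(x) / var(y), tolerance = 1e-9)
  expect_equal(unname(pve[1, 1]), 25, tolerance = 2)
})

test_that("univariate MIM is the E = 1 special case of the machinery", {
  pos <- mkGridPositions(1, 40, 2)
  X <- simGridScores(100, pos, 70)
  q <- which(pos$cM == 20)
  set.seed(71)
  Y <- matrix(X[, q] + rnorm(100), 100, 1)
  sc <- scoreScan(Y, X)
  # statistic equals the univariate score form U^2 / (s2 * sigma2)
  xr <- residuals(lm(X[, q] ~ 1))
  e <- Y[, 1] - mean(Y[, 1])
  s2hat <- mean(e^2)
  expect_equal(unname(sc$stat[q]),
               sum(xr * e)^2 / (sum(xr^2) * s2hat), tolerance = 1e-9)
})

test_that("report rows are named and ordered by genome position", {
  pos <- mkGridPositions(2, 60, 2)
  X <- simGridScores(150, pos, 80)
  qa <- which(pos$group == "chr1" & pos$cM == 40)
  qb <- which(pos$group == "chr1" & pos$cM == 10)
  set.seed(81)
  Y <- X[, c(qa, qb)] %*% rbind(c(1, 1, 1), c(0.9, 0.9, 0.9)) +
    matrix(rnorm(150 * 3), 150)
  mod <- mtmim:::newQTLModel(Y, X, pos, c(qa, qb), scanSettings())
  rep1 <- qtlReport(mod, Y, X, pos, trait = "FLW", analysis = "MT",
                    supportIntervals = FALSE)
  expect_equal(rep1$qtl, c("FLW-MT.1", "FLW-MT.2"))
  expect_equal(rep1$cM, c(10, 40))      # numbered by increasing position
  out <- buildReport(list(rep1))
  sm <- attr(out, "summary")
  expect_equal(sm$nQtl, 2)
  expect_equal(sm$nAllTrials, 2)
  expect_equal(sm$nWithSur, 0)
})
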