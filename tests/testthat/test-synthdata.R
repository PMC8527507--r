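test_that("truth maps include endpoints and are strictly increasing", {
  m1 <- makeTruthMap(1, 100, 2, seed = 1)
  expect_equal(m1@markers$pos_cM, c(0, 100))
  m2 <- makeTruthMap(10, 140, 40, seed = 1)
  expect_equal(nrow(m2@markers), 400)
  expect_true(all(table(m2@markers$chrom) == 40))
  m3 <- makeTruthMap(1, 100, 11, seed = 7)
  expect_true(all(diff(m3@markers$pos_cM) > 0))
  expect_true(all(diff(m3@markers$pos_bp) > 0))
  expect_error(makeTruthMap(1, -5, 10, seed = 1), "chromLen")
  expect_error(makeTruthMap(1, 100, 1, seed = 1), "nMarkers")
  # deterministic given seed
  expect_identical(makeTruthMap(3, 120, 15, seed = 9)@markers$pos_cM,
                   makeTruthMap(3, 120, 15, seed = 9)@markers$pos_cM)
})

test_that("heterozygosity decays as (1/2)^(g-1) under single-seed descent", {
  map <- makeTruthMap(1, 100, 2, seed = 1)
  n <- 10000
  for (g in c(2L, 4L, 6L)) {
    rl <- simulateRILs(map, n, g, seed = 11 + g, keepHet = TRUE)
    het <- mean(calls(rl)[1, ] == 0)
    p <- 0.5^(g - 1)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(het - p), 3 * se)
  }
  expect_error(simulateRILs(map, 5, 1, seed = 1), "generations")
})

test_that("markers at (effectively) zero distance are identical and far pairs
           follow the selfed-RIL recombinant fraction", {
  # two markers 1e-6 cM apart: recombination probability ~ 1e-8
  near <- methods::new("SimMap",
    markers = S4Vectors::DataFrame(name = c("a", "b"), chrom = "chr1",
                                   pos_cM = c(50, 50 + 1e-6),
                                   pos_bp = c(100L, 101L)),
    chromLen = c(chr1 = 100), mapFunction = "kosambi", bpPerCM = 250000)
  rl <- simulateRILs(near, 300, 6, seed = 2, keepHet = TRUE)
  expect_identical(calls(rl)[1, ], calls(rl)[2, ])

  map <- makeTruthMap(1, 100, 2, seed = 1)  # markers 100 cM apart
  n <- 10000
  rl <- simulateRILs(map, n, 6, seed = 5, keepHet = TRUE)
  m <- calls(rl)
  ok <- m[1, ] != 0L & m[2, ] != 0L
  Rhat <- mean(m[1, ok] != m[2, ok])
  r <- (1 - exp(-2)) / 2
  Rexp <- 2 * r / (1 + 2 * r)
  expect_lt(abs(Rhat - Rexp), 3 * sqrt(Rexp * (1 - Rexp) / sum(ok)))
})

test_that("marker allele frequencies center on 1/2", {
  map <- makeTruthMap(5, 100, 20, seed = 3)
  rl <- simulateRILs(map, 400, 6, seed = 7, engine = "markov")
  freq <- rowMeans(calls(rl) == 1L, na.rm = TRUE)
  se <- sd(freq) / sqrt(length(freq))
  expect_lt(abs(mean(freq) - 0.5), 3 * max(se, 1e-3))
})

test_that("degradeGenotypes hits its missing and error rates and is a no-op
           at zero rates", {
  map <- makeTruthMap(2, 100, 50, seed = 4)
  rl <- simulateRILs(map, 100, 6, seed = 4, engine = "markov")
  expect_identical(calls(degradeGenotypes(rl, 0, 0, seed = 1)), calls(rl))
  allmiss <- degradeGenotypes(rl, 1, 0, seed = 1)
  expect_true(all(is.na(calls(allmiss))))
  deg <- degradeGenotypes(rl, 0.25, 0.01, seed = 9)
  base <- calls(rl); d <- calls(deg)
  nObs <- sum(!is.na(base))
  missFrac <- sum(is.na(d) & !is.na(base)) / nObs
  expect_lt(abs(missFrac - 0.25), 3 * sqrt(0.25 * 0.75 / nObs))
  surv <- !is.na(d) & !is.na(base)
  flipFrac <- mean(d[surv] != base[surv])
  expect_lt(abs(flipFrac - 0.01), 3 * sqrt(0.01 * 0.99 / sum(surv)))
  expect_error(degradeGenotypes(rl, -0.1, 0), "missingRate")
  expect_error(degradeGenotypes(rl, 0, 2), "errorRate")
})

test_that("phenotype model equation is exact in the noise-free limit", {
  map <- makeTruthMap(1, 100, 5, seed = 2)
  qpos <- map@markers$pos_cM[3]
  qtls <- data.frame(chrom = "chr1", pos_cM = qpos, T1 = 1, T2 = 2, T3 = 3)
  truth <- simTruth(map, qtls, mu = c(0, 0, 0), sigmaE = diag(3) * 1e-18,
                    seed = 5)
  rl <- simulateRILs(map, 50, 6, seed = 5, engine = "markov", keepHet = TRUE)
  ph <- simulatePhenotypes(rl, truth)
  brandes <- which(calls(rl)[3, ] == 1L)[1]
  expect_equal(unname(ph$Y[brandes, ]), c(1, 2, 3), tolerance = 1e-6)
  wray <- which(calls(rl)[3, ] == -1L)[1]
  expect_equal(unname(ph$Y[wray, ]), c(-1, -2, -3), tolerance = 1e-6)
})

test_that("residual covariance across environments converges to Sigma_E", {
  map <- makeTruthMap(1, 50, 3, seed = 6)
  truth <- simTruth(map, data.frame(chrom = character(0), pos_cM = numeric(0),
                                    T1 = numeric(0), T2 = numeric(0),
                                    T3 = numeric(0)),
                    mu = c(0, 0, 0), sigmaE = diag(3), seed = 8)
  rl <- simulateRILs(map, 5000, 6, seed = 8, engine = "markov", keepHet = TRUE)
  ph <- simulatePhenotypes(rl, truth)
  expect_lt(max(abs(cov(ph$Y) - diag(3))), 0.05)
})

test_that("QTL positions off the map are rejected", {
  map <- makeTruthMap(1, 100, 5, seed = 2)
  expect_error(
    simTruth(map, data.frame(chrom = "chr1", pos_cM = 500, T1 = 1, T2 = 1,
                             T3 = 1), mu = c(0, 0, 0), sigmaE = diag(3)),
    "off-map")
  bad <- data.frame(chrom = "chr1", pos_cM = 33.33, T1 = 1, T2 = 1, T3 = 1)
  truth <- tryCatch(simTruth(map, bad, mu = c(0, 0, 0), sigmaE = diag(3)),
                    error = function(e) NULL)
  if (!is.null(truth)) {
    rl <- simulateRILs(map, 10, 6, seed = 1, engine = "markov", keepHet = TRUE)
    expect_error(simulatePhenotypes(rl, truth), "off-map")
  }
})

test_that("simulated trial data recovers its variance components", {
  st <- simulateStudy(nInd = 150, nChrom = 3, chromLen = 100,
                      markersPerChrom = 12, engine = "markov", seed = 21)
  f <- fitSingleTrial(st$trial, "y", "random", trial = "T2")
  vc <- varComp(f)
  d <- st$truth@design
  # generous simulation tolerances: one replicate of the design
  expect_lt(abs(vc[["sigma2"]] - d$sigma2), 0.35)
  expect_lt(abs(vc[["sigma_b2"]] - d$sigma_b2), 0.3)
  # sigma_g2 = QTL variance + residual individual variance in T2
  eff <- st$truth@qtlEffects[, 2]
  sgTrue <- sum(eff^2) + st$truth@sigmaE[2, 2]
  expect_lt(abs(vc[["sigma_g2"]] - sgTrue) / sgTrue, 0.35)
})
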