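test_that("forward-backward posteriors match brute-force path enumeration", {
  # property check over random small instances with missing data and errors
  for (s in 1:12) {
    set.seed(s)
    M <- sample(2:4, 1)
    n <- sample(1:5, 1)
    err <- sample(c(0, 0.01, 0.1), 1)
    R <- runif(M - 1, 0, 0.45)
    obs <- matrix(sample(c(1L, -1L, NA), M * n, TRUE, prob = c(.4, .4, .2)),
                  M, n)
    fb <- mtmim:::hmmForwardBackward(obs, R, err)$post
    for (i in seq_len(n)) {
      oracle <- bruteForcePosterior(obs[, i], R, err)
      got <- cbind(fb[i, , 1], fb[i, , 2])
      expect_lt(max(abs(got - oracle)), 1e-9)
    }
  }
})

test_that("posterior edge cases follow the emission model", {
  # single typed marker: prior (1/2,1/2) x emission (0.99, 0.01)
  gmap <- methods::new("GeneticMap",
    table = S4Vectors::DataFrame(marker = "M1", group = "g1", cM = 0,
                                 chrom = "1", bp = 1L),
    rf = list(g1 = numeric(0)), mapFunction = "kosambi")
  mm <- MarkerMatrix(matrix(1L, 1, 1), chrom = "1", pos = 1L,
                     markerNames = "M1")
  gp <- calcGenoProb(mm, gmap, step = 1, errorRate = 0.01)
  expect_equal(gp@probs[1, 1, ], c(0.99, 0.01), tolerance = 1e-12)

  # fully missing individual: (0.5, 0.5) everywhere
  m <- rbind(c(1L, NA), c(-1L, NA), c(1L, NA))
  mm2 <- MarkerMatrix(m, chrom = rep("1", 3), pos = c(1L, 2L, 3L))
  gmap2 <- methods::new("GeneticMap",
    table = S4Vectors::DataFrame(marker = paste0("M", 1:3), group = "g1",
                                 cM = c(0, 10, 20), chrom = "1",
                                 bp = c(1L, 2L, 3L)),
    rf = list(g1 = rep(0.1, 2)), mapFunction = "kosambi")
  gp2 <- calcGenoProb(mm2, gmap2, step = 1, errorRate = 0.01)
  expect_true(all(abs(gp2@probs[2, , ] - 0.5) < 1e-12))
  expect_error(calcGenoProb(mm2, gmap2, step = 0), "step")

  # pseudomarker midway on a 2-cM interval between two A calls
  m3 <- matrix(c(1L, 1L), 2, 1)
  mm3 <- MarkerMatrix(m3, chrom = c("1", "1"), pos = c(1L, 2L))
  gmap3 <- methods::new("GeneticMap",
    table = S4Vectors::DataFrame(marker = c("M1", "M2"), group = "g1",
                                 cM = c(0, 2), chrom = "1", bp = c(1L, 2L)),
    rf = list(g1 = mapInverse(2, "kosambi")), mapFunction = "kosambi")
  gp3 <- calcGenoProb(mm3, gmap3, step = 1, errorRate = 0)
  mid <- which(gp3@positions$cM == 1)
  expect_true(gp3@positions$pseudo[mid])
  expect_gt(gp3@probs[1, mid, 1], 0.99)

  # normalization invariant on a larger random instance
  set.seed(9)
  m4 <- matrix(sample(c(1L, -1L, NA), 20 * 30, TRUE), 20, 30)
  mm4 <- MarkerMatrix(m4, chrom = rep("1", 20), pos = 1:20)
  gmap4 <- methods::new("GeneticMap",
    table = S4Vectors::DataFrame(marker = paste0("M", 1:20), group = "g1",
                                 cM = seq(0, 95, by = 5), chrom = "1",
                                 bp = 1:20),
    rf = list(g1 = rep(mapInverse(5, "kosambi"), 19)), mapFunction = "kosambi")
  gp4 <- calcGenoProb(mm4, gmap4)
  expect_lt(max(abs(gp4@probs[, , 1] + gp4@probs[, , 2] - 1)), 1e-9)
})

test_that("EM multipoint distances reduce to two-point for marker pairs and
           apply the chosen map function", {
  set.seed(5)
  base <- sample(c(1L, -1L), 300, TRUE)
  other <- ifelse(runif(300) < 0.18, -base, base)
  mm <- MarkerMatrix(matrix(c(base, other), 2, byrow = TRUE),
                     chrom = c("1", "1"), pos = c(1L, 2L))
  tp <- twoPoint(mm, 1, 2)
  gmapK <- estimateMap(mm, list(g1 = c("M1", "M2")), errorRate = 0,
                       mapFunction = "kosambi")
  expect_equal(gmapK@rf$g1, tp$r_hat, tolerance = 1e-4)
  expect_equal(max(gmapK@table$cM), mapDistance(tp$r_hat, "kosambi"),
               tolerance = 1e-3)
  gmapH <- estimateMap(mm, list(g1 = c("M1", "M2")), errorRate = 0,
                       mapFunction = "haldane")
  expect_equal(max(gmapH@table$cM), mapDistance(tp$r_hat, "haldane"),
               tolerance = 1e-3)

  # identical adjacent markers -> 0 cM gap
  mm0 <- MarkerMatrix(matrix(c(base, base, other), 3, byrow = TRUE),
                      chrom = rep("1", 3), pos = 1:3)
  gmap0 <- estimateMap(mm0, list(g1 = paste0("M", 1:3)), errorRate = 0)
  expect_equal(gmap0@table$cM[2], 0, tolerance = 1e-6)
  expect_warning(estimateMap(mm0, list(g1 = "M1", g2 = paste0("M", 2:3))),
                 "fewer than 2")
})

test_that("multipoint rf estimates recover simulated truth under noise", {
  map <- makeTruthMap(1, 80, 9, seed = 31)
  rl <- simulateRILs(map, 200, 6, seed = 31, engine = "markov")
  deg <- degradeGenotypes(rl, 0.05, 0.01, seed = 32)
  gmap <- estimateMap(deg, list(chr1 = rownames(calls(deg))),
                      errorRate = 0.01, mapFunction = "kosambi")
  rTrue <- mapInverse(diff(map@markers$pos_cM), "kosambi")
  Rtrue <- rilR(rTrue)
  Rhat <- rilR(gmap@rf$chr1)
  se <- sqrt(Rtrue * (1 - Rtrue) / 200) + 0.01
  expect_true(all(abs(Rhat - Rtrue) < 3 * se))
})
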