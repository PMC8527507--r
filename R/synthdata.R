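# Synthetic-data generator: RIL populations by single-seed descent, GBS-like
# genotype degradation, and multi-environment lattice-trial phenotypes.

#' Generate a synthetic truth map
#'
#' Marker positions are drawn uniformly per chromosome with both chromosome
#' endpoints (0 and \code{chromLen}) always included. Physical positions
#' follow a fixed linear scale (\code{bpPerCM}), a purely synthetic
#' convention recorded in the object so physical-map-mode scans are testable.
#'
#' @param nChrom number of chromosomes (>= 1).
#' @param chromLen chromosome length in cM (scalar or per-chromosome).
#' @param nMarkersPerChrom markers per chromosome (>= 2).
#' @param seed integer seed.
#' @param bpPerCM synthetic physical scale (default 250 kb/cM).
#' @param mapFunction map function label carried by the map.
#' @return A \linkS4class{SimMap}.
#' @export
makeTruthMap <- function(nChrom, chromLen, nMarkersPerChrom, seed,
                         bpPerCM = 250000, mapFunction = "kosambi") {
  stopIfNot(nChrom >= 1, "nChrom must be >= 1")
  stopIfNot(all(chromLen > 0), "chromLen must be > 0")
  stopIfNot(nMarkersPerChrom >= 2, "nMarkersPerChrom must be >= 2")
  chromLen <- rep_len(chromLen, nChrom)
  chromNames <- paste0("chr", seq_len(nChrom))
  names(chromLen) <- chromNames
  mk <- withSeed(subSeed(seed, "truthmap"), {
    do.call(rbind, lapply(seq_len(nChrom), function(c) {
      len <- chromLen[c]
      pos <- c(0, sort(runif(nMarkersPerChrom - 2, 0, len)), len)
      # enforce strict increase (ties have probability ~0, but be safe)
      while (any(diff(pos) <= 0)) pos <- c(0, sort(runif(nMarkersPerChrom - 2, 0, len)), len)
      bp <- as.integer(round(pos * bpPerCM)) + 1L
      bp <- as.integer(cummax(bp + seq_along(bp) - 1L))  # strictly increasing
      data.frame(name = paste0("S", c, "_", bp), chrom = chromNames[c],
                 pos_cM = pos, pos_bp = bp, stringsAsFactors = FALSE)
    }))
  })
  methods::new("SimMap", markers = S4Vectors::DataFrame(mk),
               chromLen = chromLen, mapFunction = mapFunction,
               bpPerCM = bpPerCM)
}

#' Assemble the generating truth of a synthetic study
#'
#' @param simMap a \linkS4class{SimMap}.
#' @param qtls data.frame with columns \code{chrom}, \code{pos_cM}, then one
#'   effect column per environment; optional logical columns
#'   \code{active.<e>}. May have zero rows.
#' @param mu per-environment intercepts.
#' @param sigmaE E x E residual covariance across environments.
#' @param design list(reps, blocks, sigma_b2, sigma2, standCoef, standMean).
#' @param generations selfing generations (>= 2; F2:6 is 6).
#' @param seed master seed.
#' @return A \linkS4class{SimTruth}.
#' @export
simTruth <- function(simMap, qtls, mu, sigmaE,
                     design = list(reps = 3L, blocks = 15L, sigma_b2 = 0.25,
                                   sigma2 = 1, standCoef = 0, standMean = 10),
                     generations = 6L, seed = 1L) {
  E <- length(mu)
  effCols <- setdiff(colnames(qtls), c("chrom", "pos_cM",
                                       grep("^active", colnames(qtls), value = TRUE)))
  stopIfNot(length(effCols) == E, "qtls must have one effect column per environment")
  eff <- as.matrix(qtls[, effCols, drop = FALSE])
  actCols <- grep("^active", colnames(qtls), value = TRUE)
  act <- if (length(actCols) == E) as.matrix(qtls[, actCols, drop = FALSE]) == TRUE
         else eff != 0
  if (nrow(qtls) == 0) {
    eff <- matrix(0, 0, E); act <- matrix(FALSE, 0, E)
  }
  methods::new("SimTruth", simMap = simMap,
               qtlChrom = as.character(qtls$chrom), qtlPos = as.numeric(qtls$pos_cM),
               qtlEffects = eff * act, qtlActive = act,
               mu = mu, sigmaE = sigmaE, design = design,
               generations = as.integer(generations), seed = as.integer(seed))
}

# -- single-seed-descent machinery --------------------------------------------
# A haplotype is a run-length encoding of parental origin along one
# chromosome: ends (ascending cM, last = chromosome length) and val (+1/-1).

hapAt <- function(h, pos) h$val[findInterval(pos - 1e-9, h$ends) + 1L]

# One meiosis: recombine two homologs with Poisson(len/100) crossovers at
# uniform positions (no interference), random starting homolog.
gamete <- function(h1, h2, len) {
  nxo <- rpois(1L, len / 100)
  if (nxo == 0L) return(if (runif(1) < 0.5) h1 else h2)
  cuts <- c(sort(runif(nxo, 0, len)), len)
  cur <- sample(c(1L, 2L), 1L)
  ends <- numeric(0); val <- integer(0)
  a <- 0
  for (b in cuts) {
    h <- if (cur == 1L) h1 else h2
    sel <- which(h$ends > a + 1e-12 & c(0, h$ends[-length(h$ends)]) < b - 1e-12)
    if (length(sel)) {
      e <- pmin(h$ends[sel], b)
      ends <- c(ends, e); val <- c(val, h$val[sel])
    }
    a <- b
    cur <- 3L - cur
  }
  keep <- c(val[-1L] != val[-length(val)], TRUE)
  list(ends = ends[keep], val = val[keep])
}

#' Simulate a RIL population
#'
#' Each individual descends from a Brandes x Wray F1 selfed by single-seed
#' descent for \code{generations - 1} meioses per lineage. Crossovers follow
#' a no-interference (Poisson) model. With the default \code{engine = "ssd"}
#' residual heterozygous calls are coded 0 and, unless \code{keepHet}, masked
#' to missing, mirroring how heterozygous GBS calls are handled. The
#' \code{"markov"} engine draws fully inbred genomes directly from the
#' Haldane-Waddington interval process (adjacent-marker flip probability
#' R = 2r/(1+2r)), the exact limit of single-seed descent as generations grow;
#' it is used for large replicated simulations.
#'
#' @param simMap a \linkS4class{SimMap}.
#' @param nInd number of individuals (>= 1).
#' @param generations selfing generations, >= 2 (F2 start of selfing).
#' @param seed integer seed.
#' @param engine \code{"ssd"} (explicit meiosis) or \code{"markov"}.
#' @param keepHet keep residual heterozygotes as 0 instead of masking to NA
#'   (truth matrices for phenotype simulation keep them).
#' @return A \linkS4class{MarkerMatrix} with \code{pos_cM} in rowData.
#' @export
simulateRILs <- function(simMap, nInd, generations = 6L, seed = 1L,
                         engine = c("ssd", "markov"), keepHet = FALSE) {
  engine <- match.arg(engine)
  stopIfNot(generations >= 2, "generations must be >= 2")
  stopIfNot(nInd >= 1, "nInd must be >= 1")
  mk <- simMap@markers
  chroms <- unique(mk$chrom)
  geno <- withSeed(subSeed(seed, paste0("rils-", engine)), {
    out <- matrix(0L, nrow(mk), nInd)
    for (ch in chroms) {
      idx <- which(mk$chrom == ch)
      pos <- mk$pos_cM[idx]
      len <- simMap@chromLen[ch]
      if (engine == "ssd") {
        for (i in seq_len(nInd)) {
          h1 <- list(ends = len, val = 1L)
          h2 <- list(ends = len, val = -1L)
          for (g in seq_len(generations - 1L)) {
            n1 <- gamete(h1, h2, len)
            n2 <- gamete(h1, h2, len)
            h1 <- n1; h2 <- n2
          }
          out[idx, i] <- as.integer((hapAt(h1, pos) + hapAt(h2, pos)) / 2)
        }
      } else {
        d <- diff(pos)
        R <- rilR(mapInverse(d, simMap@mapFunction))
        s <- matrix(0L, length(idx), nInd)
        s[1L, ] <- sample(c(1L, -1L), nInd, replace = TRUE)
        if (length(idx) > 1L) for (m in 2L:length(idx)) {
          flip <- runif(nInd) < R[m - 1L]
          s[m, ] <- ifelse(flip, -s[m - 1L, ], s[m - 1L, ])
        }
        out[idx, ] <- s
      }
    }
    out
  })
  if (!keepHet) geno[geno == 0L] <- NA_integer_
  MarkerMatrix(geno, chrom = mk$chrom, pos = mk$pos_bp, pos_cM = mk$pos_cM,
               markerNames = mk$name,
               individualIds = sprintf("RIL%03d", seq_len(nInd)))
}

#' Degrade genotype calls with missingness and genotyping error
#'
#' Each observed call is independently set to missing with
#' \code{missingRate}; each surviving homozygous call is flipped to the other
#' parental allele with \code{errorRate}. Emulates GBS missingness and the
#' error level the mapping HMM is designed to absorb.
#'
#' @param mm a \linkS4class{MarkerMatrix}.
#' @param missingRate,errorRate fractions in [0, 1].
#' @param seed integer seed.
#' @return A degraded \linkS4class{MarkerMatrix}; the input is untouched.
#' @export
degradeGenotypes <- function(mm, missingRate, errorRate, seed = 1L) {
  stopIfNot(missingRate >= 0 && missingRate <= 1, "missingRate must be in [0,1]")
  stopIfNot(errorRate >= 0 && errorRate <= 1, "errorRate must be in [0,1]")
  m <- calls(mm)
  withSeed(subSeed(seed, "degrade"), {
    obs <- which(!is.na(m))
    if (missingRate > 0) {
      drop <- obs[runif(length(obs)) < missingRate]
      m[drop] <- NA_integer_
    }
    if (errorRate > 0) {
      left <- which(!is.na(m) & m != 0L)
      flip <- left[runif(length(left)) < errorRate]
      m[flip] <- -m[flip]
    }
  })
  out <- mm
  SummarizedExperiment::assay(out, "calls") <- m
  out
}

#' Simulate multi-environment phenotypes
#'
#' Genetic value of individual i in environment e is
#' mu_e + sum_r a_er x_ir with x in \{-1, +1\} (+1 = Brandes-like allele,
#' -1 = Wray-like; residual heterozygotes score 0). Individual-level
#' residuals are drawn from N(0, Sigma_E). With \code{trialData = TRUE},
#' plot values in a lattice design add fixed replicate effects, random block
#' effects N(0, sigma_b2), a plant-count (stand) covariate contribution and
#' plot residuals N(0, sigma2); the two parents are included as checks.
#'
#' @param truthGeno truth \linkS4class{MarkerMatrix} (no missing calls;
#'   simulate with \code{keepHet = TRUE}).
#' @param truth a \linkS4class{SimTruth}; every QTL position must coincide
#'   with a marker of \code{truthGeno}.
#' @param trialData also generate plot-level lattice data.
#' @return list with \code{Y} (individuals x environments genetic means) and
#'   \code{trial} (plot-level data.frame or NULL).
#' @export
simulatePhenotypes <- function(truthGeno, truth, trialData = FALSE) {
  m <- calls(truthGeno)
  stopIfNot(!anyNA(m), "truthGeno must have no missing values")
  rd <- SummarizedExperiment::rowData(truthGeno)
  E <- length(truth@mu)
  R <- length(truth@qtlPos)
  I <- ncol(m)
  qidx <- integer(R)
  if (R > 0) {
    key <- paste(rd$chrom, round(rd$pos_cM, 6))
    qidx <- match(paste(truth@qtlChrom, round(truth@qtlPos, 6)), key)
    if (anyNA(qidx))
      stop("QTL position off-map: no marker at ",
           paste(truth@qtlChrom[is.na(qidx)], truth@qtlPos[is.na(qidx)],
                 collapse = "; "), call. = FALSE)
  }
  X <- if (R > 0) t(m[qidx, , drop = FALSE]) else matrix(0, I, 0)
  eff <- truth@qtlEffects * truth@qtlActive
  G <- matrix(truth@mu, I, E, byrow = TRUE) +
    (if (R > 0) X %*% eff else 0)
  Y <- withSeed(subSeed(truth@seed, "phenotypes"),
                G + rmvn(I, truth@sigmaE))
  dimnames(Y) <- list(colnames(m), paste0("T", seq_len(E)))
  trial <- NULL
  if (trialData) {
    d <- truth@design
    trial <- withSeed(subSeed(truth@seed, "trial"), {
      Gall <- rbind(Y, matrix(truth@mu, 2, E, byrow = TRUE) +
                      rbind(colSums(eff), -colSums(eff)) +
                      rmvn(2, truth@sigmaE))
      ids <- c(rownames(Y), "BRANDES", "WRAY")
      role <- c(rep("line", I), "check", "check")
      n <- length(ids)
      rows <- list()
      for (e in seq_len(E)) {
        repEff <- rnorm(d$reps, 0, 1)
        for (k in seq_len(d$reps)) {
          perm <- sample.int(n)
          blk <- sort(rep(seq_len(d$blocks), length.out = n))[order(perm)]
          blockEff <- rnorm(d$blocks, 0, sqrt(d$sigma_b2))
          stand <- pmax(rpois(n, d$standMean), 1L)
          y <- Gall[, e] + repEff[k] + blockEff[blk] +
            d$standCoef * (stand - d$standMean) + rnorm(n, 0, sqrt(d$sigma2))
          rows[[length(rows) + 1L]] <- data.frame(
            trial = paste0("T", e), rep = k, block = blk,
            genotype = ids, role = role, stand = stand, y = y,
            stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows)
    })
    rownames(trial) <- NULL
  }
  list(Y = Y, trial = trial)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper tying the generator together under study-like
#' conditions: a 10-chromosome genome, a biparental RIL population at F2:6,
#' GBS-like missingness with 1\% genotyping error, and three lattice trials
#' (15 incomplete blocks, 3 replicates) with environment-specific QTL effects
#' and a correlated residual covariance across trials.
#'
#' @param nInd number of RILs (default 223, the phenotyped population size).
#' @param nChrom,chromLen,markersPerChrom genome layout defaults: 10
#'   chromosomes of ~137 cM (matching a ~1,370 cM total map).
#' @param qtls QTL table as in \code{\link{simTruth}}; NULL for the default
#'   five-QTL architecture (one QTL inactive in trial 1).
#' @param missingRate,errorRate degradation applied to the observed genotype
#'   matrix.
#' @param generations selfing generations.
#' @param engine RIL simulation engine (see \code{\link{simulateRILs}}).
#' @param seed master seed.
#' @return list(truth, truthGeno, geno, Y, trial).
#' @export
simulateStudy <- function(nInd = 223L, nChrom = 10L, chromLen = 137,
                          markersPerChrom = 40L, qtls = NULL,
                          missingRate = 0.15, errorRate = 0.01,
                          generations = 6L, engine = "ssd", seed = 1L) {
  map <- makeTruthMap(nChrom, chromLen, markersPerChrom, seed = seed)
  if (is.null(qtls)) {
    # five QTLs spread over the genome, one inactive in trial 1; positions
    # scale with the requested genome so smaller test genomes stay valid
    chrIdx <- pmax(1L, pmin(nChrom, ceiling(c(1, 3, 6, 6, 9) / 10 * nChrom)))
    qtls <- data.frame(
      chrom = paste0("chr", chrIdx),
      pos_cM = c(0.22, 0.44, 0.29, 0.66, 0.51) * min(chromLen),
      T1 = c(0.4, -0.5, 0.6, -0.5, 0.0),
      T2 = c(0.4, -0.5, 0.9, -0.5, 0.5),
      T3 = c(0.4, -0.5, 0.8, -0.5, 0.5))
    qtls <- qtls[!duplicated(paste(qtls$chrom, round(qtls$pos_cM, 3))), ]
  }
  map <- insertMapPositions(map, qtls$chrom, qtls$pos_cM)
  sigmaE <- outer(sqrt(c(1, 1.2, 0.8)), sqrt(c(1, 1.2, 0.8))) *
    (0.5 + 0.5 * diag(3))
  truth <- simTruth(map, qtls, mu = c(80, 85, 83), sigmaE = sigmaE,
                    generations = generations, seed = seed)
  truthGeno <- simulateRILs(map, nInd, generations, seed = seed,
                            engine = engine, keepHet = TRUE)
  ph <- simulatePhenotypes(truthGeno, truth, trialData = TRUE)
  geno <- truthGeno
  gcalls <- calls(geno)
  gcalls[gcalls == 0L] <- NA_integer_  # mask residual heterozygotes
  SummarizedExperiment::assay(geno, "calls") <- gcalls
  geno <- degradeGenotypes(geno, missingRate, errorRate, seed = seed)
  list(truth = truth, truthGeno = truthGeno, geno = geno,
       Y = ph$Y, trial = ph$trial)
}

# Ensure markers exist at given (chrom, cM) positions, inserting synthetic
# markers when needed (used to place QTLs exactly on the marker grid).
insertMapPositions <- function(simMap, chrom, pos_cM) {
  mk <- as.data.frame(simMap@markers)
  for (r in seq_along(chrom)) {
    hit <- mk$chrom == chrom[r] & abs(mk$pos_cM - pos_cM[r]) < 1e-6
    if (!any(hit)) {
      bp <- as.integer(round(pos_cM[r] * simMap@bpPerCM)) + 1L
      mk <- rbind(mk, data.frame(name = paste0("Q", chrom[r], "_", bp),
                                 chrom = chrom[r], pos_cM = pos_cM[r],
                                 pos_bp = bp, stringsAsFactors = FALSE))
    }
  }
  mk <- mk[order(match(mk$chrom, names(simMap@chromLen)), mk$pos_cM), ]
  # keep bp strictly increasing within chromosome after insertion
  for (ch in unique(mk$chrom)) {
    i <- which(mk$chrom == ch)
    while (any(diff(mk$pos_bp[i]) <= 0)) {
      j <- i[which(diff(mk$pos_bp[i]) <= 0) + 1L]
      mk$pos_bp[j] <- mk$pos_bp[j - 1L] + 1L
    }
  }
  methods::new("SimMap", markers = S4Vectors::DataFrame(mk, row.names = NULL),
               chromLen = simMap@chromLen, mapFunction = simMap@mapFunction,
               bpPerCM = simMap@bpPerCM)
}
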