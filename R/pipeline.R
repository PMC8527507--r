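# Run configuration and the stage-chaining pipeline. All numeric defaults
# mirror the analysis constants used throughout the package: marker filters
# (25% missing, distortion alpha 0.05 Bonferroni), grouping (rf < 0.35,
# LOD > 8), HMM error 1%, 1-cM grid, 10-cM / 100-kb / 200-kb windows, and
# genome-wide 5% forward / 1% backward levels.

#' Default run configuration
#'
#' @param seed master seed; every stochastic stage derives a sub-stream
#'   from it.
#' @return nested list of stage parameters; see the YAML written next to any
#'   pipeline run for the resolved values.
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = c("simulate", "buildmap", "pheno", "scan", "report"),
    simulate = list(nInd = 223L, nChrom = 10L, chromLen = 137,
                    markersPerChrom = 40L, missingRate = 0.15,
                    errorRate = 0.01, generations = 6L, engine = "ssd"),
    filters = list(maxMissing = 0.25, distortionAlpha = 0.05),
    grouping = list(maxRf = 0.35, minLod = 8),
    map = list(errorRate = 0.01, mapFunction = "kosambi", step = 1),
    scan = list(mode = "genetic", window = 10, windowUnit = "cM",
                alphaForward = 0.05, alphaBackward = 0.01,
                nResamples = 1000L, surAlpha = 0.05))
}

#' Read a YAML run configuration
#'
#' Values present in the file override the defaults; everything else keeps
#' the package defaults of \code{\link{defaultRunConfig}}.
#'
#' @param path YAML file.
#' @return resolved configuration list.
#' @export
readRunConfig <- function(path) {
  usr <- yaml::read_yaml(path)
  cfg <- defaultRunConfig(if (!is.null(usr$seed)) usr$seed else 1L)
  merge2 <- function(a, b) {
    for (n in names(b))
      a[[n]] <- if (is.list(a[[n]]) && is.list(b[[n]])) merge2(a[[n]], b[[n]])
                else b[[n]]
    a
  }
  merge2(cfg, usr)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages (simulate -> buildmap -> pheno -> scan ->
#' report) on synthetic data, writing every artifact plus the resolved
#' configuration and an md5 manifest to \code{outDir}. Identical
#' configuration and seed give byte-identical outputs.
#'
#' @param config configuration list (see \code{\link{defaultRunConfig}}).
#' @param outDir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisible list of in-memory stage results.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir, quiet = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  res <- list()
  art <- character(0)
  putTsv <- function(x, name) {
    p <- file.path(outDir, name)
    write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    art <<- c(art, p)
    p
  }
  stages <- config$stages

  if ("simulate" %in% stages) {
    s <- config$simulate
    say("simulate: ", s$nInd, " RILs, ", s$nChrom, " chromosomes")
    res$study <- do.call(simulateStudy, c(s, list(seed = config$seed)))
    art <- c(art, writeHapMap(res$study$geno, file.path(outDir, "genotypes.hapmap.txt")))
    art <- c(art, writePhenotypes(res$study$trial, file.path(outDir, "phenotypes.csv")))
    tr <- res$study$truth
    yaml::write_yaml(list(seed = tr@seed, generations = tr@generations,
                          mu = as.numeric(tr@mu),
                          sigmaE = apply(tr@sigmaE, 1, as.numeric, simplify = FALSE),
                          qtls = list(chrom = tr@qtlChrom, pos_cM = tr@qtlPos,
                                      effects = apply(tr@qtlEffects, 1,
                                                      as.numeric, simplify = FALSE)),
                          design = tr@design),
                     file.path(outDir, "truth.yaml"))
    art <- c(art, file.path(outDir, "truth.yaml"))
  }

  if ("buildmap" %in% stages) {
    stopIfNot(!is.null(res$study), "buildmap requires the simulate stage")
    f <- config$filters
    flt <- filterMarkers(res$study$geno, f$maxMissing, f$distortionAlpha)
    say("buildmap: ", paste(flt$counts$n_out, collapse = " -> "), " markers")
    tp <- pairwiseTwoPoint(flt$mm)
    grp <- groupMarkers(tp, flt$mm, config$grouping$maxRf, config$grouping$minLod)
    gmap <- estimateMap(flt$mm, grp$groups, config$map$errorRate,
                        config$map$mapFunction)
    gp <- calcGenoProb(flt$mm, gmap, config$map$step, config$map$errorRate)
    res$filterCounts <- flt$counts
    res$gmap <- gmap; res$genoprob <- gp; res$mm <- flt$mm
    putTsv(flt$counts, "stage_counts.tsv")
    putTsv(as.data.frame(gmap@table), "map.tsv")
    pg <- as.data.frame(gp@positions)
    pg <- cbind(pg, t(gp@probs[, , 1]))
    colnames(pg)[-(1:5)] <- gp@individuals
    putTsv(pg, "genoprob_pAA.tsv")
  }

  if ("pheno" %in% stages) {
    stopIfNot(!is.null(res$study), "pheno requires the simulate stage")
    trial <- res$study$trial
    trials <- sort(unique(trial$trial))
    say("pheno: REML per trial over ", length(trials), " trials")
    fits <- lapply(trials, function(tl) fitSingleTrial(trial, "y", "random", trial = tl))
    names(fits) <- trials
    vt <- do.call(rbind, lapply(trials, function(tl) {
      sm <- summarizeFit(fits[[tl]])
      vc <- varComp(fits[[tl]])
      data.frame(trial = tl, sigma_g2 = vc[["sigma_g2"]],
                 sigma_b2 = vc[["sigma_b2"]], sigma2 = vc[["sigma2"]],
                 CV = sm$CV, h2 = sm$h2)
    }))
    res$trialFits <- fits
    res$varTable <- vt
    putTsv(vt, "variance_components.tsv")
    gn <- sort(fits[[1]]@means$genotype)
    Y <- vapply(fits, function(f) f@means$mean[match(gn, f@means$genotype)],
                numeric(length(gn)))
    dimnames(Y) <- list(gn, trials)
    res$Y <- Y
    mn <- data.frame(genotype = rownames(Y), Y, check.names = FALSE)
    p <- file.path(outDir, "adjusted_means.csv")
    write.csv(mn, p, row.names = FALSE, quote = FALSE)
    art <- c(art, p)
    gge <- ggeBiplot(Y)
    putTsv(data.frame(component = seq_along(gge@pctVar), pctVar = gge@pctVar),
           "gge_variance.tsv")
  }

  if ("scan" %in% stages) {
    stopIfNot(!is.null(res$Y) && !is.null(res$genoprob),
              "scan requires buildmap and pheno stages")
    gp <- res$genoprob
    X <- expectedScores(gp)
    keep <- intersect(rownames(res$Y), gp@individuals)
    Y <- res$Y[keep, , drop = FALSE]
    X <- X[match(keep, gp@individuals), , drop = FALSE]
    sset <- scanSettings(step = config$map$step, window = config$scan$window,
                         windowUnit = config$scan$windowUnit,
                         alphaForward = config$scan$alphaForward,
                         alphaBackward = config$scan$alphaBackward,
                         nResamples = config$scan$nResamples,
                         surAlpha = config$scan$surAlpha,
                         seed = subSeed(config$seed, "scan"))
    pos <- as.data.frame(gp@positions)
    say("scan: ", nrow(pos), " grid positions, ", ncol(Y), " environments")
    mod <- modelSearch(Y, X, pos, sset)
    mod <- surPrune(mod, Y, X)
    res$model <- mod; res$scanX <- X; res$scanY <- Y; res$positions <- pos
    say("scan: ", nrow(mod@qtls), " QTLs retained")
  }

  if ("report" %in% stages) {
    stopIfNot(!is.null(res$model), "report requires the scan stage")
    rep1 <- qtlReport(res$model, res$scanY, res$scanX, res$positions,
                      trait = "TRAIT", analysis = "MT")
    out <- buildReport(list(rep1))
    res$report <- out
    putTsv(out, "qtl_report.tsv")
    if (nrow(out)) {
      bed <- data.frame(chrom = out$group,
                        intervalStart_bp = NA_integer_,
                        intervalEnd_bp = NA_integer_,
                        name = out$qtl, lod = out$lod)
      pos <- res$positions
      for (i in seq_len(nrow(out))) {
        gsel <- pos$group == out$group[i]
        bed$intervalStart_bp[i] <-
          pos$bp[gsel][which.min(abs(pos$cM[gsel] - out$ci_lo[i]))]
        bed$intervalEnd_bp[i] <-
          pos$bp[gsel][which.min(abs(pos$cM[gsel] - out$ci_hi[i]))] + 1L
      }
      putTsv(bed, "support_intervals.tsv")
    }
  }

  yaml::write_yaml(config, file.path(outDir, "config.yaml"))
  art <- c(art, file.path(outDir, "config.yaml"))
  manifest <- data.frame(file = basename(art),
                         md5 = unname(tools::md5sum(art)))
  write.table(manifest, file.path(outDir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(res)
}
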