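# End-to-end orchestration: one config drives simulation, QC,
# association, meta-analysis, GRS, spatial autocorrelation, kriging and
# ecological regression, with per-stage sub-seeds and a hashed manifest.

#' Default pipeline configuration
#'
#' Returns the full configuration list with the default study
#' conditions: 60 SNPs in 5-SNP LD blocks (latent AR(1) rho = 0.6),
#' three case-control studies of 2000 cases / 2000 controls drawn from a
#' logistic disease model with 4 causal SNPs (log odds ratios spaced in
#' \[0.2, 0.5\]), two replicate dosage sets per study, a panel of 30
#' populations of 40 individuals on a European latitude/longitude window
#' with a northward frequency cline at the causal SNPs, and an 11-
#' population event-rate table coupled linearly to mean GRS.
#'
#' @return nested configuration list
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    snps = list(n = 60L, block_size = 5L, rho = 0.6),
    cline = list(base_freq = 0.3, lat_slope_risk = 0.03,
                 lat_slope_other = 0, lon_slope = 0),
    disease = list(n_causal = 4L, beta_min = 0.2, beta_max = 0.5,
                   beta0 = -2.5, beta_age = 0.01, beta_sex = 0.2),
    studies = list(n = 3L, n_cases = 2000L, n_controls = 2000L,
                   replicates = 2L, missing_rate = 0.02),
    populations = list(n = 30L, n_per_pop = 40L,
                       lat_range = c(35, 65), lon_range = c(-10, 30)),
    qc = list(min_call_rate = 0.75, min_imputation_quality = 0.6,
              ld_prefilter_r2 = 0.8),
    selection = list(p_max = 0.1, prune_r2 = 0.2),
    spatial = list(weights = "inverse-distance", n_perm = 999L,
                   n_classes = 6L),
    kriging = list(n_lags = 10L, n_grid = 100L),
    eco = list(n_populations = 11L, intercept = 20, slope = 30,
               noise_sd = 5)
  )
}

#' Read and validate a pipeline configuration
#'
#' Reads a YAML file, overlays it on [defaultPipelineConfig], rejects
#' unknown keys, and checks all thresholds against their documented
#' ranges. All validation errors are reported at once.
#'
#' @param path YAML file (NULL returns the validated defaults)
#' @param overrides named list applied after the file (e.g. from CLI
#'   flags)
#' @return validated configuration list
#' @export
readPipelineConfig <- function(path = NULL, overrides = list()) {
  cfg <- defaultPipelineConfig()
  mergeIn <- function(base, user, prefix, errs) {
    for (k in names(user)) {
      if (!k %in% names(base)) {
        errs <<- c(errs, sprintf("unknown key '%s%s'", prefix, k))
        next
      }
      if (is.list(base[[k]]) && is.list(user[[k]])) {
        base[[k]] <- mergeIn(base[[k]], user[[k]],
                             paste0(prefix, k, "."), errs)
      } else base[[k]] <- user[[k]]
    }
    base
  }
  errs <- character()
  if (!is.null(path)) cfg <- mergeIn(cfg, read_yaml(path), "", errs)
  if (length(overrides)) cfg <- mergeIn(cfg, overrides, "", errs)
  inRange <- function(x, lo, hi, what, loOpen = FALSE, hiOpen = FALSE) {
    bad <- !is.numeric(x) || length(x) != 1 || !is.finite(x) ||
      (if (loOpen) x <= lo else x < lo) ||
      (if (hiOpen) x >= hi else x > hi)
    if (bad) errs <<- c(errs, sprintf("%s must be in %s%g, %g%s", what,
                                      if (loOpen) "(" else "[", lo, hi,
                                      if (hiOpen) ")" else "]"))
  }
  inRange(cfg$qc$min_call_rate, 0, 1, "qc.min_call_rate")
  inRange(cfg$qc$min_imputation_quality, 0, 1, "qc.min_imputation_quality")
  inRange(cfg$qc$ld_prefilter_r2, 0, 1, "qc.ld_prefilter_r2")
  inRange(cfg$selection$p_max, 0, 1, "selection.p_max", loOpen = TRUE)
  inRange(cfg$selection$prune_r2, 0, 1, "selection.prune_r2")
  inRange(cfg$snps$rho, 0, 1, "snps.rho", hiOpen = TRUE)
  inRange(cfg$studies$missing_rate, 0, 1, "studies.missing_rate",
          hiOpen = TRUE)
  if (cfg$spatial$n_perm < 99) errs <- c(errs, "spatial.n_perm must be >= 99")
  if (length(errs))
    ecoStop("ecogrs_config_error",
            paste0("invalid configuration:\n  ",
                   paste(errs, collapse = "\n  ")))
  cfg
}

# Build the generative specs (cline, LD blocks, disease model, panel
# populations) implied by a configuration; deterministic given the seed.
buildSimSpecs <- function(cfg) {
  nSnp <- cfg$snps$n
  causal <- with_seed(deriveSeed(cfg$seed, 11L),
                      sort(sample.int(nSnp, cfg$disease$n_causal)))
  beta <- rep(0, nSnp)
  beta[causal] <- seq(cfg$disease$beta_min, cfg$disease$beta_max,
                      length.out = cfg$disease$n_causal)
  latMid <- mean(cfg$populations$lat_range)
  b <- rep(cfg$cline$lat_slope_other, nSnp)
  b[causal] <- cfg$cline$lat_slope_risk
  # intercept chosen so the frequency at mid-latitude equals base_freq
  a <- log(cfg$cline$base_freq / (1 - cfg$cline$base_freq)) - b * latMid
  nBlocks <- ceiling(nSnp / cfg$snps$block_size)
  sizes <- rep(cfg$snps$block_size, nBlocks)
  sizes[nBlocks] <- nSnp - sum(sizes[-nBlocks])
  pops <- with_seed(deriveSeed(cfg$seed, 12L), data.frame(
    name = sprintf("pop%02d", seq_len(cfg$populations$n)),
    lat = runif(cfg$populations$n, cfg$populations$lat_range[1],
                cfg$populations$lat_range[2]),
    lon = runif(cfg$populations$n, cfg$populations$lon_range[1],
                cfg$populations$lon_range[2]),
    n = cfg$populations$n_per_pop, stringsAsFactors = FALSE))
  list(cline = ClineSpec(a, b, rep(cfg$cline$lon_slope, nSnp)),
       blocks = LDBlockSpec(sizes, cfg$snps$rho),
       disease = DiseaseModelSpec(cfg$disease$beta0, beta,
                                  cfg$disease$beta_age,
                                  cfg$disease$beta_sex),
       pops = pops, causal = causal)
}

#' Run the full pipeline
#'
#' Executes simulation, QC, per-study association scans over replicate
#' dosage sets, fixed-effect meta-analysis, GRS construction and
#' prediction metrics, population scoring, spatial autocorrelation,
#' kriging and ecological regression, writing each stage's outputs as
#' TSV (plus VCF and an ESRI ASCII grid) into `outDir`. A manifest with
#' content hashes of every output is written even if a stage fails;
#' identical config + seed gives byte-identical outputs.
#'
#' @param config configuration list from [readPipelineConfig]
#' @param outDir output directory (created if absent)
#' @return the manifest data.frame (file, stage, hash), invisibly
#' @export
runPipeline <- function(config = readPipelineConfig(), outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(file = character(), stage = character(),
                         stringsAsFactors = FALSE)
  emit <- function(stage, file) {
    manifest <<- rbind(manifest, data.frame(file = file, stage = stage,
                                            stringsAsFactors = FALSE))
  }
  writeManifest <- function() {
    manifest$hash <- as.character(tools::md5sum(
      file.path(outDir, manifest$file)))
    writeTsv(manifest, file.path(outDir, "manifest.tsv"))
    manifest
  }
  on.exit(writeManifest())
  seed <- config$seed
  spec <- buildSimSpecs(config)

  ## stage 1: simulate panel and studies
  panel <- drawPopulationPanel(spec$pops, spec$cline, spec$blocks,
                               seed = deriveSeed(seed, 21L))
  writeGenotypeVcf(panel, file.path(outDir, "panel.vcf"))
  writeSampleMeta(panel, file.path(outDir, "panel_samples.tsv"))
  emit("simulate", "panel.vcf"); emit("simulate", "panel_samples.tsv")
  studyNames <- sprintf("study%d", seq_len(config$studies$n))
  studyLat <- seq(config$populations$lat_range[1],
                  config$populations$lat_range[2],
                  length.out = config$studies$n)
  studies <- lapply(seq_along(studyNames), function(i) {
    f <- alleleFreqAt(spec$cline, studyLat[i],
                      mean(config$populations$lon_range))[1, ]
    drawCaseControlStudy(f, spec$disease, config$studies$n_cases,
                         config$studies$n_controls, blocks = spec$blocks,
                         seed = deriveSeed(seed, 30L + i),
                         study = studyNames[i])
  })

  ## stage 2+3: per-replicate QC and association scan, per study
  scans <- vector("list", config$studies$replicates)
  keptSnps <- NULL
  for (r in seq_len(config$studies$replicates)) {
    scans[[r]] <- lapply(seq_along(studies), function(i) {
      ds <- applyMissingness(studies[[i]], config$studies$missing_rate,
                             seed = deriveSeed(seed, 100L * r + i))
      ds <- filterVariants(ds, config$qc$min_call_rate)$dataset
      ds <- filterSamples(ds, config$qc$min_call_rate)$dataset
      ds <- imputeExpectedDosage(ds, byPopulation = FALSE)
      if (i == 1 && r == 1)
        keptSnps <<- ldPrefilter(ds, config$qc$ld_prefilter_r2)$kept
      associationScan(ds, snps = intersect(keptSnps, rownames(ds)))
    })
    assocTab <- do.call(rbind, scans[[r]])
    writeTsv(assocTab, file.path(outDir, sprintf("assoc_rep%d.tsv", r)))
    emit("assoc", sprintf("assoc_rep%d.tsv", r))
  }

  ## stage 4: meta-analysis per replicate
  metas <- lapply(seq_len(config$studies$replicates), function(r) {
    al <- alignAlleles(scans[[r]])
    metaFixedEffects(al$aligned)
  })
  for (r in seq_along(metas)) {
    writeTsv(metas[[r]], file.path(outDir, sprintf("meta_rep%d.tsv", r)))
    emit("meta", sprintf("meta_rep%d.tsv", r))
  }

  ## stage 5: GRS model, individual scores, prediction metrics
  model <- selectScoreSnps(metas, config$selection$p_max,
                           config$selection$prune_r2, ldReference = panel)
  writeTsv(modelSnps(model, keptOnly = FALSE),
           file.path(outDir, "model.tsv"))
  emit("grs", "model.tsv")
  pm <- do.call(rbind, lapply(seq_along(studies), function(i) {
    ss <- computeScores(studies[[i]], model, groupBy = "study")
    m <- predictionMetrics(phenotype(studies[[i]]), scoreTable(ss)$grs)
    data.frame(study = studyNames[i], nagelkerke_r2 = m$nagelkerkeR2,
               auc = m$auc, auc_lo = m$aucCi[1], auc_hi = m$aucCi[2],
               n_cases = m$nCases, n_controls = m$nControls)
  }))
  writeTsv(pm, file.path(outDir, "prediction_metrics.tsv"))
  emit("grs", "prediction_metrics.tsv")
  panelScores <- computeScores(panel, model, groupBy = "population")
  writeTsv(scoreTable(panelScores), file.path(outDir, "scores.tsv"))
  popTab <- merge(groupSummary(panelScores),
                  setNames(spec$pops[, c("name", "lat", "lon")],
                           c("group", "lat", "lon")), by = "group")
  popTab <- popTab[order(popTab$group), ]
  writeTsv(popTab, file.path(outDir, "pop_scores.tsv"))
  emit("grs", "scores.tsv"); emit("grs", "pop_scores.tsv")

  ## stage 6: spatial autocorrelation of population mean GRS
  W <- buildWeights(popTab$lat, popTab$lon, scheme = config$spatial$weights)
  auto <- do.call(rbind, lapply(c("moran", "geary"), function(st) {
    r <- randomizationTest(popTab$mean, W, st,
                           nPerm = config$spatial$n_perm,
                           seed = deriveSeed(seed, 61L))
    data.frame(statistic = st, observed = r@observed,
               perm_mean = r@permMean, p = r@p, n_perm = r@nPerm,
               alternative = r@alternative)
  }))
  writeTsv(auto, file.path(outDir, "autocorrelation.tsv"))
  cg <- correlogram(popTab$lat, popTab$lon, popTab$mean,
                    nClasses = config$spatial$n_classes,
                    nPerm = config$spatial$n_perm,
                    seed = deriveSeed(seed, 62L))
  writeTsv(cg, file.path(outDir, "correlogram.tsv"))
  emit("spatial", "autocorrelation.tsv"); emit("spatial", "correlogram.tsv")

  ## stage 7: kriging
  emp <- empiricalSemivariogram(popTab$lat, popTab$lon, popTab$mean,
                                nLags = config$kriging$n_lags)
  vm <- fitSpherical(emp)
  writeTsv(data.frame(c0 = vm@c0, c1 = vm@c1, range_km = vm@a),
           file.path(outDir, "variogram.tsv"))
  grid <- ordinaryKrige(popTab$lat, popTab$lon, popTab$mean, vm,
                        nGrid = config$kriging$n_grid)
  writeAsciiGrid(grid, file.path(outDir, "grs_surface.asc"))
  emit("kriging", "variogram.tsv"); emit("kriging", "grs_surface.asc")

  ## stage 8: ecological regression against simulated event rates
  mon <- head(popTab, config$eco$n_populations)
  eco <- do.call(rbind, lapply(c("men", "women"), function(sx) {
    tab <- drawEventRateTable(setNames(mon$mean, mon$group),
                              config$eco$intercept, config$eco$slope,
                              config$eco$noise_sd,
                              seed = deriveSeed(seed,
                                                if (sx == "men") 71L else 72L))
    cbind(tab[, "population", drop = FALSE], sex_stratum = sx,
          tab[, c("mean_grs", "event_rate")],
          lat = mon$lat, lon = mon$lon)
  }))
  writeEcoTable(eco, file.path(outDir, "eco.tsv"))
  rep <- ecoReport(eco, predictors = c("mean_grs", "lat"),
                   outlierPolicy = "exclude-and-refit")
  ecoTab <- do.call(rbind, lapply(names(rep), function(sx) {
    u <- rep[[sx]]$univariate
    u$stratum <- sx
    u$model_adj_r2 <- if (is.null(rep[[sx]]$multivariate)) NA_real_
                      else rep[[sx]]$multivariate$adjR2
    u$excluded <- paste(rep[[sx]]$excluded, collapse = ",")
    u
  }))
  writeEcoTable(ecoTab, file.path(outDir, "eco_report.tsv"))
  emit("ecoreg", "eco.tsv"); emit("ecoreg", "eco_report.tsv")

  on.exit()
  invisible(writeManifest())
}
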