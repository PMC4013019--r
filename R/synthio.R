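#' Specify a logit-linear allele-frequency cline
#'
#' @param a per-SNP intercept (logit units)
#' @param b per-SNP latitude slope (logit per degree north)
#' @param c per-SNP longitude slope (logit per degree east)
#' @return A [ClineSpec-class]
#' @export
ClineSpec <- function(a, b = rep(0, length(a)), c = rep(0, length(a))) {
  new("ClineSpec", a = as.numeric(a), b = as.numeric(b), c = as.numeric(c))
}

#' Specify block-wise LD structure
#'
#' @param blockSizes sizes of contiguous SNP blocks (they partition
#'   `1:sum(blockSizes)`)
#' @param rho within-block latent AR(1) correlation, in \[0, 1)
#' @return An [LDBlockSpec-class]
#' @export
LDBlockSpec <- function(blockSizes, rho = 0) {
  ends <- cumsum(blockSizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  blocks <- mapply(seq.int, starts, ends, SIMPLIFY = FALSE)
  new("LDBlockSpec", blocks = blocks, rho = rho)
}

#' Specify a logistic disease model
#'
#' @param beta0 baseline log-odds
#' @param beta per-SNP log odds ratio per alternate-allele copy
#' @param betaAge log odds ratio per year of age
#' @param betaSex log odds ratio for sex = 1
#' @return A [DiseaseModelSpec-class]
#' @export
DiseaseModelSpec <- function(beta0, beta, betaAge = 0, betaSex = 0) {
  new("DiseaseModelSpec", beta0 = beta0, beta = as.numeric(beta),
      betaAge = betaAge, betaSex = betaSex)
}

#' Alternate-allele frequencies under a geographic cline
#'
#' Evaluates `plogis(a_s + b_s * lat + c_s * lon)` for every SNP at every
#' coordinate.
#'
#' @param cline a [ClineSpec-class]
#' @param lat,lon coordinates in decimal degrees (equal length)
#' @return A `length(lat)` x `nSnps` matrix of frequencies in (0, 1).
#' @export
alleleFreqAt <- function(cline, lat, lon) {
  checkFinite(lat, "lat"); checkFinite(lon, "lon")
  if (length(lat) != length(lon))
    ecoStop("ecogrs_invalid_argument", "lat and lon must have equal length")
  eta <- outer(lat, cline@b) + outer(lon, cline@c)
  eta <- sweep(eta, 2, cline@a, "+")
  invLogit(eta)
}

# Default SNP map: ids, three contigs mirroring the candidate-gene regions
# on chromosomes 7, 12 and 17, positions 5 kb apart within each contig.
makeSnpInfo <- function(nSnps) {
  n7 <- round(nSnps * 13 / 78)
  n12 <- round(nSnps * 43 / 78)
  n17 <- max(0L, nSnps - n7 - n12)
  n12 <- nSnps - n7 - n17
  chrom <- rep(c("7", "12", "17"), times = c(n7, n12, n17))
  pos <- unlist(lapply(c(n7, n12, n17), function(k) 1e6 + 5000 * seq_len(k)))
  data.frame(snp = sprintf("snp%03d", seq_len(nSnps)),
             chrom = chrom, pos = as.integer(pos),
             ref = "A", alt = "G", stringsAsFactors = FALSE)
}

# Draw nHap haplotypes for SNPs with alternate frequencies p under a latent
# Gaussian AR(1) copula within each LD block. Marginal frequencies are exact
# (allele is alternate iff the latent N(0,1) value < qnorm(p)).
drawHaplotypes <- function(nHap, p, blocks) {
  nSnp <- length(p)
  Z <- matrix(0, nHap, nSnp)
  rho <- blocks@rho
  for (blk in blocks@blocks) {
    m <- length(blk)
    E <- matrix(rnorm(nHap * m), nHap, m)
    Z[, blk[1]] <- E[, 1]
    if (m > 1) {
      s <- sqrt(1 - rho^2)
      for (k in 2:m)
        Z[, blk[k]] <- rho * Z[, blk[k - 1]] + s * E[, k]
    }
  }
  # haplotype matrix: 1 = alternate allele
  sweep(Z, 2, qnorm(p), "<") * 1L
}

drawGenotypes <- function(n, p, blocks) {
  drawHaplotypes(n, p, blocks) + drawHaplotypes(n, p, blocks)
}

#' Draw a multi-population genotype panel
#'
#' Genotypes for each population are drawn from Hardy-Weinberg proportions
#' at the cline frequencies of its coordinates, with within-block LD from
#' a latent AR(1) Gaussian copula. Haplotypes are independent across
#' blocks and individuals; each genotype is the sum of two haplotypes.
#'
#' @param pops data.frame with columns `name`, `lat`, `lon`, `n`
#' @param cline a [ClineSpec-class]
#' @param blocks an [LDBlockSpec-class] covering the cline's SNPs
#' @param seed integer seed (the draw is deterministic given the seed)
#' @param snpInfo optional SNP table (default [makeSnpInfo] layout)
#' @return A [GenotypeExperiment-class] without phenotype.
#' @export
drawPopulationPanel <- function(pops, cline, blocks, seed, snpInfo = NULL) {
  if (nrow(pops) == 0)
    ecoStop("ecogrs_invalid_argument", "population list is empty")
  if (any(abs(pops$lat) > 90) || any(abs(pops$lon) > 180) || any(pops$n < 1))
    ecoStop("ecogrs_invalid_argument", "invalid population coordinates or sizes")
  nSnp <- length(cline@a)
  if (length(unlist(blocks@blocks)) != nSnp)
    ecoStop("ecogrs_invalid_argument", "LD blocks do not cover the SNP range")
  if (is.null(snpInfo)) snpInfo <- makeSnpInfo(nSnp)
  freqs <- alleleFreqAt(cline, pops$lat, pops$lon)
  with_seed(seed, {
    G <- vector("list", nrow(pops))
    for (i in seq_len(nrow(pops)))
      G[[i]] <- drawGenotypes(pops$n[i], freqs[i, ], blocks)
    G <- do.call(rbind, G)
  })
  sampleInfo <- data.frame(
    sample_id = sprintf("%s_%03d", rep(pops$name, pops$n),
                        unlist(lapply(pops$n, seq_len))),
    status = NA_integer_,
    age = NA_real_, sex = NA_integer_,
    population = rep(pops$name, pops$n),
    study = "panel",
    lat = rep(pops$lat, pops$n), lon = rep(pops$lon, pops$n),
    stringsAsFactors = FALSE)
  GenotypeExperiment(t(G), snpInfo, sampleInfo)
}

#' Draw a case-control study from a logistic disease model
#'
#' Individuals are sampled with genotypes at the given frequencies (LD as
#' in [drawPopulationPanel]), age ~ Normal, sex ~ Bernoulli, and case
#' status ~ Bernoulli(plogis(beta0 + sum(beta_s g_s) + betaAge age +
#' betaSex sex)). Sampling continues in batches until both the case and
#' control quotas are filled; the total number of attempts is capped at
#' 100 * (nCases + nControls).
#'
#' @param freqs per-SNP alternate-allele frequency
#' @param model a [DiseaseModelSpec-class] with one `beta` per SNP
#' @param nCases,nControls quotas (>= 1)
#' @param ageMean,ageSd age distribution in years
#' @param sexProb probability of sex = 1
#' @param blocks an [LDBlockSpec-class]
#' @param seed integer seed
#' @param study study label stored in the sample metadata
#' @param snpInfo optional SNP table
#' @return A [GenotypeExperiment-class] with exactly `nCases` cases and
#'   `nControls` controls.
#' @export
drawCaseControlStudy <- function(freqs, model, nCases, nControls,
                                 ageMean = 60, ageSd = 10, sexProb = 0.5,
                                 blocks, seed, study = "study1",
                                 snpInfo = NULL) {
  if (nCases < 1 || nControls < 1)
    ecoStop("ecogrs_invalid_argument", "case and control quotas must be >= 1")
  nSnp <- length(freqs)
  if (length(model@beta) != nSnp)
    ecoStop("ecogrs_invalid_argument",
            "disease model dimension does not match number of SNPs")
  checkProb(freqs, "freqs")
  if (is.null(snpInfo)) snpInfo <- makeSnpInfo(nSnp)
  cap <- 100 * (nCases + nControls)
  batch <- min(cap, max(2000L, 2L * (nCases + nControls)))
  with_seed(seed, {
    caseG <- list(); ctrlG <- list()
    caseCov <- list(); ctrlCov <- list()
    gotCase <- 0L; gotCtrl <- 0L; attempts <- 0L
    while ((gotCase < nCases || gotCtrl < nControls) && attempts < cap) {
      b <- min(batch, cap - attempts)
      attempts <- attempts + b
      G <- drawGenotypes(b, freqs, blocks)
      age <- rnorm(b, ageMean, ageSd)
      sex <- rbinom(b, 1, sexProb)
      eta <- model@beta0 + as.vector(G %*% model@beta) +
        model@betaAge * age + model@betaSex * sex
      y <- rbinom(b, 1, invLogit(eta))
      if (gotCase < nCases && any(y == 1)) {
        take <- which(y == 1)[seq_len(min(sum(y == 1), nCases - gotCase))]
        caseG[[length(caseG) + 1L]] <- G[take, , drop = FALSE]
        caseCov[[length(caseCov) + 1L]] <- cbind(age[take], sex[take])
        gotCase <- gotCase + length(take)
      }
      if (gotCtrl < nControls && any(y == 0)) {
        take <- which(y == 0)[seq_len(min(sum(y == 0), nControls - gotCtrl))]
        ctrlG[[length(ctrlG) + 1L]] <- G[take, , drop = FALSE]
        ctrlCov[[length(ctrlCov) + 1L]] <- cbind(age[take], sex[take])
        gotCtrl <- gotCtrl + length(take)
      }
    }
  })
  if (gotCase < nCases || gotCtrl < nControls)
    ecoStop("ecogrs_sampling_cap",
            sprintf(paste0("attempt cap (%d draws) reached with %d/%d cases ",
                           "and %d/%d controls; the disease model is too ",
                           "extreme for outcome-conditional sampling"),
                    cap, gotCase, nCases, gotCtrl, nControls))
  G <- rbind(do.call(rbind, caseG), do.call(rbind, ctrlG))
  cov <- rbind(do.call(rbind, caseCov), do.call(rbind, ctrlCov))
  sampleInfo <- data.frame(
    sample_id = sprintf("%s_%05d", study, seq_len(nCases + nControls)),
    status = rep(c(1L, 0L), c(nCases, nControls)),
    age = cov[, 1], sex = as.integer(cov[, 2]),
    population = study, study = study,
    stringsAsFactors = FALSE)
  GenotypeExperiment(t(G), snpInfo, sampleInfo)
}

#' Mask genotypes missing completely at random
#'
#' Each observed genotype is independently set missing with the given
#' probability; the missingness is recorded as `NA` in the dosage matrix.
#'
#' @param ds a [GenotypeExperiment-class]
#' @param rate missingness probability in \[0, 1)
#' @param seed integer seed
#' @return The dataset with entries masked.
#' @export
applyMissingness <- function(ds, rate, seed) {
  checkProb(rate, "rate", openRight = TRUE)
  if (rate == 0) return(ds)
  d <- dosage(ds)
  obs <- which(!is.na(d))
  with_seed(seed, {
    hit <- obs[runif(length(obs)) < rate]
  })
  d[hit] <- NA_real_
  se <- as(ds, "SummarizedExperiment")
  assays(se)$dosage <- d
  new("GenotypeExperiment", se)
}

#' Draw a population event-rate table coupled to mean GRS
#'
#' Event rate per population = intercept + slope * meanScore + Normal(0,
#' noiseSd). Negative draws are truncated at 0 with a warning (rates are
#' physical quantities).
#'
#' @param meanScores named numeric vector of per-population mean GRS
#' @param intercept baseline rate (events per 100,000 per year)
#' @param slope rate change per score unit
#' @param noiseSd Normal noise SD (>= 0)
#' @param seed integer seed
#' @return data.frame with columns `population`, `mean_grs`, `event_rate`.
#' @export
drawEventRateTable <- function(meanScores, intercept, slope, noiseSd, seed) {
  if (length(meanScores) == 0)
    ecoStop("ecogrs_invalid_argument", "population list is empty")
  if (noiseSd < 0)
    ecoStop("ecogrs_invalid_argument", "noiseSd must be >= 0")
  with_seed(seed, {
    rate <- intercept + slope * meanScores + rnorm(length(meanScores), 0, noiseSd)
  })
  if (any(rate < 0)) {
    warning("negative simulated event rates truncated at 0")
    rate[rate < 0] <- 0
  }
  data.frame(population = names(meanScores) %||%
               sprintf("pop%02d", seq_along(meanScores)),
             mean_grs = as.numeric(meanScores),
             event_rate = as.numeric(rate),
             stringsAsFactors = FALSE, row.names = NULL)
}
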