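# Fixtures built in code: small genotype datasets and spatial frames.

# Dataset from an explicit dosage matrix (SNPs x samples); fractional or
# continuous entries can be allowed by marking everything imputed.
toyDataset <- function(d, status = NULL, population = NULL,
                       allImputed = FALSE, ref = NULL, alt = NULL,
                       impQuality = NULL) {
  d <- as.matrix(d)
  nS <- nrow(d); nI <- ncol(d)
  info <- data.frame(snp = sprintf("s%02d", seq_len(nS)),
                     chrom = "7", pos = 1000L * seq_len(nS),
                     ref = ref %||% rep("A", nS),
                     alt = alt %||% rep("G", nS),
                     stringsAsFactors = FALSE)
  if (!is.null(impQuality)) info$impQuality <- impQuality
  meta <- data.frame(sample_id = sprintf("i%03d", seq_len(nI)),
                     status = status %||% rep(NA_integer_, nI),
                     age = rep(60, nI), sex = rep(0L, nI),
                     population = population %||% rep("p1", nI),
                     study = "toy", stringsAsFactors = FALSE)
  im <- matrix(allImputed & !is.na(d), nS, nI)
  ecogrs::GenotypeExperiment(d, info, meta, imputed = im)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random spatial frame: n sites on a European-like window.
randomFrame <- function(n, seed) {
  withr::with_seed(seed, data.frame(
    lat = runif(n, 36, 64), lon = runif(n, -8, 28),
    value = rnorm(n)))
}

# A simple 4-SNP risk model with alternate alleles as risk alleles.
toyModel <- function(snps = sprintf("s%02d", 1:4), risk = rep("G", 4)) {
  tab <- data.frame(snp = snps, risk_allele = risk, weight = 1,
                    min_p = 0.01, kept = TRUE, pruned_by = NA_character_,
                    stringsAsFactors = FALSE)
  new("RiskScoreModel", snps = tab,
      thresholds = list(pMax = 0.1, r2Max = 0.2, nReplicates = 1L))
}
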