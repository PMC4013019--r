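# Quality control: call rates, MAF, Hardy-Weinberg exact test, LD r2,
# threshold filters, and expected-dosage imputation.

# Hard genotype calls only (not imputed, not missing).
hardCallMask <- function(ds) !is.na(dosage(ds)) & !imputedMask(ds)

#' Summarize genotype quality control
#'
#' Computes per-SNP and per-sample call rates over hard genotype calls,
#' per-SNP minor allele frequency, Hardy-Weinberg exact p-values from the
#' observed genotype counts, and the polymorphic flag (MAF > 0). SNPs with
#' no observed genotype get call rate 0 and undefined (`NA`) MAF and HWE p.
#'
#' @param ds a [GenotypeExperiment-class]
#' @return A [QCReport-class]
#' @export
summarizeQC <- function(ds) {
  if (nrow(ds) == 0 || ncol(ds) == 0)
    ecoStop("ecogrs_invalid_argument", "dataset is empty")
  d <- dosage(ds)
  hard <- hardCallMask(ds)
  nObs <- rowSums(hard)
  altFreq <- ifelse(nObs > 0, rowSums(d * hard, na.rm = TRUE) / (2 * nObs), NA)
  maf <- pmin(altFreq, 1 - altFreq)
  hwe <- rep(NA_real_, nrow(d))
  for (i in which(nObs > 0)) {
    g <- round(d[i, hard[i, ]])
    hwe[i] <- hweExactP(sum(g == 0), sum(g == 1), sum(g == 2))
  }
  info <- snpInfo(ds)
  snpStats <- data.frame(
    snp = rownames(ds),
    call_rate = nObs / ncol(d),
    n_obs = nObs,
    alt_freq = altFreq,
    maf = maf,
    hwe_p = hwe,
    polymorphic = !is.na(maf) & maf > 0,
    stringsAsFactors = FALSE, row.names = NULL)
  if ("impQuality" %in% colnames(info))
    snpStats$imp_quality <- info$impQuality
  sampleStats <- data.frame(
    sample_id = colnames(ds),
    call_rate = colSums(hard) / nrow(d),
    stringsAsFactors = FALSE, row.names = NULL)
  new("QCReport", snpStats = snpStats, sampleStats = sampleStats,
      removed = data.frame(item = character(), kind = character(),
                           reason = character(), stringsAsFactors = FALSE))
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test on genotype counts: given the observed allele
#' counts, all heterozygote counts of the right parity are enumerated and
#' the p-value is the summed probability of configurations no more likely
#' than the observed one (the standard two-sided exact definition; no
#' mid-p correction).
#'
#' @param nHomRef,nHet,nHomAlt genotype counts (hom-ref, het, hom-alt)
#' @return p-value in (0, 1\]
#' @export
hweExactP <- function(nHomRef, nHet, nHomAlt) {
  counts <- c(nHomRef, nHet, nHomAlt)
  if (any(counts < 0) || any(counts != round(counts)))
    ecoStop("ecogrs_invalid_argument", "genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1)
    ecoStop("ecogrs_undefined_result", "all genotype counts are zero")
  nRef <- 2 * nHomRef + nHet
  nAlt <- 2 * nHomAlt + nHet
  rare <- min(nRef, nAlt)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  homRare <- (rare - hets) / 2
  homCommon <- (max(nRef, nAlt) - hets) / 2
  lp <- hets * log(2) - lfactorial(hets) - lfactorial(homRare) -
    lfactorial(homCommon)
  lp <- lp - max(lp)
  pr <- exp(lp) / sum(exp(lp))
  pObs <- pr[match(nHet, hets)]
  min(1, sum(pr[pr <= pObs * (1 + 1e-12)]))
}

#' Pairwise LD as squared dosage correlation
#'
#' Composite LD: the squared Pearson correlation of the two dosage vectors
#' over pairwise-complete samples (no phase information is used).
#'
#' @param ds a [GenotypeExperiment-class]
#' @param snpI,snpJ SNP ids or indices
#' @return r2 in \[0, 1\]
#' @export
ldR2 <- function(ds, snpI, snpJ) {
  d <- dosage(ds)
  i <- if (is.character(snpI)) match(snpI, rownames(d)) else snpI
  j <- if (is.character(snpJ)) match(snpJ, rownames(d)) else snpJ
  xi <- d[i, ]; xj <- d[j, ]
  ok <- !is.na(xi) & !is.na(xj)
  if (sum(ok) < 2)
    ecoStop("ecogrs_undefined_result", "fewer than 2 pairwise-complete samples")
  if (var(xi[ok]) == 0 || var(xj[ok]) == 0)
    ecoStop("ecogrs_undefined_result", "zero dosage variance at one SNP")
  cor(xi[ok], xj[ok])^2
}

# Full pairwise r2 matrix over a SNP subset (pairwise-complete dosages).
ldMatrix <- function(ds, snps = rownames(ds)) {
  d <- t(dosage(ds)[snps, , drop = FALSE])
  r <- suppressWarnings(cor(d, use = "pairwise.complete.obs"))
  r^2
}

#' Filter SNPs on call rate, polymorphism and imputation quality
#'
#' Removes SNPs with call rate strictly below `minCallRate`, monomorphic
#' SNPs (when `requirePolymorphic`), and - when `minImputationQuality` is
#' given and the dataset carries quality scores - SNPs whose score is not
#' strictly above the threshold. Each removed SNP gets one primary reason
#' code (call rate checked first, then polymorphism, then quality).
#'
#' @param ds a [GenotypeExperiment-class]
#' @param minCallRate call-rate threshold (default 0.75)
#' @param requirePolymorphic drop monomorphic SNPs (default TRUE)
#' @param minImputationQuality optional quality threshold (keep strictly
#'   above; the conventional cutoff is 0.6)
#' @return `list(dataset =, report =)` with the sample set unchanged.
#' @export
filterVariants <- function(ds, minCallRate = 0.75, requirePolymorphic = TRUE,
                           minImputationQuality = NULL) {
  checkProb(minCallRate, "minCallRate")
  qc <- summarizeQC(ds)
  st <- qc@snpStats
  reason <- rep(NA_character_, nrow(st))
  reason[is.na(reason) & st$call_rate < minCallRate] <- "low_call_rate"
  if (requirePolymorphic)
    reason[is.na(reason) & !st$polymorphic] <- "monomorphic"
  if (!is.null(minImputationQuality)) {
    checkProb(minImputationQuality, "minImputationQuality")
    if (!"imp_quality" %in% colnames(st))
      ecoStop("ecogrs_invalid_argument",
              "no imputation-quality scores in dataset")
    reason[is.na(reason) & !(st$imp_quality > minImputationQuality)] <-
      "low_imputation_quality"
  }
  drop <- !is.na(reason)
  removed <- data.frame(item = st$snp[drop],
                        kind = rep("snp", sum(drop)),
                        reason = reason[drop], stringsAsFactors = FALSE)
  report <- new("QCReport", snpStats = st, sampleStats = qc@sampleStats,
                removed = removed)
  if (all(drop))
    ecoStop("ecogrs_empty_result", "all SNPs removed by variant filters",
            data = report)
  list(dataset = ds[!drop, ], report = report)
}

#' Filter samples on call rate
#'
#' Removes samples with call rate strictly below the threshold; the SNP
#' set is unchanged.
#'
#' @param ds a [GenotypeExperiment-class]
#' @param minCallRate call-rate threshold (default 0.75)
#' @return `list(dataset =, report =)`
#' @export
filterSamples <- function(ds, minCallRate = 0.75) {
  checkProb(minCallRate, "minCallRate")
  qc <- summarizeQC(ds)
  st <- qc@sampleStats
  drop <- st$call_rate < minCallRate
  removed <- data.frame(item = st$sample_id[drop],
                        kind = rep("sample", sum(drop)),
                        reason = rep("low_call_rate", sum(drop)),
                        stringsAsFactors = FALSE)
  report <- new("QCReport", snpStats = qc@snpStats, sampleStats = st,
                removed = removed)
  if (all(drop))
    ecoStop("ecogrs_empty_result", "all samples removed by call-rate filter",
            data = report)
  list(dataset = ds[, !drop], report = report)
}

#' Expected-dosage imputation of missing genotypes
#'
#' Replaces each missing entry by `2 * p`, where `p` is the observed
#' alternate-allele frequency among hard calls within the sample's group
#' (its population when `byPopulation`, otherwise the whole dataset).
#' Imputed entries are flagged in the `imputed` assay; observed entries
#' are untouched. SNPs with no observed genotype in a group stay missing
#' and are reported in a warning.
#'
#' @param ds a [GenotypeExperiment-class]
#' @param byPopulation group by population label (default TRUE)
#' @return The imputed dataset.
#' @export
imputeExpectedDosage <- function(ds, byPopulation = TRUE) {
  checkFlag(byPopulation, "byPopulation")
  d <- dosage(ds)
  im <- imputedMask(ds)
  if (!anyNA(d)) return(ds)
  groups <- if (byPopulation) population(ds) else rep("all", ncol(ds))
  groups[is.na(groups)] <- "all"
  unfilled <- character()
  for (g in unique(groups)) {
    cols <- which(groups == g)
    sub <- d[, cols, drop = FALSE]
    hard <- !is.na(sub) & !im[, cols, drop = FALSE]
    nObs <- rowSums(hard)
    p <- rowSums(sub * hard, na.rm = TRUE) / (2 * nObs)
    for (i in seq_len(nrow(sub))) {
      miss <- is.na(sub[i, ])
      if (!any(miss)) next
      if (nObs[i] == 0) {
        unfilled <- c(unfilled, sprintf("%s@%s", rownames(d)[i], g))
        next
      }
      d[i, cols[miss]] <- 2 * p[i]
      im[i, cols[miss]] <- TRUE
    }
  }
  if (length(unfilled))
    warning("no observed genotypes to impute from: ",
            paste(unfilled, collapse = ", "))
  se <- as(ds, "SummarizedExperiment")
  assays(se)$dosage <- d
  assays(se)$imputed <- im
  new("GenotypeExperiment", se)
}

setMethod("show", "QCReport", function(object) {
  cat(sprintf("QCReport: %d SNPs, %d samples; %d item(s) removed\n",
              nrow(object@snpStats), nrow(object@sampleStats),
              nrow(object@removed)))
  if (nrow(object@removed))
    print(table(object@removed$reason))
})

#' @rdname QCReport-accessors
#' @param x a [QCReport-class]
#' @export
snpStats <- function(x) x@snpStats

#' Accessors for QCReport
#'
#' `snpStats()`, `sampleStats()` and `removedItems()` return the per-SNP
#' table, the per-sample table and the removal log.
#'
#' @name QCReport-accessors
#' @rdname QCReport-accessors
#' @export
sampleStats <- function(x) x@sampleStats

#' @rdname QCReport-accessors
#' @export
removedItems <- function(x) x@removed
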