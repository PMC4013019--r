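# Genetic risk score construction and interindividual prediction metrics.

#' Select risk SNPs for the genetic risk score
#'
#' Candidates are SNPs with meta-analysis p below `pMax` in every
#' replicate dataset and a concordant risk allele (the allele with
#' pooled beta > 0) across replicates. Candidates are then pruned
#' greedily by LD, sorted by ascending p (minimum across replicates):
#' a SNP is kept iff its r2 with every already-kept SNP is strictly
#' below `r2Max` in the reference dataset.
#'
#' @param metaReplicates list of meta-analysis data.frames (one per
#'   replicate imputation dataset; see [metaFixedEffects])
#' @param pMax selection threshold (default 0.1, strict "<")
#' @param r2Max pruning ceiling (default 0.2, keep strictly below)
#' @param ldReference a [GenotypeExperiment-class] in which pairwise r2
#'   is computed
#' @return A [RiskScoreModel-class] with a full audit table.
#' @export
selectScoreSnps <- function(metaReplicates, pMax = 0.1, r2Max = 0.2,
                            ldReference) {
  if (length(metaReplicates) < 1)
    ecoStop("ecogrs_invalid_argument", "need at least one replicate meta result")
  common <- Reduce(intersect, lapply(metaReplicates, `[[`, "snp"))
  rows <- lapply(metaReplicates, function(m) m[match(common, m$snp), ])
  pMat <- sapply(rows, `[[`, "p")
  if (is.null(dim(pMat))) pMat <- matrix(pMat, nrow = length(common))
  riskAll <- sapply(rows, function(m) ifelse(m$beta > 0, m$allele, m$other))
  if (is.null(dim(riskAll))) riskAll <- matrix(riskAll, nrow = length(common))
  lowP <- rowSums(pMat < pMax) == ncol(pMat)
  concord <- apply(riskAll, 1, function(a) length(unique(a)) == 1)
  cand <- common[lowP & concord]
  if (length(cand) == 0)
    ecoStop("ecogrs_empty_model",
            "no SNP passes the p-value intersection and concordance rules")
  ci <- match(cand, common)
  minP <- apply(pMat[ci, , drop = FALSE], 1, min)
  ord <- order(minP)
  cand <- cand[ord]; ci <- ci[ord]; minP <- minP[ord]
  present <- cand %in% rownames(ldReference)
  if (!all(present))
    ecoStop("ecogrs_missing_variant",
            paste("candidates absent from LD reference:",
                  paste(cand[!present], collapse = ", ")))
  R2 <- ldMatrix(ldReference, cand)
  kept <- character(); prunedBy <- setNames(rep(NA_character_, length(cand)), cand)
  for (s in cand) {
    hit <- kept[which(!is.na(R2[s, kept]) & R2[s, kept] >= r2Max)]
    if (length(hit)) prunedBy[s] <- hit[1] else kept <- c(kept, s)
  }
  tab <- data.frame(
    snp = cand,
    risk_allele = riskAll[ci, 1],
    weight = 1,
    min_p = minP,
    kept = is.na(prunedBy),
    pruned_by = unname(prunedBy),
    stringsAsFactors = FALSE, row.names = NULL)
  for (r in seq_along(metaReplicates))
    tab[[sprintf("p_rep%d", r)]] <- pMat[ci, r]
  new("RiskScoreModel", snps = tab,
      thresholds = list(pMax = pMax, r2Max = r2Max,
                        nReplicates = length(metaReplicates)))
}

#' @rdname modelSnps
#' @param x a [RiskScoreModel-class]
#' @param keptOnly return only SNPs kept after pruning (default TRUE)
#' @export
setMethod("modelSnps", "RiskScoreModel", function(x, keptOnly = TRUE) {
  if (keptOnly) x@snps[x@snps$kept, , drop = FALSE] else x@snps
})

setMethod("show", "RiskScoreModel", function(object) {
  k <- sum(object@snps$kept)
  cat(sprintf("RiskScoreModel: %d SNP(s) kept of %d candidate(s) (p < %g, prune r2 < %g)\n",
              k, nrow(object@snps), object@thresholds$pMax,
              object@thresholds$r2Max))
  print(modelSnps(object)[, c("snp", "risk_allele", "min_p")])
})

#' Compute genetic risk scores
#'
#' GRS per individual = sum over model SNPs of the risk-allele dosage:
#' homozygotes for the reference (non-risk) allele contribute 0 and
#' homozygotes for the risk allele 2, so 0 <= GRS <= 2m for m SNPs.
#' Fractional imputed dosages contribute their expected value; missing
#' dosages are expectation-imputed within the grouping variable first.
#'
#' @param ds a [GenotypeExperiment-class] containing all model SNPs
#' @param model a [RiskScoreModel-class]
#' @param groupBy sample-metadata column used for group summaries
#'   (default "population")
#' @param normality "ad" for Anderson-Darling (default) or "shapiro"
#' @return A [ScoreSet-class] with per-group mean, SD, min, max and a
#'   normality-test p per group.
#' @export
computeScores <- function(ds, model, groupBy = "population",
                          normality = c("ad", "shapiro")) {
  normality <- match.arg(normality)
  snps <- modelSnps(model)
  absent <- setdiff(snps$snp, rownames(ds))
  if (length(absent))
    ecoStop("ecogrs_missing_variant",
            paste("model SNPs absent from dataset:",
                  paste(absent, collapse = ", ")))
  if (anyNA(dosage(ds)[snps$snp, , drop = FALSE]))
    ds <- imputeExpectedDosage(ds, byPopulation = groupBy == "population")
  riskD <- vapply(seq_len(nrow(snps)), function(k)
    alleleDosage(ds, snps$snp[k], snps$risk_allele[k]) * snps$weight[k],
    numeric(ncol(ds)))
  grs <- rowSums(riskD)
  cd <- colData(ds)
  group <- if (groupBy %in% colnames(cd)) as.character(cd[[groupBy]])
           else rep("all", ncol(ds))
  scores <- data.frame(sample_id = colnames(ds), group = group, grs = grs,
                       stringsAsFactors = FALSE, row.names = NULL)
  normP <- function(x) {
    if (length(x) < 8 || sd(x) == 0) return(NA_real_)
    if (normality == "ad") ad.test(x)$p.value else shapiro.test(x)$p.value
  }
  gs <- do.call(rbind, lapply(split(scores$grs, scores$group), function(x)
    data.frame(n = length(x), mean = mean(x), sd = sd(x),
               min = min(x), max = max(x), normality_p = normP(x))))
  gs <- cbind(data.frame(group = rownames(gs), stringsAsFactors = FALSE), gs)
  rownames(gs) <- NULL
  new("ScoreSet", scores = scores, groupSummary = gs,
      nSnps = nrow(snps))
}

#' @rdname scoreTable
#' @param x a [ScoreSet-class]
#' @export
setMethod("scoreTable", "ScoreSet", function(x) x@scores)

#' ScoreSet accessors
#'
#' `scoreTable()` returns per-individual scores; `groupSummary()` the
#' per-group summary table (n, mean, sd, min, max, normality p).
#'
#' @name scoreTable
#' @rdname scoreTable
#' @export
setMethod("groupSummary", "ScoreSet", function(x) x@groupSummary)

setMethod("show", "ScoreSet", function(object) {
  cat(sprintf("ScoreSet: %d individuals, %d SNP model (GRS range [0, %d])\n",
              nrow(object@scores), object@nSnps, 2L * object@nSnps))
  print(head(object@groupSummary, 10))
})

#' Nagelkerke pseudo-R2 of a GRS predictive model
#'
#' Fits logistic `y ~ intercept + GRS`; Cox-Snell R2 =
#' `1 - exp((2/n) (ll0 - ll1))`, rescaled by its maximum
#' `1 - exp((2/n) ll0)` to give Nagelkerke R2 in \[0, 1\]. If the score
#' separates the classes perfectly the maximum (R2 = 1) is returned with
#' attribute `separation = TRUE`.
#'
#' @param y binary outcome (both classes present)
#' @param scores per-individual GRS
#' @return Nagelkerke R2.
#' @export
nagelkerkeR2 <- function(y, scores) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2)
    ecoStop("ecogrs_invalid_argument", "outcome must contain both classes")
  n <- length(y)
  fit <- tryCatch(fitLogistic(y, cbind(1, grs = scores)),
                  ecogrs_separation = function(e) NULL)
  p0 <- mean(y)
  ll0 <- n * (p0 * log(p0) + (1 - p0) * log(1 - p0))
  maxR2 <- 1 - exp(2 * ll0 / n)
  if (is.null(fit)) {
    r2 <- 1
    attr(r2, "separation") <- TRUE
    return(r2)
  }
  cs <- 1 - exp(2 * (ll0 - fit$logLik) / n)
  min(1, max(0, cs / maxR2))
}

#' ROC AUC with Hanley-McNeil confidence interval
#'
#' AUC as the tie-corrected rank statistic (concordant case-control
#' pairs plus half ties over all pairs); the confidence interval uses
#' the Hanley-McNeil variance formula and is truncated to \[0, 1\].
#'
#' @param y binary outcome (both classes present)
#' @param scores predictor values
#' @param alpha two-sided error level (default 0.05)
#' @return list with `auc`, `ci` (length 2), `nCases`, `nControls`.
#' @export
rocAucCi <- function(y, scores, alpha = 0.05) {
  y <- as.numeric(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    ecoStop("ecogrs_invalid_argument", "both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
          (n0 - 1) * (q2 - auc^2)) / (n1 * n0)
  zq <- qnorm(1 - alpha / 2)
  ci <- c(max(0, auc - zq * sqrt(max(0, v))), min(1, auc + zq * sqrt(max(0, v))))
  list(auc = auc, ci = ci, nCases = n1, nControls = n0)
}

#' Interindividual prediction metrics for a score
#'
#' Convenience wrapper returning Nagelkerke R2 and ROC AUC with its 95%
#' confidence interval for a case-control score vector.
#'
#' @inheritParams rocAucCi
#' @return list with `nagelkerkeR2`, `auc`, `aucCi`, `nCases`,
#'   `nControls`.
#' @export
predictionMetrics <- function(y, scores, alpha = 0.05) {
  roc <- rocAucCi(y, scores, alpha)
  list(nagelkerkeR2 = as.numeric(nagelkerkeR2(y, scores)),
       auc = roc$auc, aucCi = roc$ci,
       nCases = roc$nCases, nControls = roc$nControls)
}
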