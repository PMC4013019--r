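#' @include utils.R
NULL

#' GenotypeExperiment: dosage matrix with sample metadata
#'
#' The central data container of the package. It extends
#' [SummarizedExperiment::SummarizedExperiment] with two assays:
#' `dosage` (alternate-allele count per SNP x sample, values in \[0,2\],
#' `NA` where missing, possibly fractional after imputation) and
#' `imputed` (logical mask marking entries filled in by expected-dosage
#' imputation). Rows are SNPs (`rowData`: `chrom`, `pos`, `ref`, `alt`,
#' optionally `impQuality`); columns are samples (`colData`: `status`
#' (case=1/control=0/`NA`), `age`, `sex` (0/1), `population`, `study`,
#' optionally `lat`/`lon`).
#'
#' Observed (non-imputed) dosages are hard genotype calls in \{0, 1, 2\};
#' imputed entries may be fractional.
#'
#' @export
setClass("GenotypeExperiment", contains = "SummarizedExperiment")

setValidity("GenotypeExperiment", function(object) {
  msgs <- character()
  an <- assayNames(object)
  if (!all(c("dosage", "imputed") %in% an))
    return("assays 'dosage' and 'imputed' are required")
  d <- assay(object, "dosage")
  im <- assay(object, "imputed")
  if (!is.numeric(d)) msgs <- c(msgs, "'dosage' must be numeric")
  if (!is.logical(im)) msgs <- c(msgs, "'imputed' must be logical")
  obs <- !is.na(d)
  if (any(d[obs] < 0 | d[obs] > 2))
    msgs <- c(msgs, "dosages must lie in [0, 2]")
  hard <- obs & !im
  if (any(abs(d[hard] - round(d[hard])) > 1e-9))
    msgs <- c(msgs, "observed (non-imputed) dosages must be integers 0/1/2")
  if (any(is.na(d) & im))
    msgs <- c(msgs, "imputed entries cannot be missing")
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% colnames(rowData(object))))
    msgs <- c(msgs, "rowData must contain chrom, pos, ref, alt")
  if (length(msgs)) msgs else TRUE
})

#' ClineSpec: logit-linear geographic allele-frequency model
#'
#' Per-SNP intercept `a` (logit units) and slopes `b` (logit per degree
#' latitude) and `c` (logit per degree longitude). The alternate-allele
#' frequency of SNP s at coordinate (lat, lon) is
#' `plogis(a_s + b_s * lat + c_s * lon)`.
#'
#' @export
setClass("ClineSpec",
         representation(a = "numeric", b = "numeric", c = "numeric"))

setValidity("ClineSpec", function(object) {
  n <- length(object@a)
  if (length(object@b) != n || length(object@c) != n)
    return("a, b, c must have equal length")
  if (any(!is.finite(c(object@a, object@b, object@c))))
    return("cline coefficients must be finite")
  TRUE
})

#' LDBlockSpec: block-wise linkage-disequilibrium structure
#'
#' Contiguous SNP index blocks and a within-block latent AR(1) correlation
#' `rho` in \[0, 1). Blocks must partition `1:nSnps`.
#'
#' @export
setClass("LDBlockSpec",
         representation(blocks = "list", rho = "numeric"))

setValidity("LDBlockSpec", function(object) {
  idx <- unlist(object@blocks)
  if (length(idx) == 0) return("blocks must be non-empty")
  if (!identical(sort(idx), seq_along(idx)))
    return("blocks must partition the SNP index range 1..n")
  if (any(vapply(object@blocks, function(b) any(diff(b) != 1L), logical(1))))
    return("each block must be a contiguous index run")
  if (length(object@rho) != 1 || !is.finite(object@rho) ||
      object@rho < 0 || object@rho >= 1)
    return("rho must be a single value in [0, 1)")
  TRUE
})

#' DiseaseModelSpec: logistic disease model for case-control sampling
#'
#' Baseline log-odds `beta0`, per-SNP log odds ratios `beta` (one per SNP),
#' and covariate coefficients `betaAge` (per year) and `betaSex`.
#'
#' @export
setClass("DiseaseModelSpec",
         representation(beta0 = "numeric", beta = "numeric",
                        betaAge = "numeric", betaSex = "numeric"))

setValidity("DiseaseModelSpec", function(object) {
  if (any(!is.finite(c(object@beta0, object@beta, object@betaAge, object@betaSex))))
    return("disease-model coefficients must be finite")
  if (length(object@beta0) != 1 || length(object@betaAge) != 1 ||
      length(object@betaSex) != 1)
    return("beta0, betaAge, betaSex must be scalars")
  TRUE
})

#' QCReport: per-SNP and per-sample quality-control summaries
#'
#' Slots `snpStats` (call rate, MAF, HWE p, polymorphic flag, optional
#' imputation quality), `sampleStats` (call rate), and `removed` (items
#' removed by a filter, with one primary reason code each).
#'
#' @export
setClass("QCReport",
         representation(snpStats = "data.frame", sampleStats = "data.frame",
                        removed = "data.frame"))

#' RiskScoreModel: selected risk SNPs for an unweighted GRS
#'
#' One row per candidate SNP with its risk allele, weight (1 for the
#' unweighted allele-count score), per-replicate meta p-values, and the
#' pruning audit (kept / pruned and by which SNP). `thresholds` records
#' the selection p-value cutoff and pruning r2 ceiling.
#'
#' @export
setClass("RiskScoreModel",
         representation(snps = "data.frame", thresholds = "list"))

setValidity("RiskScoreModel", function(object) {
  need <- c("snp", "risk_allele", "weight", "kept")
  if (!all(need %in% colnames(object@snps)))
    return("snps table must contain snp, risk_allele, weight, kept")
  TRUE
})

#' ScoreSet: per-individual genetic risk scores with group summaries
#'
#' `scores`: sample_id, group, grs. `groupSummary`: per-group n, mean, sd,
#' min, max and a normality-test p-value. `nSnps` is the number of SNPs in
#' the scoring model, so 0 <= GRS <= 2 * nSnps.
#'
#' @export
setClass("ScoreSet",
         representation(scores = "data.frame", groupSummary = "data.frame",
                        nSnps = "integer"))

#' SpatialWeights: spatial weight matrix for autocorrelation statistics
#'
#' Non-negative n x n matrix with zero diagonal. `scheme` is one of
#' "inverse-distance", "binary" or "class"; `rowStandardized` records
#' whether rows were scaled to sum to one (applied after the symmetric
#' weights are formed).
#'
#' @export
setClass("SpatialWeights",
         representation(W = "matrix", scheme = "character",
                        rowStandardized = "logical"))

setValidity("SpatialWeights", function(object) {
  W <- object@W
  if (nrow(W) != ncol(W)) return("weight matrix must be square")
  if (any(diag(W) != 0)) return("diagonal weights must be zero")
  if (any(W < 0)) return("weights must be non-negative")
  if (sum(W) <= 0) return("sum of weights must be positive")
  TRUE
})

#' AutocorrResult: randomization test for spatial autocorrelation
#'
#' Observed Moran's I or Geary's C, the mean of the permutation null,
#' the permutation p-value ("+1" convention), the number of permutations,
#' the alternative hypothesis, and the seed used.
#'
#' @export
setClass("AutocorrResult",
         representation(statistic = "character", observed = "numeric",
                        permMean = "numeric", p = "numeric",
                        nPerm = "integer", alternative = "character",
                        seed = "integer"))

#' EmpiricalVariogram: binned semivariance estimates
#'
#' Lag-bin centers `h` (km), semivariance estimates `gamma`, and pair
#' counts `np` per retained (non-empty) bin.
#'
#' @export
setClass("EmpiricalVariogram",
         representation(h = "numeric", gamma = "numeric", np = "integer",
                        maxLag = "numeric"))

#' VariogramModel: spherical semivariogram
#'
#' Nugget `c0`, partial sill `c1` (both in squared score units) and range
#' `a` (km); `flat` flags a degenerate all-zero empirical variogram.
#'
#' @export
setClass("VariogramModel",
         representation(c0 = "numeric", c1 = "numeric", a = "numeric",
                        flat = "logical"))

setValidity("VariogramModel", function(object) {
  if (object@c0 < 0 || object@c1 < 0) return("c0 and c1 must be >= 0")
  if (object@a <= 0) return("range a must be > 0")
  TRUE
})

#' KrigingGrid: ordinary-kriging predictions on a regular grid
#'
#' Node latitudes and longitudes (regular spacing), prediction and kriging
#' variance matrices (rows = latitudes from south to north, columns =
#' longitudes from west to east).
#'
#' @export
setClass("KrigingGrid",
         representation(lat = "numeric", lon = "numeric",
                        pred = "matrix", krigVar = "matrix"))

setValidity("KrigingGrid", function(object) {
  if (nrow(object@pred) != length(object@lat) ||
      ncol(object@pred) != length(object@lon))
    return("prediction matrix must be length(lat) x length(lon)")
  if (!identical(dim(object@pred), dim(object@krigVar)))
    return("prediction and variance grids must have identical shape")
  if (any(object@krigVar < -1e-9, na.rm = TRUE))
    return("kriging variance below numerical floor")
  TRUE
})
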