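#' Construct a GenotypeExperiment
#'
#' @param dosage numeric SNP x sample matrix of alternate-allele dosages
#'   (`NA` = missing; non-imputed entries must be 0/1/2).
#' @param snpInfo data.frame with columns `snp`, `chrom`, `pos`, `ref`,
#'   `alt` and optionally `impQuality`; one row per row of `dosage`.
#' @param sampleInfo data.frame with one row per column of `dosage`;
#'   recognised columns: `sample_id`, `status`, `age`, `sex`,
#'   `population`, `study`, `lat`, `lon`.
#' @param imputed optional logical matrix marking imputed entries
#'   (default: none imputed).
#'
#' @return A [GenotypeExperiment-class] object.
#' @export
GenotypeExperiment <- function(dosage, snpInfo, sampleInfo, imputed = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(imputed))
    imputed <- matrix(FALSE, nrow(dosage), ncol(dosage))
  if (nrow(snpInfo) != nrow(dosage))
    ecoStop("ecogrs_invalid_argument", "snpInfo rows must match dosage rows")
  if (nrow(sampleInfo) != ncol(dosage))
    ecoStop("ecogrs_invalid_argument", "sampleInfo rows must match dosage columns")
  rownames(dosage) <- rownames(imputed) <- snpInfo$snp
  sid <- sampleInfo$sample_id %||% sprintf("S%04d", seq_len(ncol(dosage)))
  colnames(dosage) <- colnames(imputed) <- sid
  rd <- DataFrame(snpInfo[setdiff(colnames(snpInfo), "snp")],
                  row.names = snpInfo$snp)
  cd <- DataFrame(sampleInfo[setdiff(colnames(sampleInfo), "sample_id")],
                  row.names = sid)
  se <- SummarizedExperiment(
    assays = list(dosage = dosage, imputed = imputed),
    rowData = rd, colData = cd)
  new("GenotypeExperiment", se)
}

#' Accessors for GenotypeExperiment
#'
#' `dosage()` returns the SNP x sample dosage matrix (`NA` = missing);
#' `imputedMask()` the logical mask of imputed entries; `missingMask()`
#' the mask of missing entries; `phenotype()` the case/control status
#' vector; `population()` the population labels; `snpInfo()` the SNP
#' table as a plain data.frame (with the `snp` column restored).
#'
#' @param x a [GenotypeExperiment-class]
#' @name GenotypeExperiment-accessors
NULL

#' @rdname GenotypeExperiment-accessors
#' @export
setMethod("dosage", "GenotypeExperiment", function(x) assay(x, "dosage"))

#' @rdname GenotypeExperiment-accessors
#' @export
setMethod("imputedMask", "GenotypeExperiment", function(x) assay(x, "imputed"))

#' @rdname GenotypeExperiment-accessors
#' @export
setMethod("missingMask", "GenotypeExperiment",
          function(x) is.na(assay(x, "dosage")))

#' @rdname GenotypeExperiment-accessors
#' @export
setMethod("phenotype", "GenotypeExperiment", function(x) {
  cd <- colData(x)
  if ("status" %in% colnames(cd)) cd$status else rep(NA_integer_, ncol(x))
})

#' @rdname GenotypeExperiment-accessors
#' @export
setMethod("population", "GenotypeExperiment", function(x) {
  cd <- colData(x)
  if ("population" %in% colnames(cd)) as.character(cd$population)
  else rep(NA_character_, ncol(x))
})

#' @rdname GenotypeExperiment-accessors
#' @export
setMethod("snpInfo", "GenotypeExperiment", function(x) {
  rd <- as.data.frame(rowData(x))
  cbind(data.frame(snp = rownames(x), stringsAsFactors = FALSE), rd)
})

setMethod("show", "GenotypeExperiment", function(object) {
  d <- assay(object, "dosage")
  st <- phenotype(object)
  cat(sprintf("GenotypeExperiment: %d SNPs x %d samples\n",
              nrow(object), ncol(object)))
  cat(sprintf("  missing: %.2f%%; imputed: %.2f%%\n",
              100 * mean(is.na(d)), 100 * mean(assay(object, "imputed"))))
  if (any(!is.na(st)))
    cat(sprintf("  case-control: %d cases / %d controls\n",
                sum(st == 1, na.rm = TRUE), sum(st == 0, na.rm = TRUE)))
  pops <- unique(population(object))
  if (any(!is.na(pops)))
    cat(sprintf("  populations: %d\n", length(pops[!is.na(pops)])))
})

# Dosages of a designated allele at one SNP: the raw dosage if the allele
# is the alternate, 2 - dosage if it is the reference.
alleleDosage <- function(ds, snp, allele) {
  info <- snpInfo(ds)
  i <- match(snp, info$snp)
  if (is.na(i))
    ecoStop("ecogrs_missing_variant", sprintf("SNP '%s' absent from dataset", snp))
  d <- dosage(ds)[i, ]
  if (allele == info$alt[i]) d
  else if (allele == info$ref[i]) 2 - d
  else ecoStop("ecogrs_invalid_argument",
               sprintf("allele '%s' is neither ref nor alt of %s", allele, snp))
}
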