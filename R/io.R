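# Standard-format I/O: VCF v4.2 genotypes, sample-metadata TSV,
# imputation-quality TSV, population/eco tables.

#' Write a GenotypeExperiment as VCF v4.2
#'
#' One alternate allele per record, unphased GT, records sorted by
#' (contig, position). Missing genotypes are written `./.`. When the
#' dataset contains imputed entries a DS (expected dosage) FORMAT field
#' is added: imputed entries carry their fractional dosage in DS and the
#' nearest integer call in GT; non-imputed entries have DS `.`.
#'
#' @param ds a [GenotypeExperiment-class]
#' @param path output file
#' @return the path, invisibly
#' @export
writeGenotypeVcf <- function(ds, path) {
  info <- snpInfo(ds)
  d <- dosage(ds)
  im <- imputedMask(ds)
  ord <- order(match(info$chrom, unique(info$chrom)), info$pos)
  hasDS <- any(im)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", unique(info$chrom)),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (hasDS)
    hdr <- c(hdr, paste0('##FORMAT=<ID=DS,Number=1,Type=Float,',
                         'Description="Expected alternate allele dosage">'))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", colnames(ds)),
                      collapse = "\t"))
  gtOf <- function(x) c("0/0", "0/1", "1/1")[round(x) + 1]
  recs <- vapply(ord, function(i) {
    gt <- ifelse(is.na(d[i, ]), "./.", gtOf(d[i, ]))
    field <- if (hasDS) {
      dsv <- ifelse(im[i, ], sprintf("%.6g", d[i, ]), ".")
      paste(gt, dsv, sep = ":")
    } else gt
    paste(c(info$chrom[i], info$pos[i], info$snp[i], info$ref[i],
            info$alt[i], ".", "PASS", ".", if (hasDS) "GT:DS" else "GT",
            field), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read genotypes from a VCF v4.2 file
#'
#' Dosage = count of alternate alleles in the unphased GT; `./.` is
#' missing. Records with more than one alternate allele are rejected.
#' A DS FORMAT value, when present and non-missing, overrides the
#' dosage and marks the entry imputed (the convention of
#' [writeGenotypeVcf]).
#'
#' @param path VCF file
#' @param meta optional sample-metadata data.frame (see
#'   [readSampleMeta]) matched on sample id
#' @return A [GenotypeExperiment-class]
#' @export
readGenotypeVcf <- function(path, meta = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE)))
    ecoStop("ecogrs_parse_error",
            paste("multi-allelic records not supported:",
                  paste(fix[grepl(",", fix[, "ALT"]), "ID"], collapse = ", ")))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dosg <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dosg[gt %in% c("0/0", "0|0")] <- 0
  dosg[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  dosg[gt %in% c("1/1", "1|1")] <- 2
  bad <- !is.na(gt) & is.na(dosg) & gt != "./." & gt != "."
  if (any(bad))
    ecoStop("ecogrs_parse_error",
            paste("unparseable GT values:", paste(unique(gt[bad]), collapse = ", ")))
  im <- matrix(FALSE, nrow(gt), ncol(gt))
  fmt <- vcf@gt[, "FORMAT"]
  if (any(grepl("DS", fmt))) {
    dsv <- suppressWarnings(vcfR::extract.gt(vcf, element = "DS"))
    num <- suppressWarnings(matrix(as.numeric(dsv), nrow(dsv), ncol(dsv)))
    has <- !is.na(num)
    dosg[has] <- num[has]
    im[has] <- TRUE
  }
  snpInfo <- data.frame(snp = fix[, "ID"], chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]), ref = fix[, "REF"],
                        alt = fix[, "ALT"], stringsAsFactors = FALSE)
  sampleInfo <- data.frame(sample_id = colnames(gt), stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    i <- match(colnames(gt), meta$sample_id)
    if (anyNA(i))
      ecoStop("ecogrs_parse_error", "VCF samples missing from metadata")
    sampleInfo <- meta[i, , drop = FALSE]
  }
  GenotypeExperiment(dosg, snpInfo, sampleInfo, imputed = im)
}

#' Write / read sample metadata TSV
#'
#' Columns: sample_id, study, population, status (1/0/NA), age, sex
#' (0/1), lat, lon.
#'
#' @param ds a [GenotypeExperiment-class]
#' @param path file path
#' @return the path ([writeSampleMeta]) or a data.frame
#'   ([readSampleMeta]), invisibly for the writer
#' @export
writeSampleMeta <- function(ds, path) {
  cd <- as.data.frame(colData(ds))
  out <- data.frame(sample_id = colnames(ds), stringsAsFactors = FALSE)
  for (col in c("study", "population", "status", "age", "sex", "lat", "lon"))
    out[[col]] <- if (col %in% colnames(cd)) cd[[col]] else NA
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSampleMeta
#' @export
readSampleMeta <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Attach per-SNP imputation-quality scores
#'
#' Quality table columns: `snp`, `study`, `quality`. The per-SNP score
#' stored in the dataset is the minimum across studies, so a downstream
#' "strictly above" filter enforces the threshold in every study.
#'
#' @param ds a [GenotypeExperiment-class]
#' @param qual data.frame(snp, study, quality)
#' @return the dataset with `impQuality` in its rowData
#' @export
attachImputationQuality <- function(ds, qual) {
  if (!all(c("snp", "quality") %in% colnames(qual)))
    ecoStop("ecogrs_invalid_argument", "quality table needs snp and quality")
  minQ <- tapply(qual$quality, qual$snp, min)
  rowData(ds)$impQuality <- as.numeric(minQ[rownames(ds)])
  ds
}

#' Write / read a population event-rate table TSV
#'
#' Columns: population, sex_stratum, event_rate, plus any risk-factor or
#' score columns present.
#'
#' @param eco data.frame
#' @param path file path
#' @return the path / data.frame
#' @export
writeEcoTable <- function(eco, path) {
  write.table(eco, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEcoTable
#' @export
readEcoTable <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
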