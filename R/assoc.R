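# Per-study logistic association and inverse-variance fixed-effect
# meta-analysis.

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with Wald standard errors from the
#' inverse observed information. Newton/IRLS steps are halved whenever
#' they would decrease the log-likelihood, so the likelihood path is
#' non-decreasing; convergence is declared when the maximum absolute
#' score falls below 1e-8 (at most 100 iterations). Quasi-complete
#' separation (any |beta| > 15 during iteration) raises a separation
#' error; a singular information matrix raises a collinearity error.
#'
#' @param y binary outcome vector (0/1, both classes present)
#' @param X design matrix including the intercept column
#' @return list with `beta`, `se`, `z`, `p` (per column), `logLik`,
#'   `logLik0` (intercept-only), `iterations`, `converged`, `n`.
#' @export
fitLogistic <- function(y, X) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- length(y)
  if (n <= ncol(X))
    ecoStop("ecogrs_invalid_argument", "need more observations than columns")
  if (length(unique(y[!is.na(y)])) < 2)
    ecoStop("ecogrs_invalid_argument", "outcome must contain both classes")
  loglik <- function(beta) {
    eta <- drop(X %*% beta)
    sum(y * eta - log1p(exp(eta)))
  }
  beta <- rep(0, ncol(X))
  ll <- loglik(beta)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    mu <- invLogit(drop(X %*% beta))
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) < 1e-8) { converged <- TRUE; break }
    if (iter > 100) break
    w <- mu * (1 - mu)
    info <- crossprod(X, X * w)
    step <- tryCatch(solve(info, score), error = function(e)
      ecoStop("ecogrs_collinearity",
              paste("singular information matrix; collinear columns:",
                    paste(colnames(X) %||% seq_len(ncol(X)), collapse = ", "))))
    # step-halving keeps the likelihood non-decreasing
    fac <- 1
    repeat {
      cand <- beta + fac * step
      llNew <- loglik(cand)
      if (llNew >= ll - 1e-12 || fac < 1e-8) break
      fac <- fac / 2
    }
    beta <- cand
    ll <- llNew
    if (any(abs(beta) > 15))
      ecoStop("ecogrs_separation",
              paste("quasi-complete separation (|beta| > 15) at column",
                    paste((colnames(X) %||% seq_len(ncol(X)))[abs(beta) > 15],
                          collapse = ", ")))
  }
  mu <- invLogit(drop(X %*% beta))
  info <- crossprod(X, X * (mu * (1 - mu)))
  cov <- tryCatch(solve(info), error = function(e)
    ecoStop("ecogrs_collinearity", "singular information matrix at optimum"))
  se <- sqrt(diag(cov))
  z <- beta / se
  p0 <- mean(y)
  ll0 <- n * (p0 * log(p0) + (1 - p0) * log(1 - p0))
  list(beta = setNames(beta, colnames(X)), se = setNames(se, colnames(X)),
       z = z, p = 2 * pnorm(-abs(z)), logLik = ll, logLik0 = ll0,
       iterations = iter, converged = converged, n = n)
}

#' Greedy LD prefilter in genomic order
#'
#' Scans SNPs in genomic order (contig order of appearance, then
#' position) and drops a SNP if its dosage r2 with any already-kept SNP
#' is at or above `r2Max`. Ties are resolved by the scan order: the
#' earlier SNP wins.
#'
#' @param ds a [GenotypeExperiment-class]
#' @param r2Max exclusion threshold (default 0.8; pairs must be strictly
#'   below it)
#' @return `list(kept = character vector, dropped = data.frame(snp,
#'   against, r2))`
#' @export
ldPrefilter <- function(ds, r2Max = 0.8) {
  info <- snpInfo(ds)
  ord <- order(match(info$chrom, unique(info$chrom)), info$pos)
  ids <- info$snp[ord]
  if (length(ids) == 0)
    return(list(kept = character(), dropped = data.frame()))
  R2 <- ldMatrix(ds, ids)
  kept <- character()
  dropped <- data.frame(snp = character(), against = character(),
                        r2 = numeric(), stringsAsFactors = FALSE)
  for (s in ids) {
    hit <- kept[which(!is.na(R2[s, kept]) & R2[s, kept] >= r2Max)]
    if (length(hit)) {
      dropped <- rbind(dropped, data.frame(
        snp = s, against = hit[1], r2 = R2[s, hit[1]],
        stringsAsFactors = FALSE))
    } else kept <- c(kept, s)
  }
  list(kept = kept, dropped = dropped)
}

#' Per-study multivariate logistic association scan
#'
#' Fits one joint logistic model of case-control status on all selected
#' SNP dosages simultaneously, plus age and sex when requested, and
#' extracts each SNP's log odds ratio, Wald SE and p-value from that
#' joint fit ("adjusted for the remaining genetic variables"). If the
#' joint fit is collinear it falls back, with a warning, to per-SNP
#' models adjusted for age and sex only. Missing dosages are imputed to
#' their expected value first.
#'
#' @param ds a case-control [GenotypeExperiment-class]
#' @param snps SNP ids to scan (default: all; typically the
#'   [ldPrefilter] survivors)
#' @param adjustAge,adjustSex include the covariate (default TRUE)
#' @param joint fit one joint model over all SNPs (default TRUE)
#' @return data.frame: study, snp, allele (tested = alternate), other,
#'   beta, se, p, n.
#' @export
associationScan <- function(ds, snps = NULL, adjustAge = TRUE,
                            adjustSex = TRUE, joint = TRUE) {
  st <- phenotype(ds)
  if (all(is.na(st)))
    ecoStop("ecogrs_invalid_argument", "dataset has no case-control phenotype")
  if (anyNA(dosage(ds)))
    ds <- imputeExpectedDosage(ds, byPopulation = FALSE)
  info <- snpInfo(ds)
  if (is.null(snps)) snps <- info$snp
  use <- !is.na(st)
  y <- st[use]
  D <- t(dosage(ds)[snps, use, drop = FALSE])
  cd <- colData(ds)[use, , drop = FALSE]
  cov <- NULL
  if (adjustAge) cov <- cbind(cov, age = as.numeric(cd$age))
  if (adjustSex) cov <- cbind(cov, sex = as.numeric(cd$sex))
  study <- unique(as.character(cd$study))[1] %||% "study"
  extract <- function(fit, ids) {
    i <- match(ids, names(fit$beta))
    data.frame(study = study, snp = ids,
               allele = info$alt[match(ids, info$snp)],
               other = info$ref[match(ids, info$snp)],
               beta = fit$beta[i], se = fit$se[i], p = fit$p[i],
               n = fit$n, stringsAsFactors = FALSE, row.names = NULL)
  }
  if (joint) {
    X <- cbind(`(Intercept)` = 1, D, cov)
    res <- tryCatch(extract(fitLogistic(y, X), snps),
                    ecogrs_collinearity = function(e) {
                      warning("joint model collinear (", conditionMessage(e),
                              "); falling back to per-SNP fits")
                      NULL
                    })
    if (!is.null(res)) return(res)
  }
  out <- lapply(snps, function(s) {
    X <- cbind(`(Intercept)` = 1, D[, s, drop = FALSE], cov)
    extract(fitLogistic(y, X), s)
  })
  do.call(rbind, out)
}

#' Align tested alleles across studies
#'
#' Chooses for every SNP a canonical tested allele (the lexicographically
#' smallest alternate allele seen across studies), sign-flips betas of
#' studies that tested the swapped allele, and excludes SNPs whose
#' alleles are not a plain ref/alt swap between studies.
#'
#' @param results list of per-study association data.frames
#'   (from [associationScan])
#' @return `list(aligned = list of data.frames, excluded =
#'   data.frame(snp, reason))`
#' @export
alignAlleles <- function(results) {
  all <- do.call(rbind, results)
  excluded <- data.frame(snp = character(), reason = character(),
                         stringsAsFactors = FALSE)
  canon <- list()
  for (s in unique(all$snp)) {
    rows <- all[all$snp == s, ]
    pairs <- unique(cbind(pmin(rows$allele, rows$other),
                          pmax(rows$allele, rows$other)))
    if (nrow(pairs) > 1) {
      excluded <- rbind(excluded, data.frame(
        snp = s, reason = "allele_mismatch", stringsAsFactors = FALSE))
      next
    }
    canon[[s]] <- list(allele = min(rows$allele), other = setdiff(
      c(pairs[1, 1], pairs[1, 2]), min(rows$allele)))
  }
  aligned <- lapply(results, function(df) {
    df <- df[!(df$snp %in% excluded$snp), , drop = FALSE]
    for (k in seq_len(nrow(df))) {
      cn <- canon[[df$snp[k]]]
      if (df$allele[k] != cn$allele) {
        df$beta[k] <- -df$beta[k]
        tmp <- df$allele[k]; df$allele[k] <- df$other[k]; df$other[k] <- tmp
      }
    }
    df
  })
  list(aligned = aligned, excluded = excluded)
}

#' Inverse-variance fixed-effect meta-analysis
#'
#' Pools allele-aligned per-study log odds ratios with weights
#' `w_i = 1/SE_i^2`: pooled beta = sum(w b)/sum(w), pooled SE =
#' sqrt(1/sum(w)), z = beta/SE, two-sided normal p.
#'
#' @param results list of per-study association data.frames with aligned
#'   tested alleles (see [alignAlleles])
#' @return data.frame: snp, allele, other, beta, se, z, p, k (number of
#'   studies pooled).
#' @export
metaFixedEffects <- function(results) {
  all <- do.call(rbind, results)
  all <- all[is.finite(all$beta) & is.finite(all$se) & all$se > 0, ]
  if (nrow(all) == 0)
    ecoStop("ecogrs_undefined_result", "no valid study results to pool")
  out <- lapply(split(all, all$snp), function(rows) {
    w <- 1 / rows$se^2
    beta <- sum(w * rows$beta) / sum(w)
    se <- sqrt(1 / sum(w))
    z <- beta / se
    data.frame(snp = rows$snp[1], allele = rows$allele[1],
               other = rows$other[1], beta = beta, se = se, z = z,
               p = 2 * pnorm(-abs(z)), k = nrow(rows),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$p), ]
}
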