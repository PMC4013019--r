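# Ecological analysis: Spearman correlation, univariate/multivariate OLS
# of population coronary event rates, Bonferroni outlier detection with
# exclusion-and-refit.

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties);
#' the two-sided p-value uses `t = rho sqrt((n-2)/(1-rho^2))` with n-2
#' degrees of freedom (p = 0 when |rho| = 1).
#'
#' @param x,y paired numeric vectors (n >= 4)
#' @return list with `rho`, `p`, `n`
#' @export
spearmanTest <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4)
    ecoStop("ecogrs_invalid_argument", "need at least 4 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0)
    ecoStop("ecogrs_undefined_result", "zero rank variance")
  rho <- cor(rx, ry)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Ordinary least squares with fit summaries
#'
#' Least squares with intercept via [stats::lm]; reports coefficients
#' with per-coefficient p-values, R2, adjusted R2
#' (`1 - (1-R2)(n-1)/(n-k-1)`), and the overall F-test p-value.
#'
#' @param y response vector
#' @param X predictor matrix or data.frame (no intercept column)
#' @return list with `coef` (data.frame: estimate, se, t, p), `r2`,
#'   `adjR2`, `fP`, `n`, `k`, and the underlying `lm` fit.
#' @export
olsFit <- function(y, X) {
  X <- as.data.frame(X)
  n <- length(y)
  k <- ncol(X)
  if (n <= k + 1)
    ecoStop("ecogrs_invalid_argument", "need n > number of predictors + 1")
  dat <- cbind(data.frame(.y = y), X)
  fit <- lm(.y ~ ., data = dat)
  if (anyNA(coef(fit)))
    ecoStop("ecogrs_collinearity",
            paste("rank-deficient design; dropped:",
                  paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  sm <- summary(fit)
  cf <- as.data.frame(sm$coefficients)
  colnames(cf) <- c("estimate", "se", "t", "p")
  fstat <- sm$fstatistic
  fP <- if (is.null(fstat)) NA_real_ else
    pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  list(coef = cf, r2 = sm$r.squared, adjR2 = sm$adj.r.squared,
       fP = unname(fP), n = n, k = k, fit = fit)
}

#' Bonferroni outlier test on a regression fit
#'
#' Externally studentized residuals with two-sided t tail probabilities
#' on n-k-2 degrees of freedom; the Bonferroni-adjusted p-value is
#' `min(1, n p)` and an observation is flagged when it falls below
#' `alpha`.
#'
#' @param fit result of [olsFit] (or an `lm` object)
#' @param alpha flag threshold on the adjusted p (default 0.05)
#' @return data.frame: obs, rstudent, p, p_bonferroni, outlier.
#' @export
bonferroniOutliers <- function(fit, alpha = 0.05) {
  lmfit <- if (is.list(fit) && !is.null(fit$fit)) fit$fit else fit
  n <- length(residuals(lmfit))
  k <- length(coef(lmfit)) - 1
  df <- n - k - 2
  if (df < 1)
    ecoStop("ecogrs_invalid_argument",
            "insufficient degrees of freedom for studentized residuals")
  rs <- stats::rstudent(lmfit)
  p <- 2 * pt(-abs(rs), df)
  pb <- pmin(1, n * p)
  data.frame(obs = seq_len(n), rstudent = as.numeric(rs), p = p,
             p_bonferroni = pb, outlier = pb < alpha, row.names = NULL)
}

#' Ecological correlation and regression report
#'
#' Per sex stratum: (1) Spearman correlation and univariate OLS of the
#' response on every predictor; (2) under `outlierPolicy =
#' "exclude-and-refit"`, populations flagged by the Bonferroni outlier
#' test (adjusted p < `outlierAlpha`) in the first predictor's
#' univariate model are excluded and all analyses rerun; (3) a
#' multivariate model is built from the predictors with univariate slope
#' p < `alphaEnter`.
#'
#' @param eco data.frame with columns `population`, optionally
#'   `sex_stratum`, the response, and the predictors
#' @param predictors predictor column names (the first one drives
#'   outlier detection; typically the mean GRS)
#' @param response response column name (default "event_rate")
#' @param outlierPolicy "report" (default; data untouched) or
#'   "exclude-and-refit"
#' @param alphaEnter univariate gate for the multivariate model
#'   (default 0.05)
#' @param outlierAlpha Bonferroni threshold for exclusion (default 0.01)
#' @return list of per-stratum results: `univariate` (predictor, rho,
#'   rho_p, adj_r2, slope, uni_p, in_multivariate), `outliers`,
#'   `excluded` (population names), `multivariate` (list with coef,
#'   adjR2, fP or NULL), `n`.
#' @export
ecoReport <- function(eco, predictors, response = "event_rate",
                      outlierPolicy = c("report", "exclude-and-refit"),
                      alphaEnter = 0.05, outlierAlpha = 0.01) {
  outlierPolicy <- match.arg(outlierPolicy)
  need <- c("population", response, predictors)
  if (!all(need %in% colnames(eco)))
    ecoStop("ecogrs_invalid_argument",
            paste("missing columns:", paste(setdiff(need, colnames(eco)),
                                            collapse = ", ")))
  strata <- if ("sex_stratum" %in% colnames(eco))
    split(eco, eco$sex_stratum) else list(all = eco)
  lapply(strata, function(dat) {
    if (nrow(dat) < 5)
      ecoStop("ecogrs_invalid_argument",
              "fewer than 5 populations in stratum")
    excluded <- character()
    outliers <- NULL
    if (outlierPolicy == "exclude-and-refit") {
      uni1 <- olsFit(dat[[response]], dat[predictors[1]])
      outliers <- bonferroniOutliers(uni1, alpha = outlierAlpha)
      bad <- outliers$outlier
      if (any(bad)) {
        excluded <- dat$population[bad]
        dat <- dat[!bad, , drop = FALSE]
        if (nrow(dat) < 5)
          ecoStop("ecogrs_invalid_argument",
                  "fewer than 5 populations left after outlier exclusion")
      }
    }
    uni <- do.call(rbind, lapply(predictors, function(pr) {
      sp <- spearmanTest(dat[[pr]], dat[[response]])
      of <- olsFit(dat[[response]], dat[pr])
      data.frame(predictor = pr, rho = sp$rho, rho_p = sp$p,
                 adj_r2 = of$adjR2, slope = of$coef$estimate[2],
                 uni_p = of$coef$p[2], stringsAsFactors = FALSE)
    }))
    uni$in_multivariate <- uni$uni_p < alphaEnter
    multi <- NULL
    sel <- uni$predictor[uni$in_multivariate]
    if (length(sel) >= 1) {
      mf <- olsFit(dat[[response]], dat[sel])
      multi <- list(predictors = sel, coef = mf$coef, adjR2 = mf$adjR2,
                    fP = mf$fP)
    }
    list(univariate = uni, outliers = outliers, excluded = excluded,
         multivariate = multi, n = nrow(dat))
  })
}
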