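test_that("Spearman correlation uses mid-ranks and the t approximation", {
  x <- 1:10
  expect_equal(spearmanTest(x, 2 * x + 3)$rho, 1)
  expect_equal(spearmanTest(x, -x^3)$rho, -1)

  withr::with_seed(7, {
    xt <- sample(rep(1:4, length.out = 10))
    yt <- rnorm(10) + xt
  })
  res <- spearmanTest(xt, yt)
  rhoOracle <- cor(oracleMidrank(xt), oracleMidrank(yt))
  expect_equal(res$rho, rhoOracle, tolerance = 1e-12)
  tOracle <- rhoOracle * sqrt(8 / (1 - rhoOracle^2))
  expect_equal(res$p, 2 * pt(-abs(tOracle), 8), tolerance = 1e-12)

  # invariance under strictly monotone transforms
  expect_equal(spearmanTest(exp(xt), yt)$rho, res$rho)
  expect_error(spearmanTest(rep(1, 5), rnorm(5)),
               class = "ecogrs_undefined_result")
  expect_error(spearmanTest(1:3, 1:3), class = "ecogrs_invalid_argument")
})

test_that("OLS matches the normal equations and is exact on linear data", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2.0, 2.9, 4.2, 4.8, 6.1)
  fit <- olsFit(y, data.frame(x = x))
  X <- cbind(1, x)
  betaOracle <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(fit$coef$estimate), unname(drop(betaOracle)),
               tolerance = 1e-12)

  exact <- olsFit(3 + 2 * x, data.frame(x = x))
  expect_equal(exact$r2, 1, tolerance = 1e-12)
  expect_equal(exact$adjR2, 1, tolerance = 1e-12)

  # adjusted R2 formula and bound
  withr::with_seed(11, {
    yy <- rnorm(12); XX <- data.frame(a = rnorm(12), b = rnorm(12))
  })
  f2 <- olsFit(yy, XX)
  expect_equal(f2$adjR2, 1 - (1 - f2$r2) * 11 / (12 - 2 - 1),
               tolerance = 1e-12)
  expect_lte(f2$adjR2, f2$r2)

  expect_error(olsFit(yy, data.frame(a = XX$a, b = 2 * XX$a)),
               class = "ecogrs_collinearity")
  expect_error(olsFit(1:3, data.frame(a = rnorm(3), b = rnorm(3))),
               class = "ecogrs_invalid_argument")
})

test_that("overall F p-values are uniform under the null", {
  withr::with_seed(23, {
    pvals <- replicate(500, olsFit(rnorm(10), data.frame(x = rnorm(10)))$fP)
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("Bonferroni outlier detection flags a gross outlier", {
  withr::with_seed(31, {
    x <- 1:11
    y <- 2 + 3 * x + rnorm(11, 0, 0.5)
  })
  y[6] <- y[6] + 10 * 0.5  # ten residual SDs
  fit <- olsFit(y, data.frame(x = x))
  out <- bonferroniOutliers(fit, alpha = 0.01)
  expect_true(out$outlier[6])
  expect_lt(out$p_bonferroni[6], 0.01)
  expect_equal(sum(out$outlier), 1)

  # agreement with car's outlierTest on the same fit
  ct <- car::outlierTest(fit$fit, cutoff = Inf, n.max = 11)
  expect_equal(out$p_bonferroni[as.integer(names(ct$bonf.p))],
               pmin(1, unname(ct$bonf.p)), tolerance = 1e-10)

  expect_error(
    bonferroniOutliers(olsFit(c(1, 2, 3.1), data.frame(x = c(1, 2, 3)))),
    class = "ecogrs_invalid_argument")
})

test_that("Bonferroni control holds under Gaussian residuals", {
  withr::with_seed(41, {
    flagged <- replicate(1000, {
      x <- rnorm(11)
      fit <- olsFit(2 + x + rnorm(11), data.frame(x = x))
      any(bonferroniOutliers(fit, alpha = 0.05)$outlier)
    })
  })
  expect_lte(mean(flagged), 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("the ecological report gates, excludes and refits", {
  pops <- sprintf("p%02d", 1:10)
  withr::with_seed(51, {
    grs <- runif(10, 5.5, 6.2)
    lat <- 35 + 28 * (grs - 5.5) / 0.7 + rnorm(10, 0, 2)
  })
  # exact linearity: single predictor explains everything
  ecoExact <- data.frame(population = pops, sex_stratum = "men",
                         event_rate = 20 + 30 * grs, mean_grs = grs,
                         lat = lat)
  rep1 <- ecoReport(ecoExact, predictors = c("mean_grs", "lat"))
  men <- rep1$men
  expect_equal(men$univariate$adj_r2[1], 1, tolerance = 1e-10)
  expect_true(men$univariate$in_multivariate[1])

  # report policy leaves the data untouched
  expect_identical(men$excluded, character(0))

  # injected outlier: excluded under exclude-and-refit, fit improves
  withr::with_seed(52, {
    noisy <- 20 + 30 * grs + rnorm(10, 0, 2)
  })
  noisy[4] <- noisy[4] + 40
  ecoOut <- data.frame(population = pops, sex_stratum = "men",
                       event_rate = noisy, mean_grs = grs, lat = lat)
  pre <- olsFit(ecoOut$event_rate, ecoOut["mean_grs"])$adjR2
  rep2 <- ecoReport(ecoOut, predictors = c("mean_grs", "lat"),
                    outlierPolicy = "exclude-and-refit")
  expect_identical(rep2$men$excluded, "p04")
  expect_gt(rep2$men$univariate$adj_r2[1], pre)

  # collinear predictors: joint fit retained, per-coefficient attenuation
  withr::with_seed(53, {
    y2 <- 20 + 30 * grs + rnorm(10, 0, 1.5)
  })
  ecoCol <- data.frame(population = pops, sex_stratum = "women",
                       event_rate = y2, mean_grs = grs, lat = lat)
  rep3 <- ecoReport(ecoCol, predictors = c("mean_grs", "lat"))
  expect_true(cor(grs, lat) > 0.9)
  w <- rep3$women
  if (all(w$univariate$in_multivariate)) {
    expect_identical(w$multivariate$predictors, c("mean_grs", "lat"))
    expect_gt(w$multivariate$coef["lat", "p"],
              w$univariate$uni_p[w$univariate$predictor == "lat"])
  }

  expect_error(ecoReport(ecoExact[1:4, ], predictors = "mean_grs"),
               class = "ecogrs_invalid_argument")
})

test_that("slope recovery: the OLS CI covers the generating slope", {
  covered <- sapply(1:100, function(s) {
    withr::with_seed(7000 + s, {
      ms <- runif(10, 5.5, 6.2)
      tab <- drawEventRateTable(setNames(ms, sprintf("p%02d", 1:10)),
                                intercept = 20, slope = 30, noiseSd = 5,
                                seed = 7000 + s)
    })
    fit <- olsFit(tab$event_rate, tab["mean_grs"])
    est <- fit$coef$estimate[2]; se <- fit$coef$se[2]
    tq <- qt(0.975, 8)
    est - tq * se <= 30 && 30 <= est + tq * se
  })
  expect_gte(mean(covered), 0.9)
})
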