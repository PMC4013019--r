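test_that("logistic slopes match the closed-form 2x2 odds ratio", {
  # collapsed 2x2: (exposed case, exposed control, unexposed case,
  # unexposed control) = (30, 70, 10, 90)
  x <- rep(c(1, 1, 0, 0), c(30, 70, 10, 90))
  y <- rep(c(1, 0, 1, 0), c(30, 70, 10, 90))
  fit <- fitLogistic(y, cbind(1, x = x))
  expect_equal(unname(fit$beta["x"]), log(30 * 90 / (70 * 10)),
               tolerance = 1e-6)

  # intercept-only model: logit of prevalence
  y2 <- rep(c(1, 0), c(40, 60))
  fit2 <- fitLogistic(y2, matrix(1, 100, 1))
  expect_equal(unname(fit2$beta[1]), log(0.4 / 0.6), tolerance = 1e-8)
})

test_that("IRLS agrees with glm and flags separation/collinearity", {
  withr::with_seed(5, {
    X <- cbind(1, a = rnorm(300), b = rbinom(300, 2, 0.3))
    y <- rbinom(300, 1, plogis(0.2 + 0.5 * X[, "a"] - 0.3 * X[, "b"]))
  })
  fit <- fitLogistic(y, X)
  ref <- glm(y ~ X[, "a"] + X[, "b"], family = binomial)
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-6)
  expect_equal(fit$logLik, as.numeric(logLik(ref)), tolerance = 1e-8)

  sep <- c(rep(0, 20), rep(1, 20))
  expect_error(fitLogistic(sep, cbind(1, x = sep * 2)),
               class = "ecogrs_separation")
  expect_error(fitLogistic(y, cbind(1, a = X[, "a"], a2 = 2 * X[, "a"])),
               class = "ecogrs_collinearity")
  expect_error(fitLogistic(rep(1, 50), matrix(1, 50, 1)),
               class = "ecogrs_invalid_argument")
})

test_that("Wald p-values are uniform under the null", {
  withr::with_seed(33, {
    pvals <- replicate(200, {
      x <- rnorm(500)
      y <- rbinom(500, 1, 0.4)
      fitLogistic(y, cbind(1, x = x))$p["x"]
    })
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("greedy LD prefilter keeps the earliest of correlated runs", {
  withr::with_seed(3, {
    r <- 0.92; s <- sqrt(1 - r^2)
    zA <- rnorm(400)
    zB <- r * zA + s * rnorm(400)
    zC <- r * zB + s * rnorm(400)
    A <- 2 * pnorm(zA); B <- 2 * pnorm(zB); C <- 2 * pnorm(zC)
  })
  ds <- toyDataset(rbind(A, B, C), allImputed = TRUE)
  R2 <- suppressWarnings(cor(cbind(A, B, C)))^2
  # constructed so A~B and B~C are over the ceiling but A~C is under it
  expect_true(R2[1, 2] >= 0.8 && R2[2, 3] >= 0.8 && R2[1, 3] < 0.8)
  res <- ldPrefilter(ds, r2Max = 0.8)
  expect_identical(res$kept, c("s01", "s03"))
  expect_identical(res$dropped$snp, "s02")

  # two perfectly correlated SNPs: the earlier by position wins
  dup <- toyDataset(rbind(c(0, 1, 2, 1), c(0, 1, 2, 1)))
  expect_identical(ldPrefilter(dup)$kept, "s01")

  # all pairs below the ceiling: identity
  withr::with_seed(4, {
    ind <- toyDataset(matrix(rbinom(3 * 500, 2, 0.4), 3, 500))
  })
  expect_identical(ldPrefilter(ind)$kept, c("s01", "s02", "s03"))
})

test_that("the joint association scan adjusts for the remaining SNPs", {
  blocks <- LDBlockSpec(rep(5, 4), rho = 0.4)
  beta <- rep(0, 20); beta[8] <- 0.5
  ds <- drawCaseControlStudy(rep(0.3, 20),
                             DiseaseModelSpec(-0.3, beta, 0.01, 0.1),
                             3000, 3000, blocks = blocks, seed = 2)
  res <- associationScan(ds)
  expect_equal(nrow(res), 20)
  causal <- res[res$snp == "snp008", ]
  expect_lt(abs(causal$beta - 0.5), 3 * causal$se)
  nulls <- res[res$snp != "snp008", ]
  expect_true(all(abs(nulls$beta) < 4 * nulls$se))

  # without adjustment, a single-SNP scan equals a plain logistic fit
  one <- associationScan(ds, snps = "snp008", adjustAge = FALSE,
                         adjustSex = FALSE)
  direct <- fitLogistic(phenotype(ds),
                        cbind(1, g = dosage(ds)["snp008", ]))
  expect_equal(one$beta, unname(direct$beta["g"]), tolerance = 1e-10)

  noPheno <- toyDataset(rbind(c(0, 1, 2, 1)))
  expect_error(associationScan(noPheno), class = "ecogrs_invalid_argument")
})

test_that("allele alignment flips swapped studies and drops mismatches", {
  mk <- function(study, snp, allele, other, beta) {
    data.frame(study = study, snp = snp, allele = allele, other = other,
               beta = beta, se = 0.1, p = 0.5, n = 100,
               stringsAsFactors = FALSE)
  }
  same <- alignAlleles(list(mk("a", "rs1", "G", "A", 0.3),
                            mk("b", "rs1", "G", "A", 0.2)))
  expect_equal(same$aligned[[2]]$beta, 0.2)

  swap <- alignAlleles(list(mk("a", "rs1", "A", "G", 0.1),
                            mk("b", "rs1", "G", "A", 0.3)))
  expect_identical(swap$aligned[[2]]$allele, "A")
  expect_equal(swap$aligned[[2]]$beta, -0.3)

  bad <- alignAlleles(list(mk("a", "rs1", "G", "A", 0.1),
                           mk("b", "rs1", "C", "A", 0.3)))
  expect_identical(bad$excluded$snp, "rs1")
  expect_equal(nrow(bad$aligned[[1]]), 0)
})

test_that("inverse-variance pooling matches hand-computed weights", {
  mk <- function(beta, se) {
    data.frame(study = paste0("s", seq_along(beta)), snp = "rs1",
               allele = "G", other = "A", beta = beta, se = se, p = 0.5,
               n = 100, stringsAsFactors = FALSE)
  }
  single <- metaFixedEffects(list(mk(0.4, 0.1)))
  expect_equal(single$beta, 0.4)
  expect_equal(single$se, 0.1)

  four <- metaFixedEffects(list(mk(rep(0.4, 4), rep(0.1, 4))))
  expect_equal(four$se, 0.05)

  two <- metaFixedEffects(list(mk(c(0.2, 0.6), c(0.1, 0.3))))
  expect_equal(two$beta, (0.2 / 0.01 + 0.6 / 0.09) / (1 / 0.01 + 1 / 0.09),
               tolerance = 1e-12)
  expect_equal(two$beta, 0.24, tolerance = 1e-12)

  # pooled SE never exceeds the best single study; order-invariant
  expect_lte(two$se, 0.1)
  rev2 <- metaFixedEffects(list(mk(c(0.6, 0.2), c(0.3, 0.1))))
  expect_equal(rev2$beta, two$beta, tolerance = 1e-14)

  # cross-check against metafor's fixed-effect model
  withr::with_seed(6, {
    b <- rnorm(5, 0.3, 0.2); s <- runif(5, 0.05, 0.3)
  })
  ours <- metaFixedEffects(list(mk(b, s)))
  ref <- metafor::rma(yi = b, sei = s, method = "FE")
  expect_equal(ours$beta, as.numeric(ref$beta), tolerance = 1e-8)
  expect_equal(ours$se, ref$se, tolerance = 1e-8)

  expect_error(metaFixedEffects(list(mk(0.4, Inf))),
               class = "ecogrs_undefined_result")
})

test_that("meta z-scores are standard normal under the null", {
  withr::with_seed(44, {
    z <- replicate(200, {
      se <- runif(3, 0.05, 0.2)
      b <- rnorm(3, 0, se)
      m <- metaFixedEffects(list(data.frame(
        study = paste0("s", 1:3), snp = "rs1", allele = "G", other = "A",
        beta = b, se = se, p = 0.5, n = 100, stringsAsFactors = FALSE)))
      m$z
    })
  })
  m <- 200
  expect_lt(abs(mean(z)), 3 / sqrt(m))
  expect_lt(abs(var(z) - 1), 3 * sqrt(2 / (m - 1)))
})
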