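mkMeta <- function(snp, beta, p, allele = "G", other = "A") {
  data.frame(snp = snp, allele = allele, other = other, beta = beta,
             se = 0.1, z = beta / 0.1, p = p, k = 3,
             stringsAsFactors = FALSE)
}

test_that("score-SNP selection applies the p-intersection and pruning rules", {
  # five candidates; two of them in strong LD -> four survive pruning
  withr::with_seed(50, {
    g <- matrix(rbinom(5 * 800, 2, 0.4), 5, 800)
    g[2, ] <- ifelse(runif(800) < 0.85, g[1, ], rbinom(800, 2, 0.4))
  })
  ref <- toyDataset(g)
  expect_gte(ldR2(ref, 1, 2), 0.2)
  m1 <- mkMeta(sprintf("s%02d", 1:5), beta = c(0.30, 0.28, 0.2, 0.18, 0.15),
               p = c(0.001, 0.002, 0.01, 0.02, 0.05))
  m2 <- mkMeta(sprintf("s%02d", 1:5), beta = c(0.31, 0.27, 0.19, 0.2, 0.14),
               p = c(0.002, 0.003, 0.02, 0.01, 0.06))
  model <- selectScoreSnps(list(m1, m2), ldReference = ref)
  kept <- modelSnps(model)
  expect_equal(nrow(kept), 4)
  expect_false("s02" %in% kept$snp)       # pruned against lower-p s01
  expect_identical(modelSnps(model, keptOnly = FALSE)$pruned_by[2], "s01")

  # p >= 0.1 in one replicate fails the intersection rule
  m2b <- m2; m2b$p[3] <- 0.2
  expect_false("s03" %in% modelSnps(selectScoreSnps(list(m1, m2b),
                                                    ldReference = ref))$snp)

  # discordant effect direction across replicates is excluded
  m2c <- m2; m2c$beta[4] <- -0.2
  expect_false("s04" %in% modelSnps(selectScoreSnps(list(m1, m2c),
                                                    ldReference = ref))$snp)

  # single candidate -> model of size 1
  one <- selectScoreSnps(list(mkMeta("s01", 0.3, 0.01)), ldReference = ref)
  expect_equal(nrow(modelSnps(one)), 1)

  expect_error(selectScoreSnps(list(mkMeta("s01", 0.3, 0.5)),
                               ldReference = ref),
               class = "ecogrs_empty_model")
})

test_that("risk alleles point at the beta > 0 allele", {
  withr::with_seed(55, {
    ref <- toyDataset(matrix(rbinom(2 * 200, 2, 0.4), 2, 200))
  })
  neg <- mkMeta(c("s01", "s02"), beta = c(0.3, -0.3), p = c(0.01, 0.01))
  model <- selectScoreSnps(list(neg), ldReference = ref)
  tab <- modelSnps(model)
  expect_identical(tab$risk_allele[tab$snp == "s01"], "G")
  expect_identical(tab$risk_allele[tab$snp == "s02"], "A")
})

test_that("the GRS is a bounded risk-allele dosage sum", {
  # 4 SNPs; sample 1 all risk-homozygote, sample 2 all reference, 3 all het
  d <- matrix(c(2, 2, 2, 2, 0, 0, 0, 0, 1, 1, 1, 1), 4, 3)
  ds <- toyDataset(d)
  ss <- computeScores(ds, toyModel())
  expect_equal(scoreTable(ss)$grs, c(8, 0, 4))

  # ref/alt relabeling with the matching risk-allele letter is invariant
  flip <- toyDataset(2 - d, ref = rep("G", 4), alt = rep("A", 4))
  ssFlip <- computeScores(flip, toyModel(risk = rep("G", 4)))
  expect_equal(scoreTable(ssFlip)$grs, scoreTable(ss)$grs)

  # fractional imputed dosages contribute their expectation
  dm <- d; dm[1, 3] <- NA
  ssm <- computeScores(toyDataset(dm), toyModel())
  expect_equal(scoreTable(ssm)$grs[3], 3 + 2 * (2 + 0) / 4)

  expect_error(computeScores(toyDataset(d[1:2, ]), toyModel()),
               class = "ecogrs_missing_variant")
})

test_that("group summaries are consistent with individual scores", {
  withr::with_seed(60, {
    d <- matrix(rbinom(4 * 60, 2, 0.5), 4, 60)
  })
  ds <- toyDataset(d, population = rep(c("x", "y"), each = 30))
  ss <- computeScores(ds, toyModel())
  tab <- scoreTable(ss)
  gs <- groupSummary(ss)
  for (g in c("x", "y")) {
    v <- tab$grs[tab$group == g]
    row <- gs[gs$group == g, ]
    expect_equal(row$mean, mean(v))
    expect_equal(row$sd, sd(v))
    expect_equal(c(row$min, row$max), range(v))
    expect_equal(row$normality_p,
                 nortest::ad.test(v)$p.value)
  }
  expect_true(all(tab$grs >= 0 & tab$grs <= 8))
})

test_that("Nagelkerke R2 matches the likelihood formula oracle", {
  # 20-observation fixture
  y <- c(1, 1, 1, 0, 1, 0, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0, 0, 0, 1, 0)
  s <- c(6, 7, 5, 4, 6, 5, 3, 8, 4, 5, 7, 6, 4, 3, 5, 4, 6, 3, 7, 5)
  fit1 <- glm(y ~ s, family = binomial)
  fit0 <- glm(y ~ 1, family = binomial)
  n <- length(y)
  cs <- 1 - exp(2 * (as.numeric(logLik(fit0)) - as.numeric(logLik(fit1))) / n)
  expected <- cs / (1 - exp(2 * as.numeric(logLik(fit0)) / n))
  expect_equal(nagelkerkeR2(y, s), expected, tolerance = 1e-10)

  # independence: negligible R2
  withr::with_seed(70, {
    yy <- rbinom(2000, 1, 0.5)
    sc <- rnorm(2000)
  })
  expect_lt(nagelkerkeR2(yy, sc), 0.01)

  # perfect separation reports the ceiling with a flag
  r2sep <- nagelkerkeR2(rep(c(0, 1), each = 30), rep(c(0, 10), each = 30))
  expect_equal(as.numeric(r2sep), 1)
  expect_true(attr(r2sep, "separation"))

  expect_error(nagelkerkeR2(rep(1, 10), rnorm(10)),
               class = "ecogrs_invalid_argument")
})

test_that("Nagelkerke R2 grows with the simulated effect size", {
  blocks <- LDBlockSpec(1, rho = 0)
  r2At <- function(beta, seed) {
    ds <- drawCaseControlStudy(0.3, DiseaseModelSpec(-0.2, beta), 750, 750,
                               blocks = blocks, seed = seed)
    nagelkerkeR2(phenotype(ds), dosage(ds)[1, ])
  }
  grid <- sapply(1:6, function(s) sapply(c(0, 0.2, 0.5, 1.0), r2At,
                                         seed = 100 + s))
  means <- rowMeans(grid)
  expect_true(all(diff(means) > 0))
})

test_that("AUC equals the pair-counting oracle and behaves at the extremes", {
  withr::with_seed(80, {
    y <- rbinom(200, 1, 0.4)
    s <- round(rnorm(200, y, 1.5), 1)  # rounding induces ties
  })
  res <- rocAucCi(y, s)
  expect_equal(res$auc, oracleAuc(y, s), tolerance = 1e-12)
  expect_equal(res$auc + rocAucCi(y, -s)$auc, 1)
  expect_true(res$ci[1] <= res$auc && res$auc <= res$ci[2])
  # cross-check against pROC
  expect_equal(res$auc,
               as.numeric(suppressMessages(pROC::auc(y, s))),
               tolerance = 1e-12)

  perfect <- rocAucCi(rep(c(1, 0), each = 20), rep(c(5, 1), each = 20))
  expect_equal(perfect$auc, 1)
  ties <- rocAucCi(rep(c(1, 0), each = 20), rep(1, 40))
  expect_equal(ties$auc, 0.5)
  expect_error(rocAucCi(rep(1, 10), rnorm(10)),
               class = "ecogrs_invalid_argument")
})

test_that("the selection pipeline recovers simulated causal SNPs", {
  # scaled-down recovery check (the acceptance suite runs the full one):
  # 4 causal among 30 SNPs in LD blocks, one study pair per seed
  blocks <- LDBlockSpec(rep(5, 6), rho = 0.6)
  causal <- c(3, 11, 19, 27)
  beta <- rep(0, 30); beta[causal] <- c(0.25, 0.3, 0.4, 0.5)
  hits <- sapply(1:5, function(s) {
    studies <- lapply(1:2, function(i)
      drawCaseControlStudy(rep(0.3, 30),
                           DiseaseModelSpec(-0.5, beta, 0.01, 0.1),
                           1200, 1200, blocks = blocks,
                           seed = 1000 * s + i,
                           study = paste0("study", i)))
    scans <- lapply(studies, function(ds)
      associationScan(ds, snps = ldPrefilter(ds, 0.8)$kept))
    meta <- metaFixedEffects(alignAlleles(scans)$aligned)
    model <- tryCatch(
      selectScoreSnps(list(meta), ldReference = studies[[1]]),
      ecogrs_empty_model = function(e) NULL)
    if (is.null(model)) 0 else
      sum(sprintf("snp%03d", causal) %in% modelSnps(model)$snp)
  })
  expect_gte(mean(hits >= 3), 0.8)
})
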