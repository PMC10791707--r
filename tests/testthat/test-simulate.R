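# Synthetic cohort generator: determinism, marginal calibration, LD
# construction, degenerate cases.

test_that("same config and seed give byte-identical cohorts", {
  cfg <- quick_config(n = 400)
  a <- simulate_cohort(cfg, seed = 11)
  b <- simulate_cohort(cfg, seed = 11)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$phenotypes, b$phenotypes)
  d <- simulate_cohort(cfg, seed = 12)
  expect_false(identical(a$phenotypes$exposure, d$phenotypes$exposure))
})

test_that("adding a variant does not perturb other genotype columns", {
  v1 <- variant_panel(c("v1", "v2"), maf = c(0.3, 0.2), beta = 0)
  v2 <- variant_panel(c("v1", "v2", "v9"), maf = c(0.3, 0.2, 0.4),
                      beta = 0)
  base <- list(n_individuals = 500, ld_rho = numeric(0),
               covariate_effects = NULL, biomarkers = list(),
               outcomes = list(), confounder_exposure_beta = 0)
  g1 <- simulate_genotypes(do.call(sim_config, c(base, list(variants = v1))),
                           seed = 5)
  g2 <- simulate_genotypes(do.call(sim_config, c(base, list(variants = v2))),
                           seed = 5)
  expect_identical(g1[, c("v1", "v2")], g2[, c("v1", "v2")])
})

test_that("dosage support and allele frequencies match the config", {
  cfg <- sim_config(
    n_individuals = 50000,
    variants = variant_panel(c("a", "b"), maf = c(0.3, 0.05), beta = 0),
    ld_rho = numeric(0), covariate_effects = NULL,
    biomarkers = list(), outcomes = list(),
    confounder_exposure_beta = 0)
  g <- simulate_genotypes(cfg, seed = 2)
  expect_true(all(g %in% 0:2))
  # sample allele frequency within 3 binomial SEs of target
  for (j in 1:2) {
    p <- cfg$variants$maf[j]
    se <- sqrt(p * (1 - p) / (2 * 50000))
    expect_lt(abs(mean(g[, j]) / 2 - p), 3 * se)
  }
  # n = 1, k = 1 edge
  cfg1 <- sim_config(n_individuals = 1,
                     variants = variant_panel("x", maf = 0.5, beta = 0),
                     ld_rho = numeric(0), covariate_effects = NULL,
                     biomarkers = list(), outcomes = list(),
                     confounder_exposure_beta = 0)
  expect_true(simulate_genotypes(cfg1, seed = 1)[1, 1] %in% 0:2)
})

test_that("within-block latent correlation induces strong dosage LD", {
  cfg <- sim_config(
    n_individuals = 50000,
    variants = variant_panel(c("a", "b"), maf = c(0.3, 0.3), beta = 0,
                             block = "bl"),
    ld_rho = c(bl = 0.95), covariate_effects = NULL,
    biomarkers = list(), outcomes = list(),
    confounder_exposure_beta = 0)
  g <- simulate_genotypes(cfg, seed = 3)
  expect_gt(cor(g[, 1], g[, 2]), 0.8)
  # and independent variants show near-zero LD
  cfg0 <- cfg; cfg0$variants$block <- NA_character_
  g0 <- simulate_genotypes(cfg0, seed = 3)
  expect_lt(abs(cor(g0[, 1], g0[, 2])), 0.05)
})

test_that("invalid configurations are refused", {
  expect_error(variant_panel("v", maf = 0.7), "0, 0.5")
  expect_error(variant_panel("v", maf = 0), "0, 0.5")
  expect_error(sim_config(n_individuals = 0), "n_individuals")
  expect_error(
    sim_config(variants = variant_panel("v", 0.3, block = "x"),
               ld_rho = c(x = 1.0)),
    "ld_rho")
  expect_error(
    sim_config(variants = variant_panel("v", 0.3, block = "x")),
    "no ld_rho entry")
})

test_that("zero noise and no covariates recover the exact linear model", {
  cfg <- sim_config(
    n_individuals = 200,
    variants = variant_panel(c("v1", "v2"), maf = c(0.3, 0.4),
                             beta = c(0.5, -0.2)),
    ld_rho = numeric(0), exposure_intercept = 5,
    exposure_noise_sd = 0, covariate_effects = NULL,
    confounder_exposure_beta = 0, biomarkers = list(), outcomes = list())
  ch <- simulate_cohort(cfg, seed = 9)
  expect_equal(ch$phenotypes$exposure,
               5 + as.numeric(ch$genotypes %*% c(0.5, -0.2)))
})

test_that("exposure moments and outcome prevalence match closed forms", {
  cfg <- quick_config(n = 50000)
  ch <- simulate_cohort(cfg, seed = 21)
  mom <- implied_exposure_moments(cfg)
  x <- ch$phenotypes$exposure
  n <- length(x)
  expect_lt(abs(mean(x) - mom$mean), 3 * sqrt(mom$var / n))
  # SD within 3 MC SEs (normal-theory SE of the SD)
  expect_lt(abs(sd(x) - sqrt(mom$var)),
            3 * sqrt(mom$var / (2 * n)))
  # prevalence close to its target and to the mean of the linear-predictor
  # probabilities
  expect_lt(abs(mean(ch$phenotypes$dz) - 0.15),
            3 * sqrt(0.15 * 0.85 / n))
})

test_that("null-effect outcomes give score-outcome estimates centred on 0", {
  cfg <- quick_config(n = 2000)
  z <- sapply(1:40, function(i) {
    ch <- simulate_cohort(cfg, seed = 4000 + i)
    iv <- gwas_ivset(ch)
    s <- compute_score(ch$genotypes, iv)
    oe <- score_outcome_effect(ch, s, "dz")
    oe$big_gamma / oe$se
  })
  expect_lt(abs(mean(z)), 3 / sqrt(40))
})

test_that("dosage-effect p-values are uniform under the global null", {
  cfg <- sim_config(
    n_individuals = 300,
    variants = variant_panel("v1", maf = 0.3, beta = 0),
    ld_rho = numeric(0), exposure_noise_sd = 1,
    covariate_effects = NULL, confounder_exposure_beta = 0,
    biomarkers = list(), outcomes = list())
  pv <- sapply(1:200, function(i) {
    ch <- simulate_cohort(cfg, seed = 6000 + i)
    variant_association(ch, "v1")$p_value
  })
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
})

test_that("prevalent flags mark the configured fraction of cases", {
  cfg <- quick_config(n = 20000)
  cfg$outcomes$dz$prevalent_fraction <- 0.3
  ch <- simulate_cohort(cfg, seed = 31)
  ph <- ch$phenotypes
  expect_true(all(ph$prevalent_dz[ph$dz == 0] == 0))
  frac <- mean(ph$prevalent_dz[ph$dz == 1])
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / sum(ph$dz)))
})

test_that("genotype missingness is generated and handled downstream", {
  cfg <- quick_config(n = 2000, genotype_missing_rate = 0.02)
  ch <- simulate_cohort(cfg, seed = 41)
  expect_gt(sum(is.na(ch$genotypes)), 0)
  iv <- gwas_ivset(ch)
  s_drop <- compute_score(ch$genotypes, iv, missing = "drop")
  s_mean <- compute_score(ch$genotypes, iv, missing = "mean")
  expect_true(anyNA(s_drop))
  expect_false(anyNA(s_mean))
  expect_equal(attr(s_drop, "n_missing"),
               sum(rowSums(is.na(ch$genotypes)) > 0))
})
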