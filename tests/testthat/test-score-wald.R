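# Genetic score arithmetic, component regressions, Wald ratio and the
# linear MR table.

toy_ivset <- function(ids, weights) {
  instrument_set_from_gwas(
    data.frame(variant_id = ids, beta = weights, p_value = 1e-9,
               stringsAsFactors = FALSE))
}

test_that("compute_score is the exact weighted dosage sum", {
  G <- matrix(c(2L, 1L, 0L, 1L, 0L, 2L), 3, 2,
              dimnames = list(NULL, c("v1", "v2")))
  iv <- toy_ivset(c("v1", "v2"), c(0.5, -0.2))
  expect_equal(as.numeric(compute_score(G, iv)),
               c(0.5 * 2 - 0.2 * 1, 0.5 * 1, -0.2 * 2))
  # printed-equation spot check: weights (0.5, -0.2), dosages (2, 1) -> 0.8
  expect_equal(as.numeric(compute_score(
    matrix(c(2L, 1L), 1, 2, dimnames = list(NULL, c("v1", "v2"))), iv)),
    0.8)
  expect_equal(as.numeric(compute_score(G, toy_ivset(c("v1", "v2"),
                                                     c(0, 0)))),
               rep(0, 3))
  ivid <- toy_ivset("v1", 1)
  expect_equal(as.numeric(compute_score(G, ivid)), as.numeric(G[, "v1"]))
  expect_error(compute_score(G[, 1, drop = FALSE],
                             toy_ivset(c("v1", "vX"), c(1, 1))),
               "missing from genotype")
})

test_that("score-exposure regression is exact on noiseless data and errors
           on a constant score", {
  n <- 90
  g <- rep(0:2, 30)
  ch <- manual_cohort(matrix(as.integer(g), n, 1,
                             dimnames = list(NULL, "v1")),
                      data.frame(id = paste0("i", 1:n),
                                 exposure = 1 + 0.4 * g))
  iv <- toy_ivset("v1", 0.4)
  s <- compute_score(ch$genotypes, iv)
  ge <- score_exposure_effect(ch, s)
  expect_equal(ge$gamma, 1, tolerance = 1e-10)
  expect_lt(ge$se, 1e-10)
  expect_error(score_exposure_effect(ch, rep(2, n)), "degenerate")
})

test_that("in-sample GWAS weights give gamma close to 1 (self-weighting)", {
  gam <- sapply(1:20, function(i) {
    ch <- simulate_cohort(quick_config(n = 4000), seed = 9000 + i)
    iv <- gwas_ivset(ch)
    s <- compute_score(ch$genotypes, iv)
    score_exposure_effect(ch, s)$gamma
  })
  expect_lt(abs(mean(gam) - 1), 3 * sd(gam) / sqrt(20))
})

test_that("logistic score-outcome fit matches an independent IRLS oracle
           on a 20-row fixture", {
  set.seed(77)
  n <- 20
  s <- rnorm(n)
  y <- c(0, 1, 0, 1, 1, 0, 0, 1, 0, 1, 1, 0, 1, 0, 1, 0, 0, 1, 1, 0)
  ch <- manual_cohort(matrix(0L, n, 1, dimnames = list(NULL, "v1")),
                      data.frame(id = paste0("i", 1:n),
                                 exposure = rnorm(n), y = y))
  oe <- score_outcome_effect(ch, s, "y")
  orc <- oracle_irls(y, cbind(s, 1))
  expect_equal(oe$big_gamma, orc$coef[1], tolerance = 1e-6)
  expect_equal(oe$se, orc$se[1], tolerance = 1e-6)
  # single-class outcome errors
  ch$phenotypes$y <- 1L
  expect_error(score_outcome_effect(ch, s, "y"), "single class")
})

test_that("wald_ratio handles the worked trivial cases", {
  # null numerator: OR exactly 1, p = 1
  w0 <- wald_ratio(list(gamma = 1, se = 0.1),
                   list(big_gamma = 0, se = 0.2))
  expect_equal(w0$or, 1)
  expect_equal(w0$p_value, 1)
  # error-free denominator collapses the delta formula
  w <- wald_ratio(list(gamma = 2, se = 0),
                  list(big_gamma = 1, se = 0.1))
  expect_equal(w$theta, 0.5)
  expect_equal(w$se, 0.05)
  expect_error(wald_ratio(list(gamma = 0, se = 0.1),
                          list(big_gamma = 1, se = 0.1)),
               "nonzero")
})

test_that("direction flip inverts the OR exactly and the OR is monotone in
           big_gamma", {
  g <- list(gamma = 1.5, se = 0.05)
  for (bg in c(-0.4, 0.1, 0.8)) {
    wi <- suppressWarnings(
      wald_ratio(g, list(big_gamma = bg, se = 0.1),
                 direction = "increase"))
    wd <- suppressWarnings(
      wald_ratio(g, list(big_gamma = bg, se = 0.1),
                 direction = "decrease"))
    expect_equal(wd$or, 1 / wi$or, tolerance = 1e-12)
    expect_equal(wd$p_value, wi$p_value)
  }
  ors <- sapply(seq(-1, 1, by = 0.25), function(bg)
    wald_ratio(g, list(big_gamma = bg, se = 0.1),
               direction = "increase")$or)
  expect_true(all(diff(ors) > 0))
})

test_that("first-order delta SE never exceeds the second-order SE", {
  set.seed(11)
  for (i in 1:50) {
    g <- list(gamma = runif(1, 0.2, 3) * sign(runif(1, -1, 1)),
              se = runif(1, 0.001, 0.5))
    G <- list(big_gamma = rnorm(1), se = runif(1, 0.001, 0.5))
    w2 <- suppressWarnings(wald_ratio(g, G, second_order = TRUE))
    w1 <- suppressWarnings(wald_ratio(g, G, second_order = FALSE))
    expect_lte(w1$se, w2$se)
    expect_true(w2$ci_low < w2$or && w2$or < w2$ci_high)
  }
})

test_that("weak denominators trigger the weak-instrument flag and Fieller
           intervals cover the ratio when bounded", {
  expect_warning(
    w <- wald_ratio(list(gamma = 0.1, se = 0.2),
                    list(big_gamma = 0.05, se = 0.1)),
    "weak instrument")
  expect_true("weak_instrument" %in% w$flags)
  wf <- wald_ratio(list(gamma = 2, se = 0.05),
                   list(big_gamma = 1, se = 0.1), fieller = TRUE)
  expect_false(is.null(wf$fieller_ci))
  expect_true(wf$fieller_ci[1] < wf$or && wf$or < wf$fieller_ci[2])
})

test_that("linear_mr returns one row per outcome and respects BMI
           adjustment invariance when BMI is independent of the score", {
  cfg <- quick_config(n = 6000)
  cfg$biomarkers$bmi <- biomarker_spec(mean = 27, sd = 4.5, loading = 0)
  cfg$outcomes$dz2 <- outcome_spec(prevalence = 0.10,
                                   effect = mr_effect("constant", 0.5),
                                   confounder_beta = 0.2)
  ch <- simulate_cohort(cfg, seed = 55)
  iv <- gwas_ivset(ch)
  res <- linear_mr(ch, iv, c("dz", "dz2"))
  expect_s3_class(res, "linear_mr")
  expect_equal(nrow(res), 2)
  expect_equal(res$outcome, c("dz", "dz2"))
  expect_true(all(res$ci_low < res$or & res$or < res$ci_high))
  radj <- linear_mr(ch, iv, "dz2", extra_adjust = "bmi")
  z <- (log(radj$or[1]) - log(res$or[2])) /
    sqrt(attr(res, "estimates")$dz2$se^2 * 0.1^2)
  expect_lt(abs(z), 1)  # adjustment shifts the estimate well within noise
  expect_error(linear_mr(ch, clump(run_region_gwas(ch, "v1"),
                                   ch$genotypes, 1e-30, 0.1), "dz"),
               "empty instrument set")
})

test_that("prevalent-case exclusion happens per outcome before estimation", {
  cfg <- quick_config(n = 3000)
  cfg$outcomes$dz$prevalent_fraction <- 0.5
  ch <- simulate_cohort(cfg, seed = 66)
  iv <- gwas_ivset(ch)
  res <- linear_mr(ch, iv, "dz", drop_prevalent = TRUE)
  expect_equal(res$n, 3000 - sum(ch$phenotypes$prevalent_dz))
  res2 <- linear_mr(ch, iv, "dz", drop_prevalent = FALSE)
  expect_equal(res2$n, 3000)
  expect_gt(res2$n_cases, res$n_cases)
})
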