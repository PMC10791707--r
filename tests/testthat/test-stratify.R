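# Residual-based, doubly-ranked and observed stratification.

test_that("with a zero score coefficient residual strata equal observed
           quartiles", {
  set.seed(19)
  n <- 400
  m <- rnorm(n, 150, 40)
  ph <- data.frame(id = paste0("i", 1:n), exposure = rnorm(n), tg = m)
  ch <- manual_cohort(matrix(0L, n, 1, dimnames = list(NULL, "v1")), ph)
  score <- rnorm(n)
  ph$tg2 <- m  # stratifier unrelated to score by construction
  # force a zero coefficient by using a score orthogonal to m
  score <- residuals(lm(score ~ m))
  a_res <- residual_stratify(ch, "tg", score, n_strata = 4)
  a_obs <- observed_stratify(ch, "tg", n_strata = 4)
  expect_equal(a_res$index, a_obs$index)
})

test_that("strata are disjoint, exhaustive and balanced to within one", {
  cfg <- quick_config(n = 1001)
  ch <- simulate_cohort(cfg, seed = 23)
  iv <- gwas_ivset(ch)
  s <- compute_score(ch$genotypes, iv)
  for (method in c("residual", "doubly_ranked", "observed")) {
    a <- switch(method,
      residual = residual_stratify(ch, "tg", s, n_strata = 4),
      doubly_ranked = doubly_ranked_stratify(ch, s, "tg", n_strata = 4),
      observed = observed_stratify(ch, "tg", n_strata = 4))
    expect_equal(length(a$index), 1001)
    expect_true(all(a$index %in% 1:4))
    sizes <- tabulate(a$index, 4)
    expect_lte(max(sizes) - min(sizes), 4 - 1)
    expect_equal(sum(sizes), 1001)
  }
  # n = 8, 4 strata -> exactly 2 per stratum
  ch8 <- manual_cohort(matrix(0L, 8, 1, dimnames = list(NULL, "v1")),
                       data.frame(id = paste0("i", 1:8),
                                  exposure = rnorm(8), tg = rnorm(8)))
  a8 <- residual_stratify(ch8, "tg", rnorm(8), n_strata = 4)
  expect_equal(unname(tabulate(a8$index, 4)), rep(2L, 4))
})

test_that("residualisation orthogonalises the stratifier against the score
           over the full sample", {
  cfg <- quick_config(n = 3000)
  cfg$biomarkers$tg$loading <- 8  # make TG depend on exposure
  ch <- simulate_cohort(cfg, seed = 29)
  iv <- gwas_ivset(ch)
  s <- compute_score(ch$genotypes, iv)
  a <- residual_stratify(ch, "tg", s, n_strata = 4)
  expect_lt(abs(cor(a$residual, s)), 1e-8)
  # intercept retained: with no covariates, residual = observed minus the
  # score contribution only
  b_s <- coef(lm(ch$phenotypes$tg ~ s))[2]
  expect_equal(a$residual, ch$phenotypes$tg - b_s * s,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("residual stratification refuses degenerate requests", {
  ch <- manual_cohort(matrix(0L, 30, 1, dimnames = list(NULL, "v1")),
                      data.frame(id = paste0("i", 1:30),
                                 exposure = rnorm(30),
                                 tg = rnorm(30), const = 1))
  expect_error(residual_stratify(ch, "const", rnorm(30)), "constant")
  expect_error(residual_stratify(ch, "tg", rnorm(30), n_strata = 20),
               "per stratum")
  expect_error(residual_stratify(ch, "ghost", rnorm(30)), "unknown")
  big <- manual_cohort(matrix(0L, 300, 1, dimnames = list(NULL, "v1")),
                       data.frame(id = paste0("i", 1:300),
                                  exposure = rnorm(300),
                                  tg = rnorm(300)))
  expect_error(residual_stratify(big, "tg", rnorm(300), n_strata = 40),
               "n/10")
})

test_that("doubly-ranked assignment matches a hand-traced 16-row fixture", {
  # scores are a shuffled permutation of 1..16; stratifier chosen so every
  # pre-stratum has a distinct within-ranking
  perm <- c(9, 3, 14, 1, 12, 6, 16, 8, 2, 11, 5, 13, 4, 15, 7, 10)
  score <- perm                 # row i has score rank perm[i]
  m <- c(5, 3, 8, 1, 7, 2, 9, 4, 6, 1, 3, 2, 10, 5, 0, 8)
  # Hand trace: sort by score -> individuals in score order are those with
  # perm values 1..16, i.e. rows c(4, 9, 2, 13, 11, 6, 15, 8, 1, 16, 10,
  # 5, 12, 3, 14, 7).  Pre-strata of 4; within each, rank by m (ties by
  # row order) and send the j-th ranked to stratum j.
  score_order <- order(score, seq_along(score))
  expect_equal(score_order, c(4, 9, 2, 13, 11, 6, 15, 8, 1, 16, 10, 5,
                              12, 3, 14, 7))
  # pre-stratum 1 = rows 4,9,2,13 with m = 1,6,3,10 -> strata 1,3,2,4
  # pre-stratum 2 = rows 11,6,15,8 with m = 3,2,0,4 -> strata 3,2,1,4
  # pre-stratum 3 = rows 1,16,10,5 with m = 5,8,1,7 -> strata 2,4,1,3
  # pre-stratum 4 = rows 12,3,14,7 with m = 2,8,5,9 -> strata 1,3,2,4
  expected <- integer(16)
  expected[c(4, 9, 2, 13)] <- c(1, 3, 2, 4)
  expected[c(11, 6, 15, 8)] <- c(3, 2, 1, 4)
  expected[c(1, 16, 10, 5)] <- c(2, 4, 1, 3)
  expected[c(12, 3, 14, 7)] <- c(1, 3, 2, 4)
  ch <- manual_cohort(matrix(0L, 16, 1, dimnames = list(NULL, "v1")),
                      data.frame(id = sprintf("i%02d", 1:16),
                                 exposure = rnorm(16), tg = m))
  a <- doubly_ranked_stratify(ch, score, "tg", n_strata = 4)
  expect_equal(a$index, expected)
})

test_that("doubly-ranked remainder members go to the lowest strata and a
           constant stratifier falls back to the row-order tie-break", {
  # n = 10, 4 strata: two full pre-strata + remainder of 2
  ch <- manual_cohort(matrix(0L, 10, 1, dimnames = list(NULL, "v1")),
                      data.frame(id = sprintf("i%02d", 1:10),
                                 exposure = rnorm(10),
                                 tg = c(4, 2, 9, 7, 1, 8, 3, 5, 6, 0)))
  a <- doubly_ranked_stratify(ch, 1:10, "tg", n_strata = 4)
  sizes <- tabulate(a$index, 4)
  expect_equal(sizes, c(3L, 3L, 2L, 2L))
  # remainder = score-ranks 9,10 (rows 9,10), m = 6,0 -> row10 stratum 1,
  # row9 stratum 2
  expect_equal(a$index[10], 1L)
  expect_equal(a$index[9], 2L)
  # constant stratifier: deterministic assignment by row order
  ch$phenotypes$tg <- 1
  b1 <- doubly_ranked_stratify(ch, 1:10, "tg", n_strata = 4)
  b2 <- doubly_ranked_stratify(ch, 1:10, "tg", n_strata = 4)
  expect_equal(b1$index, b2$index)
  expect_equal(b1$index[1:4], 1:4)  # ties broken by row order
})

test_that("score distributions are exchangeable across doubly-ranked strata
           when the stratifier is independent of the score", {
  cfg <- quick_config(n = 20000)
  ch <- simulate_cohort(cfg, seed = 37)
  iv <- gwas_ivset(ch)
  s <- compute_score(ch$genotypes, iv)
  a <- doubly_ranked_stratify(ch, s, "tg", n_strata = 4)
  ks <- suppressWarnings(stats::ks.test(s[a$index == 1],
                                        s[a$index == 4]))
  expect_gt(ks$p.value, 0.01)
})
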