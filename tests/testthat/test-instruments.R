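# Clumping, exclusion lists, instrument strength, negative controls.

fake_assoc <- function(ids, p, beta = 0.1) {
  data.frame(variant_id = ids, beta = beta, se = 0.01, p_value = p,
             allele_freq = 0.3, n_used = 100, status = "ok",
             stringsAsFactors = FALSE)
}

test_that("clumping keeps the top of perfectly correlated pairs and
           handles empty results", {
  set.seed(1)
  g1 <- rbinom(200, 2, 0.3)
  G <- cbind(a = g1, b = g1)  # r2 = 1
  a <- fake_assoc(c("a", "b"), c(1e-9, 1e-8))
  iv <- clump(a, G, p_threshold = 1e-6, r2_threshold = 0.1)
  expect_equal(iv$variants$variant_id, "a")
  # single significant variant is retained
  iv1 <- clump(fake_assoc("a", 1e-9), G[, "a", drop = FALSE], 1e-6, 0.1)
  expect_equal(nrow(iv1$variants), 1)
  # nothing significant -> explicit status, not an error
  iv0 <- clump(fake_assoc(c("a", "b"), c(0.5, 0.9)), G, 1e-6, 0.1)
  expect_equal(nrow(iv0$variants), 0)
  expect_equal(iv0$status, "no_significant_variant")
})

test_that("clumping matches brute-force greedy enumeration on 8 simulated
           variants", {
  for (rep in 1:10) {
    set.seed(100 + rep)
    n <- 400
    base <- matrix(rbinom(n * 4, 2, 0.3), n, 4)
    # build 8 columns with assorted LD by copying/perturbing
    G <- cbind(base,
               ifelse(runif(n) < 0.9, base[, 1], rbinom(n, 2, 0.3)),
               ifelse(runif(n) < 0.7, base[, 2], rbinom(n, 2, 0.3)),
               rbinom(n, 2, 0.2), rbinom(n, 2, 0.4))
    colnames(G) <- paste0("s", 1:8)
    p <- 10^-runif(8, 0, 9)
    a <- fake_assoc(colnames(G), p)
    r2mat <- cor(G)^2
    expected <- oracle_clump(colnames(G), p, r2mat, 1e-3, 0.1)
    got <- clump(a, G, 1e-3, 0.1)$variants$variant_id
    expect_equal(got, expected)
  }
})

test_that("clumping output does not depend on input order for distinct
           p-values, and ties break lexicographically", {
  set.seed(7)
  G <- matrix(rbinom(300 * 4, 2, 0.3), 300, 4,
              dimnames = list(NULL, c("w", "x", "y", "z")))
  a <- fake_assoc(colnames(G), c(1e-8, 1e-6, 1e-7, 1e-5))
  perm <- a[c(3, 1, 4, 2), ]
  expect_equal(clump(a, G, 1e-3, 0.2)$variants$variant_id,
               clump(perm, G, 1e-3, 0.2)$variants$variant_id)
  tied <- fake_assoc(c("zz", "aa"), c(1e-8, 1e-8))
  Gt <- matrix(rbinom(300 * 2, 2, 0.3), 300, 2,
               dimnames = list(NULL, c("zz", "aa")))
  expect_equal(clump(tied, Gt, 1e-3, 1)$variants$variant_id[1], "aa")
})

test_that("in-sample r2 equals the squared two-pass Pearson correlation", {
  set.seed(3)
  x <- rbinom(500, 2, 0.3); y <- rbinom(500, 2, 0.4)
  naive <- (sum((x - mean(x)) * (y - mean(y))) /
              sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))^2
  expect_equal(cor(x, y)^2, naive, tolerance = 1e-12)
})

test_that("exclusion lists remove named variants and warn on unknown IDs", {
  a <- fake_assoc(c("a", "b", "c"), c(1e-9, 1e-8, 1e-7))
  G <- matrix(rbinom(300 * 3, 2, 0.3), 300, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  iv <- clump(a, G, 1e-3, 1)
  expect_identical(apply_exclusion_list(iv, character(0)), iv)
  iv2 <- apply_exclusion_list(iv, "b")
  expect_equal(iv2$variants$variant_id, c("a", "c"))
  expect_equal(iv2$variants$weight,
               iv$variants$weight[iv$variants$variant_id != "b"])
  expect_warning(iv3 <- apply_exclusion_list(iv, "ghost"), "ghost")
  expect_equal(iv3$variants, iv$variants)
  iv4 <- suppressWarnings(apply_exclusion_list(iv, c("a", "b", "c")))
  expect_equal(iv4$status, "empty_after_exclusion")
})

test_that("gene-specific Bonferroni threshold follows 0.05/k", {
  expect_equal(bonferroni_threshold(5279), 0.05 / 5279)
  expect_equal(signif(bonferroni_threshold(5279), 3), 9.47e-6)
})

test_that("a noiseless single-variant exposure gives R2 -> 1 and F = Inf", {
  n <- 90
  g <- rep(0:2, 30)
  ch <- manual_cohort(matrix(as.integer(g), n, 1,
                             dimnames = list(NULL, "v1")),
                      data.frame(id = paste0("i", 1:n),
                                 exposure = 2 + 0.4 * g))
  iv <- instrument_set_from_gwas(run_region_gwas(ch, "v1"))
  st <- instrument_strength(ch, iv)
  expect_equal(st$r_squared, 1, tolerance = 1e-10)
  expect_equal(st$f_statistic, Inf)
})

test_that("joint F matches its closed-form expectation for 3 instruments
           explaining 1% of variance", {
  cfg <- mr_scenario("linear_recovery", n = 20000)
  fs <- sapply(1:30, function(i) {
    ch <- simulate_cohort(cfg, seed = 8000 + i)
    iv <- gwas_ivset(ch)
    instrument_strength(ch, iv)$f_statistic
  })
  n <- 20000
  expected <- (0.01 / 3) * (n - 4) / 0.99
  expect_lt(abs(mean(fs) - expected) / expected, 0.15)
})

test_that("zero-effect instruments give F with mean about 1", {
  cfg <- quick_config(n = 2000)
  cfg$variants$beta <- 0
  fs <- sapply(1:40, function(i) {
    ch <- simulate_cohort(cfg, seed = 8500 + i)
    iv <- instrument_set_from_gwas(
      run_region_gwas(ch, ch$variants$id))
    instrument_strength(ch, iv)$f_statistic
  })
  # under H0, F ~ F(3, n-4): mean = (n-4)/(n-6) ~ 1, sd ~ sqrt(2/3)
  expect_lt(abs(mean(fs) - 1), 3 * sqrt(2 / 3) / sqrt(40))
})

test_that("collinear instruments are refused by name", {
  set.seed(5)
  g <- rbinom(100, 2, 0.3)
  G <- cbind(a = g, b = g)
  ch <- manual_cohort(G, data.frame(id = paste0("i", 1:100),
                                    exposure = rnorm(100)))
  iv <- instrument_set_from_gwas(
    fake_assoc(c("a", "b"), c(1e-9, 1e-8)))
  expect_error(instrument_strength(ch, iv), "collinear")
})

test_that("negative-control check flags a constant score as degenerate", {
  cfg <- quick_config(n = 500)
  ch <- simulate_cohort(cfg, seed = 15)
  nc <- negative_control_check(ch, rep(1, 500))
  expect_true(all(nc$status == "degenerate"))
  expect_error(negative_control_check(ch, rnorm(500),
                                      control_names = "ghost"),
               "unknown control")
  # well-behaved score: returns one row per control with finite stats
  iv <- gwas_ivset(ch)
  s <- compute_score(ch$genotypes, iv)
  nc2 <- negative_control_check(ch, s)
  expect_equal(nc2$control, c("age", "sex"))
  expect_true(all(is.finite(nc2$p)))
})
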