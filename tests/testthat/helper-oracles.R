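# Independent oracles used to cross-check the package's estimators, plus
# small fixture builders.

# shared state between the null-calibration and assumption-check blocks
.acceptance_cache <- new.env(parent = emptyenv())

# Oracles deliberately use a different algorithmic route than the
# implementation.

# OLS by the normal equations (the implementation uses QR).
oracle_ols <- function(y, X) {
  X <- as.matrix(X)
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  r <- y - X %*% b
  s2 <- sum(r^2) / (nrow(X) - ncol(X))
  se <- sqrt(diag(solve(XtX)) * s2)
  list(coef = as.numeric(b), se = as.numeric(se))
}

# Logistic regression by a hand-written IRLS loop (the implementation uses
# glm.fit).
oracle_irls <- function(y, X, tol = 1e-12, maxit = 200) {
  X <- as.matrix(X)
  b <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- as.numeric(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    z <- eta + (y - mu) / W
    XtWX <- crossprod(X, X * W)
    bnew <- solve(XtWX, crossprod(X, W * z))
    if (max(abs(bnew - b)) < tol) { b <- as.numeric(bnew); break }
    b <- as.numeric(bnew)
  }
  eta <- as.numeric(X %*% b)
  mu <- 1 / (1 + exp(-eta))
  se <- unname(sqrt(diag(solve(crossprod(X, X * (mu * (1 - mu)))))))
  list(coef = b, se = se)
}

# Greedy clumping by exhaustive precomputed-r2 scan (the implementation
# prunes a shrinking candidate list).
oracle_clump <- function(ids, pvals, r2mat, p_threshold, r2_threshold) {
  keep <- character(0)
  avail <- order(pvals, ids)
  avail <- avail[pvals[avail] < p_threshold]
  removed <- rep(FALSE, length(ids))
  for (i in avail) {
    if (removed[i]) next
    keep <- c(keep, ids[i])
    for (j in seq_along(ids)) {
      if (j != i && !removed[j] && r2mat[i, j] >= r2_threshold)
        removed[j] <- TRUE
    }
    removed[i] <- TRUE
  }
  keep
}

# A cohort with fully hand-controlled columns, bypassing the simulator.
manual_cohort <- function(genotypes, phenotypes, variants = NULL) {
  if (is.null(variants))
    variants <- data.frame(id = colnames(genotypes),
                           chrom = "2",
                           pos = seq_len(ncol(genotypes)) * 1000L,
                           stringsAsFactors = FALSE)
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 variants = variants, config = NULL, seed = NA_integer_),
            class = "mr_cohort")
}

# Small fast default: a 3-variant config with strong effects.
quick_config <- function(n = 1500, ...) {
  sim_config(
    n_individuals = n,
    variants = variant_panel(c("v1", "v2", "v3"), maf = c(0.3, 0.25, 0.4),
                             beta = c(0.21, 0.22, 0.20)),
    ld_rho = numeric(0),
    exposure_intercept = 5.2, exposure_noise_sd = 1.3,
    covariate_effects = NULL, confounder_exposure_beta = 0.3,
    biomarkers = list(tg = biomarker_spec(mean = 154.8, sd = 88,
                                          loading = 0)),
    outcomes = list(dz = outcome_spec(prevalence = 0.15,
                                      effect = mr_effect("constant", 0),
                                      confounder_beta = 0.3)),
    ...
  )
}

gwas_ivset <- function(cohort, covs = NULL) {
  g <- run_region_gwas(cohort, cohort$variants$id, covs)
  instrument_set_from_gwas(g)
}
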