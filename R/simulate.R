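# Seeded generation of synthetic cohorts.

#' Simulate genotype dosages
#'
#' Dosages in `{0, 1, 2}` are produced by thresholding a standard-normal
#' latent variable at the Hardy-Weinberg genotype-frequency cutpoints for
#' each variant's allele frequency, so `E[dosage] = 2 * maf` exactly.
#' Variants sharing an LD-block label draw their latents as
#' `sqrt(rho) * f_block + sqrt(1 - rho) * u_variant`, giving exchangeable
#' latent correlation `rho` within the block; the induced dosage-scale
#' correlation is smaller (roughly 0.9 * rho for common variants) and is
#' zero across blocks.  Each variant and each block factor has its own
#' random substream derived from the master seed, so adding a variant
#' leaves every other column unchanged.
#'
#' @param config a [sim_config()].
#' @param seed master seed; defaults to the seed stored in the config.
#' @return integer matrix (individuals x variants) with variant IDs as
#'   column names, possibly containing `NA` when
#'   `genotype_missing_rate > 0`.
#' @export
simulate_genotypes <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  v <- config$variants
  k <- nrow(v)
  block_factors <- new.env(parent = emptyenv())
  g <- matrix(NA_integer_, n, k, dimnames = list(NULL, v$id))
  for (j in seq_len(k)) {
    rho <- 0
    f <- 0
    if (!is.na(v$block[j])) {
      rho <- unname(config$ld_rho[[v$block[j]]])
      key <- v$block[j]
      if (!exists(key, envir = block_factors)) {
        assign(key, with_substream(seed, paste0("ld_block:", key),
                                   stats::rnorm(n)),
               envir = block_factors)
      }
      f <- get(key, envir = block_factors)
    }
    u <- with_substream(seed, paste0("geno:", v$id[j]), stats::rnorm(n))
    z <- sqrt(rho) * f + sqrt(1 - rho) * u
    p <- v$maf[j]
    c0 <- stats::qnorm((1 - p)^2)
    c1 <- stats::qnorm((1 - p)^2 + 2 * p * (1 - p))
    g[, j] <- (z > c0) + (z > c1)
  }
  if (config$genotype_missing_rate > 0) {
    miss <- with_substream(seed, "geno_missing",
                           stats::runif(n * k) < config$genotype_missing_rate)
    g[matrix(miss, n, k)] <- NA_integer_
  }
  storage.mode(g) <- "integer"
  g
}

# Band-specific coefficient vector for a piecewise/polynomial effect.
effect_theta <- function(effect, exposure_centered, modifiers) {
  switch(effect$type,
    constant = rep(effect$value, length(exposure_centered)),
    piecewise = {
      m <- modifiers[[effect$modifier]]
      cuts <- stats::quantile(m, probs = effect$probs, type = 7,
                              names = FALSE)
      band <- findInterval(m, cuts, left.open = TRUE) + 1L
      effect$values[band]
    },
    polynomial = {
      m <- modifiers[[effect$modifier]]
      mc <- m - mean(m)
      th <- 0
      for (j in seq_along(effect$coef)) th <- th + effect$coef[j] * mc^(j - 1L)
      th
    }
  )
}

#' Simulate phenotypes, biomarkers and outcomes for a genotype matrix
#'
#' Builds the phenotype table of a synthetic cohort: covariates (age, sex,
#' five ancestry principal components, genotyping array and assessment
#' centre labels), the continuous exposure
#' `intercept + sum(beta_g * dosage) + covariate effects + confounder +
#' noise`, each biomarker as its configured linear (or log-linear)
#' function of the exposure, and each binary outcome from a logistic model
#' whose exposure coefficient may vary with a modifier biomarker.
#' Prevalent-case flags mark cases diagnosed before exposure measurement.
#'
#' @param genotypes matrix from [simulate_genotypes()]; its column set
#'   must equal the config's variant list.
#' @param config a [sim_config()].
#' @param seed master seed (same value as used for the genotypes gives the
#'   jointly seeded cohort).
#' @return object of class `mr_cohort`; see [simulate_cohort()].
#' @export
simulate_phenotypes <- function(genotypes, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  if (nrow(genotypes) != n || !identical(colnames(genotypes),
                                         config$variants$id))
    stop("genotype matrix does not match the configuration's variant list",
         call. = FALSE)

  ph <- data.frame(id = sprintf("ind%06d", seq_len(n)))
  ph$age <- with_substream(seed, "covar:age",
                           pmin(pmax(stats::rnorm(n, 56.5, 8.1), 37), 73))
  ph$sex <- with_substream(seed, "covar:sex",
                           stats::rbinom(n, 1L, 0.5))
  for (j in 1:5)
    ph[[paste0("pc", j)]] <- with_substream(seed, paste0("covar:pc", j),
                                            stats::rnorm(n))
  ph$array <- with_substream(seed, "covar:array",
                             sample(c("axiom", "bileve"), n, TRUE,
                                    prob = c(0.9, 0.1)))
  ph$centre <- with_substream(seed, "covar:centre",
                              sample(paste0("c", 1:3), n, TRUE))
  confounder <- with_substream(seed, "confounder", stats::rnorm(n))

  gd <- genotypes
  if (anyNA(gd)) {
    # mean-impute for phenotype construction only; the analysis modules see
    # the missing values
    for (j in seq_len(ncol(gd))) {
      nas <- is.na(gd[, j])
      if (any(nas)) gd[nas, j] <- mean(gd[, j], na.rm = TRUE)
    }
  }
  if (config$age_dosage_beta != 0)
    ph$age <- ph$age + config$age_dosage_beta * rowSums(gd)

  genetic <- as.numeric(gd %*% config$variants$beta)
  if (!is.null(config$genetic_effect_modifier)) {
    gem <- config$genetic_effect_modifier
    spec <- config$biomarkers[[gem$biomarker]]
    m_val <- biomarker_values(spec, gem$biomarker, exposure_centered = 0,
                              ph, seed)
    z <- (m_val - mean(m_val)) / stats::sd(m_val)
    genetic <- genetic * (1 + gem$lambda * z)
    premade <- stats::setNames(list(m_val), gem$biomarker)
  } else premade <- list()

  cov_part <- numeric(n)
  ce <- config$covariate_effects
  for (nm in names(ce)) cov_part <- cov_part + ce[[nm]] * ph[[nm]]
  noise <- with_substream(seed, "exposure_noise",
                          stats::rnorm(n, 0, config$exposure_noise_sd))
  ph$exposure <- config$exposure_intercept + genetic + cov_part +
    config$confounder_exposure_beta * confounder + noise

  mu_x <- implied_exposure_moments(config)$mean
  xc <- ph$exposure - mu_x

  for (nm in names(config$biomarkers)) {
    ph[[nm]] <- if (nm %in% names(premade)) premade[[nm]]
    else biomarker_values(config$biomarkers[[nm]], nm, xc, ph, seed)
  }

  modifiers <- ph[names(config$biomarkers)]
  for (nm in names(config$outcomes)) {
    os <- config$outcomes[[nm]]
    theta <- outcome_theta(os, config, xc, modifiers)
    lp_slope <- theta$theta_i * xc
    lp_cov <- numeric(n)
    for (cn in names(os$covariate_effects))
      lp_cov <- lp_cov + os$covariate_effects[[cn]] *
        (ph[[cn]] - covariate_means[[cn]])
    lp_rest <- lp_cov + os$confounder_beta * confounder
    alpha <- outcome_intercept(os, theta, config, lp_slope + lp_rest)
    pr <- stats::plogis(alpha + lp_slope + lp_rest)
    y <- with_substream(seed, paste0("outcome:", nm),
                        stats::rbinom(n, 1L, pr))
    ph[[nm]] <- y
    if (os$prevalent_fraction > 0) {
      pp <- stats::plogis(stats::qlogis(os$prevalent_fraction) +
                            config$prevalent_exposure_beta * xc)
      flag <- with_substream(seed, paste0("prevalent:", nm),
                             stats::runif(n) < pp)
      ph[[paste0("prevalent_", nm)]] <- as.integer(y == 1L & flag)
    } else {
      ph[[paste0("prevalent_", nm)]] <- 0L
    }
  }

  structure(list(
    genotypes = genotypes,
    phenotypes = ph,
    variants = config$variants,
    config = config,
    seed = as.integer(seed)
  ), class = "mr_cohort")
}

biomarker_values <- function(spec, name, exposure_centered, ph, seed) {
  n <- nrow(ph)
  cov_part <- numeric(n)
  for (cn in names(spec$covariate_effects))
    cov_part <- cov_part + spec$covariate_effects[[cn]] *
      (ph[[cn]] - covariate_means[[cn]])
  e <- with_substream(seed, paste0("biomarker:", name),
                      stats::rnorm(n, 0, spec$sd))
  core <- spec$mean + spec$loading * exposure_centered + cov_part + e
  if (isTRUE(spec$lognormal)) exp(core) else core
}

# Resolve the per-individual exposure coefficient (and, for marginal-scale
# constant effects, the calibrated conditional coefficient and intercept).
outcome_theta <- function(os, config, xc, modifiers) {
  eff <- os$effect
  if (eff$type == "constant" && eff$scale == "marginal") {
    if (length(os$covariate_effects))
      stop("marginal-scale outcomes cannot have covariate effects",
           call. = FALSE)
    if (length(config$covariate_effects) &&
        any(config$covariate_effects != 0))
      stop("marginal-scale calibration requires a configuration with no ",
           "covariate effects on the exposure", call. = FALSE)
    if (is.null(os$prevalence))
      stop("marginal-scale outcomes must state a target prevalence",
           call. = FALSE)
    mom <- implied_exposure_moments(config)
    kappa <- config$confounder_exposure_beta
    sde <- config$exposure_noise_sd
    q <- os$confounder_beta
    cal <- calibrate_marginal_effect(
      target_slope = eff$value,
      prevalence = os$prevalence,
      v_s = mom$score_var,
      resid_sd_fun = function(th) sqrt(th^2 * sde^2 + (th * kappa + q)^2)
    )
    list(theta_i = rep(cal$theta, length(xc)), alpha = cal$alpha,
         calibrated = TRUE)
  } else {
    list(theta_i = effect_theta(eff, xc, modifiers), alpha = NULL,
         calibrated = FALSE)
  }
}

outcome_intercept <- function(os, theta, config, lp) {
  if (theta$calibrated) return(theta$alpha)
  if (!is.null(os$prevalence)) {
    # deterministic given the realised linear predictors
    f <- function(a) mean(stats::plogis(a + lp)) - os$prevalence
    stats::uniroot(f, c(-40, 40), tol = 1e-10)$root
  } else {
    os$baseline
  }
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running [simulate_genotypes()] then
#' [simulate_phenotypes()] under one master seed.  Identical
#' (config, seed) pairs give identical cohorts.
#'
#' @inheritParams simulate_genotypes
#' @return An object of class `mr_cohort`: a list with `genotypes`
#'   (dosage matrix), `phenotypes` (data.frame keyed by `id`, aligned
#'   row-for-row with the genotype matrix), `variants` (annotation
#'   data.frame), and the generating `config` and `seed`.
#' @examples
#' cfg <- sim_config(n_individuals = 500)
#' ch <- simulate_cohort(cfg, seed = 7)
#' ch
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  g <- simulate_genotypes(config, seed)
  simulate_phenotypes(g, config, seed)
}

#' @export
print.mr_cohort <- function(x, ...) {
  ph <- x$phenotypes
  outs <- names(x$config$outcomes)
  cat("Synthetic MR cohort\n")
  cat(sprintf("  individuals: %d   variants: %d (seed %d)\n",
              nrow(ph), ncol(x$genotypes), x$seed))
  cat(sprintf("  exposure: mean %.2f, sd %.2f\n",
              mean(ph$exposure), stats::sd(ph$exposure)))
  if (length(outs)) {
    cs <- vapply(outs, function(o) sum(ph[[o]]), numeric(1))
    cat("  cases:", paste(sprintf("%s=%d", outs, cs), collapse = ", "),
        "\n")
  }
  invisible(x)
}
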