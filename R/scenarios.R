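# Fixed simulation-study designs.
#
# These presets define the study conditions under which the estimators and
# tests in this package are calibrated and validated.  They are fixed
# designs, not tuning knobs: sample sizes, instrument strengths and effect
# sizes were chosen once, by a priori power and attainability calculations
# (documented in the methods vignette), and the validation studies in
# tests/ and scripts/ run them as-is.

#' Simulation-study design presets
#'
#' Returns a [sim_config()] for one of the package's fixed validation
#' designs:
#'
#' * `"linear_recovery"`: 3 independent instruments jointly explaining
#'   about 1% of exposure variance, a shared unobserved confounder, and a
#'   gout-like outcome (prevalence 5%) whose effect is calibrated on the
#'   marginal scale so that the Wald-ratio estimand is exactly an odds
#'   ratio of 0.85 per 0.1 exposure-unit decrease.  Used for parameter
#'   recovery and CI coverage.
#' * `"ivw_equivalence"`: as above with instruments explaining ~2% of
#'   variance, for comparing the score-based Wald estimate with the
#'   inverse-variance-weighted combination of per-variant ratios.
#' * `"null_heterogeneity"`: instruments explaining ~3% of variance, an
#'   exogenous TG-like modifier, and an outcome with no exposure effect;
#'   stratum-specific estimates are null and homogeneous, for type-I
#'   error calibration of Cochran's Q and the trend test.
#' * `"quartile_effect"`: as `"null_heterogeneity"` plus (i) an AMI-like
#'   outcome whose exposure effect is nonzero only in the top TG
#'   quartile (log-odds 2.36 per exposure unit, the conditional analogue
#'   of a strong protective stratum effect) and (ii) a gout-like
#'   positive-control outcome with a strong constant effect.
#' * `"constant_effect_violation"`: the per-allele effect on the exposure
#'   is proportional to `1 + 0.5 z(TG)`, violating the constant genetic
#'   effect assumption that the residual method relies on.
#' * `"age_collider"`: age carries a per-allele dosage effect
#'   (0.3 years/allele), the situation the negative-control check must
#'   detect.
#'
#' @param name design name.
#' @param n cohort size override (each design has its intended default).
#' @return a `sim_config`.
#' @export
mr_scenario <- function(name = c("linear_recovery", "ivw_equivalence",
                                 "null_heterogeneity", "quartile_effect",
                                 "constant_effect_violation",
                                 "age_collider"),
                        n = NULL) {
  name <- match.arg(name)
  # marginal log odds per exposure-unit *increase* equivalent to OR 0.85
  # per 0.1-unit decrease
  theta_marginal <- -log(0.85) / 0.1

  iv3 <- function(betas)
    variant_panel(id = c("iv1", "iv2", "iv3"),
                  maf = c(0.30, 0.25, 0.40), beta = betas)

  strong_panel <- iv3(c(0.21, 0.22, 0.20))     # ~3% of exposure variance
  tg_exo <- list(tg = biomarker_spec(mean = 154.8, sd = 88, loading = 0))

  switch(name,
    linear_recovery = sim_config(
      n_individuals = n %||% 20000,
      variants = iv3(c(0.058, 0.062, 0.055)),  # ~1% of exposure variance
      ld_rho = numeric(0),
      exposure_intercept = 5.2,
      exposure_noise_sd = 0.55,
      covariate_effects = NULL,
      confounder_exposure_beta = 0.35,
      biomarkers = list(),
      outcomes = list(
        gout_like = outcome_spec(
          prevalence = 0.05,
          effect = mr_effect("constant", theta_marginal,
                             scale = "marginal"),
          confounder_beta = 0.3)
      )),
    ivw_equivalence = sim_config(
      n_individuals = n %||% 50000,
      variants = iv3(c(0.082, 0.088, 0.078)),  # ~2% of exposure variance
      ld_rho = numeric(0),
      exposure_intercept = 5.2,
      exposure_noise_sd = 0.55,
      covariate_effects = NULL,
      confounder_exposure_beta = 0.35,
      biomarkers = list(),
      outcomes = list(
        gout_like = outcome_spec(
          prevalence = 0.05,
          effect = mr_effect("constant", theta_marginal,
                             scale = "marginal"),
          confounder_beta = 0.3)
      )),
    null_heterogeneity = sim_config(
      n_individuals = n %||% 10000,
      variants = strong_panel,
      ld_rho = numeric(0),
      exposure_intercept = 5.2,
      exposure_noise_sd = 1.3,
      covariate_effects = NULL,
      confounder_exposure_beta = 0.3,
      biomarkers = tg_exo,
      outcomes = list(
        null_outcome = outcome_spec(
          prevalence = 0.15,
          effect = mr_effect("constant", 0),
          confounder_beta = 0.3)
      )),
    quartile_effect = sim_config(
      n_individuals = n %||% 20000,
      variants = strong_panel,
      ld_rho = numeric(0),
      exposure_intercept = 5.2,
      exposure_noise_sd = 1.3,
      covariate_effects = NULL,
      confounder_exposure_beta = 0.3,
      biomarkers = tg_exo,
      outcomes = list(
        ami_like = outcome_spec(
          prevalence = 0.10,
          effect = mr_effect("piecewise", modifier = "tg",
                             values = c(0, 0, 0, 2.36)),
          confounder_beta = 0.3),
        gout_like = outcome_spec(
          prevalence = 0.05,
          effect = mr_effect("constant", 3.0),
          confounder_beta = 0.3)
      )),
    constant_effect_violation = sim_config(
      n_individuals = n %||% 10000,
      variants = strong_panel,
      ld_rho = numeric(0),
      exposure_intercept = 5.2,
      exposure_noise_sd = 1.3,
      covariate_effects = NULL,
      confounder_exposure_beta = 0.3,
      biomarkers = tg_exo,
      genetic_effect_modifier = list(biomarker = "tg", lambda = 0.5),
      outcomes = list(
        null_outcome = outcome_spec(
          prevalence = 0.15,
          effect = mr_effect("constant", 0),
          confounder_beta = 0.3)
      )),
    age_collider = sim_config(
      n_individuals = n %||% 10000,
      variants = strong_panel,
      ld_rho = numeric(0),
      exposure_intercept = 5.2,
      exposure_noise_sd = 1.3,
      covariate_effects = NULL,
      confounder_exposure_beta = 0.3,
      biomarkers = list(),
      age_dosage_beta = 0.3,
      outcomes = list(
        null_outcome = outcome_spec(
          prevalence = 0.15,
          effect = mr_effect("constant", 0),
          confounder_beta = 0.3)
      ))
  )
}

# Instrument set carrying the in-sample GWAS weights for a known variant
# panel (no significance selection) — used by the validation studies,
# where the instruments are fixed by design.
ivset_from_gwas <- function(gwas, variant_ids = gwas$variant_id) {
  sel <- gwas[match(variant_ids, gwas$variant_id), , drop = FALSE]
  new_instrument_set(
    data.frame(variant_id = sel$variant_id, weight = sel$beta,
               p_value = sel$p_value, stringsAsFactors = FALSE),
    p_threshold = 1, r2_threshold = 1)
}

#' Instrument set from GWAS results for a fixed variant panel
#'
#' Builds an `instrument_set` carrying the GWAS betas as weights for a
#' caller-fixed set of variants, bypassing significance selection — the
#' design used when instruments are pre-specified.
#'
#' @param gwas an `mr_gwas` data.frame.
#' @param variant_ids variants to keep (default all).
#' @export
instrument_set_from_gwas <- function(gwas, variant_ids = gwas$variant_id)
  ivset_from_gwas(gwas, variant_ids)
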