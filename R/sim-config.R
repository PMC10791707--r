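# Simulation configuration for synthetic biobank-style cohorts.

#' Specify the variant panel of a simulated gene region
#'
#' @param id character vector of variant IDs.
#' @param maf minor (effect) allele frequencies in (0, 0.5].
#' @param beta per-allele effect on the exposure, in exposure units
#'   (mg/dL for a urate-like biomarker).  Zero for non-causal variants.
#' @param chrom,pos chromosome and 1-based position used by region filters.
#' @param block optional LD-block label; variants sharing a label are
#'   generated with correlated latent genotypes (see [sim_config()]'s
#'   `ld_rho`).  `NA` means the variant is independent of all others.
#' @return data.frame with one row per variant.
#' @export
variant_panel <- function(id, maf, beta = 0, chrom = "2", pos = NULL,
                          block = NA_character_) {
  k <- length(id)
  if (anyDuplicated(id)) stop("variant ids must be unique", call. = FALSE)
  if (is.null(pos)) pos <- 31500000 + seq_len(k) * 10000L
  out <- data.frame(
    id = as.character(id),
    maf = rep_len(maf, k),
    beta = rep_len(beta, k),
    chrom = rep_len(as.character(chrom), k),
    pos = rep_len(as.integer(pos), k),
    block = rep_len(as.character(block), k),
    stringsAsFactors = FALSE
  )
  if (any(out$maf <= 0 | out$maf > 0.5))
    stop("minor-allele frequencies must lie in (0, 0.5]", call. = FALSE)
  if (any(!is.finite(out$beta)))
    stop("variant effects must be finite", call. = FALSE)
  out
}

#' Specify a simulated biomarker
#'
#' Biomarkers are linear-Gaussian by default: `value = mean + loading *
#' (exposure - mean(exposure)) + covariate effects + Normal(0, sd)`.
#' With `lognormal = TRUE` the same linear construction is
#' built on the log scale and exponentiated, producing the heavier right
#' tail typical of triglycerides.
#'
#' @param mean marginal centre (mg/dL, kg/m2, or a ratio).
#' @param sd independent noise SD on the same scale (log scale if
#'   `lognormal`).
#' @param loading change in biomarker per exposure unit.
#' @param covariate_effects named numeric vector of linear effects of
#'   simulated covariates (`age`, `sex`, `pc1`..`pc5`) on the biomarker.
#' @param lognormal exponentiate a Gaussian core instead (off by default).
#' @export
biomarker_spec <- function(mean, sd, loading = 0,
                           covariate_effects = NULL, lognormal = FALSE) {
  stopifnot(is.numeric(mean), is.numeric(sd), sd >= 0)
  list(mean = mean, sd = sd, loading = loading,
       covariate_effects = covariate_effects, lognormal = lognormal)
}

#' Specify the causal effect of the exposure on a simulated outcome
#'
#' The outcome linear predictor is `baseline + theta_i * (exposure_i -
#' mean(exposure)) + confounder_beta * U_i + covariate effects`, with
#' `theta_i` given by the effect specification:
#'
#' * `constant`: one log-odds coefficient per exposure unit.  With
#'   `scale = "marginal"` the generator calibrates the conditional
#'   coefficient so that the instrument-level (Wald ratio) estimand equals
#'   `value` — see [calibrate_marginal_effect()] for why the two scales
#'   differ under a logistic link.
#' * `piecewise`: `theta_i` is constant within quantile bands of a named
#'   modifier biomarker (`probs` are interior band boundaries on the
#'   quantile scale, `values` has `length(probs) + 1` coefficients).
#' * `polynomial`: `theta_i = sum(coef[j] * m_c^(j-1))` where `m_c` is the
#'   centred modifier value.
#'
#' @param type one of "constant", "piecewise", "polynomial".
#' @param value constant log-odds per exposure unit.
#' @param scale "conditional" (default) or "marginal" (constant type only).
#' @param modifier biomarker name for piecewise/polynomial effects.
#' @param probs,values piecewise band boundaries and per-band coefficients.
#' @param coef polynomial coefficients, lowest order first.
#' @export
mr_effect <- function(type = c("constant", "piecewise", "polynomial"),
                      value = 0, scale = c("conditional", "marginal"),
                      modifier = NULL, probs = c(0.25, 0.5, 0.75),
                      values = NULL, coef = NULL) {
  type <- match.arg(type)
  scale <- match.arg(scale)
  if (type != "constant" && scale == "marginal")
    stop("marginal-scale calibration is only supported for constant effects",
         call. = FALSE)
  if (type %in% c("piecewise", "polynomial") && is.null(modifier))
    stop("piecewise/polynomial effects need a modifier biomarker",
         call. = FALSE)
  if (type == "piecewise") {
    if (is.null(values) || length(values) != length(probs) + 1L)
      stop("piecewise effects need length(probs) + 1 values", call. = FALSE)
  }
  if (type == "polynomial" && is.null(coef))
    stop("polynomial effects need coefficients", call. = FALSE)
  list(type = type, value = value, scale = scale, modifier = modifier,
       probs = probs, values = values, coef = coef)
}

#' Specify a simulated binary outcome
#'
#' @param baseline baseline log-odds at the exposure mean.  Alternatively
#'   give `prevalence` and the intercept is solved for.
#' @param prevalence target marginal prevalence in (0,1); overrides
#'   `baseline`.
#' @param effect an [mr_effect()] specification.
#' @param confounder_beta log-odds effect of the shared standard-normal
#'   confounder that also enters the exposure.
#' @param covariate_effects named log-odds effects of covariates.
#' @param prevalent_fraction expected fraction of cases flagged as
#'   diagnosed before exposure measurement.
#' @export
outcome_spec <- function(baseline = NULL, prevalence = NULL,
                         effect = mr_effect("constant", 0),
                         confounder_beta = 0, covariate_effects = NULL,
                         prevalent_fraction = 0) {
  if (is.null(baseline) && is.null(prevalence))
    stop("give either baseline log-odds or a target prevalence",
         call. = FALSE)
  if (!is.null(prevalence) && (prevalence <= 0 || prevalence >= 1))
    stop("prevalence must be in (0,1)", call. = FALSE)
  stopifnot(prevalent_fraction >= 0, prevalent_fraction <= 1)
  list(baseline = baseline, prevalence = prevalence, effect = effect,
       confounder_beta = confounder_beta,
       covariate_effects = covariate_effects,
       prevalent_fraction = prevalent_fraction)
}

default_biomarkers <- function() {
  # Marginal centres and spreads follow published UK-Biobank-scale summary
  # statistics for the lipid panel; the joint lipid-urate dependence is not
  # published at individual level, so loadings are free configuration with
  # modest defaults (positive for LDL-C/TG/TC:HDL, inverse for HDL-C).
  list(
    ldl = biomarker_spec(mean = 137.5, sd = 33, loading = 4,
                         covariate_effects = c(age = 0.3)),
    hdl = biomarker_spec(mean = 56.0, sd = 14.2, loading = -2,
                         covariate_effects = c(sex = -6)),
    tg = biomarker_spec(mean = 154.8, sd = 88, loading = 10),
    tc_hdl = biomarker_spec(mean = 4.24, sd = 1.2, loading = 0.15),
    bmi = biomarker_spec(mean = 27.3, sd = 4.5, loading = 0)
  )
}

default_outcomes <- function() {
  list(
    gout = outcome_spec(prevalence = 0.05,
                        effect = mr_effect("constant", 0.8),
                        confounder_beta = 0.2, prevalent_fraction = 0.3),
    ami = outcome_spec(prevalence = 0.03,
                       effect = mr_effect("piecewise", modifier = "tg",
                                          values = c(0, 0, 0, 0.6)),
                       confounder_beta = 0.2, prevalent_fraction = 0.1),
    ihd = outcome_spec(prevalence = 0.10,
                       effect = mr_effect("constant", 0),
                       confounder_beta = 0.2, prevalent_fraction = 0.1),
    cerebral_infarction = outcome_spec(
      prevalence = 0.02,
      effect = mr_effect("piecewise", modifier = "ldl",
                         values = c(0.5, 0.3, 0.5, 0)),
      confounder_beta = 0.2, prevalent_fraction = 0.1),
    tia = outcome_spec(prevalence = 0.015,
                       effect = mr_effect("constant", 0),
                       confounder_beta = 0.2, prevalent_fraction = 0.1),
    ischemic = outcome_spec(prevalence = 0.12,
                            effect = mr_effect("constant", 0.1),
                            confounder_beta = 0.2, prevalent_fraction = 0.1)
  )
}

default_variants <- function() {
  # A 12-variant cis region with three causal variants (the study design
  # this emulates settled on three instruments), two LD blocks and several
  # null variants.  Effects are sized so the three instruments jointly
  # explain about 1% of exposure variance at desk-scale n — large relative
  # to a biobank-scale cis signal, deliberately, so instrument selection
  # and estimation are well powered at simulable sample sizes.
  variant_panel(
    id = sprintf("rs%04d", 1:12),
    maf = c(0.30, 0.25, 0.40, 0.18, 0.32, 0.10, 0.45, 0.22, 0.35, 0.28,
            0.15, 0.38),
    beta = c(0.20, -0.18, 0.15, rep(0, 9)),
    pos = 31400000 + (0:11) * 90000L,
    block = c("b1", NA, NA, "b1", NA, "b2", "b2", NA, NA, NA, NA, NA)
  )
}

#' Build a simulation configuration
#'
#' Defines the full data-generating model for a synthetic cohort with a
#' biobank-like structure: genotype dosages in one gene region, a
#' continuous exposure biomarker (urate-like, mg/dL), correlated lipid
#' biomarkers, binary disease outcomes from logistic models whose exposure
#' effect may vary across modifier strata, and prevalent-case flags.
#'
#' @param n_individuals cohort size (>= 1).
#' @param variants a [variant_panel()] data.frame.
#' @param ld_rho named vector of within-block latent correlations in
#'   `[0, 1)`, one per block label used in `variants`.
#' @param exposure_intercept exposure value at zero dosage/covariates.
#' @param exposure_noise_sd SD of the independent exposure noise (mg/dL).
#' @param covariate_effects named effects of `age`, `sex`, `pc1`..`pc5` on
#'   the exposure (per year, per unit, ...).
#' @param confounder_exposure_beta effect of the shared standard-normal
#'   confounder on the exposure.
#' @param biomarkers named list of [biomarker_spec()]s.
#' @param outcomes named list of [outcome_spec()]s.
#' @param age_dosage_beta per-allele effect of total dosage on age; zero by
#'   default (age is a negative control), nonzero only for stress-testing
#'   the negative-control check.
#' @param genetic_effect_modifier optional `list(biomarker=, lambda=)`
#'   making the per-allele exposure effect proportional to
#'   `1 + lambda * z` where `z` is the standardised modifier value; the
#'   modifier must have zero loading on the exposure.  Used to stress-test
#'   the constant-genetic-effect assumption.
#' @param prevalent_exposure_beta log-odds effect of the centred exposure
#'   on the prevalent-case flag (zero keeps the flags independent of
#'   genotype so the prevalent-case filter can be exercised without
#'   biasing the GWAS).
#' @param genotype_missing_rate per-entry probability of a missing dosage.
#' @param seed default master seed used by [simulate_cohort()].
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 20000,
                       variants = default_variants(),
                       ld_rho = c(b1 = 0.85, b2 = 0.5),
                       exposure_intercept = 5.2,
                       exposure_noise_sd = 1.2,
                       covariate_effects = c(age = 0.01, sex = 0.8,
                                             pc1 = 0.05),
                       confounder_exposure_beta = 0.3,
                       biomarkers = default_biomarkers(),
                       outcomes = default_outcomes(),
                       age_dosage_beta = 0,
                       genetic_effect_modifier = NULL,
                       prevalent_exposure_beta = 0,
                       genotype_missing_rate = 0,
                       seed = 1L) {
  if (!is.numeric(n_individuals) || n_individuals < 1)
    stop("n_individuals must be >= 1", call. = FALSE)
  if (any(variants$maf <= 0 | variants$maf > 0.5))
    stop("minor-allele frequencies must lie in (0, 0.5]", call. = FALSE)
  blocks <- unique(stats::na.omit(variants$block))
  for (b in blocks) {
    if (!b %in% names(ld_rho))
      stop(sprintf("no ld_rho entry for block '%s'", b), call. = FALSE)
  }
  if (length(ld_rho) && any(ld_rho < 0 | ld_rho >= 1))
    stop("ld_rho values must lie in [0, 1)", call. = FALSE)
  if (exposure_noise_sd < 0) stop("exposure_noise_sd must be >= 0",
                                  call. = FALSE)
  if (!is.null(genetic_effect_modifier)) {
    m <- genetic_effect_modifier$biomarker
    if (is.null(biomarkers[[m]]))
      stop("genetic_effect_modifier biomarker not in biomarker list",
           call. = FALSE)
    if (biomarkers[[m]]$loading != 0)
      stop("the genetic-effect modifier biomarker must have zero loading ",
           "on the exposure (it must be exogenous)", call. = FALSE)
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    variants = variants,
    ld_rho = ld_rho,
    exposure_intercept = exposure_intercept,
    exposure_noise_sd = exposure_noise_sd,
    covariate_effects = covariate_effects,
    confounder_exposure_beta = confounder_exposure_beta,
    biomarkers = biomarkers,
    outcomes = outcomes,
    age_dosage_beta = age_dosage_beta,
    genetic_effect_modifier = genetic_effect_modifier,
    prevalent_exposure_beta = prevalent_exposure_beta,
    genotype_missing_rate = genotype_missing_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Closed-form moments implied by a configuration (independent of any draw).
# Covariate means: age 56.5, sex 0.5, pcs 0.  Used by marginal checks and
# by outcome-intercept calibration.
covariate_means <- c(age = 56.5, sex = 0.5, pc1 = 0, pc2 = 0, pc3 = 0,
                     pc4 = 0, pc5 = 0)
covariate_vars <- c(age = 8.1^2, sex = 0.25, pc1 = 1, pc2 = 1, pc3 = 1,
                    pc4 = 1, pc5 = 1)

#' Moments of the simulated exposure implied by a configuration
#'
#' Returns the closed-form mean and variance of the exposure under the
#' generator, plus the variance of the true-weight genetic score, assuming
#' the configured LD structure (correlated variants contribute covariance
#' via their latent-threshold construction only when in the same block;
#' the closed form here treats nonzero-effect variants as independent and
#' refuses blocks containing two causal variants).
#'
#' @param config a [sim_config()].
#' @export
implied_exposure_moments <- function(config) {
  v <- config$variants
  causal <- v[v$beta != 0, , drop = FALSE]
  if (any(duplicated(stats::na.omit(causal$block))))
    stop("closed-form moments unavailable: two causal variants share an ",
         "LD block", call. = FALSE)
  vg <- sum(causal$beta^2 * 2 * causal$maf * (1 - causal$maf))
  mg <- sum(causal$beta * 2 * causal$maf)
  ce <- config$covariate_effects
  ce <- ce[!is.na(ce)]
  mc <- sum(ce * covariate_means[names(ce)])
  vc <- sum(ce^2 * covariate_vars[names(ce)])
  list(
    mean = config$exposure_intercept + mg + mc,
    var = vg + vc + config$confounder_exposure_beta^2 +
      config$exposure_noise_sd^2,
    score_var = vg,
    score_mean = mg
  )
}
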