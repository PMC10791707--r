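# End-to-end orchestration: simulate -> gwas -> select-iv -> score ->
# mr-linear -> mr-nonlinear, with a JSON config, a run manifest and
# deterministic outputs.

default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "dtmr_run",
    simulation = list(n_individuals = 5000),
    region = NULL,               # "chrom:start-end"; NULL = all variants
    flank = 5e5,
    covariates = c("age", "sex", "pc1", "pc2", "pc3", "pc4", "pc5",
                   "array", "centre"),
    p_threshold = "bonferroni",  # or a number; "genome_wide" = 5e-8
    r2_threshold = 0.1,
    exclusion_list = NULL,       # path, one variant ID per line
    outcomes = NULL,             # NULL = all configured outcomes
    stratifiers = c("ldl", "hdl", "tg", "tc_hdl"),
    n_strata = 4L,
    scale = 0.1,
    direction = "decrease",
    alpha = 0.05
  )
}

#' Validate and complete a pipeline run configuration
#'
#' Fills defaults (scale 0.1, quartile strata, alpha 0.05, r2 0.1,
#' gene-specific Bonferroni p threshold) and checks types before any
#' stage runs.
#'
#' @param config named list (e.g. from [jsonlite::read_json()]) or a path
#'   to a JSON file.
#' @return validated config list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  base <- default_run_config()
  unknown <- setdiff(names(config), c(names(base), "input_dir"))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(base, config)
  if (is.null(cfg$simulation) && is.null(cfg$input_dir))
    stop("config must provide either a 'simulation' block or an ",
         "'input_dir' with cohort TSVs", call. = FALSE)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L)
    stop("config 'seed' must be a single integer", call. = FALSE)
  if (!(is.numeric(cfg$r2_threshold) && cfg$r2_threshold > 0 &&
        cfg$r2_threshold <= 1))
    stop("config 'r2_threshold' must be in (0, 1]", call. = FALSE)
  if (is.character(cfg$p_threshold) &&
      !cfg$p_threshold %in% c("bonferroni", "genome_wide"))
    stop("config 'p_threshold' must be numeric, 'bonferroni' or ",
         "'genome_wide'", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_strata <- as.integer(cfg$n_strata)
  cfg
}

# Coerce a simulation block parsed from JSON (plain nested lists) into the
# typed spec objects the generator expects.  Already-typed values pass
# through untouched.
normalize_sim_spec <- function(sim) {
  if (!is.null(sim$variants) && !is.data.frame(sim$variants))
    sim$variants <- do.call(variant_panel,
                            lapply(sim$variants, unlist))
  if (!is.null(sim$ld_rho)) sim$ld_rho <- unlist(sim$ld_rho)
  if (!is.null(sim$covariate_effects))
    sim$covariate_effects <- unlist(sim$covariate_effects)
  if (!is.null(sim$biomarkers))
    sim$biomarkers <- lapply(sim$biomarkers, function(b) {
      if (!is.null(b$covariate_effects))
        b$covariate_effects <- unlist(b$covariate_effects)
      do.call(biomarker_spec, b)
    })
  if (!is.null(sim$outcomes))
    sim$outcomes <- lapply(sim$outcomes, function(o) {
      if (!is.null(o$effect))
        o$effect <- do.call(mr_effect, lapply(o$effect, function(x)
          if (is.list(x)) unlist(x) else x))
      if (!is.null(o$covariate_effects))
        o$covariate_effects <- unlist(o$covariate_effects)
      do.call(outcome_spec, o)
    })
  sim
}

#' Build a simulation config from a pipeline run config
#'
#' @param cfg validated run config (see [validate_run_config()]).
#' @return a `sim_config` seeded from the run config.
#' @export
sim_config_from_run <- function(cfg) {
  sim <- normalize_sim_spec(cfg$simulation)
  do.call(sim_config, c(sim, list(seed = cfg$seed)))
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(structure(class = c("dtmr_stage_error", "error", "condition"),
                   list(message = sprintf("[stage %s] %s", name,
                                          conditionMessage(e)),
                        call = NULL, stage = name,
                        code = paste0("E_", toupper(name)))))
  })
}

log_stage <- function(quiet, stage, seed, fmt, ...) {
  if (!quiet)
    message(sprintf("[%s seed=%d] %s", stage, seed, sprintf(fmt, ...)))
}

#' Run the full drug-target MR pipeline
#'
#' Executes simulate (or load) -> exposure GWAS -> instrument selection
#' (clumping, optional exclusion list, strength, negative controls) ->
#' genetic score -> linear MR -> nonlinear MR, writing each stage's
#' outputs under `config$out_dir` together with a `manifest.json`
#' recording the config hash, seed and package version.  Re-running with
#' an identical config and seed reproduces the outputs.
#'
#' @param config a config list or JSON path; see [validate_run_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a results bundle: cohort, gwas, ivset, linear and
#'   nonlinear results, paths.
#' @export
run_full_pipeline <- function(config, quiet = FALSE) {
  cfg <- pipeline_stage("config", validate_run_config(config))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed

  cohort <- pipeline_stage("simulate", {
    if (!is.null(cfg$input_dir)) {
      ch <- read_cohort(cfg$input_dir)
      log_stage(quiet, "simulate", seed, "loaded %d individuals from %s",
                nrow(ch$phenotypes), cfg$input_dir)
      ch
    } else {
      sc <- sim_config_from_run(cfg)
      ch <- simulate_cohort(sc, seed)
      log_stage(quiet, "simulate", seed, "simulated %d individuals, %d variants",
                nrow(ch$phenotypes), ncol(ch$genotypes))
      ch
    }
  })

  outcome_names <- cfg$outcomes %||% names(cohort$config$outcomes) %||%
    stop("no outcomes configured", call. = FALSE)
  gwas_outcome <- outcome_names[1L]  # exposure GWAS filters its
                                     # positive-control outcome's
                                     # prevalent cases

  gwas <- pipeline_stage("gwas", {
    region_ids <- if (is.null(cfg$region)) cohort$variants$id
    else variants_in_region(cohort$variants, cfg$region, cfg$flank)
    gcoh <- filter_cohort(cohort, gwas_outcome, drop_prevalent = TRUE)
    log_stage(quiet, "gwas", seed, "%d rows after prevalent-case filter (%d removed)",
              nrow(gcoh$phenotypes), attr(gcoh, "n_removed"))
    g <- run_region_gwas(gcoh, region_ids, cfg$covariates)
    write_gwas(g, file.path(cfg$out_dir, "gwas.tsv"))
    g
  })

  ivset <- pipeline_stage("select-iv", {
    p_thr <- if (identical(cfg$p_threshold, "bonferroni"))
      bonferroni_threshold(nrow(gwas))
    else if (identical(cfg$p_threshold, "genome_wide")) 5e-8
    else as.numeric(cfg$p_threshold)
    gcoh <- filter_cohort(cohort, gwas_outcome, drop_prevalent = TRUE)
    iv <- clump(gwas, gcoh$genotypes, p_thr, cfg$r2_threshold)
    if (!is.null(cfg$exclusion_list))
      iv <- apply_exclusion_list(iv, read_exclusion_list(cfg$exclusion_list))
    if (nrow(iv$variants) == 0L)
      stop("no instruments retained", call. = FALSE)
    st <- instrument_strength(gcoh, iv, cfg$covariates)
    iv$f_statistic <- st$f_statistic
    iv$r_squared <- st$r_squared
    write_instrument_set(iv, file.path(cfg$out_dir, "instruments.json"))
    log_stage(quiet, "select-iv", seed, "%d instruments (F = %.2f, R2 = %.4g)",
              nrow(iv$variants), st$f_statistic, st$r_squared)
    iv
  })

  neg <- pipeline_stage("score", {
    score <- compute_score(cohort$genotypes, ivset)
    nc <- negative_control_check(cohort, score, alpha = cfg$alpha)
    utils::write.table(nc, file.path(cfg$out_dir, "negative_controls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage(quiet, "score", seed, "score computed for %d individuals",
              length(score))
    nc
  })

  lin <- pipeline_stage("mr-linear", {
    lm_res <- linear_mr(cohort, ivset, outcome_names, cfg$covariates,
                        scale = cfg$scale, direction = cfg$direction)
    utils::write.table(as.data.frame(lm_res),
                       file.path(cfg$out_dir, "linear_mr.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage(quiet, "mr-linear", seed, "%d outcomes estimated",
              nrow(lm_res))
    lm_res
  })

  nl <- pipeline_stage("mr-nonlinear", {
    score <- compute_score(cohort$genotypes, ivset)
    plei <- pleiotropy_biomarker_check(
      cohort, score, intersect(cfg$stratifiers,
                               names(cohort$phenotypes)),
      cfg$covariates)
    res <- list(); tests <- list(); strata_rows <- list()
    n_tests <- 0L
    for (out in outcome_names) {
      for (st in cfg$stratifiers) {
        fit <- nonlinear_mr(cohort, ivset, out, st, cfg$covariates,
                            cfg$n_strata, method = "residual",
                            scale = cfg$scale,
                            direction = cfg$direction,
                            alpha = cfg$alpha)
        key <- paste(out, st, sep = ".")
        res[[key]] <- fit
        n_tests <- n_tests + 2L
        s <- fit$strata
        strata_rows[[key]] <- data.frame(
          outcome = out, stratifier = st, method = fit$method,
          s[, c("stratum", "n", "n_cases", "stratifier_mean",
                "stratifier_min", "stratifier_max", "or", "ci_low",
                "ci_high", "p_value")])
        tests[[key]] <- data.frame(
          outcome = out, stratifier = st,
          q = fit$heterogeneity$q %||% NA_real_,
          p_heterogeneity = fit$heterogeneity$p %||% NA_real_,
          trend_slope = fit$trend$slope %||% NA_real_,
          p_trend = fit$trend$p_trend %||% NA_real_,
          p_quadratic = fit$trend$p_quadratic %||% NA_real_,
          p_constant_effect = fit$constant_effect$p_heterogeneity)
      }
    }
    utils::write.table(do.call(rbind, strata_rows),
                       file.path(cfg$out_dir, "nonlinear_strata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(do.call(rbind, tests),
                       file.path(cfg$out_dir, "nonlinear_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(plei,
                       file.path(cfg$out_dir, "pleiotropy_biomarkers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage(quiet, "mr-nonlinear", seed,
              "%d outcome x stratifier fits; %d tests performed (no multiplicity correction applied)",
              length(res), n_tests)
    list(fits = res, tests = do.call(rbind, tests), pleiotropy = plei)
  })

  manifest <- pipeline_stage("report", {
    cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                                 null = "null")
    tmp <- tempfile(); writeLines(cfg_json, tmp)
    man <- list(
      package = "dtmr",
      version = as.character(utils::packageVersion("dtmr")),
      seed = seed,
      config = cfg,
      config_hash = unname(tools::md5sum(tmp)),
      n_individuals = nrow(cohort$phenotypes)
    )
    unlink(tmp)
    jsonlite::write_json(man, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    report <- list(
      manifest = man,
      instruments = ivset$variants,
      instrument_strength = list(f = ivset$f_statistic,
                                 r_squared = ivset$r_squared),
      negative_controls = neg,
      linear_mr = as.data.frame(lin),
      nonlinear_tests = nl$tests,
      pleiotropy_biomarkers = nl$pleiotropy
    )
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null", null = "null")
    man
  })

  invisible(list(config = cfg, cohort = cohort, gwas = gwas,
                 ivset = ivset, negative_controls = neg, linear = lin,
                 nonlinear = nl, manifest = manifest,
                 out_dir = cfg$out_dir))
}
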