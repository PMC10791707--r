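# Stratum-specific Wald estimation, heterogeneity and trend tests, and the
# assumption checks of nonlinear MR.

#' Stratum-specific Wald estimates
#'
#' Re-fits the score-exposure and score-outcome regressions within each
#' stratum and forms the Wald ratio per stratum.  Strata in which the
#' outcome has a single class yield a flagged missing estimate (excluded
#' from downstream tests with a warning) rather than an error.
#'
#' @param cohort an `mr_cohort` (same rows the assignment was built on).
#' @param assignment a `stratum_assignment`.
#' @param ivset an `instrument_set`.
#' @param outcome_name binary outcome column.
#' @param covariate_names covariates for both regressions.
#' @param scale,direction reporting scale; see [wald_ratio()].
#' @return data.frame with one row per stratum (stratifier summary, case
#'   counts, OR, CI, p, theta, se, status); full `wald_estimate` objects
#'   in the `"estimates"` attribute.
#' @export
stratum_estimates <- function(cohort, assignment, ivset, outcome_name,
                              covariate_names = NULL, scale = 0.1,
                              direction = "decrease") {
  stopifnot(inherits(assignment, "stratum_assignment"))
  n <- nrow(cohort$phenotypes)
  if (length(assignment$index) != n)
    stop("assignment does not match cohort rows", call. = FALSE)
  score <- compute_score(cohort$genotypes, ivset)
  rows <- list(); ests <- list()
  for (j in seq_len(assignment$n_strata)) {
    in_j <- assignment$index == j
    sub <- cohort
    sub$phenotypes <- cohort$phenotypes[in_j, , drop = FALSE]
    sub$genotypes <- cohort$genotypes[in_j, , drop = FALSE]
    s_j <- score[in_j]
    summ <- assignment$summary[assignment$summary$stratum == j, ]
    base <- data.frame(
      stratum = j, n = sum(in_j),
      stratifier_mean = summ$mean, stratifier_min = summ$min,
      stratifier_max = summ$max, n_cases = NA_integer_,
      theta = NA_real_, se = NA_real_, or = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
      status = "ok", stringsAsFactors = FALSE)
    est <- tryCatch({
      ge <- score_exposure_effect(sub, s_j, covariate_names)
      oe <- score_outcome_effect(sub, s_j, outcome_name, covariate_names)
      w <- suppressWarnings(
        wald_ratio(ge, oe, scale = scale, direction = direction))
      base$n_cases <- oe$n_cases
      base$theta <- w$theta; base$se <- w$se; base$or <- w$or
      base$ci_low <- w$ci_low; base$ci_high <- w$ci_high
      base$p_value <- w$p_value
      if (length(w$flags)) base$status <- paste(w$flags, collapse = ";")
      ests[[j]] <- w
      base
    }, error = function(e) {
      warning(sprintf("stratum %d: %s", j, conditionMessage(e)),
              call. = FALSE)
      base$status <- "no_estimate"
      base
    })
    rows[[j]] <- est
  }
  out <- do.call(rbind, rows)
  attr(out, "estimates") <- ests
  attr(out, "outcome") <- outcome_name
  attr(out, "assignment") <- assignment
  out
}

#' Cochran's Q heterogeneity test
#'
#' With inverse-variance weights `w_j = 1/se_j^2` and pooled effect
#' `theta_bar = sum(w theta)/sum(w)`,
#' `Q = sum(w_j (theta_j - theta_bar)^2)` is referred to a chi-square
#' distribution with `J - 1` degrees of freedom.
#'
#' @param estimates data.frame (or list) with `theta` and `se` columns;
#'   rows with missing values are dropped.
#' @return list: `q`, `df`, `p`, `theta_pooled`.
#' @export
cochran_q <- function(estimates) {
  est <- as.data.frame(estimates)
  est <- est[is.finite(est$theta) & is.finite(est$se), , drop = FALSE]
  if (nrow(est) < 2L)
    stop("cochran_q: need at least 2 estimates with finite SEs",
         call. = FALSE)
  w <- 1 / est$se^2
  tb <- sum(w * est$theta) / sum(w)
  q <- sum(w * (est$theta - tb)^2)
  df <- nrow(est) - 1L
  list(q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE),
       theta_pooled = tb)
}

#' Trend test across stratum-specific estimates
#'
#' Weighted least squares of the stratum effects `theta_j` on the stratum
#' means `m_j` of the observed stratifier, with known-variance weights
#' `1/se_j^2`; the two-sided normal test of the linear slope is the
#' default `p_trend` (a linear trend in stratum log odds ratios
#' corresponds to a quadratic overall exposure-outcome shape, hence
#' "quadratic-trend test").  With at least 4 usable strata a quadratic
#' coefficient (on `m_j^2`) is additionally reported from the
#' linear+quadratic fit.  Set `use_index = TRUE` to regress on the
#' stratum index instead of the stratum means.
#'
#' @param estimates data.frame with `theta` and `se`.
#' @param stratum_means stratum means of the observed stratifier (same
#'   length); ignored when `use_index = TRUE`.
#' @param use_index regress on 1..J instead of the means.
#' @return list: `slope`, `slope_se`, `p_trend`, and (when estimable)
#'   `quadratic`, `quadratic_se`, `p_quadratic`.
#' @export
trend_test <- function(estimates, stratum_means = NULL,
                       use_index = FALSE) {
  est <- as.data.frame(estimates)
  J0 <- nrow(est)
  if (use_index) stratum_means <- seq_len(J0)
  if (is.null(stratum_means) && "stratifier_mean" %in% names(est))
    stratum_means <- est$stratifier_mean
  if (length(stratum_means) != J0)
    stop("stratum_means must match the number of estimates",
         call. = FALSE)
  ok <- is.finite(est$theta) & is.finite(est$se) &
    is.finite(stratum_means)
  est <- est[ok, , drop = FALSE]
  m <- stratum_means[ok]
  J <- nrow(est)
  if (J < 3L)
    stop("trend_test: need at least 3 usable strata", call. = FALSE)
  w <- 1 / est$se^2
  wls <- function(Xm) {
    WX <- Xm * w
    V <- solve(crossprod(Xm, WX))
    b <- V %*% crossprod(WX, est$theta)
    list(b = as.numeric(b), se = unname(sqrt(diag(V))))
  }
  mc <- m - mean(m)
  lin <- wls(cbind(1, mc))
  slope <- lin$b[2L]; slope_se <- lin$se[2L]
  out <- list(slope = slope, slope_se = slope_se,
              p_trend = 2 * stats::pnorm(-abs(slope / slope_se)),
              quadratic = NA_real_, quadratic_se = NA_real_,
              p_quadratic = NA_real_)
  if (J >= 4L) {
    quad <- wls(cbind(1, mc, mc^2))
    out$quadratic <- quad$b[3L]
    out$quadratic_se <- quad$se[3L]
    out$p_quadratic <- 2 * stats::pnorm(-abs(quad$b[3L] / quad$se[3L]))
  }
  out
}

#' Constant-genetic-effect check
#'
#' The residual method assumes the genetic effect on the exposure is the
#' same for everyone.  The check estimates the score-exposure coefficient
#' within each doubly-ranked stratum and compares them with Cochran's Q; a
#' small heterogeneity p-value flags a violation.
#'
#' @param cohort an `mr_cohort`.
#' @param assignment a doubly-ranked `stratum_assignment`.
#' @param ivset an `instrument_set`.
#' @param covariate_names covariates for the per-stratum regressions.
#' @param alpha flag threshold.
#' @return list: per-stratum `gammas` data.frame, `q`, `df`,
#'   `p_heterogeneity`, `pass`.
#' @export
constant_effect_check <- function(cohort, assignment, ivset,
                                  covariate_names = NULL, alpha = 0.05) {
  stopifnot(inherits(assignment, "stratum_assignment"))
  if (assignment$n_strata < 2L)
    stop("constant_effect_check: need at least 2 strata", call. = FALSE)
  score <- compute_score(cohort$genotypes, ivset)
  rows <- lapply(seq_len(assignment$n_strata), function(j) {
    in_j <- assignment$index == j
    sub <- cohort
    sub$phenotypes <- cohort$phenotypes[in_j, , drop = FALSE]
    sub$genotypes <- cohort$genotypes[in_j, , drop = FALSE]
    ge <- score_exposure_effect(sub, score[in_j], covariate_names)
    data.frame(stratum = j, theta = ge$gamma, se = ge$se)
  })
  tab <- do.call(rbind, rows)
  q <- cochran_q(tab)
  list(gammas = data.frame(stratum = tab$stratum, gamma = tab$theta,
                           se = tab$se),
       q = q$q, df = q$df, p_heterogeneity = q$p,
       pass = q$p >= alpha, alpha = alpha)
}

#' Score-biomarker pleiotropy check
#'
#' OLS of each biomarker on the genetic score plus covariates.  Null
#' associations support the assumption that the score affects the outcome
#' only through the exposure (not through the lipid profile) and that
#' stratifying on the biomarkers is safe.
#'
#' @param cohort an `mr_cohort`.
#' @param score per-individual genetic score.
#' @param biomarker_names biomarker columns to test.
#' @param covariate_names adjustment covariates.
#' @return data.frame: biomarker, beta, se, p, status.
#' @export
pleiotropy_biomarker_check <- function(cohort, score, biomarker_names,
                                       covariate_names = NULL) {
  ph <- cohort$phenotypes
  missing_cols <- setdiff(biomarker_names, names(ph))
  if (length(missing_cols))
    stop("unknown biomarker columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  s <- as.numeric(score)
  X <- build_design(ph, covariate_names)
  rows <- lapply(biomarker_names, function(bn) {
    yv <- as.numeric(ph[[bn]])
    ok <- complete_rows(X, s, yv)
    if (stats::sd(yv[ok]) == 0)
      return(data.frame(biomarker = bn, beta = NA_real_, se = NA_real_,
                        p = NA_real_, status = "degenerate"))
    fit <- ols_fit(yv[ok], cbind(score = s[ok], X[ok, , drop = FALSE]))
    data.frame(biomarker = bn, beta = unname(fit$coef["score"]),
               se = unname(fit$se["score"]), p = unname(fit$p["score"]),
               status = "ok")
  })
  do.call(rbind, rows)
}

#' Nonlinear MR: stratum-specific causal effects with nonlinearity tests
#'
#' The top-level fitting function for stratified (nonlinear) MR of one
#' outcome.  Prevalent cases of the outcome are excluded; the cohort is
#' stratified on `stratifier_name` by the requested method; the Wald
#' ratio is estimated within each stratum; heterogeneity (Cochran's Q)
#' and the quadratic-trend test summarise nonlinearity; and the
#' constant-genetic-effect assumption is checked on a doubly-ranked
#' assignment.
#'
#' @param cohort an `mr_cohort`.
#' @param ivset an `instrument_set`.
#' @param outcome_name binary outcome column.
#' @param stratifier_name biomarker (or `"exposure"`) to stratify on.
#' @param covariate_names GWAS covariates.
#' @param n_strata number of strata (quartiles by default).
#' @param method stratification method.
#' @param scale,direction reporting scale; see [wald_ratio()].
#' @param alpha flag threshold for the assumption checks.
#' @param drop_prevalent exclude prevalent cases of the outcome.
#' @return object of class `nonlinear_mr`: stratum table, Q and trend
#'   tests, constant-effect check, assignment, call.
#' @export
nonlinear_mr <- function(cohort, ivset, outcome_name, stratifier_name,
                         covariate_names = NULL, n_strata = 4L,
                         method = c("residual", "doubly_ranked",
                                    "observed"),
                         scale = 0.1, direction = "decrease",
                         alpha = 0.05, drop_prevalent = TRUE) {
  method <- match.arg(method)
  sub <- filter_cohort(cohort, outcome_name,
                       drop_prevalent = drop_prevalent)
  score <- compute_score(sub$genotypes, ivset)
  assignment <- switch(method,
    residual = residual_stratify(sub, stratifier_name, score,
                                 covariate_names, n_strata),
    doubly_ranked = doubly_ranked_stratify(sub, score, stratifier_name,
                                           n_strata),
    observed = observed_stratify(sub, stratifier_name, n_strata))
  strata <- stratum_estimates(sub, assignment, ivset, outcome_name,
                              covariate_names, scale, direction)
  usable <- strata[strata$status != "no_estimate", , drop = FALSE]
  q <- if (nrow(usable) >= 2L) cochran_q(usable) else NULL
  tr <- if (nrow(usable) >= 3L)
    trend_test(usable, usable$stratifier_mean) else NULL
  dr <- if (method == "doubly_ranked") assignment
  else doubly_ranked_stratify(sub, score, stratifier_name, n_strata)
  cec <- constant_effect_check(sub, dr, ivset, covariate_names, alpha)
  structure(list(
    outcome = outcome_name, stratifier = stratifier_name,
    method = method, n_strata = n_strata,
    strata = strata, heterogeneity = q, trend = tr,
    constant_effect = cec, assignment = assignment,
    scale = scale, direction = direction,
    n = nrow(sub$phenotypes), call = match.call()
  ), class = "nonlinear_mr")
}

#' @export
print.nonlinear_mr <- function(x, ...) {
  cat(sprintf(
    "Nonlinear MR: %s across %s-strata of '%s' (%d individuals)\n",
    x$outcome, x$method, x$stratifier, x$n))
  cols <- c("stratum", "n", "n_cases", "stratifier_mean",
            "stratifier_min", "stratifier_max", "or", "ci_low",
            "ci_high", "p_value")
  print.data.frame(x$strata[, cols], digits = 4, row.names = FALSE)
  if (!is.null(x$heterogeneity))
    cat(sprintf("Heterogeneity: Q = %.3f (df %d), p = %.3g\n",
                x$heterogeneity$q, x$heterogeneity$df,
                x$heterogeneity$p))
  if (!is.null(x$trend))
    cat(sprintf("Trend: slope = %.4g (se %.3g), p_trend = %.3g\n",
                x$trend$slope, x$trend$slope_se, x$trend$p_trend))
  cat(sprintf("Constant genetic effect: Q p = %.3g (%s)\n",
              x$constant_effect$p_heterogeneity,
              if (x$constant_effect$pass) "no violation detected"
              else "possible violation"))
  invisible(x)
}

#' @export
summary.nonlinear_mr <- function(object, ...) {
  out <- list(
    outcome = object$outcome, stratifier = object$stratifier,
    method = object$method, strata = object$strata,
    q = object$heterogeneity$q %||% NA_real_,
    p_heterogeneity = object$heterogeneity$p %||% NA_real_,
    trend_slope = object$trend$slope %||% NA_real_,
    p_trend = object$trend$p_trend %||% NA_real_,
    p_quadratic = object$trend$p_quadratic %||% NA_real_,
    p_constant_effect = object$constant_effect$p_heterogeneity)
  class(out) <- "summary.nonlinear_mr"
  out
}

#' @export
print.summary.nonlinear_mr <- function(x, ...) {
  cat(sprintf("%s | %s (%s): p_het = %.3g, p_trend = %.3g, p_quad = %.3g,",
              x$outcome, x$stratifier, x$method, x$p_heterogeneity,
              x$p_trend, x$p_quadratic))
  cat(sprintf(" p_const = %.3g\n", x$p_constant_effect))
  invisible(x)
}

#' @export
coef.nonlinear_mr <- function(object, ...) {
  stats::setNames(object$strata$theta,
                  paste0("stratum", object$strata$stratum))
}
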