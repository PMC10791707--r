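# Ratio-of-coefficients (Wald) estimation and the linear MR table.

#' Wald ratio estimate with delta-method uncertainty
#'
#' The causal log odds ratio per exposure unit is
#' `theta = big_gamma / gamma`, the score-outcome log-odds effect divided
#' by the score-exposure effect.  Its standard error uses the second-order
#' delta method
#' `se^2 = se_G^2 / gamma^2 + big_gamma^2 * se_g^2 / gamma^4`
#' (first-order `se_G / |gamma|` behind `second_order = FALSE`).  Results
#' are reported as an odds ratio per `scale` exposure units
#' (`OR = exp(s * theta * scale)` with `s = -1` for `direction =
#' "decrease"`), with a 95% normal-approximation CI and two-sided p-value
#' on `theta / se`.  Internally `theta` is always per exposure-unit
#' increase; the direction flip happens only at reporting.  A Fieller CI
#' for weak-instrument robustness is available via `fieller = TRUE`
#' (assuming independent numerator and denominator estimates).
#'
#' @param gamma_est list with `gamma` and `se` (from
#'   [score_exposure_effect()]).
#' @param big_gamma_est list with `big_gamma` and `se` (from
#'   [score_outcome_effect()]).
#' @param scale exposure units per reported unit (default 0.1, i.e.
#'   results per 0.1 mg/dL for a urate-like exposure).
#' @param direction report per-increase or per-decrease of the exposure.
#' @param second_order use the second-order delta SE (default).
#' @param fieller also compute a Fieller confidence interval.
#' @param weak_f_floor attach a weak-instrument flag when
#'   `(gamma/se_gamma)^2` falls below this F floor (default 10).
#' @param conf_level confidence level.
#' @return object of class `wald_estimate`.
#' @export
wald_ratio <- function(gamma_est, big_gamma_est, scale = 0.1,
                       direction = c("decrease", "increase"),
                       second_order = TRUE, fieller = FALSE,
                       weak_f_floor = 10, conf_level = 0.95) {
  direction <- match.arg(direction)
  g <- gamma_est$gamma; seg <- gamma_est$se
  G <- big_gamma_est$big_gamma; seG <- big_gamma_est$se
  if (!is.finite(g) || g == 0)
    stop("wald_ratio: score-exposure effect (gamma) must be nonzero",
         call. = FALSE)
  theta <- G / g
  se <- if (second_order) {
    sqrt(seG^2 / g^2 + G^2 * seg^2 / g^4)
  } else {
    seG / abs(g)
  }
  flags <- character(0)
  fstat <- (g / seg)^2
  if (is.finite(fstat) && fstat < weak_f_floor) {
    flags <- c(flags, "weak_instrument")
    warning(sprintf(
      "weak instrument: denominator F = %.2f below floor %.1f",
      fstat, weak_f_floor), call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  s <- if (direction == "decrease") -1 else 1
  or <- exp(s * theta * scale)
  ci <- sort(exp(s * scale * (theta + c(-1, 1) * z * se)))
  p <- if (se == 0) as.numeric(theta == 0) else
    2 * stats::pnorm(-abs(theta / se))
  fieller_ci <- NULL
  if (fieller) {
    # Fieller's theorem for G/g with independent normal errors
    a <- g^2 - z^2 * seg^2
    b <- -2 * G * g
    cc <- G^2 - z^2 * seG^2
    disc <- b^2 - 4 * a * cc
    if (a > 0 && disc >= 0) {
      r <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
      fieller_ci <- sort(exp(s * scale * r))
    } else {
      flags <- c(flags, "fieller_unbounded")
    }
  }
  structure(list(
    gamma = g, gamma_se = seg, big_gamma = G, big_gamma_se = seG,
    theta = theta, se = se, scale = scale, direction = direction,
    or = or, ci_low = ci[1L], ci_high = ci[2L], p_value = p,
    conf_level = conf_level, fieller_ci = fieller_ci,
    denominator_f = fstat, flags = flags,
    second_order = second_order
  ), class = "wald_estimate")
}

#' @export
print.wald_estimate <- function(x, ...) {
  cat(sprintf(
    "Wald ratio: OR %.3f (%.0f%% CI %.3f-%.3f), p = %.3g\n",
    x$or, 100 * x$conf_level, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  per %g exposure-unit %s; theta = %.4f (se %.4f)\n",
              x$scale, x$direction, x$theta, x$se))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "),
                           "\n")
  invisible(x)
}

#' @export
coef.wald_estimate <- function(object, ...) {
  c(theta = object$theta, se = object$se)
}

#' Linear MR across outcomes using a weighted genetic score
#'
#' The full score-based pipeline per outcome: prevalent cases of that
#' outcome are excluded, the score-exposure and score-outcome regressions
#' are fitted on the remaining rows with the GWAS covariates (plus any
#' `extra_adjust` columns, e.g. BMI for the pleiotropy sensitivity
#' analysis), and the Wald ratio is formed.
#'
#' @param cohort an `mr_cohort` (unfiltered; filtering is per outcome).
#' @param ivset an `instrument_set`.
#' @param outcome_names binary outcome columns to analyse.
#' @param covariate_names GWAS covariates used in both regressions.
#' @param extra_adjust additional adjustment columns (default none).
#' @param scale,direction,conf_level reporting scale; see [wald_ratio()].
#' @param drop_prevalent exclude prevalent cases per outcome.
#' @return data.frame of class `linear_mr`, one row per outcome, with the
#'   full `wald_estimate` objects in the `"estimates"` attribute.
#' @export
linear_mr <- function(cohort, ivset, outcome_names,
                      covariate_names = NULL, extra_adjust = NULL,
                      scale = 0.1, direction = "decrease",
                      conf_level = 0.95, drop_prevalent = TRUE) {
  stopifnot(inherits(cohort, "mr_cohort"), inherits(ivset, "instrument_set"))
  if (nrow(ivset$variants) == 0L)
    stop("empty instrument set", call. = FALSE)
  covs <- c(covariate_names, extra_adjust)
  rows <- list()
  ests <- list()
  for (out in outcome_names) {
    sub <- filter_cohort(cohort, out, drop_prevalent = drop_prevalent)
    score <- compute_score(sub$genotypes, ivset)
    ge <- score_exposure_effect(sub, score, covs)
    oe <- score_outcome_effect(sub, score, out, covs)
    w <- wald_ratio(ge, oe, scale = scale, direction = direction,
                    conf_level = conf_level)
    ests[[out]] <- w
    rows[[out]] <- data.frame(
      outcome = out, n = nrow(sub$phenotypes), n_cases = oe$n_cases,
      n_controls = oe$n_used - oe$n_cases,
      gamma = ge$gamma, gamma_se = ge$se,
      big_gamma = oe$big_gamma, big_gamma_se = oe$se,
      or = w$or, ci_low = w$ci_low, ci_high = w$ci_high,
      p_value = w$p_value,
      flags = paste(w$flags, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "estimates") <- ests
  attr(res, "scale") <- scale
  attr(res, "direction") <- direction
  class(res) <- c("linear_mr", "data.frame")
  res
}

#' @export
print.linear_mr <- function(x, ...) {
  cat(sprintf(
    "Linear MR (Wald ratio), OR per %g exposure-unit %s:\n",
    attr(x, "scale"), attr(x, "direction")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.linear_mr <- function(object, ...) {
  ests <- attr(object, "estimates")
  vapply(ests, function(e) e$theta, numeric(1))
}

#' Inverse-variance-weighted MR from per-variant Wald ratios
#'
#' Computes a per-variant ratio `theta_j = big_gamma_j / gamma_j` (logistic
#' outcome coefficient over GWAS exposure coefficient, both per allele)
#' with first-order SE `se_Gj / |gamma_j|`, then pools with weights
#' `1/se_j^2`.  For mutually uncorrelated valid instruments this is
#' asymptotically equivalent to the score-based Wald ratio, which is the
#' basis of a cross-check between the two estimators.
#'
#' @inheritParams linear_mr
#' @param outcome_name one binary outcome.
#' @return list: pooled `theta`, `se`, per-variant table, and the reported
#'   `or`/CI on the requested scale.
#' @export
ivw_mr <- function(cohort, ivset, outcome_name, covariate_names = NULL,
                   scale = 0.1, direction = "decrease",
                   drop_prevalent = TRUE) {
  stopifnot(inherits(ivset, "instrument_set"))
  sub <- filter_cohort(cohort, outcome_name,
                       drop_prevalent = drop_prevalent)
  ids <- ivset$variants$variant_id
  X <- build_design(sub$phenotypes, covariate_names)
  y <- sub$phenotypes[[outcome_name]]
  ex <- sub$phenotypes$exposure
  per <- lapply(ids, function(v) {
    gvec <- as.numeric(sub$genotypes[, v])
    ok <- complete_rows(X, gvec, y, ex)
    fit_x <- ols_fit(ex[ok], cbind(dosage = gvec[ok], X[ok, , drop = FALSE]))
    fit_y <- logit_fit(y[ok], cbind(dosage = gvec[ok], X[ok, , drop = FALSE]))
    gam <- unname(fit_x$coef["dosage"]); seg <- unname(fit_x$se["dosage"])
    Gam <- unname(fit_y$coef["dosage"]); seG <- unname(fit_y$se["dosage"])
    data.frame(variant_id = v, gamma = gam, gamma_se = seg,
               big_gamma = Gam, big_gamma_se = seG,
               theta = Gam / gam, se = seG / abs(gam))
  })
  tab <- do.call(rbind, per)
  w <- 1 / tab$se^2
  theta <- sum(w * tab$theta) / sum(w)
  se <- sqrt(1 / sum(w))
  s <- if (direction == "decrease") -1 else 1
  z <- stats::qnorm(0.975)
  list(theta = theta, se = se, per_variant = tab,
       or = exp(s * theta * scale),
       ci = sort(exp(s * scale * (theta + c(-1, 1) * z * se))),
       p_value = 2 * stats::pnorm(-abs(theta / se)))
}
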