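# Stratum construction for nonlinear MR: residual-based and doubly-ranked
# methods.

new_stratum_assignment <- function(method, stratifier_name, n_strata,
                                   index, observed, residual = NULL) {
  tab <- do.call(rbind, lapply(seq_len(n_strata), function(j) {
    v <- observed[index == j]
    data.frame(stratum = j, n = length(v), mean = mean(v),
               min = min(v), max = max(v))
  }))
  structure(list(
    method = method, stratifier_name = stratifier_name,
    n_strata = as.integer(n_strata), index = as.integer(index),
    summary = tab, residual = residual
  ), class = "stratum_assignment")
}

# Equal-size quantile grouping: rank with ties broken by row order (stable),
# then cut into n groups whose sizes differ by at most 1.  For distinct
# values this coincides with type-7 quantile cutpoints.
quantile_groups <- function(x, n_groups) {
  n <- length(x)
  ord <- order(x, seq_len(n))
  sizes <- diff(floor(n * (0:n_groups) / n_groups))
  idx <- integer(n)
  idx[ord] <- rep(seq_len(n_groups), times = sizes)
  idx
}

check_strata_args <- function(x, n_strata, allow_constant = FALSE) {
  n <- length(x)
  if (!allow_constant && stats::sd(x) == 0)
    stop("stratifier is constant", call. = FALSE)
  if (n_strata < 2L) stop("need at least 2 strata", call. = FALSE)
  if (2 * n_strata > n)
    stop("refusing: fewer than 2 individuals per stratum", call. = FALSE)
  # at analysis scale, very thin strata give unusable ratio estimates
  if (n >= 100 && n_strata > n / 10)
    stop("refusing n_strata > n/10: strata would be too small",
         call. = FALSE)
}

#' Residual-based stratification
#'
#' Stratifying on a biomarker that the genetic score may itself affect can
#' induce collider bias; the residual method instead stratifies on the
#' biomarker after removing the score's and the covariates' contributions.
#' The residual keeps the fitted intercept
#' (`residual = observed - score*coef - covariate contributions`), so it
#' preserves the biomarker's location.  Strata are quantile groups of the
#' residual (equal sizes up to one individual; ties broken by row order),
#' so the observed-value ranges of adjacent strata may overlap — stratum
#' summaries report observed values deliberately.
#'
#' @param cohort an `mr_cohort` (already filtered for the analysis).
#' @param stratifier_name biomarker (or `"exposure"`) column to stratify
#'   on.
#' @param score per-individual genetic score aligned with the cohort.
#' @param covariate_names covariates removed along with the score.
#' @param n_strata number of strata (quartiles by default).
#' @return object of class `stratum_assignment`.
#' @export
residual_stratify <- function(cohort, stratifier_name, score,
                              covariate_names = NULL, n_strata = 4L) {
  ph <- cohort$phenotypes
  if (!stratifier_name %in% names(ph))
    stop(sprintf("unknown stratifier '%s'", stratifier_name),
         call. = FALSE)
  m <- as.numeric(ph[[stratifier_name]])
  check_strata_args(m, n_strata)
  s <- as.numeric(score)
  X <- build_design(ph, covariate_names)  # includes intercept
  fit <- ols_fit(m, cbind(score = s, X))
  contrib <- cbind(score = s, X) %*% ifelse(is.na(fit$coef), 0, fit$coef)
  intercept <- fit$coef["(Intercept)"]
  resid <- m - as.numeric(contrib) + unname(intercept)
  idx <- quantile_groups(resid, n_strata)
  new_stratum_assignment("residual", stratifier_name, n_strata, idx, m,
                         residual = resid)
}

#' Doubly-ranked stratification
#'
#' Rank-based stratification that does not assume a constant genetic
#' effect: individuals are first ranked by the genetic score and cut into
#' consecutive pre-strata of size `n_strata`; within each pre-stratum they
#' are ranked by the stratifier, and the j-th ranked individual joins
#' stratum j.  A final partial pre-stratum distributes its members, in
#' stratifier order, to the lowest-indexed strata.  All ties are broken by
#' row order (stable), so the assignment is deterministic.
#'
#' @inheritParams residual_stratify
#' @export
doubly_ranked_stratify <- function(cohort, score, stratifier_name,
                                   n_strata = 4L) {
  ph <- cohort$phenotypes
  if (!stratifier_name %in% names(ph))
    stop(sprintf("unknown stratifier '%s'", stratifier_name),
         call. = FALSE)
  m <- as.numeric(ph[[stratifier_name]])
  # a constant stratifier degenerates to the documented row-order
  # tie-break; allowed, unlike in the residual method
  check_strata_args(m, n_strata, allow_constant = TRUE)
  s <- as.numeric(score)
  n <- length(s)
  ord_score <- order(s, seq_len(n))
  idx <- integer(n)
  pos <- 1L
  while (pos <= n) {
    members <- ord_score[pos:min(pos + n_strata - 1L, n)]
    ord_m <- members[order(m[members], members)]
    idx[ord_m] <- seq_along(ord_m)
    pos <- pos + n_strata
  }
  new_stratum_assignment("doubly_ranked", stratifier_name, n_strata, idx,
                         m)
}

#' Observed-value stratification
#'
#' Plain quantile groups of the observed stratifier (no residualisation);
#' exposed for comparison and for stratifiers known to be independent of
#' the score.
#'
#' @inheritParams residual_stratify
#' @export
observed_stratify <- function(cohort, stratifier_name, n_strata = 4L) {
  ph <- cohort$phenotypes
  if (!stratifier_name %in% names(ph))
    stop(sprintf("unknown stratifier '%s'", stratifier_name),
         call. = FALSE)
  m <- as.numeric(ph[[stratifier_name]])
  check_strata_args(m, n_strata)
  idx <- quantile_groups(m, n_strata)
  new_stratum_assignment("observed", stratifier_name, n_strata, idx, m)
}

#' @export
print.stratum_assignment <- function(x, ...) {
  cat(sprintf("%s stratification on '%s' (%d strata)\n", x$method,
              x$stratifier_name, x$n_strata))
  print.data.frame(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}
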