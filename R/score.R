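# Weighted genetic score and its component regressions.

#' Compute the weighted genetic score
#'
#' `score_i = sum_k beta_k * g_ik`, the exact inner product of each
#' individual's dosages with the instrument weights (exposure-GWAS betas).
#'
#' @param genotypes dosage matrix containing all instrument variants.
#' @param ivset an `instrument_set`.
#' @param missing one of "drop" (default: individuals with a missing
#'   instrument dosage get `NA` score, dropped by downstream regressions)
#'   or "mean" (mean-impute the missing dosage from the observed column).
#' @return numeric vector of per-individual scores, in exposure units;
#'   attribute `n_missing` counts individuals affected by missingness.
#' @export
compute_score <- function(genotypes, ivset, missing = c("drop", "mean")) {
  missing <- match.arg(missing)
  stopifnot(inherits(ivset, "instrument_set"))
  ids <- ivset$variants$variant_id
  if (!all(ids %in% colnames(genotypes)))
    stop("instrument variants missing from genotype matrix: ",
         paste(setdiff(ids, colnames(genotypes)), collapse = ", "),
         call. = FALSE)
  G <- genotypes[, ids, drop = FALSE]
  storage.mode(G) <- "double"
  n_missing <- sum(rowSums(is.na(G)) > 0L)
  if (n_missing > 0L && missing == "mean") {
    for (j in seq_len(ncol(G))) {
      nas <- is.na(G[, j])
      if (any(nas)) G[nas, j] <- mean(G[, j], na.rm = TRUE)
    }
  }
  s <- as.numeric(G %*% ivset$variants$weight)
  attr(s, "n_missing") <- n_missing
  attr(s, "missing_policy") <- missing
  s
}

#' Effect of the genetic score on the exposure
#'
#' OLS of the exposure on the score plus the GWAS covariates.  With
#' unshrunk in-sample GWAS weights the coefficient is close to 1 by
#' construction (the score is calibrated in exposure units).
#'
#' @param cohort an `mr_cohort`.
#' @param score from [compute_score()], aligned with the cohort rows.
#' @param covariate_names covariates (same set as the GWAS).
#' @return list: `gamma`, `se`, `p`, `n_used`.
#' @export
score_exposure_effect <- function(cohort, score, covariate_names = NULL) {
  y <- cohort$phenotypes$exposure
  s <- as.numeric(score)
  if (length(s) != length(y))
    stop("score length does not match cohort", call. = FALSE)
  X <- build_design(cohort$phenotypes, covariate_names)
  ok <- complete_rows(X, s, y)
  s2 <- s[ok]
  if (stats::sd(s2) == 0)
    stop("degenerate score: constant among used rows", call. = FALSE)
  fit <- ols_fit(y[ok], cbind(score = s2, X[ok, , drop = FALSE]))
  list(gamma = unname(fit$coef["score"]), se = unname(fit$se["score"]),
       p = unname(fit$p["score"]), n_used = fit$n)
}

#' Effect of the genetic score on a binary outcome
#'
#' Maximum-likelihood logistic regression of the outcome on the score plus
#' covariates; returns the log-odds coefficient of the score.
#'
#' @param cohort an `mr_cohort`.
#' @param score from [compute_score()].
#' @param outcome_name binary phenotype column.
#' @param covariate_names covariates (same set as the GWAS).
#' @return list: `big_gamma` (log-odds per score unit), `se`, `p`,
#'   `n_used`, `n_cases`.
#' @export
score_outcome_effect <- function(cohort, score, outcome_name,
                                 covariate_names = NULL) {
  ph <- cohort$phenotypes
  if (!outcome_name %in% names(ph))
    stop(sprintf("unknown outcome '%s'", outcome_name), call. = FALSE)
  y <- ph[[outcome_name]]
  s <- as.numeric(score)
  X <- build_design(ph, covariate_names)
  ok <- complete_rows(X, s, y)
  y <- y[ok]; s <- s[ok]; X <- X[ok, , drop = FALSE]
  if (length(unique(y)) < 2L)
    stop(sprintf("outcome '%s' has a single class among used rows",
                 outcome_name), call. = FALSE)
  fit <- logit_fit(y, cbind(score = s, X))
  list(big_gamma = unname(fit$coef["score"]),
       se = unname(fit$se["score"]), p = unname(fit$p["score"]),
       n_used = fit$n, n_cases = sum(y == 1L))
}
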