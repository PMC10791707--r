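# Instrument selection: LD clumping, pleiotropy exclusion lists,
# instrument strength, negative-control checks.

new_instrument_set <- function(variants, p_threshold, r2_threshold,
                               status = "ok", f_statistic = NA_real_,
                               r_squared = NA_real_) {
  structure(list(
    variants = variants,  # data.frame: variant_id, weight, p_value
    p_threshold = p_threshold,
    r2_threshold = r2_threshold,
    f_statistic = f_statistic,
    r_squared = r_squared,
    status = status
  ), class = "instrument_set")
}

#' Greedy LD clumping of GWAS associations
#'
#' Classic p-value-prioritised clumping: among variants significant at
#' `p_threshold`, repeatedly keep the variant with the smallest p-value
#' (ties broken by lexicographic variant ID) and discard every remaining
#' variant whose squared in-sample Pearson dosage correlation with it is
#' `>= r2_threshold`.  Retained variants carry their GWAS betas as score
#' weights.  LD is computed from the analysis cohort's dosages.
#'
#' @param associations an `mr_gwas` data.frame (or compatible) with
#'   `variant_id`, `beta`, `p_value`, `status` columns.
#' @param genotypes dosage matrix whose columns cover the association
#'   variants.
#' @param p_threshold significance threshold; see also
#'   [bonferroni_threshold()] for the gene-specific convention.
#' @param r2_threshold LD r-squared threshold in (0, 1] (0.1 and 0.3 are
#'   the conventional strict/lenient choices).
#' @return an `instrument_set`; when no variant passes the threshold the
#'   set is empty with `status = "no_significant_variant"`.
#' @export
clump <- function(associations, genotypes, p_threshold = 5e-8,
                  r2_threshold = 0.1) {
  stopifnot(p_threshold > 0, p_threshold <= 1,
            r2_threshold > 0, r2_threshold <= 1)
  a <- as.data.frame(associations)
  if (!all(a$variant_id %in% colnames(genotypes)))
    stop("associations and genotype columns do not align", call. = FALSE)
  usable <- a$status == "ok" & !is.na(a$p_value) & a$p_value < p_threshold
  cand <- a[usable, , drop = FALSE]
  if (nrow(cand) == 0L)
    return(new_instrument_set(
      data.frame(variant_id = character(0), weight = numeric(0),
                 p_value = numeric(0)),
      p_threshold, r2_threshold, status = "no_significant_variant"))
  cand <- cand[order(cand$p_value, cand$variant_id), , drop = FALSE]
  kept <- character(0)
  while (nrow(cand) > 0L) {
    top <- cand$variant_id[1L]
    kept <- c(kept, top)
    cand <- cand[-1L, , drop = FALSE]
    if (nrow(cand) > 0L) {
      r <- suppressWarnings(stats::cor(genotypes[, top],
                                       genotypes[, cand$variant_id,
                                                 drop = FALSE],
                                       use = "pairwise.complete.obs"))
      r2 <- as.numeric(r)^2
      r2[is.na(r2)] <- 0
      cand <- cand[r2 < r2_threshold, , drop = FALSE]
    }
  }
  sel <- a[match(kept, a$variant_id), , drop = FALSE]
  new_instrument_set(
    data.frame(variant_id = sel$variant_id, weight = sel$beta,
               p_value = sel$p_value, stringsAsFactors = FALSE),
    p_threshold, r2_threshold)
}

#' Gene-specific Bonferroni significance threshold
#'
#' `0.05 / n_variants_in_region`: the cis-region analogue of genome-wide
#' significance (e.g. 0.05/5279 = 9.47e-6 for a region holding 5279
#' variants).
#'
#' @param n_variants number of variants tested in the region.
#' @export
bonferroni_threshold <- function(n_variants) {
  stopifnot(n_variants >= 1)
  0.05 / n_variants
}

#' Remove listed (potentially pleiotropic) variants from an instrument set
#'
#' External pleiotropy lookups (eQTL/GWAS-catalog/PhenoScanner style) are
#' expected to be done by the caller; this applies the resulting exclusion
#' list.  IDs not in the set produce a warning and are ignored.
#'
#' @param ivset an `instrument_set`.
#' @param excluded_variant_ids character vector (possibly empty); see
#'   [read_exclusion_list()] for the one-ID-per-line file format.
#' @export
apply_exclusion_list <- function(ivset, excluded_variant_ids) {
  stopifnot(inherits(ivset, "instrument_set"))
  if (length(excluded_variant_ids) == 0L) return(ivset)
  unknown <- setdiff(excluded_variant_ids, ivset$variants$variant_id)
  if (length(unknown))
    warning("exclusion list IDs not in the instrument set: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  keep <- !ivset$variants$variant_id %in% excluded_variant_ids
  ivset$variants <- ivset$variants[keep, , drop = FALSE]
  if (nrow(ivset$variants) == 0L) ivset$status <- "empty_after_exclusion"
  ivset$f_statistic <- NA_real_
  ivset$r_squared <- NA_real_
  ivset
}

#' Instrument strength: incremental F-statistic and variance explained
#'
#' From the joint OLS of the exposure on the selected dosages plus
#' covariates: `r_squared` is the incremental variance explained by the
#' dosages over the covariate-only model, and
#' `F = ((R2_full - R2_cov)/k) / ((1 - R2_full)/(n - p_full))` with
#' `p_full` the number of regressors including the intercept.  A perfect
#' fit reports `F = Inf`.
#'
#' @param cohort an `mr_cohort`.
#' @param ivset an `instrument_set` with at least one variant.
#' @param covariate_names covariates used in the GWAS.
#' @return list with `f_statistic` and `r_squared`.
#' @export
instrument_strength <- function(cohort, ivset, covariate_names = NULL) {
  stopifnot(inherits(ivset, "instrument_set"))
  ids <- ivset$variants$variant_id
  if (length(ids) == 0L) stop("empty instrument set", call. = FALSE)
  G <- cohort$genotypes[, ids, drop = FALSE]
  storage.mode(G) <- "double"
  y <- cohort$phenotypes$exposure
  X <- build_design(cohort$phenotypes, covariate_names)
  ok <- complete_rows(X, G, y)
  y <- y[ok]; X <- X[ok, , drop = FALSE]; G <- G[ok, , drop = FALSE]
  k <- ncol(G)
  full <- cbind(G, X)
  fit_full <- stats::lm.fit(full, y)
  if (fit_full$rank < ncol(full)) {
    piv <- fit_full$qr$pivot
    aliased <- colnames(full)[piv[-seq_len(fit_full$rank)]]
    if (any(aliased %in% ids))
      stop("collinear instruments: ",
           paste(intersect(aliased, ids), collapse = ", "), call. = FALSE)
  }
  tss <- sum((y - mean(y))^2)
  r2_full <- 1 - sum(fit_full$residuals^2) / tss
  fit_cov <- stats::lm.fit(X, y)
  r2_cov <- 1 - sum(fit_cov$residuals^2) / tss
  n <- length(y)
  p_full <- ncol(full)
  denom <- (1 - r2_full) / (n - p_full)
  f <- if (denom <= .Machine$double.eps) Inf
  else ((r2_full - r2_cov) / k) / denom
  list(f_statistic = f, r_squared = r2_full - r2_cov)
}

#' Negative-control association check
#'
#' Regresses each negative-control trait (by convention age and sex,
#' which the instruments cannot cause) on the genetic score or on each
#' variant, without covariates.  A significant association at `alpha`
#' flags possible collider/selection bias; the pipeline reports but does
#' not halt on failure.
#'
#' @param cohort an `mr_cohort`.
#' @param score numeric per-individual score (from [compute_score()]), or
#'   `NULL` to test each variant in `variant_ids` separately.
#' @param control_names phenotype columns to test.
#' @param variant_ids used when `score` is NULL.
#' @param alpha flag threshold.
#' @return data.frame: control (and variant when per-variant), beta, se,
#'   p, pass, status ("ok" or "degenerate" for a constant regressor).
#' @export
negative_control_check <- function(cohort, score = NULL,
                                   control_names = c("age", "sex"),
                                   variant_ids = NULL, alpha = 0.05) {
  ph <- cohort$phenotypes
  missing_cols <- setdiff(control_names, names(ph))
  if (length(missing_cols))
    stop("unknown control columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  preds <- if (!is.null(score)) list(score = as.numeric(score))
  else {
    stopifnot(!is.null(variant_ids))
    stats::setNames(
      lapply(variant_ids, function(v) as.numeric(cohort$genotypes[, v])),
      variant_ids)
  }
  rows <- list()
  for (pn in names(preds)) {
    x <- preds[[pn]]
    for (cn in control_names) {
      yv <- as.numeric(ph[[cn]])
      ok <- complete_rows(x, yv)
      xi <- x[ok]; yi <- yv[ok]
      if (stats::sd(xi) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          predictor = pn, control = cn, beta = NA_real_, se = NA_real_,
          p = NA_real_, pass = NA, status = "degenerate")
        next
      }
      fit <- ols_fit(yi, cbind(1, x = xi))
      rows[[length(rows) + 1L]] <- data.frame(
        predictor = pn, control = cn, beta = unname(fit$coef["x"]),
        se = unname(fit$se["x"]), p = unname(fit$p["x"]),
        pass = unname(fit$p["x"]) >= alpha, status = "ok")
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  out
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set (%s): %d variant(s), p < %.3g, r2 < %.2g\n",
              x$status, nrow(x$variants), x$p_threshold, x$r2_threshold))
  if (nrow(x$variants)) print.data.frame(x$variants, digits = 4,
                                         row.names = FALSE)
  if (!is.na(x$f_statistic))
    cat(sprintf("  F = %.2f, incremental R^2 = %.4g\n",
                x$f_statistic, x$r_squared))
  invisible(x)
}
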