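# Per-variant exposure GWAS with covariate adjustment and prevalent-case
# exclusion.

#' Filter a cohort before association analysis
#'
#' Removes individuals flagged as diagnosed with the named outcome before
#' exposure measurement (prevalent cases), and optionally individuals
#' failing caller-supplied boolean QC flags (a `TRUE`/1 flag value marks a
#' row for removal).  Per-filter removal counts are attached as the
#' `"filter_counts"` attribute; overlapping filters are counted per filter
#' but each row is removed once.
#'
#' @param cohort an `mr_cohort`.
#' @param outcome_name outcome whose prevalent flag is applied (used when
#'   `drop_prevalent = TRUE`); the flag column is
#'   `prevalent_<outcome_name>`.
#' @param drop_prevalent drop prevalent cases of `outcome_name`.
#' @param qc_flags character vector of additional boolean phenotype
#'   columns marking rows to drop.
#' @return the filtered `mr_cohort`, with attribute `filter_counts`.
#' @export
filter_cohort <- function(cohort, outcome_name = NULL,
                          drop_prevalent = TRUE, qc_flags = NULL) {
  stopifnot(inherits(cohort, "mr_cohort"))
  ph <- cohort$phenotypes
  drop <- rep(FALSE, nrow(ph))
  counts <- integer(0)
  if (drop_prevalent && !is.null(outcome_name)) {
    col <- paste0("prevalent_", outcome_name)
    if (!col %in% names(ph))
      stop(sprintf("unknown prevalent-flag column '%s'", col),
           call. = FALSE)
    f <- ph[[col]] == 1L
    counts["prevalent"] <- sum(f)
    drop <- drop | f
  }
  for (qc in qc_flags) {
    if (!qc %in% names(ph))
      stop(sprintf("unknown QC flag column '%s'", qc), call. = FALSE)
    f <- as.logical(ph[[qc]]) %in% TRUE
    counts[qc] <- sum(f)
    drop <- drop | f
  }
  keep <- !drop
  out <- cohort
  out$phenotypes <- ph[keep, , drop = FALSE]
  out$genotypes <- cohort$genotypes[keep, , drop = FALSE]
  attr(out, "filter_counts") <- as.list(counts)
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Association of one variant with the exposure
#'
#' Ordinary least squares of the exposure on the variant's dosage plus
#' covariates (categorical covariates are one-hot encoded against the
#' first level).  Rows with any missing regressor are dropped
#' (complete-case) and `n_used` records the rows analysed.  The two-sided
#' p-value uses the t distribution with residual degrees of freedom.
#'
#' @param cohort an `mr_cohort` (already filtered as desired).
#' @param variant_id a genotype column name.
#' @param covariate_names phenotype columns to adjust for (may be NULL).
#' @return one-row data.frame: `variant_id`, `beta` (exposure units per
#'   effect allele), `se`, `p_value`, `allele_freq`, `n_used`, `status`
#'   ("ok" or "monomorphic"; monomorphic variants carry `NA` estimates).
#' @export
variant_association <- function(cohort, variant_id, covariate_names = NULL) {
  stopifnot(inherits(cohort, "mr_cohort"))
  if (!variant_id %in% colnames(cohort$genotypes))
    stop(sprintf("unknown variant '%s'", variant_id), call. = FALSE)
  g <- as.numeric(cohort$genotypes[, variant_id])
  y <- cohort$phenotypes$exposure
  X <- build_design(cohort$phenotypes, covariate_names)
  ok <- complete_rows(X, g, y)
  g <- g[ok]; y <- y[ok]; X <- X[ok, , drop = FALSE]
  res <- data.frame(variant_id = variant_id, beta = NA_real_,
                    se = NA_real_, p_value = NA_real_,
                    allele_freq = if (length(g)) mean(g) / 2 else NA_real_,
                    n_used = length(g), status = "ok",
                    stringsAsFactors = FALSE)
  if (length(unique(g)) < 2L) {
    res$status <- "monomorphic"
    return(res)
  }
  Xg <- cbind(dosage = g, X)
  if (nrow(Xg) <= ncol(Xg))
    stop("variant_association: fewer rows than regressors", call. = FALSE)
  fit <- ols_fit(y, Xg)
  if (any(fit$aliased)) {
    bad <- names(fit$coef)[fit$aliased]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  res$beta <- unname(fit$coef["dosage"])
  res$se <- unname(fit$se["dosage"])
  res$p_value <- unname(fit$p["dosage"])
  res
}

#' Exposure GWAS over a set of region variants
#'
#' Runs [variant_association()] for every variant in the region with a
#' common row filter.  Per-variant failures (monomorphism) are returned as
#' flagged records rather than aborting the scan.
#'
#' @param cohort an `mr_cohort`.
#' @param variant_ids character vector of genotype columns in the region
#'   (resolve coordinates with [variants_in_region()]).
#' @param covariate_names covariates for adjustment.
#' @return data.frame of class `mr_gwas`, one row per variant.
#' @export
run_region_gwas <- function(cohort, variant_ids, covariate_names = NULL) {
  if (length(variant_ids) == 0L)
    stop("empty region: no variants to test", call. = FALSE)
  rows <- lapply(variant_ids, function(v)
    variant_association(cohort, v, covariate_names))
  out <- do.call(rbind, rows)
  attr(out, "covariate_names") <- covariate_names
  class(out) <- c("mr_gwas", "data.frame")
  out
}

#' @export
print.mr_gwas <- function(x, ...) {
  cat(sprintf("Exposure GWAS: %d variants (%d usable)\n", nrow(x),
              sum(x$status == "ok")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Parse a genomic region specification
#'
#' @param region string `"chrom:start-end"` (1-based, inclusive).
#' @return list with `chrom`, `start`, `end`.
#' @export
parse_region <- function(region) {
  m <- regmatches(region,
                  regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1L]]
  if (length(m) != 4L)
    stop("region must look like 'chrom:start-end'", call. = FALSE)
  list(chrom = m[2L], start = as.numeric(m[3L]), end = as.numeric(m[4L]))
}

#' Variants inside a flanked region
#'
#' @param annotation data.frame with `id`, `chrom`, `pos`.
#' @param region a `"chrom:start-end"` string (e.g. a gene's span).
#' @param flank symmetric flank in bases added to both ends (the
#'   cis-region convention is 500 kb).
#' @return character vector of variant IDs.
#' @export
variants_in_region <- function(annotation, region, flank = 5e5) {
  r <- parse_region(region)
  hit <- annotation$chrom == r$chrom &
    annotation$pos >= r$start - flank &
    annotation$pos <= r$end + flank
  annotation$id[hit]
}
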