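# Plain-text serialisation: TSV cohort tables, minimal VCF, GWAS summary
# TSV, instrument-set JSON, exclusion lists.

#' Write a cohort to TSV files
#'
#' Genotypes go to `<dir>/genotypes.tsv` (first column `id`, then one
#' column per variant ID, dosages 0/1/2), phenotypes to
#' `<dir>/phenotypes.tsv`, the variant annotation to
#' `<dir>/variants.tsv`.
#'
#' @param cohort an `mr_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gpath <- file.path(dir, "genotypes.tsv")
  ppath <- file.path(dir, "phenotypes.tsv")
  vpath <- file.path(dir, "variants.tsv")
  g <- data.frame(id = cohort$phenotypes$id, cohort$genotypes,
                  check.names = FALSE)
  utils::write.table(g, gpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$phenotypes, ppath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$variants, vpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(genotypes = gpath, phenotypes = ppath, variants = vpath))
}

#' Read a cohort from TSV files written by [write_cohort()]
#'
#' @param dir directory holding `genotypes.tsv`, `phenotypes.tsv` and
#'   `variants.tsv`.
#' @return an `mr_cohort` (without a generating config).
#' @export
read_cohort <- function(dir) {
  g <- utils::read.table(file.path(dir, "genotypes.tsv"), header = TRUE,
                         sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  ph <- utils::read.table(file.path(dir, "phenotypes.tsv"), header = TRUE,
                          sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  v <- utils::read.table(file.path(dir, "variants.tsv"), header = TRUE,
                         sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (!identical(g$id, ph$id))
    stop("genotype and phenotype tables disagree on row identity",
         call. = FALSE)
  gm <- as.matrix(g[, setdiff(names(g), "id"), drop = FALSE])
  storage.mode(gm) <- "integer"
  structure(list(genotypes = gm, phenotypes = ph, variants = v,
                 config = NULL, seed = NA_integer_),
            class = "mr_cohort")
}

#' Write genotypes as a minimal VCF (GT field only)
#'
#' Dosages are emitted as unphased genotypes (0 -> 0/0, 1 -> 0/1,
#' 2 -> 1/1, NA -> ./.) with placeholder REF/ALT alleles.
#'
#' @param cohort an `mr_cohort`.
#' @param path output `.vcf` path.
#' @export
write_vcf <- function(cohort, path) {
  v <- cohort$variants
  ids <- cohort$phenotypes$id
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=dtmr synthetic cohort",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", ids),
                     collapse = "\t")), con)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(nrow(v))) {
    d <- cohort$genotypes[, v$id[j]]
    gt <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], "A", "G", ".",
                       "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a GWAS summary table as TSV
#'
#' Columns: variant_id, effect_allele, beta, se, p, af, n.
#'
#' @param gwas an `mr_gwas` data.frame.
#' @param path output path.
#' @export
write_gwas <- function(gwas, path) {
  out <- data.frame(variant_id = gwas$variant_id, effect_allele = "G",
                    beta = gwas$beta, se = gwas$se, p = gwas$p_value,
                    af = gwas$allele_freq, n = gwas$n_used)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialise an instrument set to JSON
#'
#' @param ivset an `instrument_set`.
#' @param path output path.
#' @export
write_instrument_set <- function(ivset, path) {
  jsonlite::write_json(list(
    variants = ivset$variants, p_threshold = ivset$p_threshold,
    r2_threshold = ivset$r2_threshold, f_statistic = ivset$f_statistic,
    r_squared = ivset$r_squared, status = ivset$status
  ), path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Read an instrument set from JSON written by [write_instrument_set()]
#' @param path JSON path.
#' @export
read_instrument_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_instrument_set(as.data.frame(x$variants), x$p_threshold,
                     x$r2_threshold, status = x$status,
                     f_statistic = x$f_statistic %||% NA_real_,
                     r_squared = x$r_squared %||% NA_real_)
}

#' Read a variant exclusion list (one variant ID per line)
#'
#' Blank lines and `#` comments are skipped.
#'
#' @param path text file path.
#' @export
read_exclusion_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}
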