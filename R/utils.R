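# Internal numerical and bookkeeping helpers shared across the package.

#' @keywords internal
"_PACKAGE"

## ---- seeded substreams -------------------------------------------------

# All randomness in the simulator flows from one master seed.  Each logical
# component (a variant column, an LD-block factor, a covariate, an outcome)
# draws from its own substream whose seed is a deterministic function of the
# master seed and a text label, so adding a variant or an outcome to a config
# does not perturb the draws of any other column.
#
# The label hash is a 31-multiplier polynomial rolling hash reduced modulo
# 2^31 - 1, kept inside R's 32-bit integer range.
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% m
  }
  as.integer((abs(seed) + h) %% m)
}

# Evaluate `expr` under a substream without disturbing the caller's RNG state.
with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, label))
  expr
}

## ---- least squares -----------------------------------------------------

# OLS with coefficient standard errors from the QR decomposition.  `x` must
# already contain an intercept column if one is wanted.  Returns NA entries
# for aliased (pivoted-out) columns rather than dropping them silently.
ols_fit <- function(y, x) {
  x <- as.matrix(x)
  fit <- stats::lm.fit(x, y)
  p <- fit$rank
  n <- length(y)
  df <- n - p
  if (df <= 0) stop("ols_fit: no residual degrees of freedom", call. = FALSE)
  rss <- sum(fit$residuals^2)
  s2 <- rss / df
  piv <- fit$qr$pivot[seq_len(p)]
  Rinv <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  se <- rep(NA_real_, ncol(x))
  se[piv] <- sqrt(pmax(diag(Rinv), 0) * s2)
  coefs <- fit$coefficients
  names(se) <- colnames(x)
  tstat <- coefs / se
  pval <- 2 * stats::pt(-abs(tstat), df)
  tss <- sum((y - mean(y))^2)
  list(coef = coefs, se = se, t = tstat, p = pval, df = df, n = n,
       sigma2 = s2, rss = rss,
       r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
       rank = fit$rank, aliased = is.na(coefs))
}

# Logistic regression by Fisher scoring (glm.fit) with Wald standard errors.
# Convergence: relative deviance tolerance 1e-8, at most 100 iterations.
logit_fit <- function(y, x) {
  x <- as.matrix(x)
  if (length(unique(y)) < 2L)
    stop("logit_fit: outcome has a single class among used rows",
         call. = FALSE)
  fit <- suppressWarnings(stats::glm.fit(
    x, y,
    family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)
  ))
  if (!fit$converged)
    stop("logit_fit: IRLS did not converge (possible separation)",
         call. = FALSE)
  mu <- fit$fitted.values
  eps <- 1e-10
  if (any(mu < eps) || any(mu > 1 - eps)) {
    if (max(abs(fit$coefficients), na.rm = TRUE) > 15)
      stop("logit_fit: fitted probabilities numerically 0 or 1 ",
           "(perfect or quasi-perfect separation)", call. = FALSE)
  }
  p <- fit$rank
  piv <- fit$qr$pivot[seq_len(p)]
  Rinv <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  se <- rep(NA_real_, ncol(x))
  se[piv] <- sqrt(pmax(diag(Rinv), 0))
  names(se) <- colnames(x)
  z <- fit$coefficients / se
  list(coef = fit$coefficients, se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)),
       n = length(y), deviance = fit$deviance,
       aliased = is.na(fit$coefficients))
}

## ---- design-matrix construction ----------------------------------------

# Build a numeric model matrix from named phenotype columns.  Character and
# factor columns are expanded to one-hot dummies with the first level as
# reference; numeric columns pass through.  Rows with any missing value are
# tracked by the caller.
build_design <- function(data, covariate_names, intercept = TRUE) {
  cols <- list()
  if (intercept) cols[["(Intercept)"]] <- rep(1, nrow(data))
  for (nm in covariate_names) {
    if (!nm %in% names(data))
      stop(sprintf("unknown covariate column '%s'", nm), call. = FALSE)
    v <- data[[nm]]
    if (is.character(v) || is.factor(v)) {
      v <- factor(v)
      lev <- levels(v)
      for (l in lev[-1L]) {
        cols[[paste0(nm, l)]] <- as.numeric(v == l)
      }
    } else {
      cols[[nm]] <- as.numeric(v)
    }
  }
  do.call(cbind, cols)
}

# Rows with complete data across a design matrix and extra numeric vectors.
complete_rows <- function(...) {
  parts <- list(...)
  ok <- rep(TRUE, NROW(parts[[1L]]))
  for (p in parts) {
    if (is.matrix(p)) ok <- ok & rowSums(is.na(p)) == 0L
    else ok <- ok & !is.na(p)
  }
  ok
}

## ---- misc ---------------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_num <- function(x, digits = 3) formatC(x, digits = digits, format = "fg")
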