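# Calibration of logistic outcome effects on the marginal (instrument-level)
# scale.
#
# Logistic models are non-collapsible: when a binary outcome is generated
# from a logistic model in the exposure, the coefficient recovered by a
# logistic regression of the outcome on a genetic score (which explains only
# a small part of the exposure) is attenuated relative to the conditional
# coefficient, because the exposure variation not captured by the score is
# marginalised over.  The ratio (Wald) estimator therefore identifies a
# marginal, population-averaged log odds ratio, not the conditional one.
#
# To simulate data whose *estimand* — the quantity the ratio method
# converges to — equals a requested log odds ratio per exposure unit, we
# numerically invert the marginalisation: given the score variance and the
# residual variance of the outcome linear predictor around the score, we
# solve for the conditional coefficient whose induced pseudo-true logistic
# slope on the score equals the target.  All integrals are Gauss-Hermite
# quadrature; the pseudo-true parameters solve the logistic score equations
# under the true mixture by Newton iteration.  Everything is deterministic.

# Gauss-Hermite nodes/weights (physicists' convention, weight e^{-x^2}) by
# the Golub-Welsch eigen decomposition of the Jacobi matrix.
gauss_hermite <- function(n = 40L) {
  i <- seq_len(n - 1L)
  off <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- off
  J[cbind(i + 1L, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = (e$vectors[1L, ord]^2) * sqrt(pi))
}

plogis_ <- stats::plogis

# E[plogis(a + Z)] with Z ~ N(0, sd^2), vectorised over `a`.
logistic_normal_mean <- function(a, sd, gh = gauss_hermite()) {
  if (sd <= 0) return(plogis_(a))
  z <- sqrt(2) * sd * gh$nodes
  w <- gh$weights / sqrt(pi)
  sapply(a, function(ai) sum(w * plogis_(ai + z)))
}

# Pseudo-true intercept and slope of a logistic regression of Y on S when
# truth is P(Y=1|S=s) = E[plogis(alpha + theta_s * s + eps)],
# eps ~ N(0, tau^2), S ~ N(0, v_s).  Solves the two population score
# equations by Newton iteration with analytic Jacobian.
pseudo_true_logistic <- function(alpha, theta_s, v_s, tau,
                                 gh = gauss_hermite()) {
  sd_s <- sqrt(v_s)
  s <- sqrt(2) * sd_s * gh$nodes
  ws <- gh$weights / sqrt(pi)
  p_true <- logistic_normal_mean(alpha + theta_s * s, tau, gh)
  a <- alpha
  b <- theta_s / sqrt(1 + 0.346 * tau^2)  # probit-style start
  for (iter in 1:50) {
    mu <- plogis_(a + b * s)
    f1 <- sum(ws * (p_true - mu))
    f2 <- sum(ws * s * (p_true - mu))
    d <- mu * (1 - mu)
    j11 <- -sum(ws * d); j12 <- -sum(ws * s * d)
    j22 <- -sum(ws * s^2 * d)
    J <- matrix(c(j11, j12, j12, j22), 2, 2)
    step <- solve(J, -c(f1, f2))
    a <- a + step[1L]; b <- b + step[2L]
    if (max(abs(step)) < 1e-12) break
  }
  c(intercept = a, slope = b)
}

# Intercept giving a requested prevalence when the full linear predictor is
# N(alpha, lp_sd^2).
calibrate_intercept <- function(prevalence, lp_sd, gh = gauss_hermite()) {
  stopifnot(prevalence > 0, prevalence < 1)
  stats::uniroot(
    function(a) logistic_normal_mean(a, lp_sd, gh) - prevalence,
    interval = c(-40, 40), tol = 1e-10
  )$root
}

#' Calibrate a conditional logistic exposure effect to a marginal target
#'
#' Finds the conditional log-odds coefficient `theta` of the exposure in a
#' logistic outcome model such that the large-sample (pseudo-true) slope of
#' a logistic regression of the outcome on the genetic score, divided by the
#' score-on-exposure slope (which is 1 when the score carries the true
#' per-allele weights), equals `target_slope` — i.e. so that the Wald ratio
#' estimand equals the requested marginal log odds ratio per exposure unit.
#'
#' The residual standard deviation of the outcome linear predictor around
#' the score is supplied as a function of `theta` because the exposure noise
#' and any shared confounder are scaled by `theta` itself.
#'
#' @param target_slope marginal log odds per exposure unit (the estimand).
#' @param prevalence   target outcome prevalence, used to set the intercept.
#' @param v_s          variance of the true-weight genetic score.
#' @param resid_sd_fun function(theta) giving the SD of the linear-predictor
#'   residual around `alpha + theta * s`.
#' @return list with `theta` (conditional coefficient), `alpha` (intercept)
#'   and `achieved` (the pseudo-true marginal slope at the solution).
#' @keywords internal
calibrate_marginal_effect <- function(target_slope, prevalence, v_s,
                                      resid_sd_fun) {
  gh <- gauss_hermite(60L)
  slope_at <- function(theta) {
    tau <- resid_sd_fun(theta)
    lp_sd <- sqrt(theta^2 * v_s + tau^2)
    alpha <- calibrate_intercept(prevalence, lp_sd, gh)
    pt <- pseudo_true_logistic(alpha, theta, v_s, tau, gh)
    list(slope = unname(pt["slope"]), alpha = alpha)
  }
  sgn <- sign(target_slope)
  if (sgn == 0) {
    alpha <- calibrate_intercept(prevalence, resid_sd_fun(0), gh)
    return(list(theta = 0, alpha = alpha, achieved = 0))
  }
  f <- function(theta) slope_at(theta)$slope - target_slope
  lo <- target_slope             # attenuation => |marginal| <= |conditional|
  hi <- target_slope
  for (i in 1:60) {
    hi <- hi * 1.25
    if (sgn * f(hi) >= 0) break
    if (i == 60)
      stop("marginal effect target is unattainable for this residual ",
           "variance: the logistic marginal slope saturates below the ",
           "requested value", call. = FALSE)
  }
  theta <- stats::uniroot(f, lower = min(lo, hi), upper = max(lo, hi),
                          tol = 1e-9)$root
  res <- slope_at(theta)
  list(theta = theta, alpha = res$alpha, achieved = res$slope)
}
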