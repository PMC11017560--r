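# Prior densities for the hierarchical model. Conventions fixed here and used
# everywhere: Gamma(shape, rate) (BUGS-style, so Gamma(2, 0.5) has mean 4) is
# placed on variances; scale parameters get half-Cauchy(0, 2.5); correlation
# matrices get LKJ(eta).

#' Hyperprior configuration
#'
#' Collects the hyperprior constants of the model: coefficients and the
#' subject random effect are Normal(0, sigma^2) with Gamma(2, rate 0.5)
#' hyperpriors on the variances, outcome-component scales are
#' half-Cauchy(0, 2.5), and the correlation matrix is LKJ(eta) (eta = 1 is
#' uniform over valid correlation matrices). The imputation-regression
#' coefficients share the same Normal/Gamma hierarchy.
#'
#' @param beta_var_shape,beta_var_rate Gamma hyperprior on the coefficient
#'   variance `sigma2_beta`.
#' @param b_var_shape,b_var_rate Gamma hyperprior on the random-effect
#'   variance `sigma2_b`.
#' @param zeta_var_shape,zeta_var_rate Gamma hyperprior on the variance of the
#'   multinomial-imputation coefficients.
#' @param tau_scale Half-Cauchy scale for the outcome-component scales `tau`.
#' @param eta LKJ shape; must be positive.
#' @return A list of class `hyperprior_config`.
#' @export
hyperprior_config <- function(beta_var_shape = 2, beta_var_rate = 0.5,
                              b_var_shape = 2, b_var_rate = 0.5,
                              zeta_var_shape = 2, zeta_var_rate = 0.5,
                              tau_scale = 2.5, eta = 1) {
  stopifnot(beta_var_shape > 0, beta_var_rate > 0, b_var_shape > 0,
            b_var_rate > 0, zeta_var_shape > 0, zeta_var_rate > 0,
            tau_scale > 0, eta > 0)
  structure(list(beta_var_shape = beta_var_shape, beta_var_rate = beta_var_rate,
                 b_var_shape = b_var_shape, b_var_rate = b_var_rate,
                 zeta_var_shape = zeta_var_shape, zeta_var_rate = zeta_var_rate,
                 tau_scale = tau_scale, eta = eta),
            class = "hyperprior_config")
}

#' Half-Cauchy log-density
#'
#' Density of a Cauchy(0, scale) variable truncated to the positive half-line,
#' the standard weakly informative prior for scale parameters.
#'
#' @param x Evaluation points (density is zero for `x < 0`).
#' @param scale Positive scale, default 2.5.
#' @param log Return the log-density?
#' @return Numeric vector of (log-)densities.
#' @export
half_cauchy_density <- function(x, scale = 2.5, log = FALSE) {
  stopifnot(scale > 0)
  ld <- ifelse(x < 0, -Inf, log(2) + dcauchy(x, 0, scale, log = TRUE))
  if (log) ld else exp(ld)
}

#' Half-Cauchy quantiles
#'
#' @param p Probabilities.
#' @param scale Positive scale.
#' @return Quantiles of |Cauchy(0, scale)|.
#' @export
half_cauchy_quantile <- function(p, scale = 2.5) {
  stopifnot(scale > 0, all(p >= 0 & p <= 1))
  scale * tan(pi * p / 2)
}

is_correlation_matrix <- function(omega, tol = 1e-8) {
  is.matrix(omega) && nrow(omega) == ncol(omega) &&
    max(abs(omega - t(omega))) < tol &&
    max(abs(diag(omega) - 1)) < tol
}

#' LKJ log-density over correlation matrices
#'
#' The LKJ(eta) density is proportional to `det(Omega)^(eta - 1)`; with
#' eta = 1 it is uniform over valid correlation matrices of the given order,
#' eta > 1 shrinks towards the identity, and 0 < eta < 1 favours strong
#' correlations. The normalizing constant is omitted by default (all MCMC use
#' is invariant to it) and available via `normalize = TRUE`.
#'
#' @param omega A correlation matrix (symmetric, unit diagonal, positive
#'   definite).
#' @param eta Positive shape parameter.
#' @param normalize Include the normalizing constant?
#' @return The log-density; `-Inf` if `omega` is not positive definite.
#' @export
lkj_logdensity <- function(omega, eta = 1, normalize = FALSE) {
  stopifnot(eta > 0)
  if (!is_correlation_matrix(omega)) {
    stop("`omega` must be a symmetric matrix with unit diagonal", call. = FALSE)
  }
  d <- nrow(omega)
  ch <- tryCatch(chol(omega), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdet <- 2 * sum(log(diag(ch)))
  ld <- (eta - 1) * logdet
  if (normalize) ld <- ld + lkj_log_normalizer(d, eta)
  ld
}

# log normalizing constant of the LKJ density, i.e. minus the log of
# integral det(Omega)^(eta - 1) dOmega over d x d correlation matrices.
# Vine factorization: partial correlations at tree level l are independent
# 2*Beta(a_l, a_l) - 1 with a_l = eta + (d - 1 - l)/2 and multiplicity d - l,
# so the integral is prod_l [2^(2 a_l - 1) B(a_l, a_l)]^(d - l).
# (Sanity anchor: d = 3, eta = 1 gives volume pi^2 / 2.)
lkj_log_normalizer <- function(d, eta) {
  if (d == 1) return(0)
  l <- seq_len(d - 1)
  a <- eta + (d - 1 - l) / 2
  -sum((d - l) * ((2 * a - 1) * log(2) + lbeta(a, a)))
}

#' Sample correlation matrices from the LKJ distribution
#'
#' Onion-method sampler. Under eta = 1 each off-diagonal of a 3 x 3 draw is
#' marginally distributed as `2 * Beta(1.5, 1.5) - 1`, which the test suite
#' verifies by a Kolmogorov-Smirnov check.
#'
#' @param n Number of draws.
#' @param d Matrix dimension (>= 2).
#' @param eta Positive shape.
#' @return A list of `n` correlation matrices.
#' @export
rlkj <- function(n, d, eta = 1) {
  stopifnot(n >= 1, d >= 2, eta > 0)
  replicate(n, rlkj_one(d, eta), simplify = FALSE)
}

rlkj_one <- function(d, eta) {
  beta0 <- eta + (d - 2) / 2
  r12 <- 2 * rbeta(1, beta0, beta0) - 1
  omega <- matrix(c(1, r12, r12, 1), 2, 2)
  if (d == 2) return(omega)
  for (k in 2:(d - 1)) {
    beta0 <- beta0 - 0.5
    y <- rbeta(1, k / 2, beta0)
    u <- rnorm(k)
    u <- u / sqrt(sum(u^2))
    w <- sqrt(y) * u
    a <- t(chol(omega))
    q <- as.vector(a %*% w)
    omega <- rbind(cbind(omega, q), c(q, 1))
    dimnames(omega) <- NULL
  }
  # symmetrize against numerical drift
  (omega + t(omega)) / 2
}
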