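# Core probability model: Bernoulli outcomes through latent multivariate-normal
# logits. For subject i the d-vector of log-odds z_i follows
#   z_i ~ MVN(mu_i, Sigma),  mu_i = t(beta) %*% x_i + b_i,
#   Sigma = diag(tau) %*% Omega %*% diag(tau),
# and each observed outcome cell is Bernoulli(plogis(z)). All pieces are
# exposed as evaluable log-density components so the joint can be checked
# against the sum of its parts.

#' Linear predictor for one subject
#'
#' Computes the mean vector of the latent logits:
#' `mu_j = sum_p beta[p, j] * x[p] + b_i` for each outcome component j. The
#' subject random effect `b_i` is a single scalar added to every component,
#' capturing within-subject clustering across regions (or defects).
#'
#' @param x_row Numeric predictor vector including the leading intercept 1.
#' @param beta `(p + 1) x d` coefficient matrix (row 1 = intercept).
#' @param b_i Scalar random effect (default 0).
#' @return Length-`d` mean vector.
#' @export
#' @examples
#' beta <- rbind(c(-1.235, -2.132, -0.383))  # intercept-only model
#' linear_predictor(1, beta)
linear_predictor <- function(x_row, beta, b_i = 0) {
  x_row <- as.numeric(x_row)
  if (!is.matrix(beta)) beta <- matrix(beta, nrow = length(x_row))
  if (length(x_row) != nrow(beta)) {
    stop(sprintf("length(x_row) = %d does not match nrow(beta) = %d",
                 length(x_row), nrow(beta)), call. = FALSE)
  }
  stopifnot(length(b_i) == 1)
  drop(crossprod(beta, x_row)) + b_i
}

#' Assemble a covariance matrix from scales and a correlation matrix
#'
#' `Sigma = diag(tau) %*% Omega %*% diag(tau)`, the Cholesky-style separation
#' of scale and correlation used for the latent-logit covariance, so that
#' `Sigma[j, j] = tau[j]^2`.
#'
#' @param tau Positive scales, length d.
#' @param omega d x d correlation matrix.
#' @return The d x d covariance matrix.
#' @export
assemble_covariance <- function(tau, omega) {
  if (length(tau) == 1 && !is.matrix(omega)) omega <- matrix(omega, 1, 1)
  stopifnot(is.matrix(omega), nrow(omega) == ncol(omega),
            length(tau) == nrow(omega))
  if (any(tau <= 0)) stop("all scales `tau` must be positive", call. = FALSE)
  if (!is_correlation_matrix(omega)) {
    stop("`omega` must be symmetric with unit diagonal", call. = FALSE)
  }
  if (nrow(omega) > 1 && inherits(tryCatch(chol(omega), error = identity), "error")) {
    stop("`omega` is not positive definite", call. = FALSE)
  }
  diag(tau, length(tau)) %*% omega %*% diag(tau, length(tau))
}

# overflow-safe log(1 + exp(x))
log1pexp <- function(x) {
  ifelse(x > 35, x, ifelse(x < -35, exp(x), log1p(exp(x))))
}

#' Bernoulli log-likelihood over observed outcome cells
#'
#' Sums `y * z - log(1 + exp(z))` over observed cells of the panel, computed
#' overflow-safely; masked cells contribute zero, which is how partially
#' observed subjects remain in the model.
#'
#' @param panel A [defect_panel()].
#' @param z n x d matrix of latent logits.
#' @return Scalar log-likelihood.
#' @export
bernoulli_loglik <- function(panel, z) {
  stopifnot(inherits(panel, "defect_panel"))
  z <- as.matrix(z)
  if (!all(dim(z) == dim(panel$y))) {
    stop("dim(z) must equal dim(panel$y)", call. = FALSE)
  }
  obs <- panel$observed
  sum(panel$y[obs] * z[obs] - log1pexp(z[obs]))
}

#' Multivariate normal log-density (Cholesky-based)
#'
#' Row-wise density of `x` under MVN(mean, sigma), with a small diagonal
#' jitter retry when `sigma` is numerically singular.
#'
#' @param x Matrix of row vectors (or a single vector).
#' @param mean Mean matrix of matching shape (or a single vector recycled).
#' @param sigma Covariance matrix.
#' @param jitter Diagonal jitter used if the Cholesky factorization fails.
#' @return Vector of per-row log-densities.
#' @export
mvn_logpdf <- function(x, mean, sigma, jitter = 1e-9) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (!is.matrix(mean)) mean <- matrix(mean, nrow = nrow(x), ncol = ncol(x), byrow = TRUE)
  d <- ncol(x)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- tryCatch(chol(sigma + diag(jitter, d)), error = function(e) NULL)
    if (is.null(ch)) stop("covariance matrix is not positive definite", call. = FALSE)
  }
  e <- x - mean
  # solve L' u = e' for quadratic form
  u <- backsolve(ch, t(e), transpose = TRUE)
  quad <- colSums(u^2)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + quad)
}

validate_params <- function(params, p1, d, n) {
  beta <- params$beta
  if (!is.matrix(beta) || nrow(beta) != p1 || ncol(beta) != d) {
    stop(sprintf("beta must be a %d x %d matrix", p1, d), call. = FALSE)
  }
  if (any(!is.finite(beta))) stop("beta contains non-finite values", call. = FALSE)
  if (!is.null(params[["b"]]) && length(params[["b"]]) != n) {
    stop("random effects b must have one entry per subject", call. = FALSE)
  }
  invisible(TRUE)
}

#' Log-prior of a complete parameter state
#'
#' Sum of: Normal(0, sigma2_beta) over all coefficients plus the Gamma
#' hyperprior on sigma2_beta; Normal(0, sigma2_b) over subject random effects
#' plus its Gamma hyperprior; half-Cauchy over the scales `tau`; LKJ(eta)
#' over `omega`; and, when Gibbs variable selection is active,
#' Bernoulli(psi) over the indicators with Beta(1/2, 1/2) over psi.
#'
#' @param params List with elements `beta`, `sigma2_beta`, `tau`, `omega`,
#'   and optionally `b`, `sigma2_b`, `indicators`, `psi`.
#' @param hyper A [hyperprior_config()].
#' @return Scalar log-density; `-Inf` for out-of-support states.
#' @export
log_prior <- function(params, hyper = hyperprior_config()) {
  stopifnot(inherits(hyper, "hyperprior_config"))
  if (any(!is.finite(params$beta))) stop("beta contains non-finite values", call. = FALSE)
  if (params$sigma2_beta <= 0) return(-Inf)
  lp <- sum(dnorm(params$beta, 0, sqrt(params$sigma2_beta), log = TRUE)) +
    dgamma(params$sigma2_beta, hyper$beta_var_shape, rate = hyper$beta_var_rate,
           log = TRUE)
  if (!is.null(params[["b"]])) {
    if (params[["sigma2_b"]] <= 0) return(-Inf)
    lp <- lp + sum(dnorm(params[["b"]], 0, sqrt(params[["sigma2_b"]]), log = TRUE)) +
      dgamma(params[["sigma2_b"]], hyper$b_var_shape, rate = hyper$b_var_rate,
             log = TRUE)
  }
  if (any(params$tau <= 0)) return(-Inf)
  lp <- lp + sum(half_cauchy_density(params$tau, hyper$tau_scale, log = TRUE))
  d <- length(params$tau)
  if (d > 1) {
    lkj <- lkj_logdensity(params$omega, hyper$eta)
    if (!is.finite(lkj)) return(-Inf)
    lp <- lp + lkj
  }
  if (!is.null(params$indicators)) {
    psi <- params[["psi"]]
    if (any(psi <= 0 | psi >= 1)) return(-Inf)
    lp <- lp + sum(params$indicators * log(psi) +
                     (1 - params$indicators) * log(1 - psi)) +
      sum(dbeta(psi, 0.5, 0.5, log = TRUE))
  }
  lp
}

#' Joint log-density of data and parameters
#'
#' Composes the model: Bernoulli likelihood over observed outcome cells, the
#' multivariate-normal density of the latent logits given the linear
#' predictor and the assembled covariance, the parameter priors, and (when
#' predictors carry missing cells) the imputation-model terms. By
#' construction it equals the sum of the independently computed components,
#' which the test suite verifies to tight tolerance.
#'
#' @param panel A [defect_panel()].
#' @param predictors A [predictor_table()], or a complete numeric matrix
#'   without intercept column.
#' @param params Parameter state: `z` (n x d latent logits), `beta`,
#'   `sigma2_beta`, `tau`, `omega`, optionally `b`, `sigma2_b`,
#'   `indicators`, `psi`, `x_complete` (matrix with imputed values filled
#'   in) and `imputation` (see [imputation_logdensity()]).
#' @param hyper A [hyperprior_config()].
#' @return Scalar log-density.
#' @export
log_joint <- function(panel, predictors, params, hyper = hyperprior_config()) {
  stopifnot(inherits(panel, "defect_panel"))
  x <- if (inherits(predictors, "predictor_table")) predictors$x else as.matrix(predictors)
  if (!is.null(params$x_complete)) x <- params$x_complete
  n <- nrow(panel$y); d <- ncol(panel$y)
  if (is.null(x)) {
    xmat <- matrix(1, n, 1)
  } else {
    xmat <- cbind(1, x)
  }
  validate_params(params, ncol(xmat), d, n)
  if (any(is.na(xmat))) {
    stop("predictor matrix still has missing cells; supply `params$x_complete`",
         call. = FALSE)
  }
  beta_eff <- params$beta
  if (!is.null(params$indicators)) {
    beta_eff <- effective_coefficients(params$beta, params$indicators)
  }
  b <- if (is.null(params[["b"]])) rep(0, n) else params[["b"]]
  mu <- xmat %*% beta_eff + b
  sigma <- assemble_covariance(params$tau, if (d == 1) matrix(1, 1, 1) else params$omega)
  ll <- bernoulli_loglik(panel, params$z) +
    sum(mvn_logpdf(params$z, mu, sigma)) +
    log_prior(params, hyper)
  if (!is.null(params$imputation)) {
    ll <- ll + imputation_logdensity(predictors, params$x_complete,
                                     params$imputation, hyper)
  }
  ll
}

#' Latent logits and their probabilities
#'
#' Small convenience wrapper pairing a logit array with its probabilities.
#'
#' @param z Numeric matrix of log-odds.
#' @return List with `z` and `pi = plogis(z)`.
#' @export
latent_logits <- function(z) {
  z <- as.matrix(z)
  list(z = z, pi = plogis(z))
}
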