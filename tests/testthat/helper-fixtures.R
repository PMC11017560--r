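# Fixtures are built in code at test time.

region_panel_df <- function() {
  data.frame(subject_id = c("s1", "s2", "s3", "s4"),
             cervical = c(0, 1, NA, 0),
             middle   = c(0, 0, 1, 1),
             incisal  = c(1, 0, 0, NA))
}

small_schema <- function() {
  predictor_schema(
    columns = c("age", "formula", "vdbp"),
    kinds = c("continuous", "binary", "categorical3"),
    levels = list(vdbp = c("1s", "1f", "2"))
  )
}

small_predictor_df <- function() {
  data.frame(age = c(1.2, -0.5, 0.3, 2.0),
             formula = c(0, 1, 1, 0),
             vdbp = c("1s", "1f", "2", "1f"),
             race = c("Caucasian", "African American", "Hispanic", "Caucasian"))
}

tiny_control <- function(...) {
  mcmc_control(chains = 2, warmup = 150, samples = 150, seed = 42, ...)
}

# random valid parameter state for the joint-density oracle
random_state <- function(panel, x, gvs = TRUE, seed = 1) {
  set.seed(seed)
  n <- nrow(panel$y); d <- ncol(panel$y); p1 <- ncol(x) + 1
  omega <- rlkj(1, d, 1)[[1]]
  params <- list(
    z = matrix(rnorm(n * d), n, d),
    beta = matrix(rnorm(p1 * d, 0, 0.8), p1, d),
    sigma2_beta = rgamma(1, 2, 0.5),
    b = rnorm(n, 0, 0.5),
    sigma2_b = rgamma(1, 2, 0.5),
    tau = abs(rcauchy(d, 0, 1)) + 0.2,
    omega = omega
  )
  if (gvs) {
    params$indicators <- matrix(rbinom((p1 - 1) * d, 1, 0.5), p1 - 1, d)
    params$psi <- matrix(runif((p1 - 1) * d, 0.05, 0.95), p1 - 1, d)
  }
  params
}

# independent computation of the joint density from its parts
log_joint_by_parts <- function(panel, x, params, hyper = hyperprior_config()) {
  x1 <- cbind(1, x)
  beta_eff <- params$beta
  if (!is.null(params$indicators)) {
    beta_eff <- effective_coefficients(params$beta, params$indicators)
  }
  b <- if (is.null(params$b)) rep(0, nrow(x1)) else params$b
  mu <- x1 %*% beta_eff + b
  d <- ncol(panel$y)
  sigma <- diag(params$tau, d) %*% params$omega %*% diag(params$tau, d)
  bernoulli_loglik(panel, params$z) +
    sum(mvn_logpdf(params$z, mu, sigma)) +
    log_prior(params, hyper)
}
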