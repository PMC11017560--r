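test_that("linear predictor composes coefficients and the shared effect", {
  beta <- matrix(0, 3, 3)
  expect_equal(linear_predictor(c(1, 0.5, -1), beta), c(0, 0, 0))

  # intercept-only pass-through of the three region intercepts
  b0 <- rbind(c(-1.235, -2.132, -0.383))
  expect_equal(linear_predictor(1, b0), c(-1.235, -2.132, -0.383))

  # the random effect adds the same scalar to every component
  set.seed(1)
  beta <- matrix(rnorm(9), 3, 3)
  x <- c(1, rnorm(2))
  expect_equal(linear_predictor(x, beta, b_i = 0.5),
               linear_predictor(x, beta) + 0.5)
  expect_error(linear_predictor(c(1, 2), beta), "match")
})

test_that("covariance assembly separates scales and correlation", {
  expect_equal(assemble_covariance(c(1, 1, 1), diag(3)), diag(3))
  expect_equal(assemble_covariance(c(2, 1, 1), diag(3)), diag(c(4, 1, 1)))
  om <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  sig <- assemble_covariance(c(1, 2), om)
  expect_equal(sig[1, 2], 1.0)
  expect_equal(diag(sig), c(1, 4))
  expect_error(assemble_covariance(c(-1, 1), diag(2)), "positive")
  om_npd <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(assemble_covariance(c(1, 1, 1), om_npd), "positive definite")
})

test_that("assembled covariances are positive definite for LKJ draws", {
  set.seed(11)
  for (i in 1:25) {
    om <- rlkj(1, 4, 1)[[1]]
    tau <- abs(rcauchy(4, 0, 2.5)) + 1e-3
    ev <- eigen(assemble_covariance(tau, om), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("Bernoulli log-likelihood is mask-aware and overflow-safe", {
  p1 <- defect_panel(data.frame(cervical = 1, middle = NA_real_,
                                incisal = NA_real_))
  z <- matrix(c(0, 5, 5), 1, 3)
  expect_equal(bernoulli_loglik(p1, z), log(0.5))

  # saturation: y = 1 at z = +50 contributes ~0 without overflow
  z2 <- matrix(c(50, 0, 0), 1, 3)
  expect_equal(bernoulli_loglik(p1, z2), 0, tolerance = 1e-12)
  expect_true(is.finite(bernoulli_loglik(p1, matrix(c(-800, 0, 0), 1, 3))))

  # symmetric two-cell case: y = (1, 0), z = (1, -1)
  p2 <- defect_panel(data.frame(cervical = 1, middle = 0, incisal = NA_real_))
  z3 <- matrix(c(1, -1, 0), 1, 3)
  expect_equal(bernoulli_loglik(p2, z3), -2 * log(1 + exp(-1)))

  expect_error(bernoulli_loglik(p1, matrix(0, 2, 3)), "dim")
})

test_that("logit/expit round-trips hold to tight tolerance", {
  p <- c(1e-9, 0.01, 0.33, 0.5, 0.77, 1 - 1e-9)
  expect_equal(plogis(qlogis(p)), p, tolerance = 1e-12)
  z <- seq(-8, 8, length.out = 50)
  expect_true(all(diff(plogis(z)) > 0))
  ll <- latent_logits(matrix(z[1:6], 2, 3))
  expect_true(all(ll$pi > 0 & ll$pi < 1))
  expect_equal(qlogis(ll$pi), ll$z, tolerance = 1e-9)
})

test_that("the MVN log-density matches the mvtnorm oracle", {
  skip_if_not_installed("mvtnorm")
  set.seed(3)
  sig <- assemble_covariance(c(1, 0.7, 1.4), rlkj(1, 3, 1)[[1]])
  x <- matrix(rnorm(15), 5, 3)
  mu <- matrix(rnorm(15), 5, 3)
  ours <- mvn_logpdf(x, mu, sig)
  oracle <- vapply(1:5, function(i) {
    mvtnorm::dmvnorm(x[i, ], mu[i, ], sig, log = TRUE)
  }, numeric(1))
  expect_equal(ours, oracle, tolerance = 1e-10)
})

test_that("log-prior matches closed-form components", {
  params <- list(beta = matrix(0, 1, 1), sigma2_beta = 4,
                 tau = 1, omega = matrix(1, 1, 1))
  lp <- log_prior(params)
  expect_equal(lp,
               dnorm(0, 0, 2, log = TRUE) +
                 -2 +                               # Gamma(2, 0.5) at 4
                 log(2) + dcauchy(1, 0, 2.5, log = TRUE))
  # out of support
  expect_identical(log_prior(utils::modifyList(params, list(tau = -1))), -Inf)
  expect_identical(log_prior(utils::modifyList(params, list(sigma2_beta = 0))), -Inf)
  expect_error(log_prior(utils::modifyList(params, list(beta = matrix(NaN, 1, 1)))),
               "non-finite")
})

test_that("the joint density equals the sum of its parts", {
  set.seed(5)
  df <- data.frame(cervical = rbinom(8, 1, 0.4),
                   middle = rbinom(8, 1, 0.4),
                   incisal = rbinom(8, 1, 0.4))
  df$middle[3] <- NA
  panel <- defect_panel(df)
  x <- matrix(rnorm(16), 8, 2, dimnames = list(NULL, c("a", "b")))
  for (s in 1:5) {
    params <- random_state(panel, x, gvs = s %% 2 == 0, seed = s)
    expect_equal(log_joint(panel, x, params),
                 log_joint_by_parts(panel, x, params),
                 tolerance = 1e-10)
  }
})

test_that("with all outcomes masked the joint reduces to MVN plus priors", {
  panel <- defect_panel(data.frame(cervical = rep(NA_real_, 6),
                                   middle = NA_real_, incisal = NA_real_))
  x <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("a", "b")))
  params <- random_state(panel, x, gvs = FALSE, seed = 9)
  x1 <- cbind(1, x)
  mu <- x1 %*% params$beta + params$b
  sig <- assemble_covariance(params$tau, params$omega)
  expect_equal(log_joint(panel, x, params),
               sum(mvn_logpdf(params$z, mu, sig)) + log_prior(params),
               tolerance = 1e-10)
})
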