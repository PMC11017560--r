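# minimal fit-shaped object for exercising summary conventions on
# hand-constructed draws
fake_fit <- function(draws, type = "beta", predictor = "x1",
                     component = "cervical") {
  info <- tibble::tibble(type = type, name = colnames(draws),
                         predictor = predictor, component = component)
  structure(list(chains = list(draws), param_info = info, gvs = FALSE,
                 diagnostics = tibble::tibble(parameter = info$name,
                                              rhat = NA_real_)),
            class = "defect_fit")
}

test_that("identical seeds reproduce identical draws", {
  set.seed(99)
  df <- data.frame(cervical = rbinom(25, 1, 0.3), middle = rbinom(25, 1, 0.3),
                   incisal = rbinom(25, 1, 0.4))
  panel <- defect_panel(df)
  x <- matrix(rnorm(50), 25, 2, dimnames = list(NULL, c("a", "b")))
  ctrl <- mcmc_control(chains = 2, warmup = 50, samples = 50, seed = 7)
  f1 <- suppressWarnings(fit_defect_model(panel, x, gvs = TRUE, control = ctrl))
  f2 <- suppressWarnings(fit_defect_model(panel, x, gvs = TRUE, control = ctrl))
  expect_identical(f1$chains, f2$chains)
  # and a different seed moves the draws
  ctrl$seed <- 8L
  f3 <- suppressWarnings(fit_defect_model(panel, x, gvs = TRUE, control = ctrl))
  expect_false(identical(f1$chains, f3$chains))
})

test_that("split R-hat separates agreeing from disagreeing chains", {
  skip_if_not_installed("coda")
  set.seed(12)
  same <- matrix(rnorm(2000), 1000, 2, dimnames = list(NULL, c("p1", "p2")))
  expect_lt(max(gelman_rubin(list(same, same + 0))$rhat), 1.05)

  far <- list(matrix(rnorm(1000, 0), ncol = 1, dimnames = list(NULL, "p")),
              matrix(rnorm(1000, 10), ncol = 1, dimnames = list(NULL, "p")))
  rh <- gelman_rubin(far)$rhat
  expect_gt(rh, 1.1)
  # coda agrees that the chains disagree badly
  oracle <- coda::gelman.diag(coda::mcmc.list(coda::mcmc(far[[1]]),
                                              coda::mcmc(far[[2]])),
                              autoburnin = FALSE)$psrf[1]
  expect_gt(oracle, 1.1)
  # exact check against an independent computation of the split PSRF
  halves <- list(far[[1]][1:500, 1], far[[1]][501:1000, 1],
                 far[[2]][1:500, 1], far[[2]][501:1000, 1])
  w <- mean(vapply(halves, var, numeric(1)))
  bn <- var(vapply(halves, mean, numeric(1)))
  expect_equal(rh, sqrt((499 / 500 * w + bn) / w), tolerance = 1e-10)

  const <- matrix(1, 100, 1, dimnames = list(NULL, "p"))
  out <- gelman_rubin(list(const, const))
  expect_equal(out$rhat, 1)
  expect_match(out$note, "degenerate")

  expect_warning(gelman_rubin(list(same)), "one chain")
})

test_that("posterior summaries follow the odds-scale conventions", {
  # constant chain at log 2
  draws <- matrix(log(2), 100, 1, dimnames = list(NULL, "beta[x1,cervical]"))
  s <- summarize_fit(fake_fit(draws), "beta", odds_scale = TRUE)
  expect_equal(s$mean, 2)
  expect_equal(c(s$conf.low, s$conf.high), c(2, 2))

  # normal draws with log-odds mean -0.248, sd 0.104 reproduce the
  # 0.78 (1.11) / (0.63, 0.95) reporting pattern
  set.seed(5)
  z <- rnorm(200000)
  z <- (z - mean(z)) / sd(z) * 0.104 - 0.248
  draws2 <- matrix(z, ncol = 1, dimnames = list(NULL, "beta[x1,cervical]"))
  s2 <- summarize_fit(fake_fit(draws2), "beta", odds_scale = TRUE)
  expect_equal(round(s2$mean, 2), 0.78)
  expect_equal(round(s2$sd, 2), 1.11)    # geometric SD
  expect_equal(round(s2$conf.low, 2), 0.64, tolerance = 0.02)
  expect_equal(round(s2$conf.high, 2), 0.96, tolerance = 0.02)

  # draws symmetric around zero give null odds
  zs <- c(seq(-2, 2, length.out = 401))
  s3 <- summarize_fit(fake_fit(matrix(zs, ncol = 1,
                                      dimnames = list(NULL, "b"))),
                      "beta", odds_scale = TRUE)
  expect_equal(s3$mean, 1)
  expect_error(summarize_fit(fake_fit(draws, type = "tau"), "tau",
                             odds_scale = TRUE), "coefficient")
})

test_that("summaries are invariant to chain concatenation order", {
  set.seed(21)
  d1 <- matrix(rnorm(300), 100, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  d2 <- matrix(rnorm(300, 0.3), 100, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  f12 <- fake_fit(rbind(d1, d2), predictor = c("a", "b", "c"))
  f21 <- fake_fit(rbind(d2, d1), predictor = c("a", "b", "c"))
  s12 <- summarize_fit(f12, "beta")
  s21 <- summarize_fit(f21, "beta")
  expect_equal(s12$mean, s21$mean)
  expect_equal(s12$conf.low, s21$conf.low)
})

test_that("correlation summaries support both reporting conventions", {
  id_draws <- replicate(50, diag(3), simplify = FALSE)
  for (conv in c("full_matrix", "cholesky_columns")) {
    s <- correlation_summary(id_draws, conv,
                             labels = c("cervical", "middle", "incisal"))
    expect_equal(s$mean, as.numeric(diag(3)[cbind(
      match(s$row, c("cervical", "middle", "incisal")),
      match(s$col, c("cervical", "middle", "incisal")))]))
    expect_equal(s$conf.high - s$conf.low, rep(0, 9))
  }

  # 2x2 with r = 0.6: lower Cholesky row 2 is (0.6, 0.8)
  om <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  s2 <- correlation_summary(replicate(20, om, simplify = FALSE),
                            "cholesky_columns", labels = c("c1", "c2"))
  expect_equal(s2$mean[s2$row == "c2" & s2$col == "c1"], 0.6)
  expect_equal(s2$mean[s2$row == "c2" & s2$col == "c2"], 0.8)
  expect_equal(s2$mean[s2$row == "c1" & s2$col == "c2"], 0)  # upper triangle

  # first Cholesky column equals the first column of Omega, draw by draw
  set.seed(17)
  oms <- rlkj(30, 3, 1)
  sc <- correlation_summary(oms, "cholesky_columns")
  sf <- correlation_summary(oms, "full_matrix")
  first_col <- sc$col == "c1"
  expect_equal(sc$mean[first_col], sf$mean[first_col], tolerance = 1e-10)
})

test_that("intercept-only fits are calibrated against sample prevalence", {
  set.seed(41)
  beta <- matrix(c(-1.1, -0.3, 0.4), 1, 3)
  panel <- generate_outcomes(beta, 0.5 * diag(3), n = 250, seed = 41)
  prev <- summarize_prevalence(panel)$percent / 100
  fit <- suppressWarnings(fit_defect_model(
    panel, NULL, gvs = FALSE, include_random_effect = FALSE,
    control = mcmc_control(chains = 2, warmup = 400, samples = 400, seed = 2)))
  draws <- do.call(rbind, fit$chains)
  b0 <- draws[, grep("^beta", colnames(draws))]
  tau <- draws[, grep("^tau", colnames(draws))]
  # posterior-predictive marginal prevalence, averaging the logistic over the
  # latent normal by quadrature
  u <- seq(-5, 5, length.out = 81)
  wu <- dnorm(u) / sum(dnorm(u))
  pp <- vapply(1:3, function(j) {
    mean(vapply(seq_len(nrow(draws)), function(t) {
      sum(plogis(b0[t, j] + tau[t, j] * u) * wu)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(pp, prev, tolerance = 0.06, ignore_attr = TRUE)
})

test_that("reduced refits keep selected predictors in every component", {
  set.seed(55)
  n <- 120
  x <- cbind(strong = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  beta <- matrix(0, 4, 3)
  beta[1, ] <- -0.4
  beta[2, ] <- c(1.6, 1.4, 1.8)
  panel <- generate_outcomes(beta, diag(3), x, seed = 56)
  fit <- suppressWarnings(fit_defect_model(panel, x, gvs = TRUE,
                                           control = tiny_control()))
  psi <- inclusion_probabilities(fit)
  expect_gt(max(psi$psi[psi$predictor == "strong"]), 0.6)
  red <- suppressWarnings(fit_reduced_model(fit, threshold = 0.6,
                                            control = tiny_control()))
  expect_false(red$gvs)
  coefs <- summarize_fit(red, "coefficients")
  expect_true(all(red$selection$predictor %in% coefs$predictor))
  expect_equal(sort(unique(coefs$component)),
               sort(c("cervical", "middle", "incisal")))
  # every selected predictor appears in all three components
  for (p in red$selection$predictor) {
    expect_equal(sum(coefs$predictor == p), 3)
  }
})
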