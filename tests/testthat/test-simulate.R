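test_that("covariate generation is reproducible and honours its config", {
  cfg <- default_covariate_config()
  a <- generate_covariates(cfg, 50, seed = 3)
  b <- generate_covariates(cfg, 50, seed = 3)
  expect_identical(a$x, b$x)

  capped <- generate_covariates(default_covariate_config(count_cap = 3),
                                500, seed = 4)
  expect_lte(max(capped$x[, "strep_mutans"]), 3)

  cfg0 <- cfg
  cfg0$par1[cfg0$predictor == "formula"] <- 0
  zeros <- generate_covariates(cfg0, 200, seed = 5)
  expect_true(all(zeros$x[, "formula"] == 0))

  cfg_bad <- cfg
  cfg_bad$dist[1] <- "lognormal"
  expect_error(generate_covariates(cfg_bad, 10, seed = 1), "unknown covariate")

  # encoded columns line up with the 26-row coefficient layout
  expect_equal(ncol(a$x), 25)
  expect_equal(colnames(a$x)[19:20], c("vdbp_1f", "vdbp_2"))
})

test_that("outcome generation matches closed-form prevalence", {
  # degenerate latent noise: prevalence equals expit of the intercept
  panel <- generate_outcomes(matrix(-1.235, 1, 3), matrix(0, 3, 3),
                             n = 100000, seed = 6)
  prev <- summarize_prevalence(panel)$percent / 100
  expect_equal(prev, rep(plogis(-1.235), 3), tolerance = 0.01,
               ignore_attr = TRUE)

  # zero coefficients with identity covariance: symmetric around 1/2
  panel2 <- generate_outcomes(matrix(0, 1, 3), diag(3), n = 100000, seed = 7)
  prev2 <- summarize_prevalence(panel2)$percent / 100
  expect_equal(prev2, rep(0.5, 3), tolerance = 0.01, ignore_attr = TRUE)

  # reproducibility
  p1 <- generate_outcomes(matrix(0, 1, 3), diag(3), n = 40, seed = 8)
  p2 <- generate_outcomes(matrix(0, 1, 3), diag(3), n = 40, seed = 8)
  expect_identical(p1$y, p2$y)

  om_npd <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(generate_outcomes(matrix(0, 1, 2), om_npd, n = 5,
                                 labels = c("a", "b")), "semi-definite")
})

test_that("scenario presets carry the packaged generating tables", {
  s1 <- scenario_preset("EH_s1")
  expect_equal(dim(s1$coefficients), c(26, 3))
  expect_equal(unname(s1$coefficients["gest_age", ]), c(0.026, -0.04, -0.198))
  expect_equal(unname(s1$coefficients["(Intercept)", ]),
               c(-1.235, -2.132, -0.383))
  expect_equal(unname(s1$covariance[1, ]), c(1.0000, 0.1685, 0.0715))
  expect_equal(s1$n, 148L)
  expect_equal(s1$iterations, 50L)

  s2 <- scenario_preset("EH_s2")
  expect_equal(unname(s2$covariance), diag(3))
  expect_equal(s2$coefficients, s1$coefficients)

  s3 <- scenario_preset("EH_s3")
  expect_equal(unname(s3$covariance), unname(s1$covariance))
  nz <- rownames(s3$coefficients)[rowSums(s3$coefficients != 0) > 0]
  expect_setequal(nz, c("(Intercept)", "child_ca", "mother_age", "mother_p_28",
                        "mother_fvdd_12", "vdbp_1f", "strep_mutans"))
  expect_equal(unname(s3$coefficients["strep_mutans", ]), c(1, 2, 1.5))

  expect_error(scenario_preset("PEB_s2"), "not available")
  expect_error(scenario_preset("OP_s1"), "user-supplied")
  expect_error(scenario_preset("EH_s9"), "unknown scenario")
  op <- scenario_preset("OP_s1", coefficients = matrix(0, 2, 3),
                        covariance = diag(3))
  expect_equal(op$defect, "OP")
})

test_that("recovery error computes MSE and MAE against truth", {
  truth <- matrix(c(1, -1), 1, 2,
                  dimnames = list("a", c("c1", "c2")))
  est <- tibble::tibble(iteration = rep(1:2, each = 2),
                        predictor = "a", component = rep(c("c1", "c2"), 2),
                        estimate = c(1, -1, 1, -1))
  expect_equal(recovery_error(est, truth, "MSE")$value, c(0, 0))

  est$estimate <- est$estimate + 1
  expect_equal(recovery_error(est, truth, "MSE")$value, c(1, 1))
  expect_equal(recovery_error(est, truth, "MAE")$value, c(1, 1))

  # deviations {+1, -1}: MSE 1, MAE 1; deviations {0, 2}: MSE 2, MAE 1
  truth1 <- matrix(0, 1, 1, dimnames = list("a", "c1"))
  dev1 <- tibble::tibble(iteration = 1:2, predictor = "a", component = "c1",
                         estimate = c(1, -1))
  dev2 <- tibble::tibble(iteration = 1:2, predictor = "a", component = "c1",
                         estimate = c(0, 2))
  expect_equal(recovery_error(dev1, truth1, "MSE")$value, 1)
  expect_equal(recovery_error(dev1, truth1, "MAE")$value, 1)
  expect_equal(recovery_error(dev2, truth1, "MSE")$value, 2)
  expect_equal(recovery_error(dev2, truth1, "MAE")$value, 1)
  # MAE <= sqrt(MSE)
  expect_lte(recovery_error(dev2, truth1, "MAE")$value,
             sqrt(recovery_error(dev2, truth1, "MSE")$value))
})

test_that("inclusion ranges report order statistics with threshold flags", {
  one <- tibble::tibble(iteration = 1, predictor = "a", component = "c1",
                        psi = 0.4)
  s1 <- inclusion_range_summary(one)
  expect_equal(c(s1$median, s1$min, s1$max), rep(0.4, 3))

  three <- tibble::tibble(iteration = 1:3, predictor = "a", component = "c1",
                          psi = c(0.2, 0.5, 0.8))
  s3 <- inclusion_range_summary(three)
  expect_equal(c(s3$median, s3$min, s3$max), c(0.5, 0.2, 0.8))
  expect_false(s3$consistently_inclusive)

  high <- tibble::tibble(iteration = 1:3, predictor = "a", component = "c1",
                         psi = c(0.7, 0.9, 0.95))
  expect_true(inclusion_range_summary(high)$consistently_inclusive)
})

test_that("the simulation study driver is reproducible and records iterations", {
  spec <- scenario_preset("EH_s3", n = 60, iterations = 2)
  # trim to a handful of predictors for a fast smoke contract
  spec$covariates <- spec$covariates[spec$covariates$predictor %in%
    c("child_ca", "mother_age", "formula"), ]
  spec$coefficients <- spec$coefficients[c("(Intercept)", "child_ca",
                                           "mother_age", "formula"), ]
  ctrl <- mcmc_control(chains = 2, warmup = 100, samples = 100, seed = 1)
  rep1 <- run_simulation_study(spec, ctrl, seed = 5, refit_reduced = TRUE)
  expect_equal(nrow(rep1$iterations), 2)
  expect_true(all(rep1$iterations$status == "ok"))
  expect_equal(sort(unique(rep1$inclusion$iteration)), 1:2)
  expect_setequal(unique(rep1$estimates$source), c("full", "reduced"))
  expect_equal(nrow(rep1$covariance), 2 * 9)

  rep2 <- run_simulation_study(spec, ctrl, seed = 5, refit_reduced = TRUE)
  expect_identical(rep1$inclusion, rep2$inclusion)
  expect_identical(rep1$estimates, rep2$estimates)

  agg <- recovery_error(dplyr::filter(rep1$estimates, source == "full"),
                        spec$coefficients, "MSE")
  expect_true(all(agg$value >= 0))
  expect_equal(unique(agg$n_iterations), 2L)
})
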