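#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of a fitted defect model
#'
#' @param x A `defect_fit`.
#' @param type Parameter block, see [summarize_fit()].
#' @param odds_scale Report coefficients on the odds scale (exponentiated
#'   mean/interval, geometric SD)?
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `component`,
#'   `estimate`, `std.error`, `conf.low`, `conf.high`, `rhat`.
#' @export
tidy.defect_fit <- function(x, type = "coefficients", odds_scale = FALSE, ...) {
  s <- summarize_fit(x, type = type, odds_scale = odds_scale)
  tibble::tibble(
    term = ifelse(is.na(s$predictor), s$parameter, s$predictor),
    component = s$component,
    estimate = s$mean, std.error = s$sd,
    conf.low = s$conf.low, conf.high = s$conf.high, rhat = s$rhat)
}

#' One-row fit summary
#'
#' @param x A `defect_fit`.
#' @param ... Unused.
#' @return A one-row tibble: problem size, chain configuration, worst
#'   Gelman-Rubin statistic, convergence flag, runtime.
#' @export
glance.defect_fit <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$panel$y),
    n_components = ncol(x$panel$y),
    n_predictors = if (is.null(x$predictors)) 0L else ncol(x$predictors$x),
    gvs = x$gvs,
    chains = x$control$chains,
    samples_per_chain = x$control$samples,
    warmup = x$control$warmup,
    max_rhat = x$convergence$max_rhat,
    converged = x$convergence$converged,
    runtime_sec = x$runtime)
}

#' Tidy a recovery report
#'
#' @param x A `recovery_report`.
#' @param ... Unused.
#' @return The per-iteration inclusion tibble joined with iteration status.
#' @export
tidy.recovery_report <- function(x, ...) {
  dplyr::left_join(x$inclusion, x$iterations[, c("iteration", "status", "converged")],
                   by = "iteration")
}

#' @export
glance.recovery_report <- function(x, ...) {
  tibble::tibble(
    scenario = x$spec$name,
    n_iterations = nrow(x$iterations),
    n_completed = sum(x$iterations$status == "ok"),
    n_subjects = x$spec$n,
    threshold = x$threshold,
    seed = x$seed)
}
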