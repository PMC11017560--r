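#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Coefficient interval plot for a fitted defect model
#'
#' Posterior means and 95% credible intervals per predictor and outcome
#' component; with `odds_scale = TRUE` a dashed line marks the null odds of 1
#' (0 on the log-odds scale otherwise).
#'
#' @param object A `defect_fit`.
#' @param odds_scale Plot on the odds scale?
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.defect_fit <- function(object, odds_scale = FALSE, ...) {
  s <- summarize_fit(object, "coefficients", odds_scale = odds_scale)
  s <- s[s$predictor != "(Intercept)", , drop = FALSE]
  null_value <- if (odds_scale) 1 else 0
  ggplot2::ggplot(s, ggplot2::aes(x = .data$mean, y = .data$predictor)) +
    ggplot2::geom_vline(xintercept = null_value, linetype = "dashed",
                        colour = "red") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::facet_wrap(~component) +
    (if (odds_scale) ggplot2::scale_x_log10() else ggplot2::scale_x_continuous()) +
    ggplot2::labs(x = if (odds_scale) "posterior mean (odds scale)" else
                    "posterior mean (log-odds)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Posterior inclusion probabilities of a fit
#'
#' Dot plot of the per-predictor, per-component posterior probabilities of
#' inclusion with the 0.5 and 0.6 thresholds marked.
#'
#' @param fit A `defect_fit` run with GVS.
#' @param threshold Strict threshold to highlight (default 0.6).
#' @return A ggplot object.
#' @export
plot_inclusion <- function(fit, threshold = 0.6) {
  psi <- inclusion_probabilities(fit)
  ggplot2::ggplot(psi, ggplot2::aes(x = .data$psi, y = .data$predictor)) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed", colour = "blue") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~component) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "posterior probability of inclusion", y = NULL) +
    ggplot2::theme_minimal()
}

#' Inclusion-range plot for a recovery study
#'
#' Median and range of the posterior inclusion probabilities across the
#' simulation iterations, the box-plot summary of a recovery study.
#'
#' @param object A `recovery_report`.
#' @param threshold Strict inclusion threshold to mark (default the
#'   report's).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_report <- function(object, threshold = object$threshold, ...) {
  ggplot2::ggplot(object$inclusion,
                  ggplot2::aes(x = .data$predictor, y = .data$psi)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "blue") +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~component, ncol = 1) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "posterior probability of inclusion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
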