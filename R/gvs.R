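# Gibbs variable selection: each non-intercept coefficient beta[p, j] is
# multiplied by a binary indicator I[p, j] ~ Bernoulli(psi[p, j]) with
# psi ~ Beta(1/2, 1/2); the effective coefficient is xi = beta * I. The
# posterior mean of an indicator is its posterior probability of inclusion,
# and predictors whose inclusion probability exceeds a threshold in at least
# one outcome component form the reduced model.

#' Effective coefficients under indicator masking
#'
#' `xi[p, j] = beta[p, j] * I[p, j]` elementwise over the non-intercept rows;
#' the intercept row (row 1) always passes through unchanged.
#'
#' @param beta `(p + 1) x d` coefficient matrix, row 1 = intercept.
#' @param indicators `p x d` binary matrix (no intercept row).
#' @return `(p + 1) x d` matrix of effective coefficients.
#' @export
effective_coefficients <- function(beta, indicators) {
  stopifnot(is.matrix(beta))
  indicators <- as.matrix(indicators)
  if (nrow(indicators) != nrow(beta) - 1 || ncol(indicators) != ncol(beta)) {
    stop(sprintf("indicators must be %d x %d (intercept row excluded)",
                 nrow(beta) - 1, ncol(beta)), call. = FALSE)
  }
  if (!all(indicators %in% c(0, 1))) {
    stop("indicators must be 0/1", call. = FALSE)
  }
  xi <- beta
  xi[-1, ] <- beta[-1, , drop = FALSE] * indicators
  xi
}

#' Posterior probabilities of inclusion
#'
#' Elementwise mean of the indicator draws across the chain(s).
#'
#' @param indicator_draws A list of `p x d` binary matrices (one per draw),
#'   or a 3-d array with draws along the first dimension.
#' @return `p x d` matrix of inclusion probabilities.
#' @export
inclusion_probability <- function(indicator_draws) {
  if (is.array(indicator_draws) && length(dim(indicator_draws)) == 3) {
    if (dim(indicator_draws)[1] == 0) stop("no indicator draws", call. = FALSE)
    return(apply(indicator_draws, c(2, 3), mean))
  }
  if (!is.list(indicator_draws) || length(indicator_draws) == 0) {
    stop("no indicator draws", call. = FALSE)
  }
  Reduce(`+`, indicator_draws) / length(indicator_draws)
}

#' Select predictors by posterior inclusion probability
#'
#' A predictor enters the reduced model when its inclusion probability is
#' strictly greater than the threshold in at least one outcome component
#' (the any-component rule); the default threshold 0.6 is the stricter cut
#' that balances parsimony against the large number of candidate predictors.
#'
#' @param psi_hat `p x d` matrix of inclusion probabilities with predictor
#'   rownames and component colnames, or a tidy tibble with columns
#'   `predictor`, `component`, `psi`.
#' @param threshold Strict inclusion cut, default 0.6.
#' @return A tibble with one row per selected predictor: `predictor`,
#'   `components` (list-column of component names where the threshold was
#'   exceeded) and `max_psi`, ordered as the predictors appear.
#' @export
select_predictors <- function(psi_hat, threshold = 0.6) {
  if (is.data.frame(psi_hat)) {
    wide <- tidyr::pivot_wider(psi_hat, id_cols = "predictor",
                               names_from = "component", values_from = "psi")
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- wide$predictor
    psi_hat <- m
  }
  stopifnot(is.matrix(psi_hat))
  if (is.null(rownames(psi_hat))) rownames(psi_hat) <- paste0("x", seq_len(nrow(psi_hat)))
  if (is.null(colnames(psi_hat))) colnames(psi_hat) <- paste0("c", seq_len(ncol(psi_hat)))
  hits <- psi_hat > threshold
  keep <- which(rowSums(hits) > 0)
  tibble::tibble(
    predictor = rownames(psi_hat)[keep],
    components = lapply(keep, function(i) colnames(psi_hat)[hits[i, ]]),
    max_psi = apply(psi_hat, 1, max)[keep]
  )
}

#' Build the reduced-model configuration from a selection
#'
#' Every selected predictor is carried into the reduced model in all outcome
#' components (matching how reduced-model tables report each selected
#' predictor in every region or defect), GVS is disabled, and the intercept
#' plus the full covariance/random-effect structure are retained. An empty
#' selection falls back to an intercept-only model with a warning.
#'
#' @param selection Output of [select_predictors()], or a character vector of
#'   predictor names.
#' @param d Number of outcome components of the reduced model.
#' @return A list with `predictors` (character), `gvs = FALSE`, and the
#'   implied coefficient dimension `coef_dim = c(length(predictors) + 1, d)`.
#' @export
build_reduced_spec <- function(selection, d) {
  preds <- if (is.data.frame(selection)) selection$predictor else as.character(selection)
  if (length(preds) == 0) {
    warning("empty selection: reduced model is intercept-only", call. = FALSE)
  }
  list(predictors = preds, gvs = FALSE, coef_dim = c(length(preds) + 1L, as.integer(d)))
}
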