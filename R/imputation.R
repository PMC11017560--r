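# Missing predictor cells are treated as parameters with their own priors
# and updated inside the MCMC (missing-at-random assumption):
#   continuous column:  x_mis ~ Normal(mean of observed cells, sigma2_col),
#                       sigma2_col ~ Gamma(2, rate 0.5)
#   binary column:      x_mis ~ Bernoulli(nu), nu ~ Uniform(0, 1)
#   3-level genotype:   category ~ Multinomial(v), with v from a
#                       multinomial-logit regression on maternal race,
#                       zeta ~ Normal(0, sigma2_zeta), sigma2_zeta ~ Gamma(2, 0.5)
# Note: the category probabilities are mapped through a softmax. A literal
# linear share (zeta0 + race * zeta1) / sum(...) is not a valid simplex map
# (it can go negative), so the standard multinomial-logit link is used; see
# the methods vignette.

#' Imputation prior for a continuous predictor column
#'
#' Missing cells of a continuous column are modelled as draws from a normal
#' distribution whose mean is the arithmetic mean of the column's observed
#' cells and whose variance carries a Gamma(2, rate 0.5) hyperprior.
#'
#' @param column Numeric vector with `NA` for missing cells.
#' @return List with `mean`, `var_shape`, `var_rate`, and `n_observed`.
#' @export
continuous_imputation_prior <- function(column) {
  obs <- column[!is.na(column)]
  if (length(obs) == 0) {
    stop(paste("cannot build an imputation prior for an entirely missing",
               "continuous column; drop the column or supply a prior mean"),
         call. = FALSE)
  }
  list(mean = mean(obs), var_shape = 2, var_rate = 0.5,
       n_observed = length(obs))
}

#' Imputation prior for a binary predictor column
#'
#' Missing cells are Bernoulli(nu) with nu ~ Uniform(0, 1); with the column's
#' cells as data the posterior of nu is conjugate,
#' `Beta(1 + successes, 1 + failures)`.
#'
#' @param column Numeric 0/1 vector with `NA` for missing cells.
#' @return List with `n_missing`, the conjugate posterior parameters
#'   `post_shape1`/`post_shape2` given the observed cells, and the posterior
#'   mean `nu_hat`.
#' @export
binary_imputation_prior <- function(column) {
  obs <- column[!is.na(column)]
  if (!all(obs %in% c(0, 1))) stop("binary column must be 0/1", call. = FALSE)
  s1 <- 1 + sum(obs)
  s2 <- 1 + sum(obs == 0)
  list(n_missing = sum(is.na(column)), post_shape1 = s1, post_shape2 = s2,
       nu_hat = s1 / (s1 + s2))
}

#' Category probabilities of the genotype imputation model
#'
#' Multinomial-logit map from maternal race to the three genotype category
#' probabilities: `v_c = exp(zeta0_c + race . zeta1_c) / sum_c' exp(...)`.
#' Always returns a strictly positive vector summing to one.
#'
#' @param race Numeric race covariate for one subject: a scalar indicator or
#'   a vector of dummy codes.
#' @param zeta0 Length-3 vector of category intercepts.
#' @param zeta1 Length-3 vector (scalar race) or `3 x k` matrix (k race
#'   dummies) of race effects.
#' @return Length-3 probability simplex.
#' @export
#' @examples
#' categorical_probabilities(0, c(log(2), 0, 0), c(0, 0, 0))  # (0.5, 0.25, 0.25)
categorical_probabilities <- function(race, zeta0, zeta1) {
  stopifnot(length(zeta0) == 3)
  race <- as.numeric(race)
  if (is.matrix(zeta1)) {
    stopifnot(nrow(zeta1) == 3, ncol(zeta1) == length(race))
    eta <- zeta0 + drop(zeta1 %*% race)
  } else {
    stopifnot(length(zeta1) == 3, length(race) == 1)
    eta <- zeta0 + race * zeta1
  }
  eta <- eta - max(eta)
  exp(eta) / sum(exp(eta))
}

race_dummies <- function(race) {
  # reference = first level; returns n x (nlevels - 1) matrix
  lv <- levels(race)
  if (length(lv) < 2) return(matrix(0, length(race), 0))
  out <- sapply(lv[-1], function(l) as.numeric(race == l))
  out <- matrix(out, nrow = length(race),
                dimnames = list(NULL, paste0("race_", lv[-1])))
  out
}

# Builds the mutable imputation state used by the sampler. Returns NULL when
# the predictor table is complete and carries its own race handling when the
# race column itself has missing entries (imputed from empirical frequencies).
build_imputation_state <- function(predictors) {
  stopifnot(inherits(predictors, "predictor_table"))
  if (all(predictors$observed) &&
      (is.null(predictors$race) || !anyNA(predictors$race))) {
    return(NULL)
  }
  x <- predictors$x
  meta <- predictors$column_meta
  n <- nrow(x)
  state <- list(continuous = list(), binary = list(), categorical = list())

  for (j in seq_len(ncol(x))) {
    kind <- meta$kind[j]
    if (kind == "categorical3") next  # handled per predictor below
    mis <- which(!predictors$observed[, j])
    if (length(mis) == 0) next
    col <- x[, j]
    col[mis] <- NA
    if (kind == "continuous") {
      pr <- continuous_imputation_prior(col)
      x[mis, j] <- pr$mean
      state$continuous[[length(state$continuous) + 1]] <-
        list(col = j, name = colnames(x)[j], prior_mean = pr$mean,
             sigma2 = max(stats::var(col[!is.na(col)]), 1e-6), missing = mis)
    } else {
      pr <- binary_imputation_prior(col)
      x[mis, j] <- rbinom(length(mis), 1, pr$nu_hat)
      state$binary[[length(state$binary) + 1]] <-
        list(col = j, name = colnames(x)[j], nu = pr$nu_hat, missing = mis)
    }
  }

  # race: empirical frequencies; missing race imputed as a categorical draw
  race_state <- NULL
  if (!is.null(predictors$race)) {
    race <- predictors$race
    freq <- prop.table(table(race))
    mis <- which(is.na(race))
    cur <- race
    if (length(mis) > 0) {
      cur[mis] <- sample(levels(race), length(mis), replace = TRUE,
                         prob = as.numeric(freq))
    }
    race_state <- list(levels = levels(race), probs = as.numeric(freq),
                       missing = mis, current = cur)
  }

  # 3-level categorical predictors (two dummy columns each)
  cat_preds <- unique(meta$predictor[meta$kind == "categorical3"])
  for (pred in cat_preds) {
    cols <- which(meta$predictor == pred)
    mis <- which(!predictors$observed[, cols[1]])
    if (length(mis) == 0) next
    sch <- predictors$schema[predictors$schema$column == pred, ]
    lv <- sch$levels[[1]]
    # current category per subject: 1 = reference, 2/3 from dummy columns
    cat_now <- 1L + 1L * (x[, cols[1]] == 1) + 2L * (x[, cols[2]] == 1)
    obs_cat <- cat_now[-mis]
    emp <- tabulate(obs_cat, 3) + 1
    draw <- sample.int(3, length(mis), replace = TRUE, prob = emp / sum(emp))
    cat_now[mis] <- draw
    x[mis, cols[1]] <- as.numeric(draw == 2)
    x[mis, cols[2]] <- as.numeric(draw == 3)
    n_racedum <- if (is.null(race_state)) 0L else length(race_state$levels) - 1L
    state$categorical[[length(state$categorical) + 1]] <-
      list(predictor = pred, cols = cols, levels = lv, missing = mis,
           category = cat_now,
           zeta0 = rep(0, 3),
           zeta1 = matrix(0, 3, n_racedum),
           sigma2_zeta = 1)
  }

  state$race <- race_state
  state$x <- x
  state
}

# Log-density of the imputation model pieces for a complete predictor matrix.
# Observed and imputed cells alike are treated as realizations of the column
# models, so the column hyperparameters are informed by the observed data.
imputation_logdensity <- function(predictors, x_complete, imp,
                                  hyper = hyperprior_config()) {
  if (is.null(imp)) return(0)
  ld <- 0
  for (cc in imp$continuous) {
    v <- x_complete[, cc$col]
    if (cc$sigma2 <= 0) return(-Inf)
    ld <- ld + sum(dnorm(v, cc$prior_mean, sqrt(cc$sigma2), log = TRUE)) +
      dgamma(cc$sigma2, 2, rate = 0.5, log = TRUE)
  }
  for (bb in imp$binary) {
    if (bb$nu <= 0 || bb$nu >= 1) return(-Inf)
    v <- x_complete[, bb$col]
    ld <- ld + sum(dbinom(v, 1, bb$nu, log = TRUE))  # Uniform(0,1) prior: log 1 = 0
  }
  for (ct in imp$categorical) {
    rd <- if (is.null(imp$race)) matrix(0, nrow(x_complete), 0) else race_dummies(imp$race$current)
    for (i in seq_len(nrow(x_complete))) {
      v <- categorical_probabilities(rd[i, ], ct$zeta0, ct$zeta1)
      ld <- ld + log(v[ct$category[i]])
    }
    if (ct$sigma2_zeta <= 0) return(-Inf)
    ld <- ld + sum(dnorm(c(ct$zeta0, ct$zeta1), 0, sqrt(ct$sigma2_zeta), log = TRUE)) +
      dgamma(ct$sigma2_zeta, hyper$zeta_var_shape, rate = hyper$zeta_var_rate,
             log = TRUE)
  }
  if (!is.null(imp$race) && length(imp$race$missing) > 0) {
    cur <- imp$race$current[imp$race$missing]
    ld <- ld + sum(log(imp$race$probs[match(cur, imp$race$levels)]))
  }
  ld
}
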