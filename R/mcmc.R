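# Metropolis-within-Gibbs sampler for the latent-logit model. Update blocks:
#   z      elliptical slice sampling per subject (compiled; exact, tuning-free)
#   b      conjugate scalar normal per subject
#   beta   joint conjugate Gaussian over the currently included coefficients
#          (the regression of the latent logits is linear-Gaussian given z);
#          excluded coefficients are refreshed from their N(0, sigma2_beta)
#          prior (Kuo-Mallick form of Gibbs variable selection)
#   I      discrete Gibbs scan (compiled)
#   psi    conjugate Beta(1/2 + I, 3/2 - I)
#   sigma2 slice sampling on the log scale (Gamma hyperpriors on variances
#          are not conjugate to the normal likelihood)
#   tau    slice sampling on the log scale under the half-Cauchy prior
#   Omega  random-walk Metropolis on each free correlation, rejecting
#          proposals outside the positive-definite set
#   missing predictors: conjugate/discrete Gibbs per cell (see imputation.R)

#' MCMC sampler settings
#'
#' Desk-scale defaults (4 chains of 1,000 warm-up + 1,000 kept draws) fit a
#' full model in minutes on one CPU. The much longer run lengths used for
#' publication-quality inference are available by raising `warmup`/`samples`.
#'
#' @param chains Number of chains (>= 2 recommended for diagnostics).
#' @param warmup Burn-in iterations discarded per chain.
#' @param samples Kept draws per chain.
#' @param thin Keep every `thin`-th post-warmup draw.
#' @param seed Integer seed; chain c uses `seed + c - 1`.
#' @param omega_step Random-walk standard deviation for correlation updates.
#' @param rhat_threshold Convergence flag threshold for the Gelman-Rubin
#'   statistic of continuous parameters.
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 4, warmup = 1000, samples = 1000, thin = 1,
                         seed = 1, omega_step = 0.2, rhat_threshold = 1.05) {
  stopifnot(chains >= 1, warmup >= 0, samples >= 1, thin >= 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 samples = as.integer(samples), thin = as.integer(thin),
                 seed = as.integer(seed), omega_step = omega_step,
                 rhat_threshold = rhat_threshold),
            class = "mcmc_control")
}

# --- internal helpers --------------------------------------------------------

clamp01 <- function(x, eps = 1e-12) pmin(pmax(x, eps), 1 - eps)

# univariate slice sampler (Neal 2003, stepping out + shrinkage)
slice_sample1 <- function(x0, logf, w = 1, m = 50) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started outside the support", call. = FALSE)
  logy <- f0 - stats::rexp(1)
  lo <- x0 - runif(1) * w
  hi <- lo + w
  j <- floor(runif(1) * m)
  k <- (m - 1) - j
  while (j > 0 && logf(lo) > logy) { lo <- lo - w; j <- j - 1 }
  while (k > 0 && logf(hi) > logy) { hi <- hi + w; k <- k - 1 }
  repeat {
    x1 <- runif(1, lo, hi)
    if (logf(x1) > logy) return(x1)
    if (x1 < x0) lo <- x1 else hi <- x1
    if (hi - lo < 1e-12) return(x0)
  }
}

# log-density of residual rows E ~ MVN(0, sigma), up to nothing (full constant)
resid_mvn_ll <- function(e, sigma) {
  ch <- tryCatch(chol(sigma), error = function(err) NULL)
  if (is.null(ch)) return(-Inf)
  u <- backsolve(ch, t(e), transpose = TRUE)
  -0.5 * (nrow(e) * (ncol(e) * log(2 * pi) + 2 * sum(log(diag(ch)))) + sum(u * u))
}

coerce_predictor_table <- function(predictors) {
  if (is.null(predictors)) return(NULL)
  if (inherits(predictors, "predictor_table")) return(predictors)
  x <- as.matrix(as.data.frame(predictors))
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  kinds <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    if (all(is.na(v) | v %in% c(0, 1))) "binary" else "continuous"
  }, character(1))
  schema <- predictor_schema(colnames(x), kinds)
  predictor_table(as.data.frame(x), schema)
}

subset_predictor_table <- function(pt, columns) {
  idx <- match(columns, colnames(pt$x))
  if (anyNA(idx)) {
    stop("unknown predictor column(s): ",
         paste(columns[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  meta <- pt$column_meta[idx, , drop = FALSE]
  keep_preds <- unique(meta$predictor)
  structure(
    list(x = pt$x[, idx, drop = FALSE],
         observed = pt$observed[, idx, drop = FALSE],
         column_meta = meta,
         schema = pt$schema[pt$schema$column %in% keep_preds, , drop = FALSE],
         race = pt$race),
    class = "predictor_table"
  )
}

# registry of stored parameters, in flattening order
build_param_info <- function(pred_names, labels, n, gvs, include_b, imp) {
  d <- length(labels)
  rows <- list()
  add <- function(type, name, predictor = NA, component = NA) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      type = type, name = name, predictor = predictor, component = component)
  }
  coef_rows <- c("(Intercept)", pred_names)
  for (j in seq_len(d)) for (p in coef_rows) {
    add("beta", sprintf("beta[%s,%s]", p, labels[j]), p, labels[j])
  }
  if (gvs) {
    for (j in seq_len(d)) for (p in coef_rows) {
      add("xi", sprintf("xi[%s,%s]", p, labels[j]), p, labels[j])
    }
    for (j in seq_len(d)) for (p in pred_names) {
      add("I", sprintf("I[%s,%s]", p, labels[j]), p, labels[j])
    }
    for (j in seq_len(d)) for (p in pred_names) {
      add("psi", sprintf("psi[%s,%s]", p, labels[j]), p, labels[j])
    }
  }
  for (j in seq_len(d)) add("tau", sprintf("tau[%s]", labels[j]), NA, labels[j])
  if (d > 1) {
    for (k in 2:d) for (j in seq_len(k - 1)) {
      add("omega", sprintf("Omega[%s,%s]", labels[k], labels[j]),
          labels[k], labels[j])
    }
  }
  add("sigma2", "sigma2_beta")
  if (include_b) {
    add("sigma2", "sigma2_b")
    for (i in seq_len(n)) add("b", sprintf("b[%d]", i))
  }
  if (!is.null(imp)) {
    for (cc in imp$continuous) {
      add("sigma2", sprintf("sigma2_col[%s]", cc$name))
      for (i in cc$missing) add("imputed", sprintf("imp[%s,%d]", cc$name, i), cc$name)
    }
    for (bb in imp$binary) {
      add("nu", sprintf("nu[%s]", bb$name))
      for (i in bb$missing) add("imputed", sprintf("imp[%s,%d]", bb$name, i), bb$name)
    }
    for (ct in imp$categorical) {
      for (c3 in 1:3) add("zeta", sprintf("zeta0[%s,%d]", ct$predictor, c3))
      if (length(ct$zeta1) > 0) {
        for (kk in seq_len(ncol(ct$zeta1))) for (c3 in 1:3) {
          add("zeta", sprintf("zeta1[%s,%d,%d]", ct$predictor, c3, kk))
        }
      }
      add("sigma2", sprintf("sigma2_zeta[%s]", ct$predictor))
      for (i in ct$missing) add("imputed", sprintf("imp[%s,%d]", ct$predictor, i),
                                ct$predictor)
    }
  }
  dplyr::bind_rows(rows)
}

flatten_state <- function(st, gvs, include_b, labels) {
  d <- length(labels)
  out <- as.numeric(st$beta)
  if (gvs) {
    xi <- effective_coefficients(st$beta, st$I)
    out <- c(out, as.numeric(xi), as.numeric(st$I), as.numeric(st$psi))
  }
  out <- c(out, st$tau)
  if (d > 1) {
    for (k in 2:d) for (j in seq_len(k - 1)) out <- c(out, st$omega[k, j])
  }
  out <- c(out, st$sigma2_beta)
  if (include_b) out <- c(out, st$sigma2_b, st$b)
  imp <- st$imp
  if (!is.null(imp)) {
    for (cc in imp$continuous) out <- c(out, cc$sigma2, imp$x[cc$missing, cc$col])
    for (bb in imp$binary) out <- c(out, bb$nu, imp$x[bb$missing, bb$col])
    for (ct in imp$categorical) {
      out <- c(out, ct$zeta0, as.numeric(ct$zeta1), ct$sigma2_zeta,
               ct$category[ct$missing])
    }
  }
  out
}

# --- the sampler -------------------------------------------------------------

init_state <- function(dat, gvs, include_b) {
  n <- dat$n; d <- dat$d; p1 <- dat$p1
  z <- matrix(0, n, d)
  z[dat$obs] <- qlogis((dat$y[dat$obs] + 0.5) / 2)
  omega <- diag(d)
  tau <- rep(1, d)
  list(
    z = z,
    beta = matrix(0, p1, d),
    I = if (gvs) matrix(1L, p1 - 1, d) else NULL,
    psi = if (gvs) matrix(0.5, p1 - 1, d) else NULL,
    b = if (include_b) rep(0, n) else NULL,
    sigma2_b = 1, sigma2_beta = 4,
    tau = tau, omega = omega,
    sigma = diag(tau^2, d), prec = diag(1 / tau^2, d),
    imp = dat$imp_template
  )
}

current_design <- function(dat, st) {
  if (!is.null(st$imp)) cbind(`(Intercept)` = 1, st$imp$x) else dat$x1
}

gibbs_sweep <- function(st, dat, cfg, hyper, gvs, include_b) {
  n <- dat$n; d <- dat$d; p1 <- dat$p1
  x1 <- current_design(dat, st)
  xi <- if (gvs) effective_coefficients(st$beta, st$I) else st$beta
  m <- x1 %*% xi
  b <- if (include_b) st$b else rep(0, n)

  # latent logits (two sweeps: cheap, and z feeds every other block)
  lchol <- t(chol(st$sigma))
  st$z <- .ess_update_z(st$z, m + b, lchol, dat$y0, dat$obs_u)
  st$z <- .ess_update_z(st$z, m + b, lchol, dat$y0, dat$obs_u)

  # subject random effect and its variance
  if (include_b) {
    psum <- sum(st$prec)
    prec_b <- psum + 1 / st$sigma2_b
    mean_b <- rowSums((st$z - m) %*% st$prec) / prec_b
    st$b <- rnorm(n, mean_b, sqrt(1 / prec_b))
    b <- st$b
    bb <- st$b
    st$sigma2_b <- exp(slice_sample1(log(st$sigma2_b), function(ls) {
      s2 <- exp(ls)
      sum(dnorm(bb, 0, sqrt(s2), log = TRUE)) +
        dgamma(s2, hyper$b_var_shape, rate = hyper$b_var_rate, log = TRUE) + ls
    }))
  }

  # coefficients: joint conjugate Gaussian over included entries
  r <- st$z - b
  xtx <- crossprod(x1)
  rhs <- crossprod(x1, r %*% st$prec)          # p1 x d
  a_full <- kronecker(st$prec, xtx)            # index (j-1)*p1 + p
  inc <- matrix(TRUE, p1, d)
  if (gvs) inc[-1, ] <- st$I == 1
  idx <- which(as.logical(inc))
  a <- a_full[idx, idx, drop = FALSE]
  diag(a) <- diag(a) + 1 / st$sigma2_beta
  ch <- chol(a)
  mu_inc <- backsolve(ch, backsolve(ch, as.numeric(rhs)[idx], transpose = TRUE))
  draw <- mu_inc + backsolve(ch, rnorm(length(idx)))
  beta <- matrix(rnorm(p1 * d, 0, sqrt(st$sigma2_beta)), p1, d) # excluded: prior
  beta[idx] <- draw
  st$beta <- beta

  # indicators and inclusion probabilities
  if (gvs) {
    xi <- effective_coefficients(st$beta, st$I)
    m <- x1 %*% xi
    upd <- .gibbs_indicators(r, m, x1, st$beta, st$I, st$psi, st$prec,
                             st$sigma2_beta)
    st$I <- upd$I
    st$beta <- upd$beta
    m <- upd$M
    st$psi <- matrix(clamp01(rbeta(length(st$I), 0.5 + st$I, 1.5 - st$I)),
                     nrow(st$I), d)
  } else {
    m <- x1 %*% st$beta
  }

  # coefficient variance
  bvec <- as.numeric(st$beta)
  st$sigma2_beta <- exp(slice_sample1(log(st$sigma2_beta), function(ls) {
    s2 <- exp(ls)
    sum(dnorm(bvec, 0, sqrt(s2), log = TRUE)) +
      dgamma(s2, hyper$beta_var_shape, rate = hyper$beta_var_rate, log = TRUE) + ls
  }))

  # covariance: scales then correlations
  e <- st$z - b - m
  for (j in seq_len(d)) {
    tau_j <- st$tau
    omega <- st$omega
    st$tau[j] <- exp(slice_sample1(log(st$tau[j]), function(lt) {
      tau_j[j] <- exp(lt)
      resid_mvn_ll(e, diag(tau_j, d) %*% omega %*% diag(tau_j, d)) +
        half_cauchy_density(tau_j[j], hyper$tau_scale, log = TRUE) + lt
    }, w = 0.5))
  }
  if (d > 1) {
    sig <- assemble_covariance(st$tau, st$omega)
    ll_cur <- resid_mvn_ll(e, sig) + lkj_logdensity(st$omega, hyper$eta)
    for (k in 2:d) for (j in seq_len(k - 1)) {
      om_new <- st$omega
      rprop <- st$omega[k, j] + rnorm(1, 0, cfg$omega_step)
      if (abs(rprop) >= 1) next
      om_new[k, j] <- om_new[j, k] <- rprop
      lkj_new <- lkj_logdensity(om_new, hyper$eta)
      if (!is.finite(lkj_new)) next
      ll_new <- resid_mvn_ll(e, assemble_covariance(st$tau, om_new)) + lkj_new
      if (log(runif(1)) < ll_new - ll_cur) {
        st$omega <- om_new
        ll_cur <- ll_new
      }
    }
  }
  # interweaved joint rescaling of (z residuals, tau) per component: the
  # latent scale is only weakly identified through the Bernoulli likelihood
  # and mixes slowly under conditional updates alone. Rescaling the
  # component's residuals together with tau leaves the standardized MVN
  # residuals invariant, so the move is accepted on the Bernoulli
  # log-likelihood change plus the half-Cauchy prior ratio and the log-s
  # Jacobian remainder.
  mu_full <- m + b
  for (j in seq_len(d)) {
    s_fac <- exp(rnorm(1, 0, 0.2))
    zj_new <- mu_full[, j] + s_fac * (st$z[, j] - mu_full[, j])
    oj <- dat$obs[, j]
    dbern <- sum(dat$y0[oj, j] * zj_new[oj] - log1pexp(zj_new[oj])) -
      sum(dat$y0[oj, j] * st$z[oj, j] - log1pexp(st$z[oj, j]))
    dprior <- half_cauchy_density(s_fac * st$tau[j], hyper$tau_scale, log = TRUE) -
      half_cauchy_density(st$tau[j], hyper$tau_scale, log = TRUE)
    if (log(runif(1)) < dbern + dprior + log(s_fac)) {
      st$z[, j] <- zj_new
      st$tau[j] <- s_fac * st$tau[j]
    }
  }
  st$sigma <- assemble_covariance(st$tau, st$omega)
  st$prec <- chol2inv(chol(st$sigma))

  # missing-predictor updates
  if (!is.null(st$imp)) {
    st$imp <- update_imputation(st, dat, hyper, gvs)
  }
  st
}

update_imputation <- function(st, dat, hyper, gvs) {
  imp <- st$imp
  d <- dat$d
  xi <- if (gvs) effective_coefficients(st$beta, st$I) else st$beta
  b <- if (is.null(st$b)) rep(0, dat$n) else st$b
  r <- st$z - b
  x1 <- cbind(1, imp$x)
  m <- x1 %*% xi
  prec <- st$prec

  refresh_row <- function(i) m[i, ] <<- drop(crossprod(xi, c(1, imp$x[i, ])))

  for (ci in seq_along(imp$continuous)) {
    cc <- imp$continuous[[ci]]
    w <- xi[cc$col + 1, ]
    wpw <- drop(t(w) %*% prec %*% w)
    for (i in cc$missing) {
      m0 <- m[i, ] - imp$x[i, cc$col] * w
      prec_x <- wpw + 1 / cc$sigma2
      mean_x <- (drop(t(w) %*% prec %*% (r[i, ] - m0)) + cc$prior_mean / cc$sigma2) / prec_x
      imp$x[i, cc$col] <- rnorm(1, mean_x, sqrt(1 / prec_x))
      m[i, ] <- m0 + imp$x[i, cc$col] * w
    }
    v <- imp$x[, cc$col]
    pm <- cc$prior_mean
    imp$continuous[[ci]]$sigma2 <- exp(slice_sample1(log(cc$sigma2), function(ls) {
      s2 <- exp(ls)
      sum(dnorm(v, pm, sqrt(s2), log = TRUE)) +
        dgamma(s2, 2, rate = 0.5, log = TRUE) + ls
    }))
  }

  for (bi in seq_along(imp$binary)) {
    bb <- imp$binary[[bi]]
    w <- xi[bb$col + 1, ]
    for (i in bb$missing) {
      m0 <- m[i, ] - imp$x[i, bb$col] * w
      ll <- vapply(c(0, 1), function(v) {
        mm <- m0 + v * w
        -0.5 * drop(t(r[i, ] - mm) %*% prec %*% (r[i, ] - mm)) +
          v * log(bb$nu) + (1 - v) * log(1 - bb$nu)
      }, numeric(1))
      pr <- 1 / (1 + exp(ll[1] - ll[2]))
      imp$x[i, bb$col] <- rbinom(1, 1, pr)
      m[i, ] <- m0 + imp$x[i, bb$col] * w
    }
    s <- sum(imp$x[, bb$col])
    imp$binary[[bi]]$nu <- clamp01(rbeta(1, 1 + s, 1 + dat$n - s))
  }

  rd <- if (is.null(imp$race)) matrix(0, dat$n, 0) else race_dummies(imp$race$current)
  for (ki in seq_along(imp$categorical)) {
    ct <- imp$categorical[[ki]]
    w1 <- xi[ct$cols[1] + 1, ]
    w2 <- xi[ct$cols[2] + 1, ]
    dummy <- rbind(c(0, 0), c(1, 0), c(0, 1))
    for (i in ct$missing) {
      v_prior <- categorical_probabilities(rd[i, ], ct$zeta0, ct$zeta1)
      m0 <- m[i, ] - imp$x[i, ct$cols[1]] * w1 - imp$x[i, ct$cols[2]] * w2
      ll <- vapply(1:3, function(cat3) {
        mm <- m0 + dummy[cat3, 1] * w1 + dummy[cat3, 2] * w2
        -0.5 * drop(t(r[i, ] - mm) %*% prec %*% (r[i, ] - mm)) + log(v_prior[cat3])
      }, numeric(1))
      pr <- exp(ll - max(ll)); pr <- pr / sum(pr)
      cat3 <- sample.int(3, 1, prob = pr)
      ct$category[i] <- cat3
      imp$x[i, ct$cols[1]] <- dummy[cat3, 1]
      imp$x[i, ct$cols[2]] <- dummy[cat3, 2]
      m[i, ] <- m0 + dummy[cat3, 1] * w1 + dummy[cat3, 2] * w2
    }
    # multinomial-logit coefficients: random-walk Metropolis per element
    cat_ll <- function(zeta0, zeta1) {
      s <- 0
      for (i in seq_len(dat$n)) {
        v <- categorical_probabilities(rd[i, ], zeta0, zeta1)
        s <- s + log(v[ct$category[i]])
      }
      s
    }
    ll_cur <- cat_ll(ct$zeta0, ct$zeta1)
    for (c3 in 1:3) {
      prop <- ct$zeta0; prop[c3] <- prop[c3] + rnorm(1, 0, 0.4)
      ll_new <- cat_ll(prop, ct$zeta1)
      dpr <- dnorm(prop[c3], 0, sqrt(ct$sigma2_zeta), log = TRUE) -
        dnorm(ct$zeta0[c3], 0, sqrt(ct$sigma2_zeta), log = TRUE)
      if (log(runif(1)) < ll_new - ll_cur + dpr) { ct$zeta0 <- prop; ll_cur <- ll_new }
    }
    if (length(ct$zeta1) > 0) {
      for (kk in seq_len(ncol(ct$zeta1))) for (c3 in 1:3) {
        prop <- ct$zeta1; prop[c3, kk] <- prop[c3, kk] + rnorm(1, 0, 0.4)
        ll_new <- cat_ll(ct$zeta0, prop)
        dpr <- dnorm(prop[c3, kk], 0, sqrt(ct$sigma2_zeta), log = TRUE) -
          dnorm(ct$zeta1[c3, kk], 0, sqrt(ct$sigma2_zeta), log = TRUE)
        if (log(runif(1)) < ll_new - ll_cur + dpr) { ct$zeta1 <- prop; ll_cur <- ll_new }
      }
    }
    zvec <- c(ct$zeta0, as.numeric(ct$zeta1))
    ct$sigma2_zeta <- exp(slice_sample1(log(ct$sigma2_zeta), function(ls) {
      s2 <- exp(ls)
      sum(dnorm(zvec, 0, sqrt(s2), log = TRUE)) +
        dgamma(s2, hyper$zeta_var_shape, rate = hyper$zeta_var_rate, log = TRUE) + ls
    }))
    imp$categorical[[ki]] <- ct
  }

  # missing maternal race: discrete Gibbs against empirical prior and the
  # genotype regression likelihood
  if (!is.null(imp$race) && length(imp$race$missing) > 0) {
    lv <- imp$race$levels
    for (i in imp$race$missing) {
      ll <- log(imp$race$probs)
      for (l in seq_along(lv)) {
        rd_l <- race_dummies(factor(lv[l], levels = lv))[1, ]
        for (ct in imp$categorical) {
          v <- categorical_probabilities(rd_l, ct$zeta0, ct$zeta1)
          ll[l] <- ll[l] + log(v[ct$category[i]])
        }
      }
      pr <- exp(ll - max(ll)); pr <- pr / sum(pr)
      imp$race$current[i] <- lv[sample.int(length(lv), 1, prob = pr)]
    }
  }
  imp
}

run_one_chain <- function(dat, cfg, hyper, seed, gvs, include_b, info) {
  set.seed(seed)
  dat$imp_template <- if (dat$has_missing) build_imputation_state(dat$predictors) else NULL
  st <- init_state(dat, gvs, include_b)
  total <- cfg$warmup + cfg$samples * cfg$thin
  out <- matrix(NA_real_, cfg$samples, nrow(info))
  colnames(out) <- info$name
  row <- 0L
  for (t in seq_len(total)) {
    st <- gibbs_sweep(st, dat, cfg, hyper, gvs, include_b)
    if (any(!is.finite(st$z))) {
      stop("sampler produced a non-finite latent state at iteration ", t,
           call. = FALSE)
    }
    if (t > cfg$warmup && (t - cfg$warmup) %% cfg$thin == 0) {
      row <- row + 1L
      out[row, ] <- flatten_state(st, gvs, include_b, dat$labels)
    }
  }
  out
}

#' Fit the Bayesian defect model by MCMC
#'
#' Fits the latent multivariate-logit model: each subject's vector of
#' log-odds across outcome components is multivariate normal around a linear
#' predictor (with an optional shared subject random effect), the covariance
#' separates into half-Cauchy scales and an LKJ-distributed correlation
#' matrix, coefficients carry normal priors with a Gamma(2, 0.5) variance
#' hyperprior, and (optionally) Gibbs variable selection masks each
#' non-intercept coefficient with a Bernoulli(psi) indicator,
#' psi ~ Beta(1/2, 1/2). Missing predictor cells are imputed as parameters
#' within the chain. Runs are reproducible given `control$seed`.
#'
#' @param panel A [defect_panel()] (masked outcome cells are skipped by the
#'   likelihood).
#' @param predictors A [predictor_table()], a plain data frame / matrix of
#'   numeric predictors, or `NULL` for an intercept-only model.
#' @param gvs Run Gibbs variable selection? Default `TRUE`.
#' @param include_random_effect Include the shared subject-level random
#'   effect? Default `TRUE`.
#' @param hyper A [hyperprior_config()].
#' @param control An [mcmc_control()].
#' @return An object of class `defect_fit` carrying the per-chain draw
#'   matrices, the parameter registry, Gelman-Rubin diagnostics, and the
#'   data/configuration needed by the summary functions.
#' @export
fit_defect_model <- function(panel, predictors = NULL, gvs = TRUE,
                             include_random_effect = TRUE,
                             hyper = hyperprior_config(),
                             control = mcmc_control()) {
  stopifnot(inherits(panel, "defect_panel"), inherits(control, "mcmc_control"))
  pt <- coerce_predictor_table(predictors)
  n <- nrow(panel$y); d <- ncol(panel$y)
  if (!is.null(pt) && nrow(pt$x) != n) {
    stop("predictor table and panel disagree on the number of subjects",
         call. = FALSE)
  }
  has_missing <- !is.null(pt) &&
    (!all(pt$observed) || (!is.null(pt$race) && anyNA(pt$race)))
  x_static <- if (is.null(pt)) NULL else pt$x
  if (gvs && is.null(pt)) gvs <- FALSE
  y0 <- panel$y
  y0[!panel$observed] <- 0
  dat <- list(
    y = panel$y, y0 = y0, obs = panel$observed,
    obs_u = matrix(as.integer(panel$observed), n, d),
    n = n, d = d, labels = panel$labels,
    p1 = 1L + if (is.null(pt)) 0L else ncol(pt$x),
    x1 = if (is.null(x_static)) {
      matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    } else {
      cbind(`(Intercept)` = 1, x_static)
    },
    predictors = pt, has_missing = has_missing
  )
  if (has_missing) {
    # template only used for the registry; each chain rebuilds its own state
    set.seed(control$seed)
    imp0 <- build_imputation_state(pt)
  } else imp0 <- NULL
  pred_names <- if (is.null(pt)) character(0) else colnames(pt$x)
  info <- build_param_info(pred_names, panel$labels, n, gvs,
                           include_random_effect, imp0)
  t0 <- Sys.time()
  chains <- lapply(seq_len(control$chains), function(ch) {
    run_one_chain(dat, control, hyper, control$seed + ch - 1L, gvs,
                  include_random_effect, info)
  })
  runtime <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  fit <- structure(
    list(chains = chains, param_info = info, panel = panel, predictors = pt,
         gvs = gvs, include_random_effect = include_random_effect,
         hyper = hyper, control = control, runtime = runtime),
    class = "defect_fit"
  )
  diag_tbl <- gelman_rubin(fit)
  cont <- diag_tbl$type %in% c("beta", "xi", "tau", "omega", "sigma2", "psi")
  worst <- suppressWarnings(max(diag_tbl$rhat[cont], na.rm = TRUE))
  converged <- is.finite(worst) && worst < control$rhat_threshold
  if (!converged) {
    warning(sprintf(paste("Gelman-Rubin diagnostic above %.2f (max %.3f);",
                          "treat results as non-converged"),
                    control$rhat_threshold, worst), call. = FALSE)
  }
  fit$diagnostics <- diag_tbl
  fit$convergence <- list(converged = converged, max_rhat = worst,
                          threshold = control$rhat_threshold)
  fit
}

#' @export
print.defect_fit <- function(x, ...) {
  cat(sprintf("<defect_fit> %d subjects x %d components (%s axis)\n",
              nrow(x$panel$y), ncol(x$panel$y), x$panel$axis_kind))
  cat(sprintf("  %d chains x %d draws (warmup %d)%s, %.1fs\n",
              x$control$chains, x$control$samples, x$control$warmup,
              if (x$gvs) ", GVS on" else "", x$runtime))
  cat(sprintf("  max split R-hat (continuous): %.3f (%s)\n",
              x$convergence$max_rhat,
              if (x$convergence$converged) "converged" else "NOT converged"))
  invisible(x)
}

# pooled draw matrix across chains
pooled_draws <- function(fit) do.call(rbind, fit$chains)

#' Gelman-Rubin potential scale reduction factor
#'
#' Split-chain R-hat for every stored parameter: each chain is halved, and
#' the PSRF compares between- to within-half variance. Values near 1 indicate
#' agreement. A single chain triggers a warning and is assessed through its
#' two halves. Zero-variance parameters (e.g. an indicator that never flips)
#' are reported as `rhat = 1` with a `"degenerate"` note.
#'
#' @param fit A `defect_fit`, or a list of draw matrices with identical
#'   columns (iterations x parameters).
#' @return A tibble with `parameter`, `type` (when known), `rhat`, `note`.
#' @export
gelman_rubin <- function(fit) {
  if (inherits(fit, "defect_fit")) {
    chains <- fit$chains
    types <- fit$param_info$type
  } else {
    chains <- fit
    types <- rep(NA_character_, ncol(chains[[1]]))
  }
  stopifnot(length(chains) >= 1)
  if (length(chains) == 1) {
    warning("only one chain: using split halves for the diagnostic",
            call. = FALSE)
  }
  len <- unique(vapply(chains, nrow, integer(1)))
  if (length(len) != 1) stop("chains must have equal length", call. = FALSE)
  half <- floor(len / 2)
  splits <- list()
  for (ch in chains) {
    splits[[length(splits) + 1]] <- ch[seq_len(half), , drop = FALSE]
    splits[[length(splits) + 1]] <- ch[(len - half + 1):len, , drop = FALSE]
  }
  m <- length(splits)
  nn <- half
  pars <- colnames(chains[[1]])
  rhat <- numeric(length(pars))
  note <- character(length(pars))
  means <- sapply(splits, colMeans)
  vars <- sapply(splits, function(s) apply(s, 2, stats::var))
  if (length(pars) == 1) { means <- matrix(means, 1); vars <- matrix(vars, 1) }
  for (j in seq_along(pars)) {
    w <- mean(vars[j, ])
    bn <- stats::var(means[j, ]) # B / n
    if (!is.finite(w) || w < .Machine$double.eps) {
      rhat[j] <- 1
      note[j] <- "degenerate (zero within-chain variance)"
    } else {
      vplus <- (nn - 1) / nn * w + bn
      rhat[j] <- sqrt(vplus / w)
      note[j] <- ""
    }
  }
  tibble::tibble(parameter = pars, type = types, rhat = rhat, note = note)
}

#' Posterior summary table
#'
#' Posterior mean, SD and equal-tailed 95% credible interval from the pooled
#' post-warmup draws. For coefficients an odds-scale convention is available:
#' the mean and interval endpoints are exponentiated log-odds summaries and
#' the dispersion is the geometric SD `exp(sd(log-odds))`, matching how
#' odds-scale tables pair e.g. 0.78 (1.11) with an interval (0.63, 0.95).
#'
#' @param fit A `defect_fit`.
#' @param type Which block to summarize: `"coefficients"` (effective
#'   coefficients xi when GVS is on, beta otherwise), `"beta"`, `"inclusion"`
#'   (psi), `"tau"`, `"omega"`, `"variances"`, `"random_effects"`,
#'   `"imputed"`.
#' @param odds_scale Exponentiate coefficient summaries? Only valid for
#'   coefficient blocks.
#' @return A tibble with `parameter`, `predictor`, `component`, `mean`, `sd`,
#'   `conf.low`, `conf.high`, `rhat`.
#' @export
summarize_fit <- function(fit, type = c("coefficients", "beta", "inclusion",
                                        "tau", "omega", "variances",
                                        "random_effects", "imputed"),
                          odds_scale = FALSE) {
  stopifnot(inherits(fit, "defect_fit"))
  type <- match.arg(type)
  tt <- switch(type,
    coefficients = if (fit$gvs) "xi" else "beta",
    beta = "beta", inclusion = "psi", tau = "tau", omega = "omega",
    variances = "sigma2", random_effects = "b", imputed = "imputed")
  if (odds_scale && !tt %in% c("xi", "beta")) {
    stop("odds_scale applies to coefficient summaries only", call. = FALSE)
  }
  keep <- which(fit$param_info$type == tt)
  if (length(keep) == 0) {
    stop("fit stores no parameters of type '", type, "'", call. = FALSE)
  }
  draws <- pooled_draws(fit)[, keep, drop = FALSE]
  info <- fit$param_info[keep, ]
  rh <- fit$diagnostics$rhat[keep]
  mu <- unname(colMeans(draws))
  sdv <- unname(apply(draws, 2, sd))
  lo <- unname(apply(draws, 2, quantile, 0.025, names = FALSE))
  hi <- unname(apply(draws, 2, quantile, 0.975, names = FALSE))
  out <- tibble::tibble(parameter = info$name, predictor = info$predictor,
                        component = info$component,
                        mean = mu, sd = sdv, conf.low = lo, conf.high = hi,
                        rhat = rh)
  if (odds_scale) {
    out$conf.low <- exp(lo)
    out$conf.high <- exp(hi)
    out$sd <- exp(sdv)        # geometric SD
    out$mean <- exp(mu)
  }
  out
}

#' @export
summary.defect_fit <- function(object, ...) summarize_fit(object, ...)

#' Posterior inclusion probabilities of a fitted model
#'
#' Pooled posterior means of the GVS indicators, per predictor and component.
#'
#' @param fit A `defect_fit` run with `gvs = TRUE`.
#' @return A tibble with `predictor`, `component`, `psi`.
#' @export
inclusion_probabilities <- function(fit) {
  stopifnot(inherits(fit, "defect_fit"))
  if (!fit$gvs) stop("model was fitted without Gibbs variable selection",
                     call. = FALSE)
  keep <- which(fit$param_info$type == "I")
  draws <- pooled_draws(fit)[, keep, drop = FALSE]
  info <- fit$param_info[keep, ]
  tibble::tibble(predictor = info$predictor, component = info$component,
                 psi = unname(colMeans(draws)))
}

#' Posterior correlation summary
#'
#' Two reporting conventions for the latent correlation matrix. With
#' `"full_matrix"` each entry of Omega is summarized elementwise (unit
#' diagonal). With `"cholesky_columns"` each posterior draw of Omega is
#' decomposed into its lower Cholesky factor and the factor is summarized
#' elementwise: the first column equals the correlations with the first
#' component, the upper triangle is identically zero, and the diagonal
#' entries fall below one as correlation accumulates — the layout used by
#' lower-triangular correlation tables whose diagonals "degrade".
#'
#' @param fit A `defect_fit` with more than one outcome component, or a
#'   plain list of correlation-matrix draws.
#' @param convention `"cholesky_columns"` (default) or `"full_matrix"`.
#' @param labels Component labels when `fit` is a list of matrices.
#' @return A tibble with `row`, `col` (component labels), `mean`,
#'   `conf.low`, `conf.high`.
#' @export
correlation_summary <- function(fit, convention = c("cholesky_columns",
                                                    "full_matrix"),
                                labels = NULL) {
  convention <- match.arg(convention)
  if (inherits(fit, "defect_fit")) {
    d <- ncol(fit$panel$y)
    if (d < 2) stop("correlation summary needs at least two components",
                    call. = FALSE)
    labels <- fit$panel$labels
    keep <- which(fit$param_info$type == "omega")
    draws <- pooled_draws(fit)[, keep, drop = FALSE]
    omegas <- lapply(seq_len(nrow(draws)), function(t) {
      om <- diag(d)
      idx <- 0
      for (k in 2:d) for (j in seq_len(k - 1)) {
        idx <- idx + 1
        om[k, j] <- om[j, k] <- draws[t, idx]
      }
      om
    })
  } else {
    omegas <- fit
    stopifnot(is.list(omegas), length(omegas) >= 1)
    d <- nrow(omegas[[1]])
    if (is.null(labels)) labels <- paste0("c", seq_len(d))
  }
  ndraw <- length(omegas)
  vals <- array(0, dim = c(ndraw, d, d))
  for (t in seq_len(ndraw)) {
    om <- omegas[[t]]
    vals[t, , ] <- if (convention == "full_matrix") om else {
      ch <- tryCatch(t(chol(om)), error = function(e) NULL)
      if (is.null(ch)) t(chol(om + diag(1e-9, d))) else ch
    }
  }
  rows <- list()
  for (k in seq_len(d)) for (j in seq_len(d)) {
    v <- vals[, k, j]
    rows[[length(rows) + 1]] <- tibble::tibble(
      row = labels[k], col = labels[j],
      mean = mean(v),
      conf.low = quantile(v, 0.025, names = FALSE),
      conf.high = quantile(v, 0.975, names = FALSE))
  }
  dplyr::bind_rows(rows)
}

#' Refit the reduced model implied by a GVS fit
#'
#' Selects the predictors whose posterior inclusion probability exceeds the
#' threshold in at least one component, then refits with exactly those
#' predictors in every component and GVS disabled.
#'
#' @param fit A `defect_fit` run with `gvs = TRUE`.
#' @param threshold Strict inclusion threshold, default 0.6.
#' @param control An [mcmc_control()] for the refit (defaults to the one used
#'   for `fit`).
#' @return A `defect_fit` of the reduced model. With an empty selection an
#'   intercept-only model is fitted, with a warning.
#' @export
fit_reduced_model <- function(fit, threshold = 0.6, control = fit$control) {
  sel <- select_predictors(inclusion_probabilities(fit), threshold)
  spec <- build_reduced_spec(sel, ncol(fit$panel$y))
  pt <- if (length(spec$predictors) == 0) NULL else
    subset_predictor_table(fit$predictors, spec$predictors)
  out <- fit_defect_model(fit$panel, pt, gvs = FALSE,
                          include_random_effect = fit$include_random_effect,
                          hyper = fit$hyper, control = control)
  out$selection <- sel
  out
}
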