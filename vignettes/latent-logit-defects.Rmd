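---
title: "Bayesian latent-logit models for multivariate dental defects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian latent-logit models for multivariate dental defects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Developmental enamel defects of the primary maxillary central incisors —
enamel hypoplasia (EH), opacity (OP), post-eruptive breakdown (PEB) — and
dental caries (DC) are scored as binary presence/absence outcomes, either
for one defect across the three horizontal tooth regions (cervical, middle,
incisal) or for all four defects jointly within one region. The regions
calcify sequentially from roughly the 14th gestational week to shortly
after birth, so maternal and child exposures timed across pregnancy
(serum calcium, phosphorus, vitamin-D metabolites, the functional
vitamin-D-deficiency ratio FVDD = 25OHD/PTH, genotype of the vitamin-D
binding protein, and others) may associate with defects region by region.
The statistical problem is threefold: correlated binary outcomes, many
candidate predictors, and missing predictor values.

## The model

For subject $i$ let $y_{ij} \in \{0,1\}$ be the outcome in component
$j = 1,\dots,d$ (regions, $d=3$, or defects, $d=4$). The package fits

$$
y_{ij} \sim \mathrm{Bernoulli}(\pi_{ij}), \qquad
\mathbf{z}_i = \mathrm{logit}(\boldsymbol\pi_i) \sim
\mathrm{MVN}(\boldsymbol\mu_i, \Sigma), \qquad
\boldsymbol\mu_i = \boldsymbol\beta^\mathsf{T}\mathbf{x}_i + b_i \mathbf{1},
$$

with $\mathbf{x}_i = (1, x_{i1}, \dots, x_{ip})^\mathsf{T}$ and
$\boldsymbol\beta$ a $(p+1)\times d$ matrix of fixed effects on the
log-odds scale. The latent covariance separates into scales and a
correlation matrix,

$$
\Sigma = \mathrm{diag}(\boldsymbol\tau)\,\Omega\,\mathrm{diag}(\boldsymbol\tau),
\qquad \tau_j \sim \mathrm{half\text{-}Cauchy}(0, 2.5),
\qquad \Omega \sim \mathrm{LKJ}(\eta),
$$

with $\eta = 1$ by default (uniform over valid correlation matrices; a
Wishart-family prior is deliberately avoided because it ties variances to
correlations and is rigid at small variances). Coefficients and the shared
subject effect have normal priors with Gamma hyperpriors **on the
variances**: $\beta_{pj} \sim N(0, \sigma^2_\beta)$,
$b_i \sim N(0, \sigma^2_b)$, and
$\sigma^2_\beta, \sigma^2_b \sim \mathrm{Gamma}(\text{shape }2,
\text{rate } 0.5)$ (mean 4). We read the Gamma under the shape–rate
(BUGS-style) convention, and the Cauchy scale prior as its positive half.
Masked outcome cells simply drop out of the Bernoulli likelihood, so
partially observed subjects remain in the model; this subsumes both a
complete-case and an at-least-one-outcome inclusion rule, and
`drop_unobserved()` exposes row-dropping for users who want it.

The random effect $b_i$ is a single scalar added to every component of
$\boldsymbol\mu_i$. With a free $\Sigma$ this direction is partially
confounded with compound-symmetric correlation, which is why
`include_random_effect = FALSE` exists and is the default in the
simulation-study driver (the generating tables have no random-effect
variance; see Design choices).

### Variable selection

Gibbs variable selection masks every non-intercept coefficient with a
binary indicator, $\xi_{pj} = \beta_{pj} I_{pj}$,
$I_{pj} \sim \mathrm{Bernoulli}(\psi_{pj})$,
$\psi_{pj} \sim \mathrm{Beta}(\tfrac12, \tfrac12)$. The posterior mean of
$I_{pj}$ is the posterior probability of inclusion; a predictor whose
inclusion probability strictly exceeds 0.6 in at least one component
enters the reduced model in **all** components (`select_predictors()`,
`fit_reduced_model()`). The strict 0.6 cut, rather than the conventional
0.5, buys parsimony with this many candidate predictors; both thresholds
are marked in the plots. No pseudo-prior is used for excluded
coefficients: when $I_{pj}=0$ the coefficient keeps its full
$N(0, \sigma^2_\beta)$ prior (the Kuo–Mallick reading of $\xi = \beta I$),
and the sampler marginalizes the coefficient out of the indicator update
(below), which removes the mixing penalty that normally motivates
pseudo-priors.

### Missing predictors

Missing predictor cells are parameters, updated within the chain under a
missing-at-random assumption: continuous cells are
$N(\bar{x}_{\mathrm{obs}}, \sigma^2_{\mathrm{col}})$ with
$\sigma^2_{\mathrm{col}} \sim \mathrm{Gamma}(2, 0.5)$; binary cells are
$\mathrm{Bernoulli}(\nu)$ with $\nu \sim \mathrm{Uniform}(0,1)$ (posterior
$\mathrm{Beta}(1+s, 1+n-s)$); the three-level genotype is imputed from a
multinomial regression on maternal race with
$\zeta \sim N(0, \sigma^2_\zeta)$, $\sigma^2_\zeta \sim \mathrm{Gamma}(2, 0.5)$.
One deliberate correction: a linear share
$(\zeta_0 + \mathrm{race}\cdot\zeta_1)/\sum(\cdot)$ is not a valid simplex
map (it can be negative), so `categorical_probabilities()` uses the
standard multinomial-logit softmax. Missing race itself is imputed from
the empirical race frequencies. Imputation never touches observed cells.

## The sampler

No general-purpose MCMC engine with an LKJ prior is assumed; the package
ships its own Metropolis-within-Gibbs sampler with the hot loops compiled:

* **latent logits** — elliptical slice sampling per subject (exact,
  tuning-free; two sweeps per scan because every other block conditions
  on $\mathbf{z}$);
* **coefficients** — the regression of $\mathbf{z}$ is linear-Gaussian, so
  the currently included coefficients are drawn jointly from their exact
  multivariate-normal conditional; excluded ones are refreshed from the
  prior;
* **indicators** — collapsed Gibbs: each $\beta_{pj}$ is integrated out
  analytically under its normal prior, $I_{pj}$ is drawn from the marginal
  conditional odds, then $\beta_{pj}$ is redrawn from its exact
  conditional. This mixes dramatically better than updating $I$ given a
  prior-drifting excluded coefficient;
* **$\psi$** — conjugate Beta; **variances** — univariate slice sampling
  on the log scale (the Gamma-on-variance hyperprior is not conjugate);
* **$\tau$** — slice sampling on the log scale, plus an interweaved joint
  move that rescales a component's latent residuals together with its
  $\tau_j$. The move leaves the standardized MVN residuals invariant, so
  it is accepted on the Bernoulli likelihood change, the half-Cauchy
  ratio, and the residual log-Jacobian — it is what lets the weakly
  identified scale mix;
* **$\Omega$** — random-walk Metropolis on each free correlation with
  positive-definiteness rejection;
* **imputed cells** — conjugate normal draws (continuous), two- or
  three-point discrete Gibbs (binary, genotype, race), random-walk
  Metropolis for the multinomial-logit coefficients.

Correctness is checked the way sampler contracts should be: a prior-only
run (all outcomes masked) must reproduce the priors — inclusion
probabilities near 1/2, $\tau$ matching half-Cauchy quantiles,
$\sigma^2_\beta$ near its prior mean 4, LKJ moments — and fits to data
generated by the package's own generator must recover the generating
coefficients within posterior uncertainty. Both are part of the test
suite, alongside exact closed-form checks of every log-density component
and an oracle identity that the joint log-density equals the sum of its
parts to `1e-10`.

### Tunable settings

`mcmc_control()` defaults to 4 chains × (1,000 warm-up + 1,000 kept
draws), which fits the full 26-coefficient, three-region model in well
under a minute on one CPU; publication-scale runs are a matter of raising
`warmup`/`samples` (runs several orders of magnitude longer are standard
for this model class). `omega_step` (default 0.2) is the correlation
random-walk step; `rhat_threshold` (default 1.05) governs the convergence
flag computed from split-chain Gelman–Rubin statistics. Seeds fully
determine runs; chain $c$ uses `seed + c - 1`.

## Reporting conventions

`summarize_fit(..., odds_scale = TRUE)` exponentiates the posterior mean
and the equal-tailed 95% interval of the log-odds draws and reports the
dispersion as the geometric SD $e^{\mathrm{sd}(\log\text{-odds})}$ — e.g.
log-odds mean $-0.248$ with SD $0.104$ prints as 0.78 (1.11) with interval
(0.63, 0.95). `correlation_summary()` offers two layouts: the elementwise
posterior mean of $\Omega$, and a lower-Cholesky-factor summary whose
first column equals the correlations with the first component, whose
upper triangle is identically zero, and whose diagonal entries fall below
one as correlation accumulates — the convention behind lower-triangular
correlation tables with "degrading" diagonals.

## The synthetic generator and the packaged scenarios

`generate_covariates()` draws predictors from a per-column configuration;
`generate_outcomes()` pushes them through the model above. The packaged
enamel-hypoplasia scenarios carry the generating tables: Scenario 1 pairs
the dense application-scale coefficient matrix (26 rows × 3 regions) with
the fitted latent covariance, Scenario 2 keeps the coefficients but
generates independent regions (identity covariance), Scenario 3 pairs a
sparse coefficient set of varying strength (seven nonzero rows, 0.25–2 in
absolute value) with the Scenario-1 covariance; $n = 148$ subjects and 50
iterations, matching the application cohort. Presets for the other
defects accept user-supplied generating tables, and the
post-eruptive-breakdown Scenario 2 preset is deliberately absent (two
regions had too few outcomes for that model to exist).

Because the covariate-generating distributions of the source study are
not published in its main text, the defaults are a scientist's plain
choices: standard normal for continuous predictors (the coefficients act
on the covariates' native scale), Bernoulli(0.5) for binary ones, uniform
over the three genotype categories, and Poisson(1) for the salivary
strep-mutans count — deliberately *not* truncated by default, although a
cap is available (`count_cap`), since uncapped counts are precisely what
makes that predictor hard to recover. What the generator does **not**
emulate: the correlation structure among real maternal biomarkers
(serial serum measures correlate strongly), covariate measurement scales,
and informative missingness. Passing recovery tests therefore says the
method works when its assumptions hold, not that real cohort inference is
this clean.

`run_simulation_study()` regenerates covariates and outcomes each
iteration (iteration $i$ uses `seed + i`), fits the full GVS model,
records inclusion probabilities and effective-coefficient posterior
means, optionally refits the reduced model given that iteration's
selection, and records the posterior-mean latent covariance. Failed
iterations are recorded with their error message, never silently dropped.
`recovery_error()` (MSE/MAE against the generating truth) and
`inclusion_range_summary()` (median and range per predictor–component)
aggregate the report.

## Numerical choices

Bernoulli terms use an overflow-safe `log1p(exp())`; MVN densities are
Cholesky-based with a `1e-9` jitter retry near singularity; softmax
probabilities are max-shifted; $\psi$ draws are clamped away from 0/1 by
`1e-12`; slice samplers step out at width 1 (0.5 for $\tau$) with
shrinkage; proposals outside the positive-definite set or the unit
interval are rejected outright. Degenerate inputs have defined behaviour:
a fully masked outcome component reports `NA` prevalence, an all-missing
continuous column is an error at imputation-prior construction (with
advice), zero-variance chains are flagged "degenerate" rather than given
a fake R-hat, and an empty selection reduces to an intercept-only model
with a warning.

## Design choices made where the design was open

* **Outcome-axis dimension.** The covariance dimension always equals the
  outcome-axis length $d$ (3 for regions, 4 for defects); the package is
  one parameterized model over a configurable axis.
* **Random effect in recovery studies.** The generating covariance tables
  contain no random-effect variance, and with $\Sigma$ free the shared
  $b_i$ is confounded with the compound-symmetric direction: fitting
  Scenario-2 data (independent regions) with $b$ on drags the fitted
  correlations negative while $\sigma^2_b$ absorbs spurious
  equicorrelation. The simulation driver therefore fits with
  `include_random_effect = FALSE` by default, while the applied-model
  default keeps $b$ on.
* **Selection granularity.** Indicators live per encoded column (each
  genotype dummy has its own), and selection is any-component: a selected
  predictor enters the reduced model in every component, matching how
  reduced-model tables report every selected predictor in every
  region/defect.
* **Reference levels.** The first declared level of a categorical
  predictor is the reference (genotype 1s; race African American).
* **$\psi$ granularity.** One $\psi_{pj}$ per predictor–component, as the
  subscripts suggest, not shared across components.
* **Covariate resampling.** Fresh covariates per simulation iteration
  (the replicates are "random datasets", not one fixed design).
* **Problem sizes in the tests.** The suite runs desk-scale chains
  (hundreds to a thousand draws, 2–4 chains) and 10 Scenario-3
  replicates; these sizes are the package's own testing choices and the
  scenario presets retain the 50-iteration default for full runs.

## Known limitations

* **Weak identifiability of the latent scale.** With $n \approx 148$
  binary observations per component, $(\boldsymbol\mu, \tau)$ are close
  to jointly rescalable (the model approaches a threshold/probit limit as
  $\tau$ grows, where only $\boldsymbol\mu/\tau$ matters), so under the
  half-Cauchy prior the posterior of $\tau$ is strongly right-skewed and
  long chains visit large-$\tau$ excursions; split R-hat flags for $\tau$
  at desk scale are common and honest. Coefficient posterior means remain
  within a few posterior SDs of generating values, but their absolute
  calibration inherits this prior sensitivity. This is a property of the
  model under these priors, not of the sampler — the prior-only run
  reproduces the half-Cauchy exactly.
* The shared-$b$/compound-symmetry confound above.
* Inference on $\psi$ near the 0.6 threshold is Monte-Carlo noisy at desk
  scale; selection for borderline predictors (|log-odds| around 0.4–0.8
  on weakly informative covariates) varies across replicates, which the
  inclusion-range summaries make visible rather than hide.
* The imputation model is MAR with unstructured column models; no
  sensitivity analysis for informative missingness is provided.
* Model comparison (DIC/WAIC) and nested region-by-defect covariance
  structures are out of scope.
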