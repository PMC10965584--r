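---
title: "Multi-scale Bayesian modelling of artificial light and bird abundance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale Bayesian modelling of artificial light and bird abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Artificial light at night (ALAN) can attract aerial insectivores to
foraging opportunities and, at the same time, raise predation risk for
species that nest on the ground. Roadside point-count surveys of
crepuscular birds such as nightjars, combined with satellite night-light
composites, make it possible to ask how relative abundance varies with
ALAN — but only if two confounders are handled explicitly:

1. **Scale of effect.** Landscape covariates act at unknown spatial
   scales. A covariate measured as the mean over a 400 m buffer around a
   station is a different predictor than the same covariate over 6400 m,
   and the informative radius differs between covariates.
2. **Detection.** Counts are *relative* abundance: they estimate a
   constant unknown fraction of the individuals present only if detection
   probability is roughly equal across surveys. ALAN itself may alter
   signalling behaviour and hence detection.

`alanbliss` implements the full modelling chain for this problem:
synthetic data generation, multi-scale covariate extraction, likelihood
family selection, Bayesian latent indicator scale selection (BLISS), final
effect estimation with posterior-prediction summaries, detection
modelling, and a simulate–refit validation harness.

# The abundance model

Counts are negative binomial with a log link (the family itself is
checked against Poisson and zero-inflated Poisson by DIC; see below):

$$y_i \sim \mathrm{NB}(\mu_i, k), \qquad
  \mathrm{Var}(y_i) = \mu_i + \mu_i^2/k,$$
$$\log \mu_i = \beta_0 + \sum_j \beta_j\, x_{ij}(s_j)
  + \beta_\times\, x_{A,i}(s_A)\, x_{U,i}(s_U) + \gamma^\top w_i .$$

Here $x_{ij}(s)$ is covariate $j$ measured at buffer radius $s \in
\{400, 1600, 6400\}$ m, $x_A$/$x_U$ are ALAN and urban cover, and $w_i$
collects fixed-scale covariates: sun angle and day-of-year with their
squares, lunar illumination, geographic terms chosen by a preliminary
AIC screen, and a prior-count site-fidelity covariate (the mean count at
the same station earlier in the same year or in the previous year; 0 when
no qualifying survey exists).

All continuous covariates are z-scored before fitting. Quadratic terms
are built by squaring the *standardized* linear term and re-standardizing,
so that linear and quadratic columns enter on comparable scales; the
construction is isolated in `standardize_design()` and recorded in a
scaling table that maps predictions back to natural units. The operation
is idempotent and exactly invertible on its inputs.

## Priors and sampling

The sampler is an adaptive random-walk Metropolis-within-Gibbs scheme
written for this package: each coefficient is updated in turn against the
incrementally maintained linear predictor, then the dispersion (on the log
scale, with the Jacobian correction) and, for ZIP, the inflation
probability (on the logit scale). Proposal standard deviations adapt
toward a 20–40% acceptance rate *during burn-in only*, so retained draws
come from a fixed transition kernel. The default configuration — 3 chains
of 12,000 iterations with 3,000 burn-in, no thinning — retains exactly
27,000 joint draws; thinning is deliberately not offered by default
because discarding draws only loses precision.

Priors are weakly informative stand-ins, surfaced in `model_spec()` so a
user can change them: Normal(0, 2.5²) on standardized-scale coefficients,
Gamma(0.1, 0.1) on the NB dispersion $k$, Uniform(0, 1) on the ZIP
inflation. On standardized covariates a coefficient of 2.5 is an enormous
effect, so the prior is mild regularization rather than information.

The engine is verified against a deterministic quadrature oracle: on 1–2
parameter Poisson models the posterior mean from MCMC must sit within
3 batch-mean Monte-Carlo standard errors of the grid-integrated posterior
mean (see `test-acceptance.R`). Split-chain R-hat is available via
`rhat()`; a constant parameter reports `NA` rather than failing.

## Model-form selection by DIC

`compute_dic()` implements $\mathrm{DIC} = \bar D + p_D$ with
$p_D = \bar D - D(\bar\theta)$ (deviance at the posterior mean —
the classic form; the half-variance alternative is available behind
`pd_form = "variance"`). On overdispersed data ($k = 0.5$) the NB model
must and does win; on equidispersed data the two families agree to within
a fraction of a percent, because the NB simply learns a very large $k$.

# Scale selection (BLISS)

Each multi-scale covariate carries a categorical latent indicator $s_j$
over the radii. A sweep alternates:

* coefficient and dispersion updates given the current scales;
* for each free indicator, a draw from its full conditional — the
  likelihood evaluated with the covariate's column swapped to each radius,
  coefficient held fixed, times a uniform prior over radii.

This holding-the-coefficient-fixed update was chosen over reversible-jump
or joint proposals for simplicity and because the coefficient is
immediately re-adapted by the following Metropolis step; with standardized
columns at every radius the coefficient scale is comparable across radii,
so the fixed-coefficient conditional is well behaved.

The interaction term is a product of the two standardized parent columns
and carries its *own pair* of indicators, one per parent, sampled the same
way. This lets the interaction act at different scales than the parents'
main effects — a configuration that does occur (and is reported
separately) in real analyses. The product column is rebuilt on the fly
whenever a parent indicator moves.

Design choices worth knowing:

* **Radius-set guard.** Scale selection across many nested radii does not
  converge: adjacent buffer means are strongly correlated, and with six
  radii the indicators mix poorly. `bliss_spec()` therefore enforces a
  configurable maximum of three radii.
* **Selection summaries.** The per-covariate proportion of retained draws
  selecting each radius is the primary output; the modal radius is the
  selected scale, with exact ties broken toward the smaller radius (a
  logged warning, not a silent choice).
* **Opposite-sign detection.** When a covariate is positive at one scale
  and negative at another, both scales should enter the final model. No
  published numeric rule exists for "opposite sign", so `sign_conflict()`
  uses an explicit stand-in: conditional 80% intervals (over draws
  selecting each scale, minimum 100 draws per scale) lying on opposite
  sides of zero.
* **Focal refit.** After a first full run, `refit_focal()` re-runs BLISS
  with only ALAN, urban and their interaction carrying indicators, all
  other landscape covariates frozen at their selected scales — sharpening
  the selection for the covariates of interest.

On synthetic data with inter-scale correlation 0.6 and $n = 800$ surveys,
the modal scale recovers the generating radius in at least 8 of 10 seeded
replicates (run routinely in the acceptance suite). With strongly
correlated nested buffers — as real skyglow produces — attribution is
genuinely diffuse, which is a property of the problem, not the sampler.

# Derived quantities

All predictions operate in natural units via the stored scaling table.

* `alan_cap()` — the 99th-percentile ALAN value among surveys with urban
  cover at or below the referenced level (nearest-rank quantile:
  `sort(x)[ceiling(0.99 n)]`), so curves never extrapolate into ALAN ×
  urban combinations that do not occur in the data.
* `predict_curve()` — per-draw expected count over an ALAN grid at fixed
  urban cover, other covariates at their means (0 standardized); posterior
  mean and 2.5/97.5 percentiles.
* `percent_change()` — summarized as the posterior mean of *per-draw
  ratios*, not the ratio of posterior means; point-estimate arithmetic on
  published coefficients will therefore differ by a point or so from a
  full-posterior summary, which is expected.
* `sign_switch()` — per draw $u^* = -\beta_A/\beta_\times$ mapped to a
  natural urban proportion. Draws with non-switching sign patterns are
  *retained* (no truncation rule is imposed); the report clips summaries
  to $[0, 1]$ and keeps the unclipped values.
* `posterior_coef_correlation()` — Pearson correlations of coefficient
  draws; |r| > 0.9 triggers a multicollinearity advisory, the symptom that
  motivates dropping an unidentifiable interaction term.
* Post-hoc tools: `drop_stations_refit()` (influence of heavily sampled
  station clusters, with survey accounting and CI-overlap flags) and
  `dual_scale_marginal()` (both scales of one covariate as separate
  columns, optionally on a filtered survey subset such as
  "no light within 1600 m").

# Detection

`fit_detection_glm()` is a binomial GLM (logit link) of minutes-detected
out of six on survey-level covariates, treating the six 1-minute intervals
as independent Bernoulli trials — the independence assumption is implied
by the binomial response and is not relaxed (within-survey autocorrelation
of cues is a known limitation). The survey-level detection probability is
$p_{\mathrm{survey}} = 1 - (1 - p_{\min})^6$, exact and monotone.

`filter_by_detection()` removes surveys below a 90% predicted detection
probability (boundary rule: exactly 90% is kept) and refits the abundance
model, reporting coefficient deltas. In simulation where *only* detection
declines with ALAN, the naive abundance fit shows a spurious negative ALAN
coefficient and the filtered refit moves it toward zero — the confounding
check run in the acceptance suite.

# Simulate–refit validation

`simulate_from_fit()` draws counts over the original design rows using
the posterior-*mean* coefficients and dispersion (a full-draw mode exists
behind `use_draws = TRUE`; the mean-based default matches the procedure of
validating against "the coefficient values estimated by the model").
`recovery_report()` then compares generating values to the refit's 95%
credible intervals and, for BLISS refits, generating scales to modal
scales. The acceptance battery requires ≥ 90% coefficient coverage over
20 replicates.

# The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions the pipeline assumes:

* **Landscape.** A 96 × 96 grid at 300 m resolution (the ~300 m grain of
  satellite night-light composites; it is also why 400 m is the smallest
  buffer). ALAN is a sum of lognormal point sources plus a Gaussian-blur
  skyglow field (default bandwidth 2,000 m — a stand-in with the right
  qualitative reach for skyglow that in reality extends tens of
  kilometres). Urban cover mixes a field seeded at the light sources
  (intensity-weighted) with an independent patch field; the mixing weight
  is tuned by bisection — on random draws fixed before the search, so it
  is deterministic — until the buffer-level ALAN–urban correlation at the
  middle radius hits the configured target (default 0.78, the value
  observed in poorwill-range survey data; the realized station-level
  correlation is controlled to roughly ±0.15). Six further cover classes
  split the remaining proportion via smoothed random shares, so per-cell
  cover sums never exceed 1.
* **Survey design.** Straight roadside routes of 6–10 stations, gaps
  jittered within ±10% of 1.6 km, placed uniformly inside the extent;
  an extent too small for a route is an explicit error.
* **Temporal covariates.** Sun angle uniform on $[-9°, +2°]$ (the
  crepuscular survey window), day of year uniform over June–July, lunar
  illumination uniform on $[0, 1]$. Real surveys compute these from
  ephemerides; that computation is out of scope and the columns are
  accepted as inputs.
* **Counts.** NB draws with each covariate acting only at its generating
  radius; optional intercept-only structural zeros. The NB dispersion
  default is $k = 2$ — a documented implementer's choice (observed counts
  in such surveys are reported as means/SDs only, which do not pin down
  $k$), giving realistic overdispersion at survey means of 1–2 birds.
* **Detection histories.** Six independent Bernoulli slots per present
  individual with a logit-linear per-minute probability (optionally
  declining in ALAN); observed count = individuals with ≥ 1 detected
  minute. Observed ≤ true always, with equality at $p_{\min} = 1$.
* The three nightjar groups (territorial nighthawk, extra-territorial
  nighthawk, poorwill) are simulated independently with separate
  parameter sets; no cross-species dependence is modelled.

What the generator does *not* emulate: road-network geometry and the
volunteer route-choice bias toward developed areas, weather- and
cloud-dependent skyglow, spatial autocorrelation of counts beyond what the
shared landscape induces, and observer heterogeneity. Passing tests on
synthetic data therefore demonstrate the *estimator's* correctness under
the stated generating process, not robustness to those unmodelled
features.

# Numerical choices and problem sizes

* Buffer means use the center-in rule (a cell belongs to the buffer if its
  center is within the radius) — night-light pixels are coarse relative to
  the 400 m buffer and no area-weighting rule is canonical; the choice is
  isolated in `buffer_mean()` so area-weighting can be swapped in.
  Edge-truncated buffers are allowed with a warning and a reported
  coverage fraction.
* Land-cover compositing: per-cell modal class across years, ties broken
  toward the most recent year holding a tied class; cells unclassified by
  both the primary and the gap-fill product get all-zero indicators.
* Nearest-rank quantiles for the 95th/99th percentile caps.
* The routine test and validation runs use deliberately reduced problem
  sizes — chains of 1,500–2,000 iterations, $n$ of 400–800 surveys, 10–20
  replicates — chosen so the full battery completes in minutes while
  leaving the Monte-Carlo error well below the margins being asserted.
  The chain-accounting check alone runs at the full 3 × 12,000
  configuration.
* Ties in `select_scale()` go to the smaller radius; degenerate posteriors
  (all draws equal) give $p_D = 0$ and zero-width intervals rather than
  errors.

# Known limitations

* The sampler is single-site random-walk Metropolis; for strongly
  correlated posteriors (e.g. ALAN, urban and their interaction under
  high landscape correlation) mixing is slower than a gradient-based
  sampler would be. The posterior-correlation advisory exists precisely
  to flag the worst cases.
* BLISS with more than three nested radii is refused rather than fixed;
  continuous scale estimation between radii is out of scope.
* Detection modelling pools individuals across surveys with survey-level
  covariates only; no station random effects.
* No spatial autocorrelation terms or route/observer random effects in
  the abundance model.
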