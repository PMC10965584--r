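Package: alanbliss
Title: Multi-Scale Bayesian Analysis of Artificial Light at Night and
    Nightjar Relative Abundance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the effect of artificial light at night
    (ALAN) on counts of crepuscular birds from roadside point-count surveys.
    Provides a synthetic-data generator for landscapes (point-source light
    plus skyglow, with urban cover correlated to ALAN) and survey designs;
    multi-scale buffer covariate extraction at 400/1600/6400 m radii; an
    adaptive Metropolis-within-Gibbs sampler for Poisson, negative-binomial
    and zero-inflated Poisson count regression; Bayesian latent indicator
    scale selection (BLISS) to choose the buffer radius at which each
    landscape covariate acts; posterior prediction curves, percent-change
    summaries and the ALAN-by-urban interaction sign-switch threshold;
    per-minute detection-probability models with a detection-filter
    sensitivity analysis; and a simulate-refit parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
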