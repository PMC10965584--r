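#' Per-minute detection probability model
#'
#' Binomial GLM (logit link) of the number of 1-minute intervals (out of
#' six) in which each detected individual was recorded, on survey-level
#' covariates — ALAN and the temporal covariates. The six minutes are
#' treated as independent Bernoulli trials at a common per-minute
#' probability.
#'
#' @param individuals data.frame with one row per detected individual:
#'   `minutes` (0-6 minutes detected) plus the covariate columns.
#' @param terms covariate columns (empty for an intercept-only model).
#' @param group optional label (`"territorial"`, `"extraterritorial"`,
#'   `"poorwill"`).
#' @return An object of class `detection_fit`: list with `coefficients`,
#'   `vcov`, `fit`, `terms`, `group`.
#' @export
fit_detection_glm <- function(individuals, terms = character(),
                              group = NULL) {
  stopifnot(!is.null(individuals$minutes),
            all(individuals$minutes >= 0), all(individuals$minutes <= 6))
  if (all(individuals$minutes == 0) || all(individuals$minutes == 6))
    warning("all responses at the same boundary; estimates may be separated")
  dat <- individuals
  fml <- stats::as.formula(paste(
    "cbind(minutes, 6 - minutes) ~",
    if (length(terms)) paste(sprintf("`%s`", terms), collapse = " + ")
    else "1"))
  fit <- stats::glm(fml, data = dat, family = stats::binomial())
  if (!fit$converged)
    warning("detection GLM did not converge (possible separation)")
  structure(list(coefficients = stats::coef(fit), vcov = stats::vcov(fit),
                 fit = fit, terms = terms, group = group),
            class = "detection_fit")
}

#' Per-minute detection probability for new surveys
#'
#' @param fit a `detection_fit`.
#' @param newdata data.frame of survey covariates.
#' @return Per-minute probabilities in (0, 1).
#' @export
predict_p_min <- function(fit, newdata) {
  stopifnot(inherits(fit, "detection_fit"))
  as.numeric(stats::predict(fit$fit, newdata = newdata, type = "response"))
}

#' Survey-level detection probability from the per-minute probability
#'
#' An individual present through a 6-minute survey is detected if it is
#' recorded in at least one minute: `p_survey = 1 - (1 - p_min)^6`. Accepts
#' either a fitted detection model plus covariates, or per-minute
#' probabilities directly.
#'
#' @param fit a `detection_fit`, or a numeric vector of per-minute
#'   probabilities.
#' @param newdata survey covariates (when `fit` is a model).
#' @return Survey-level detection probabilities.
#' @export
survey_detection_prob <- function(fit, newdata = NULL) {
  p_min <- if (is.numeric(fit)) fit else predict_p_min(fit, newdata)
  stopifnot(all(p_min >= 0), all(p_min <= 1))
  1 - (1 - p_min)^6
}

#' Detection-probability filter with abundance refit
#'
#' The detection sensitivity analysis: surveys whose predicted survey-level
#' detection probability falls below the threshold are removed (boundary
#' rule: `>= threshold` is kept), the abundance model is refit on the
#' remainder with the same chain configuration, and per-coefficient
#' posterior-mean deltas are reported.
#'
#' @param fit an `abundance_fit` (carries its design and response).
#' @param p_survey survey-level detection probabilities, one per design
#'   row (e.g. from [survey_detection_prob()]).
#' @param threshold minimum detection probability kept (default 0.90).
#' @return list with `kept` (logical), `n_removed`, `refit` (an
#'   `abundance_fit`), and `deltas` (as in [drop_stations_refit()]).
#' @export
filter_by_detection <- function(fit, p_survey, threshold = 0.90) {
  stopifnot(inherits(fit, "abundance_fit"),
            length(p_survey) == nrow(fit$design))
  kept <- p_survey >= threshold
  if (!any(kept)) stop("detection filter removes every survey")
  design2 <- fit$design[kept, , drop = FALSE]
  attr(design2, "scaling") <- fit$scaling
  samples2 <- run_mcmc(fit$spec, design2, fit$y[kept], fit$cfg)
  fit2 <- fit
  fit2$samples <- samples2
  fit2$design <- design2
  fit2$y <- fit$y[kept]
  fit2$dic <- compute_dic(samples2, fit$spec, design2, fit2$y)
  s1 <- coef_summary(fit)
  s2 <- coef_summary(fit2)
  deltas <- data.frame(param = s1$param, mean_before = s1$mean,
                       mean_after = s2$mean, delta = s2$mean - s1$mean,
                       zero_in_ci_before = s1$lo <= 0 & s1$hi >= 0,
                       zero_in_ci_after = s2$lo <= 0 & s2$hi >= 0)
  list(kept = kept, n_removed = sum(!kept), refit = fit2, deltas = deltas)
}

#' Simulate counts from a fitted model's coefficient estimates
#'
#' The first half of the simulate-refit validation: negative-binomial
#' counts are drawn over the fit's own design rows using the posterior-mean
#' coefficients and dispersion (a draw-based mode, resampling whole
#' posterior draws per replicate, is available via `use_draws`).
#'
#' @param fit an `abundance_fit`.
#' @param design optional replacement design (defaults to the fit's).
#' @param seed integer seed.
#' @param use_draws if `TRUE`, use one randomly chosen posterior draw
#'   instead of the posterior means.
#' @return Integer vector of simulated counts, with attribute `params`
#'   (the generating parameter vector).
#' @export
simulate_from_fit <- function(fit, design = NULL, seed = 1L,
                              use_draws = FALSE) {
  stopifnot(inherits(fit, "abundance_fit"))
  if (is.null(design)) design <- fit$design
  set.seed(seed)
  draws <- fit$samples$draws
  theta <- if (use_draws) draws[sample.int(nrow(draws), 1), ]
  else colMeans(draws)
  X <- design_matrix(design, fit$spec$terms)
  eta <- drop(X %*% theta[colnames(X)])
  mu <- exp(eta)
  y <- if (fit$spec$family == "negbin")
    stats::rnbinom(length(mu), size = theta[["k"]], mu = mu)
  else stats::rpois(length(mu), mu)
  structure(y, params = theta)
}

#' Parameter-recovery report for a simulate-refit validation
#'
#' Compares the generating ("true") parameter values to the refit's 95%
#' credible intervals, flagging each parameter as recovered or not, and
#' optionally compares each covariate's true acting scale to the refit's
#' modal selected scale.
#'
#' @param refit an `abundance_fit` or `bliss_posterior` fitted to the
#'   simulated counts.
#' @param truth named numeric vector of generating parameter values
#'   (names must match the refit's parameter names).
#' @param true_scales optional named vector of generating radii per
#'   multi-scale covariate (for a `bliss_posterior` refit).
#' @return An object of class `recovery_report`: list with `params`
#'   (data.frame: `param`, `truth`, `mean`, `lo`, `hi`, `inside`),
#'   `coverage` (fraction inside), and `scales` (data.frame: `covariate`,
#'   `true_scale`, `modal_scale`, `match`) when `true_scales` given.
#' @export
recovery_report <- function(refit, truth, true_scales = NULL) {
  s <- coef_summary(refit)
  miss <- setdiff(names(truth), s$param)
  if (length(miss)) stop("truth names not in the refit: ",
                         paste(miss, collapse = ", "))
  s <- s[match(names(truth), s$param), ]
  params <- data.frame(param = names(truth), truth = as.numeric(truth),
                       mean = s$mean, lo = s$lo, hi = s$hi,
                       inside = s$lo <= as.numeric(truth) &
                         as.numeric(truth) <= s$hi,
                       row.names = NULL)
  scales <- NULL
  if (!is.null(true_scales)) {
    if (!inherits(refit, "bliss_posterior"))
      stop("scale matching requires a bliss_posterior refit")
    scales <- data.frame(
      covariate = names(true_scales),
      true_scale = as.numeric(true_scales),
      modal_scale = vapply(names(true_scales), function(cv)
        as.numeric(select_scale(refit, cv)), 0),
      row.names = NULL)
    scales$match <- scales$true_scale == scales$modal_scale
  }
  structure(list(params = params, coverage = mean(params$inside),
                 scales = scales),
            class = "recovery_report")
}
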