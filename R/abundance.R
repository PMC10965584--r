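#' Fit the final fixed-scale relative-abundance model
#'
#' Negative-binomial (by default) regression of survey counts on the
#' covariates at their selected buffer scales, with an optional
#' ALAN-by-urban product term built from the standardized parent columns.
#' Wraps [run_mcmc()] and attaches everything needed for posterior
#' prediction in natural units: the design's standardization metadata, the
#' identity of the ALAN/urban/interaction columns, and the model DIC.
#'
#' @param design standardized design table (carries the `scaling`
#'   attribute).
#' @param y nonnegative integer counts (one per design row).
#' @param terms design columns entering the model.
#' @param alan_col,urban_col names of the (standardized) ALAN and urban
#'   columns at their selected scales; `NULL` if absent from the model.
#' @param interaction logical; include the `alan_col * urban_col` product.
#' @param family,priors as in [model_spec()].
#' @param cfg a [chain_config()].
#' @return An object of class `abundance_fit`.
#' @export
fit_final <- function(design, y, terms, alan_col = NULL, urban_col = NULL,
                      interaction = FALSE, family = "negbin",
                      priors = list(), cfg = chain_config()) {
  interaction_col <- NULL
  if (interaction) {
    if (is.null(alan_col) || is.null(urban_col))
      stop("interaction requires both alan_col and urban_col")
    interaction_col <- paste(alan_col, urban_col, sep = "_x_")
    design[[interaction_col]] <- design[[alan_col]] * design[[urban_col]]
    terms <- union(terms, interaction_col)
  }
  if (anyDuplicated(terms))
    stop("duplicate model terms: ",
         paste(terms[duplicated(terms)], collapse = ", "))
  spec <- model_spec(family = family, terms = terms, priors = priors)
  samples <- run_mcmc(spec, design, y, cfg)
  dic <- compute_dic(samples, spec, design, y)
  structure(list(samples = samples, spec = spec, cfg = cfg,
                 design = design, y = y, terms = terms,
                 alan_col = alan_col, urban_col = urban_col,
                 interaction_col = interaction_col,
                 scaling = attr(design, "scaling"), dic = dic),
            class = "abundance_fit")
}

#' Construct an abundance fit from an explicit draw matrix
#'
#' For worked examples and checks where the posterior is specified
#' directly (e.g. a degenerate one-draw "posterior" carrying a published
#' coefficient). Columns must include `(Intercept)` and any of
#' `alan_col`/`urban_col`/`interaction_col` used downstream; scaling
#' defaults to identity (natural units).
#'
#' @param draws numeric matrix of posterior draws with named columns.
#' @param alan_col,urban_col,interaction_col column roles.
#' @param scaling optional data.frame (`column`, `mean`, `sd`).
#' @param family likelihood family label.
#' @return An `abundance_fit` usable by the prediction functions.
#' @export
as_abundance_fit <- function(draws, alan_col = NULL, urban_col = NULL,
                             interaction_col = NULL, scaling = NULL,
                             family = "negbin") {
  draws <- as.matrix(draws)
  if (is.null(scaling)) {
    cols <- setdiff(colnames(draws), c("(Intercept)", "k", "pi"))
    scaling <- data.frame(column = cols, mean = 0, sd = 1)
  }
  samples <- structure(list(draws = draws, loglik = rep(NA_real_,
                                                        nrow(draws)),
                            chain = rep(1L, nrow(draws)),
                            spec = model_spec(family = family,
                                              terms = setdiff(
                                                colnames(draws),
                                                c("(Intercept)", "k", "pi")))),
                       class = "posterior_samples")
  structure(list(samples = samples, spec = samples$spec, cfg = NULL,
                 design = NULL, y = NULL,
                 terms = samples$spec$terms,
                 alan_col = alan_col, urban_col = urban_col,
                 interaction_col = interaction_col, scaling = scaling,
                 dic = NULL),
            class = "abundance_fit")
}

#' Posterior coefficient summaries of an abundance fit
#'
#' @param fit an `abundance_fit` (or `posterior_samples`).
#' @param level credible level (default 0.95).
#' @return data.frame: `param`, `mean`, `sd`, `lo`, `hi`.
#' @export
coef_summary <- function(fit, level = 0.95) {
  draws <- if (inherits(fit, "abundance_fit")) fit$samples$draws
  else fit$draws
  a <- (1 - level) / 2
  data.frame(param = colnames(draws),
             mean = colMeans(draws),
             sd = apply(draws, 2, stats::sd),
             lo = apply(draws, 2, stats::quantile, a, names = FALSE),
             hi = apply(draws, 2, stats::quantile, 1 - a, names = FALSE),
             row.names = NULL)
}

nearest_rank <- function(x, p) {
  x <- sort(x)
  x[max(1L, ceiling(p * length(x)))]
}

scaling_of <- function(fit, column) {
  sc <- fit$scaling
  i <- match(column, sc$column)
  if (is.na(i)) c(mean = 0, sd = 1) else c(mean = sc$mean[i], sd = sc$sd[i])
}

#' Conditional ALAN cap for prediction ranges
#'
#' The empirical 99th-percentile ALAN value (natural units, nearest-rank
#' rule) among surveys whose urban cover is at or below `urban_level`, so
#' that prediction curves never extrapolate beyond the ALAN range that
#' actually occurs at a given urbanization level.
#'
#' @param fit an `abundance_fit` whose design holds the standardized ALAN
#'   and urban columns.
#' @param urban_level urban proportion (natural units).
#' @param prob percentile (default 0.99).
#' @return ALAN cap in nW cm-2 sr-1.
#' @export
alan_cap <- function(fit, urban_level, prob = 0.99) {
  stopifnot(inherits(fit, "abundance_fit"), !is.null(fit$design))
  sa <- scaling_of(fit, fit$alan_col)
  su <- scaling_of(fit, fit$urban_col)
  alan_nat <- fit$design[[fit$alan_col]] * sa["sd"] + sa["mean"]
  urban_nat <- fit$design[[fit$urban_col]] * su["sd"] + su["mean"]
  qual <- urban_nat <= urban_level
  if (sum(qual) == 0) stop("no surveys with urban cover <= ", urban_level)
  if (sum(qual) < 10)
    warning("fewer than 10 qualifying surveys for the ALAN cap")
  nearest_rank(alan_nat[qual], prob)
}

# per-draw linear predictor over an ALAN grid at fixed urban level,
# all other covariates at their (standardized) mean of 0
eta_draws <- function(fit, alan_grid, urban_level) {
  draws <- fit$samples$draws
  sa <- if (is.null(fit$alan_col)) c(mean = 0, sd = 1)
  else scaling_of(fit, fit$alan_col)
  za <- (alan_grid - sa["mean"]) / sa["sd"]
  eta <- outer(draws[, "(Intercept)"], rep(1, length(za)))
  if (!is.null(fit$alan_col) && fit$alan_col %in% colnames(draws))
    eta <- eta + outer(draws[, fit$alan_col], za)
  if (!is.null(fit$urban_col) && fit$urban_col %in% colnames(draws)) {
    if (is.null(urban_level))
      stop("urban_level required: the model contains an urban term")
    su <- scaling_of(fit, fit$urban_col)
    zu <- (urban_level - su["mean"]) / su["sd"]
    eta <- eta + draws[, fit$urban_col] * zu
    if (!is.null(fit$interaction_col) &&
        fit$interaction_col %in% colnames(draws))
      eta <- eta + outer(draws[, fit$interaction_col], za) * zu
  }
  eta
}

#' Posterior prediction curve of expected count over an ALAN gradient
#'
#' For each retained draw, the expected count `exp(eta)` is evaluated over
#' the ALAN grid (natural units) at a fixed urban-cover level, with all
#' other covariates at their means (0 on the standardized scale); for a ZIP
#' fit the mean is multiplied by `1 - pi`. Summaries are the across-draw
#' mean and 2.5/97.5 percentiles.
#'
#' @param fit an `abundance_fit`.
#' @param alan_grid increasing ALAN values, natural units.
#' @param urban_level urban proportion (natural units); may be `NULL` for a
#'   model without an urban term.
#' @param cap optional [alan_cap()] value; grid points beyond it are an
#'   error unless `force = TRUE`.
#' @param force allow the grid to exceed `cap`.
#' @return data.frame of class `prediction_summary`: `alan`, `mean`, `lo`,
#'   `hi`; attribute `urban_level`.
#' @export
predict_curve <- function(fit, alan_grid, urban_level = NULL, cap = NULL,
                          force = FALSE) {
  if (!is.null(cap) && any(alan_grid > cap) && !force)
    stop("ALAN grid exceeds the conditional cap (", signif(cap, 4),
         "); pass force = TRUE to override")
  eta <- eta_draws(fit, alan_grid, urban_level)
  mu <- exp(eta)
  if ("pi" %in% colnames(fit$samples$draws))
    mu <- mu * (1 - fit$samples$draws[, "pi"])
  out <- data.frame(alan = alan_grid,
                    mean = colMeans(mu),
                    lo = apply(mu, 2, stats::quantile, 0.025, names = FALSE),
                    hi = apply(mu, 2, stats::quantile, 0.975, names = FALSE))
  attr(out, "urban_level") <- urban_level
  class(out) <- c("prediction_summary", "data.frame")
  out
}

#' Posterior percent change in expected count between two ALAN levels
#'
#' Per draw, `100 * (E[count | alan1] / E[count | alan0] - 1)` at the fixed
#' urban level; summarized by the posterior mean and the 2.5/97.5
#' percentiles. Negative values are declines. The ratio is invariant to the
#' standardization constants (natural-unit contract).
#'
#' @param fit an `abundance_fit`.
#' @param alan0,alan1 ALAN endpoints, natural units.
#' @param urban_level urban proportion (natural units) or `NULL`.
#' @return list with `mean`, `lo`, `hi` (percent), and `draws`.
#' @export
percent_change <- function(fit, alan0, alan1, urban_level = NULL) {
  eta <- eta_draws(fit, c(alan0, alan1), urban_level)
  pc <- 100 * (exp(eta[, 2] - eta[, 1]) - 1)
  list(mean = mean(pc),
       lo = stats::quantile(pc, 0.025, names = FALSE),
       hi = stats::quantile(pc, 0.975, names = FALSE),
       draws = pc)
}

#' Urban-cover threshold at which the ALAN effect switches sign
#'
#' Under the interaction model the marginal ALAN effect is
#' `beta_ALAN + beta_int * z_urban`; it changes sign at
#' `z* = -beta_ALAN / beta_int`. Per draw, `z*` is mapped to a natural
#' urban proportion via the stored standardization; draws in which the
#' coefficients have a non-switching sign pattern are retained (no
#' truncation). The report clips the summaries to [0, 1]; the unclipped
#' draws are returned.
#'
#' @param fit an `abundance_fit` containing the interaction term.
#' @return list with `mean`, `lo`, `hi` (clipped to [0,1]),
#'   `mean_unclipped`, `lo_unclipped`, `hi_unclipped`, and `draws`
#'   (natural-unit, unclipped).
#' @export
sign_switch <- function(fit) {
  if (is.null(fit$interaction_col) ||
      !(fit$interaction_col %in% colnames(fit$samples$draws)))
    stop("sign_switch requires a fit with the ALAN-by-urban interaction")
  draws <- fit$samples$draws
  zstar <- -draws[, fit$alan_col] / draws[, fit$interaction_col]
  su <- scaling_of(fit, fit$urban_col)
  ustar <- su["mean"] + su["sd"] * zstar
  q <- stats::quantile(ustar, c(0.025, 0.975), names = FALSE)
  clip <- function(v) pmin(1, pmax(0, v))
  list(mean = clip(mean(ustar)), lo = clip(q[1]), hi = clip(q[2]),
       mean_unclipped = mean(ustar), lo_unclipped = q[1],
       hi_unclipped = q[2], draws = unname(ustar))
}

#' Pearson correlation between coefficients across posterior draws
#'
#' Diagnoses multicollinearity among correlated covariates (typically
#' urban cover, ALAN and their interaction): a |r| > 0.9 pair triggers an
#' advisory, the situation in which dropping the interaction term should
#' be considered.
#'
#' @param fit an `abundance_fit` or `posterior_samples`.
#' @param pairs list of length-2 character vectors of parameter names.
#' @return data.frame: `param1`, `param2`, `r`, `advisory`.
#' @export
posterior_coef_correlation <- function(fit, pairs) {
  draws <- if (inherits(fit, "abundance_fit")) fit$samples$draws
  else fit$draws
  rows <- lapply(pairs, function(pr) {
    miss <- setdiff(pr, colnames(draws))
    if (length(miss)) stop("unknown parameter: ", paste(miss, collapse = ", "))
    r <- stats::cor(draws[, pr[1]], draws[, pr[2]])
    data.frame(param1 = pr[1], param2 = pr[2], r = r,
               advisory = is.finite(r) && abs(r) > 0.9)
  })
  out <- do.call(rbind, rows)
  if (any(out$advisory))
    message("multicollinearity advisory: |posterior correlation| > 0.9 for ",
            paste(sprintf("%s~%s", out$param1[out$advisory],
                          out$param2[out$advisory]), collapse = ", "))
  out
}

#' Refit after dropping stations, with coefficient deltas
#'
#' Removes every survey at the named stations, refits the same model with
#' the same chain configuration, and reports per-coefficient posterior-mean
#' differences together with whether each coefficient's 95% CI overlaps
#' zero before and after removal.
#'
#' @param fit an `abundance_fit` whose design has a `station_id` column.
#' @param station_ids stations to drop.
#' @return list with `fit` (the refit), `deltas` (data.frame: `param`,
#'   `mean_before`, `mean_after`, `delta`, `zero_in_ci_before`,
#'   `zero_in_ci_after`), and `n_removed`.
#' @export
drop_stations_refit <- function(fit, station_ids) {
  stopifnot(inherits(fit, "abundance_fit"), !is.null(fit$design$station_id))
  unknown <- setdiff(station_ids, fit$design$station_id)
  if (length(unknown)) stop("unknown stations: ",
                            paste(unknown, collapse = ", "))
  keep <- !(fit$design$station_id %in% station_ids)
  if (!any(keep)) stop("removing these stations empties the data")
  design2 <- fit$design[keep, , drop = FALSE]
  attr(design2, "scaling") <- fit$scaling
  samples2 <- run_mcmc(fit$spec, design2, fit$y[keep], fit$cfg)
  fit2 <- fit
  fit2$samples <- samples2
  fit2$design <- design2
  fit2$y <- fit$y[keep]
  fit2$dic <- compute_dic(samples2, fit$spec, design2, fit2$y)
  s1 <- coef_summary(fit)
  s2 <- coef_summary(fit2)
  deltas <- data.frame(param = s1$param, mean_before = s1$mean,
                       mean_after = s2$mean, delta = s2$mean - s1$mean,
                       zero_in_ci_before = s1$lo <= 0 & s1$hi >= 0,
                       zero_in_ci_after = s2$lo <= 0 & s2$hi >= 0)
  list(fit = fit2, deltas = deltas, n_removed = sum(!keep))
}

#' Fit a covariate at two scales simultaneously
#'
#' Post-hoc marginal-effect model: both buffer scales of one covariate
#' (e.g. intermediate- and landscape-scale ALAN) enter the model as
#' separate columns, optionally on a filtered survey subset (e.g. only
#' stations with no artificial light within the intermediate radius).
#'
#' @param design standardized design.
#' @param y counts.
#' @param covariate base name (columns `<covariate>_<scale>` must exist).
#' @param scales the two radii.
#' @param other_terms further model columns.
#' @param filter optional logical vector (or function of the design
#'   returning one) selecting surveys to keep.
#' @param family,priors,cfg fitting controls.
#' @return list with `fit` (an `abundance_fit`) and `summary` (the two
#'   scale coefficients' posterior summaries).
#' @export
dual_scale_marginal <- function(design, y, covariate = "alan",
                                scales = c(1600, 6400),
                                other_terms = character(),
                                filter = NULL, family = "negbin",
                                priors = list(), cfg = chain_config()) {
  cols <- paste(covariate, scales, sep = "_")
  miss <- setdiff(cols, names(design))
  if (length(miss)) stop("missing scale columns: ",
                         paste(miss, collapse = ", "))
  keep <- rep(TRUE, nrow(design))
  if (!is.null(filter))
    keep <- if (is.function(filter)) filter(design) else filter
  if (!any(keep)) stop("filter removes every survey")
  design2 <- design[keep, , drop = FALSE]
  attr(design2, "scaling") <- attr(design, "scaling")
  fit <- fit_final(design2, y[keep], terms = c(cols, other_terms),
                   family = family, priors = priors, cfg = cfg)
  s <- coef_summary(fit)
  list(fit = fit, summary = s[s$param %in% cols, ])
}
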