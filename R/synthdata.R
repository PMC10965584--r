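#' Simulation configuration for synthetic surveys and landscapes
#'
#' Bundles every knob of the synthetic-data generator: the raster grid, the
#' artificial-light source process, the skyglow kernel, the ALAN-urban
#' coupling target, and the roadside survey design. Defaults emulate the
#' study conditions of a provincial-scale roadside nightjar survey: routes of
#' 6-10 stations spaced ~1.6 km apart, 6-minute counts, and satellite
#' night-light rasters with a ~300 m grain.
#'
#' @param grid_dim number of cells per side of the (square) raster grid.
#' @param res cell resolution in metres.
#' @param n_sources number of artificial light point sources.
#' @param source_log_mean,source_log_sd lognormal parameters of source
#'   intensity (radiance units, nW cm-2 sr-1, before skyglow smoothing).
#' @param skyglow_bw Gaussian skyglow kernel bandwidth in metres.
#' @param skyglow_frac fraction of each source's radiance re-emitted as
#'   diffuse skyglow.
#' @param target_cor target station-level Pearson correlation between ALAN
#'   and urban cover at the middle buffer radius.
#' @param n_routes number of survey routes.
#' @param stations_range integer range (min, max) of stations per route.
#' @param spacing nominal between-station spacing in metres.
#' @param surveys_per_station surveys per station per year.
#' @param years number of survey years.
#' @param radii buffer radii in metres, strictly increasing.
#' @param seed integer random seed used by the generator functions.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(grid_dim = 96, res = 300,
                       n_sources = 40, source_log_mean = 1.5,
                       source_log_sd = 1, skyglow_bw = 2000,
                       skyglow_frac = 0.5,
                       target_cor = 0.78,
                       n_routes = 8, stations_range = c(6L, 10L),
                       spacing = 1600, surveys_per_station = 2,
                       years = 2,
                       radii = c(400, 1600, 6400), seed = 1L) {
  stopifnot(res > 0, spacing > 0, length(radii) >= 1,
            all(diff(radii) > 0), n_sources >= 0,
            length(stations_range) == 2,
            stations_range[1] <= stations_range[2])
  if (grid_dim < 8) stop("degenerate grid: need at least 8x8 cells")
  if (stations_range[1] < 1) stop("stations per route must be positive")
  structure(list(grid_dim = as.integer(grid_dim), res = res,
                 n_sources = as.integer(n_sources),
                 source_log_mean = source_log_mean,
                 source_log_sd = source_log_sd,
                 skyglow_bw = skyglow_bw, skyglow_frac = skyglow_frac,
                 target_cor = target_cor, n_routes = as.integer(n_routes),
                 stations_range = as.integer(stations_range),
                 spacing = spacing,
                 surveys_per_station = as.integer(surveys_per_station),
                 years = as.integer(years), radii = radii,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generating ("true") parameters for count and detection simulation
#'
#' Holds the parameters of the data-generating process on the log link:
#' an intercept, per-covariate coefficients each acting at one buffer radius
#' (optionally two radii with separate coefficients for the same covariate),
#' an ALAN-by-urban interaction whose two parents can act at different radii,
#' temporal/geographic/prior-count coefficients, the negative-binomial
#' dispersion, an optional structural-zero probability, and the per-minute
#' detection model on the logit scale.
#'
#' @param intercept log-scale intercept.
#' @param coefs named list; each element `list(beta=, scale=)` gives a
#'   landscape covariate's coefficient and its acting buffer radius (m). A
#'   covariate may appear twice (dual-scale) by listing two elements with the
#'   same `name` field, e.g. `list(list(name="alan", beta=-0.2, scale=1600),
#'   list(name="alan", beta=-0.1, scale=6400))`; plain named elements are
#'   also accepted.
#' @param interaction `NULL` or `list(beta=, scale_alan=, scale_urban=)`,
#'   the product-term coefficient with each parent's acting radius.
#' @param temporal named numeric vector of coefficients for temporal
#'   covariates (e.g. `sun_angle`, `sun_angle_sq`, `day_of_year`,
#'   `day_of_year_sq`, `lunar`).
#' @param geo named numeric vector of geographic coefficients.
#' @param prior_count coefficient on the prior-mean-count covariate.
#' @param dispersion negative-binomial size parameter k (> 0); variance is
#'   mu + mu^2/k.
#' @param zero_inflation structural-zero probability in [0, 1).
#' @param det_intercept,det_slopes per-minute detection model on the logit
#'   scale; `det_slopes` is a named numeric vector over survey covariates
#'   (standardized scale), typically including `alan`.
#'
#' @return An object of class `true_params`.
#' @export
true_params <- function(intercept = 0, coefs = list(), interaction = NULL,
                        temporal = numeric(), geo = numeric(),
                        prior_count = 0, dispersion = 2,
                        zero_inflation = 0,
                        det_intercept = 2, det_slopes = numeric()) {
  stopifnot(dispersion > 0, zero_inflation >= 0, zero_inflation < 1)
  coefs <- lapply(seq_along(coefs), function(i) {
    el <- coefs[[i]]
    if (is.null(el$name)) el$name <- names(coefs)[i]
    stopifnot(!is.null(el$name), is.numeric(el$beta), is.numeric(el$scale))
    el
  })
  if (!is.null(interaction))
    stopifnot(is.numeric(interaction$beta),
              !is.null(interaction$scale_alan),
              !is.null(interaction$scale_urban))
  structure(list(intercept = intercept, coefs = coefs,
                 interaction = interaction, temporal = temporal, geo = geo,
                 prior_count = prior_count, dispersion = dispersion,
                 zero_inflation = zero_inflation,
                 det_intercept = det_intercept, det_slopes = det_slopes),
            class = "true_params")
}

gaussian_blur <- function(mat, sigma_cells) {
  if (sigma_cells <= 0) return(mat)
  half <- max(1L, ceiling(3 * sigma_cells))
  kx <- stats::dnorm(seq(-half, half), sd = sigma_cells)
  kx <- kx / sum(kx)
  n <- nrow(mat)
  # banded smoothing matrix with renormalised edge rows (no mass lost at
  # the boundary, so a constant field stays constant)
  idx <- seq_len(n)
  S <- matrix(0, n, n)
  for (o in seq(-half, half)) {
    j <- idx + o
    ok <- j >= 1 & j <= n
    S[cbind(idx[ok], j[ok])] <- S[cbind(idx[ok], j[ok])] + kx[o + half + 1]
  }
  S <- S / rowSums(S)
  S %*% mat %*% t(S)
}

#' Generate a synthetic landscape of ALAN and land-cover rasters
#'
#' Builds an artificial-light raster as the sum of point-source emission and
#' a Gaussian-smoothed skyglow field, an urban-cover layer spatially coupled
#' to the light sources so that the station-level ALAN-urban correlation at
#' the middle buffer radius matches a configured target, and a set of
#' additional land-cover proportion layers (cropland, pasture,
#' water/wetland, sparse forest, shrubland, grassland) whose per-cell sum
#' with urban never exceeds 1.
#'
#' The coupling is tuned by bisection on the fraction of urban patches
#' seeded at light-source locations (the remainder are placed independently
#' at random); all random draws are fixed before the bisection so the search
#' is deterministic and monotone.
#'
#' @param config a [sim_config()].
#' @param seed optional integer overriding `config$seed`.
#'
#' @return An object of class `landscape`: a list with `layers` (named list
#'   of matrices; `alan` in nW cm-2 sr-1, the rest proportions in [0,1]),
#'   `origin` (xy of the lower-left corner, metres), and `res`.
#' @export
generate_landscape <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(if (is.null(seed)) config$seed else seed)
  n <- config$grid_dim
  res <- config$res
  extent <- n * res

  src_xy <- if (config$n_sources > 0)
    cbind(stats::runif(config$n_sources, 0, extent),
          stats::runif(config$n_sources, 0, extent))
  else matrix(numeric(), 0, 2)
  src_int <- stats::rlnorm(config$n_sources, config$source_log_mean,
                           config$source_log_sd)

  direct <- matrix(0, n, n)
  if (config$n_sources > 0) {
    ij <- cbind(pmin(n, pmax(1L, ceiling(src_xy[, 2] / res))),
                pmin(n, pmax(1L, ceiling(src_xy[, 1] / res))))
    for (s in seq_len(config$n_sources))
      direct[ij[s, 1], ij[s, 2]] <- direct[ij[s, 1], ij[s, 2]] + src_int[s]
  }
  sky <- gaussian_blur(direct, config$skyglow_bw / res)
  alan <- direct + config$skyglow_frac * sky

  # urban patches: pre-draw both candidate centre sets, then bisect the
  # source-seeded fraction w to hit the target buffer-level correlation
  n_patch <- max(8L, config$n_sources)
  rand_xy <- cbind(stats::runif(n_patch, 0, extent),
                   stats::runif(n_patch, 0, extent))
  probe <- probe_points(extent, margin = config$radii[
    min(2, length(config$radii))])
  mid_r <- config$radii[min(2, length(config$radii))]

  bump_field <- function(pts, wts) {
    fld <- matrix(0, n, n)
    ij <- cbind(pmin(n, pmax(1L, ceiling(pts[, 2] / res))),
                pmin(n, pmax(1L, ceiling(pts[, 1] / res))))
    for (s in seq_len(nrow(ij)))
      fld[ij[s, 1], ij[s, 2]] <- fld[ij[s, 1], ij[s, 2]] + wts[s]
    fld <- gaussian_blur(fld, 800 / res)
    if (max(fld) > 0) fld / max(fld) else fld
  }
  # two normalized fields: urban mass at the light sources (weighted by
  # source intensity - towns emit in proportion to size) and a dense
  # independent patch field; the mixing weight w sets the coupling
  fld_src <- if (config$n_sources > 0)
    bump_field(src_xy, src_int) else matrix(0, n, n)
  fld_rand <- bump_field(rand_xy, rep(1, n_patch))
  urban_field <- function(w) {
    fld <- w * fld_src + (1 - w) * fld_rand
    if (max(fld) > 0) 0.9 * fld / max(fld) else fld
  }
  realized_cor <- function(w) {
    u <- urban_field(w)
    a <- vapply(seq_len(nrow(probe)), function(i)
      buffer_mean_matrix(alan, probe[i, ], mid_r, c(0, 0), res), 0)
    b <- vapply(seq_len(nrow(probe)), function(i)
      buffer_mean_matrix(u, probe[i, ], mid_r, c(0, 0), res), 0)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }

  if (config$n_sources == 0) {
    urban <- urban_field(0)
  } else {
    lo <- 0; hi <- 1
    w <- 1
    r <- realized_cor(w)
    if (is.na(r) || r < config$target_cor - 0.15) {
      # even full coupling falls short; keep w = 1 and report below
    } else if (realized_cor(0) > config$target_cor + 0.15) {
      w <- 0
    } else {
      for (it in 1:12) {
        w <- (lo + hi) / 2
        r <- realized_cor(w)
        if (is.na(r)) break
        if (abs(r - config$target_cor) <= 0.05) break
        if (r < config$target_cor) lo <- w else hi <- w
      }
    }
    urban <- urban_field(w)
    r_final <- realized_cor(w)
    if (!is.na(r_final) && abs(r_final - config$target_cor) > 0.15)
      warning(sprintf(
        "ALAN-urban correlation target %.2f unreachable after bisection (realized %.2f)",
        config$target_cor, r_final))
  }

  # remaining cover split among other classes via smoothed random shares
  others <- c("cropland", "pasture", "water_wetland", "sparse_forest",
              "shrubland", "grassland")
  shares <- lapply(others, function(cl)
    gaussian_blur(matrix(stats::runif(n * n), n, n), 1000 / res))
  tot <- Reduce(`+`, shares) + 0.5  # 0.5 share left unclassified ("bare")
  layers <- c(list(alan = alan, urban = urban),
              stats::setNames(lapply(shares, function(s)
                (1 - urban) * s / tot), others))

  structure(list(layers = layers, origin = c(0, 0), res = res,
                 extent = extent), class = "landscape")
}

probe_points <- function(extent, margin, k = 10) {
  g <- seq(margin, extent - margin, length.out = k)
  as.matrix(expand.grid(x = g, y = g))
}

#' Generate a roadside survey design of routes and stations
#'
#' Places straight roadside routes of 6-10 stations at ~1.6 km spacing
#' (each gap jittered within +/-10% of nominal) uniformly at random inside
#' the landscape extent. Routes that would extend beyond the raster are
#' re-drawn; an extent too small to hold a route is an explicit error that
#' names the required extent.
#'
#' @param landscape a [generate_landscape()] result.
#' @param config a [sim_config()].
#' @param seed optional integer overriding `config$seed`.
#'
#' @return A data.frame with columns `station_id`, `route_id`, `x`, `y`
#'   (metres).
#' @export
generate_survey_design <- function(landscape, config, seed = NULL) {
  stopifnot(inherits(landscape, "landscape"), inherits(config, "sim_config"))
  set.seed(if (is.null(seed)) config$seed else seed + 1L)
  extent <- landscape$extent
  out <- list()
  if (config$n_routes == 0)
    return(data.frame(station_id = character(), route_id = character(),
                      x = numeric(), y = numeric()))
  for (r in seq_len(config$n_routes)) {
    n_st <- if (config$stations_range[1] == config$stations_range[2])
      config$stations_range[1]
    else sample(seq(config$stations_range[1], config$stations_range[2]), 1)
    span_max <- (n_st - 1) * config$spacing * 1.1
    if (span_max > sqrt(2) * extent)
      stop(sprintf(
        "extent too small for a %d-station route: need at least %.0f m per side, have %.0f m",
        n_st, span_max / sqrt(2), extent))
    ok <- FALSE
    for (try in 1:500) {
      theta <- stats::runif(1, 0, 2 * pi)
      gaps <- config$spacing * stats::runif(n_st - 1, 0.92, 1.08)
      d <- c(0, cumsum(gaps))
      x0 <- stats::runif(1, 0, extent)
      y0 <- stats::runif(1, 0, extent)
      xs <- x0 + d * cos(theta)
      ys <- y0 + d * sin(theta)
      if (all(xs >= 0 & xs <= extent & ys >= 0 & ys <= extent)) {
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop(sprintf(
        "could not place a %d-station route inside a %.0f m extent; need at least %.0f m per side",
        n_st, extent, span_max))
    out[[r]] <- data.frame(
      station_id = sprintf("R%02d-S%02d", r, seq_len(n_st)),
      route_id = sprintf("R%02d", r), x = xs, y = ys)
  }
  do.call(rbind, out)
}

# linear predictor on the log link from a standardized design + true_params
linpred_from_truth <- function(design, truth) {
  eta <- rep(truth$intercept, nrow(design))
  need <- function(col) {
    if (is.null(design[[col]]))
      stop("design lacks required column: ", col)
    v <- design[[col]]
    if (any(!is.finite(v)))
      stop("non-finite values in covariate column: ", col)
    v
  }
  for (el in truth$coefs)
    eta <- eta + el$beta * need(paste(el$name, el$scale, sep = "_"))
  if (!is.null(truth$interaction)) {
    ia <- truth$interaction
    eta <- eta + ia$beta *
      need(paste("alan", ia$scale_alan, sep = "_")) *
      need(paste("urban", ia$scale_urban, sep = "_"))
  }
  for (nm in names(truth$temporal))
    eta <- eta + truth$temporal[[nm]] * need(nm)
  for (nm in names(truth$geo))
    eta <- eta + truth$geo[[nm]] * need(nm)
  if (truth$prior_count != 0)
    eta <- eta + truth$prior_count * need("prior_count")
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  eta
}

#' Simulate survey counts from a multi-scale design and true parameters
#'
#' Draws negative-binomial counts with log-link mean `exp(eta)` where `eta`
#' uses each landscape covariate only at its acting buffer radius, plus an
#' optional ALAN-by-urban product term and temporal/geographic/prior-count
#' terms. With a positive structural-zero probability, each draw is replaced
#' by zero independently with that probability (zero-inflation).
#'
#' @param design standardized multi-scale design table (see
#'   [standardize_design()]); columns named `<covariate>_<radius>` plus any
#'   temporal/geographic columns the truth references.
#' @param truth a [true_params()].
#' @param seed integer seed.
#'
#' @return `design` with added columns `eta_true`, `count_true`.
#' @export
simulate_counts <- function(design, truth, seed = 1L) {
  stopifnot(inherits(truth, "true_params"))
  set.seed(seed)
  eta <- linpred_from_truth(design, truth)
  mu <- exp(eta)
  y <- stats::rnbinom(length(mu), size = truth$dispersion, mu = mu)
  if (truth$zero_inflation > 0) {
    z <- stats::rbinom(length(mu), 1, truth$zero_inflation)
    y[z == 1] <- 0L
  }
  design$eta_true <- eta
  design$count_true <- y
  design
}

#' Simulate per-minute detection histories and observed counts
#'
#' Each truly present individual is detected independently in each of six
#' 1-minute intervals with probability `p_min`, where `logit(p_min)` is the
#' detection intercept plus slopes times survey-level covariates (typically
#' including ALAN, so detection can weaken under light). The observed count
#' is the number of individuals with at least one detected minute; histories
#' are stored as ";"-separated 6-character 0/1 strings per survey.
#'
#' @param table output of [simulate_counts()] (needs `count_true`).
#' @param truth a [true_params()] with `det_intercept`, `det_slopes`.
#' @param seed integer seed.
#'
#' @return `table` with added columns `p_min`, `count_obs`, `histories`.
#' @export
simulate_detection_histories <- function(table, truth, seed = 1L) {
  stopifnot(inherits(truth, "true_params"), !is.null(table$count_true))
  set.seed(seed + 1L)
  lp <- rep(truth$det_intercept, nrow(table))
  for (nm in names(truth$det_slopes)) {
    if (is.null(table[[nm]]))
      stop("detection slope references missing column: ", nm)
    lp <- lp + truth$det_slopes[[nm]] * table[[nm]]
  }
  p_min <- stats::plogis(lp)
  obs <- integer(nrow(table))
  hist_str <- character(nrow(table))
  for (i in seq_len(nrow(table))) {
    k <- table$count_true[i]
    if (k == 0) { hist_str[i] <- ""; next }
    slots <- matrix(stats::rbinom(6 * k, 1, p_min[i]), nrow = k)
    seen <- rowSums(slots) > 0
    obs[i] <- sum(seen)
    hist_str[i] <- paste(apply(
      slots[seen, , drop = FALSE], 1, paste0, collapse = ""),
      collapse = ";")
  }
  table$p_min <- p_min
  table$count_obs <- obs
  table$histories <- hist_str
  table
}

#' Write/read a landscape as plain-text grids with a JSON sidecar
#'
#' One whitespace-delimited numeric grid file per layer
#' (`<name>.grid.txt`), plus `landscape.json` recording origin, resolution
#' and layer names.
#'
#' @param landscape a `landscape` object.
#' @param dir output directory (created if needed).
#' @return `write_landscape`: the directory, invisibly. `read_landscape`:
#'   a `landscape` object.
#' @export
write_landscape <- function(landscape, dir) {
  stopifnot(inherits(landscape, "landscape"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(landscape$layers))
    utils::write.table(landscape$layers[[nm]],
                       file.path(dir, paste0(nm, ".grid.txt")),
                       row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(origin = landscape$origin, res = landscape$res,
         extent = landscape$extent, layers = names(landscape$layers)),
    file.path(dir, "landscape.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "landscape.json"),
                              simplifyVector = TRUE)
  layers <- lapply(meta$layers, function(nm)
    as.matrix(utils::read.table(file.path(dir, paste0(nm, ".grid.txt")))))
  layers <- lapply(layers, unname)
  names(layers) <- meta$layers
  structure(list(layers = layers, origin = meta$origin, res = meta$res,
                 extent = meta$extent), class = "landscape")
}
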