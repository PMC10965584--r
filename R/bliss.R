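#' Specification for Bayesian latent indicator scale selection
#'
#' BLISS augments a count regression with one categorical latent indicator
#' per multi-scale covariate: the indicator chooses which buffer radius's
#' measurement of that covariate enters the linear predictor, and is
#' sampled jointly with the coefficients. An optional ALAN-by-urban product
#' term carries its own *pair* of indicators (one per parent), so the
#' interaction's scales can differ from the main effects'.
#'
#' @param multiscale named list; element `cov` is a named character vector
#'   mapping radius label -> design column, e.g.
#'   `list(alan = c("400"="alan_400", "1600"="alan_1600"))`. All covariates
#'   must share the same radius set. See [multiscale_terms()].
#' @param fixed_terms design columns entering at a single fixed scale
#'   (temporal, geographic, prior-count).
#' @param interaction `NULL`, or length-2 character vector naming the two
#'   multi-scale covariates whose product enters the model (each parent of
#'   the product gets its own scale indicator).
#' @param family,priors as in [model_spec()].
#' @param indicator_prior prior probabilities over the radii (uniform by
#'   default).
#' @param max_radii guard on the number of radii (scale selection over many
#'   strongly correlated radii does not converge); default 3.
#' @return An object of class `bliss_spec`.
#' @export
bliss_spec <- function(multiscale, fixed_terms = character(),
                       interaction = NULL,
                       family = "negbin", priors = list(),
                       indicator_prior = NULL, max_radii = 3) {
  stopifnot(length(multiscale) >= 1)
  radii <- names(multiscale[[1]])
  for (cov in names(multiscale))
    if (!identical(names(multiscale[[cov]]), radii))
      stop("radius sets differ across covariates (", cov, ")")
  if (length(radii) > max_radii)
    stop("more than ", max_radii,
         " radii; scale selection over many correlated radii is unreliable")
  if (!is.null(interaction)) {
    stopifnot(length(interaction) == 2)
    miss <- setdiff(interaction, names(multiscale))
    if (length(miss)) stop("interaction parents not in covariate list: ",
                           paste(miss, collapse = ", "))
  }
  if (is.null(indicator_prior))
    indicator_prior <- rep(1 / length(radii), length(radii))
  stopifnot(length(indicator_prior) == length(radii),
            abs(sum(indicator_prior) - 1) < 1e-8)
  base <- model_spec(family = family, priors = priors)
  structure(list(multiscale = multiscale, fixed_terms = fixed_terms,
                 interaction = interaction, family = base$family,
                 priors = base$priors, radii = radii,
                 indicator_prior = indicator_prior),
            class = "bliss_spec")
}

#' Build the radius->column map for multi-scale covariates
#'
#' @param covariates covariate base names (e.g. `c("alan", "urban")`).
#' @param radii numeric radii; columns are assumed named
#'   `<covariate>_<radius>`.
#' @return Named list suitable for [bliss_spec()].
#' @export
multiscale_terms <- function(covariates, radii) {
  out <- lapply(covariates, function(cv)
    stats::setNames(paste(cv, radii, sep = "_"), as.character(radii)))
  names(out) <- covariates
  out
}

#' Run the BLISS sampler
#'
#' Each MCMC sweep updates (a) every coefficient and the NB dispersion by
#' adaptive random-walk Metropolis, holding the current scales fixed, and
#' (b) every free scale indicator by a draw from its full conditional
#' categorical distribution over the radii, holding the coefficients fixed.
#' The interaction product column is rebuilt on the fly from its parents'
#' current scales. Draw accounting is identical to [run_mcmc()].
#'
#' @param spec a [bliss_spec()].
#' @param design standardized multi-scale design.
#' @param y counts.
#' @param cfg a [chain_config()].
#' @param focal covariates whose indicators are sampled; defaults to all.
#'   Non-focal covariates must have an entry in `fixed_scales`. The
#'   interaction's pair of indicators is free iff `"interaction"` is in
#'   `focal` (default: free whenever an interaction is specified).
#' @param fixed_scales named vector radius-label per non-focal covariate
#'   (for the interaction parents use names `int.<parent>`).
#' @return An object of class `bliss_posterior` (extends
#'   `posterior_samples`): adds `indicators` (retained draws x indicator
#'   matrix of radius labels), `proportions` (per-indicator selection
#'   proportions) and `radii`.
#' @export
run_bliss <- function(spec, design, y, cfg, focal = NULL,
                      fixed_scales = NULL) {
  stopifnot(inherits(spec, "bliss_spec"), inherits(cfg, "chain_config"))
  covs <- names(spec$multiscale)
  ind_names <- covs
  if (!is.null(spec$interaction))
    ind_names <- c(ind_names, paste0("int.", spec$interaction))
  if (is.null(focal)) focal <- c(covs,
                                 if (!is.null(spec$interaction)) "interaction")
  free <- c(intersect(covs, focal),
            if (!is.null(spec$interaction) && "interaction" %in% focal)
              paste0("int.", spec$interaction))
  fixed_ind <- setdiff(ind_names, free)
  for (fi in fixed_ind) {
    if (is.null(fixed_scales) || is.na(match(fi, names(fixed_scales))))
      stop("missing fixed scale for non-focal covariate: ", fi)
    if (!(as.character(fixed_scales[[fi]]) %in% spec$radii))
      stop("fixed scale for ", fi, " is not one of the configured radii")
  }
  Z <- lapply(covs, function(cv)
    as.matrix(design[spec$multiscale[[cv]]]))
  names(Z) <- covs
  Xfix <- if (length(spec$fixed_terms))
    as.matrix(design[spec$fixed_terms]) else NULL

  res <- lapply(seq_len(cfg$chains), function(ch)
    bliss_chain(spec, Z, Xfix, y, cfg, ch, ind_names, free, fixed_scales))
  draws <- do.call(rbind, lapply(res, `[[`, "draws"))
  indicators <- do.call(rbind, lapply(res, `[[`, "ind"))
  stopifnot(nrow(draws) == cfg$retained)
  post <- structure(list(
    draws = draws, loglik = unlist(lapply(res, `[[`, "loglik")),
    chain = rep(seq_len(cfg$chains), each = cfg$iterations - cfg$burnin),
    indicators = indicators,
    accept = Reduce(`+`, lapply(res, `[[`, "accept")) / cfg$chains,
    spec = spec, cfg = cfg, radii = spec$radii),
    class = c("bliss_posterior", "posterior_samples"))
  post$proportions <- scale_selection_table(post)
  post
}

bliss_chain <- function(spec, Z, Xfix, y, cfg, ch, ind_names, free,
                        fixed_scales) {
  set.seed(cfg$seed + 17L * ch)
  K <- length(spec$radii)
  covs <- names(Z)
  n <- length(y)
  has_int <- !is.null(spec$interaction)
  pri <- spec$priors
  has_k <- spec$family == "negbin"

  # indicator state: radius index per indicator
  s <- stats::setNames(integer(length(ind_names)), ind_names)
  for (d in ind_names) {
    s[d] <- if (d %in% free) sample.int(K, 1)
    else match(as.character(fixed_scales[[d]]), spec$radii)
  }
  int_col <- function() {
    a <- spec$interaction[1]; b <- spec$interaction[2]
    Z[[a]][, s[paste0("int.", a)]] * Z[[b]][, s[paste0("int.", b)]]
  }
  # coefficient vector: intercept, one per multiscale covariate,
  # fixed terms, interaction
  cn <- c("(Intercept)", covs, colnames(Xfix),
          if (has_int) "interaction")
  p <- length(cn)
  beta <- stats::setNames(rep(0, p), cn)
  beta[1] <- log(mean(y) + 0.1)
  col_of <- function(j) {
    nmj <- cn[j]
    if (nmj == "(Intercept)") rep(1, n)
    else if (nmj %in% covs) Z[[nmj]][, s[nmj]]
    else if (nmj == "interaction") int_col()
    else Xfix[, nmj]
  }
  eta <- rep(beta[1], n)
  for (j in seq_len(p)[-1]) if (beta[j] != 0)
    eta <- eta + beta[j] * col_of(j)
  k <- if (has_k) 1 else NULL
  logk <- 0
  llsum <- sum(loglik_eta(spec$family, y, eta, k, NULL))
  step <- rep(0.15, p + has_k)
  acc <- numeric(p + has_k)
  keep <- cfg$iterations - cfg$burnin
  draws <- matrix(NA_real_, keep, p + has_k,
                  dimnames = list(NULL, c(cn, if (has_k) "k")))
  ind_out <- matrix(NA_character_, keep, length(ind_names),
                    dimnames = list(NULL, ind_names))
  ll_out <- numeric(keep)
  lprior_ind <- log(spec$indicator_prior)

  for (it in seq_len(cfg$iterations)) {
    gam <- if (it <= cfg$burnin) min(0.25, 2 / sqrt(it)) else 0
    for (j in seq_len(p)) {
      xj <- col_of(j)
      prop <- beta[j] + stats::rnorm(1, 0, step[j])
      eta_p <- eta + xj * (prop - beta[j])
      llp <- sum(loglik_eta(spec$family, y, eta_p, k, NULL))
      la <- llp - llsum + log_prior_beta(prop, pri) -
        log_prior_beta(beta[j], pri)
      a <- min(1, exp(la))
      if (is.finite(la) && stats::runif(1) < a) {
        beta[j] <- prop; eta <- eta_p; llsum <- llp
        acc[j] <- acc[j] + 1
      }
      if (gam > 0) step[j] <- step[j] * exp(gam * (a - 0.3))
    }
    if (has_k) {
      prop <- logk + stats::rnorm(1, 0, step[p + 1])
      kp <- exp(prop)
      llp <- sum(loglik_eta(spec$family, y, eta, kp, NULL))
      la <- llp - llsum +
        stats::dgamma(kp, pri$k_shape, pri$k_rate, log = TRUE) -
        stats::dgamma(k, pri$k_shape, pri$k_rate, log = TRUE) +
        prop - logk
      a <- min(1, exp(la))
      if (is.finite(la) && stats::runif(1) < a) {
        logk <- prop; k <- kp; llsum <- llp
        acc[p + 1] <- acc[p + 1] + 1
      }
      if (gam > 0) step[p + 1] <- step[p + 1] * exp(gam * (a - 0.3))
    }
    # full-conditional categorical indicator updates, coefficients fixed
    for (d in intersect(ind_names, free)) {
      if (startsWith(d, "int.")) {
        parent <- sub("^int\\.", "", d)
        other <- setdiff(spec$interaction, parent)
        zo <- Z[[other]][, s[paste0("int.", other)]]
        cur <- Z[[parent]][, s[d]] * zo
        b <- beta["interaction"]
        cand <- vapply(seq_len(K), function(r) {
          if (r == s[d]) return(llsum + lprior_ind[r])
          eta_r <- eta + b * (Z[[parent]][, r] * zo - cur)
          sum(loglik_eta(spec$family, y, eta_r, k, NULL)) + lprior_ind[r]
        }, 0)
      } else {
        b <- beta[d]
        cur <- Z[[d]][, s[d]]
        cand <- vapply(seq_len(K), function(r) {
          if (r == s[d]) return(llsum + lprior_ind[r])
          eta_r <- eta + b * (Z[[d]][, r] - cur)
          sum(loglik_eta(spec$family, y, eta_r, k, NULL)) + lprior_ind[r]
        }, 0)
      }
      w <- exp(cand - max(cand))
      new_r <- sample.int(K, 1, prob = w)
      if (new_r != s[d]) {
        if (startsWith(d, "int.")) {
          parent <- sub("^int\\.", "", d)
          other <- setdiff(spec$interaction, parent)
          zo <- Z[[other]][, s[paste0("int.", other)]]
          eta <- eta + beta["interaction"] *
            (Z[[parent]][, new_r] * zo - Z[[parent]][, s[d]] * zo)
        } else {
          eta <- eta + beta[d] * (Z[[d]][, new_r] - Z[[d]][, s[d]])
        }
        s[d] <- new_r
        llsum <- sum(loglik_eta(spec$family, y, eta, k, NULL))
      }
    }
    if (it > cfg$burnin) {
      i <- it - cfg$burnin
      draws[i, ] <- c(beta, if (has_k) k)
      ind_out[i, ] <- spec$radii[s]
      ll_out[i] <- llsum
    }
  }
  list(draws = draws, ind = ind_out, loglik = ll_out,
       accept = stats::setNames(acc / cfg$iterations,
                                c(cn, if (has_k) "k")))
}

#' Per-covariate scale-selection proportions
#'
#' The fraction of retained posterior draws in which each buffer radius was
#' selected for each multi-scale covariate (and for each parent of the
#' interaction term). Proportions sum to 1 across radii per covariate.
#'
#' @param post a `bliss_posterior`.
#' @return data.frame: `covariate`, one column per radius.
#' @export
scale_selection_table <- function(post) {
  stopifnot(inherits(post, "bliss_posterior"))
  radii <- post$radii
  tab <- t(apply(post$indicators, 2, function(col) {
    cnt <- table(factor(col, levels = radii))
    as.numeric(cnt) / length(col)
  }))
  out <- data.frame(covariate = colnames(post$indicators), tab,
                    check.names = FALSE, row.names = NULL)
  names(out)[-1] <- radii
  out
}

#' Modal selected scale for a covariate
#'
#' The radius selected in the largest proportion of the posterior; exact
#' ties are broken toward the smaller radius with a warning.
#'
#' @param post a `bliss_posterior`.
#' @param covariate indicator name (covariate base name, or
#'   `int.<parent>`).
#' @return The selected radius (numeric if the labels are numeric).
#' @export
select_scale <- function(post, covariate) {
  tab <- post$proportions
  row <- tab[tab$covariate == covariate, -1, drop = FALSE]
  if (nrow(row) == 0) stop("unknown covariate: ", covariate)
  p <- as.numeric(row[1, ])
  radii <- as.numeric(names(row))
  top <- which(p == max(p))
  if (length(top) > 1) {
    top <- top[which.min(radii[top])]
    warning("tied selection proportions for ", covariate,
            "; choosing the smaller radius")
  }
  radii[top]
}

#' Detect opposite-sign effects across selected scales
#'
#' For each radius with at least `min_draws` posterior draws selecting it,
#' summarizes the covariate's coefficient conditional on that selection.
#' The conflict flag is raised when two scales' conditional `level`
#' credible intervals lie on opposite sides of zero — the situation in
#' which the covariate should enter the final model at both scales as
#' separate terms.
#'
#' @param post a `bliss_posterior`.
#' @param covariate multi-scale covariate name.
#' @param level conditional interval level (default 0.80).
#' @param min_draws minimum draws selecting a scale for it to be
#'   summarized (default 100).
#' @return list with `flag`, and `table` (per-scale `n`, `mean`, `lo`,
#'   `hi`, `skipped`).
#' @export
sign_conflict <- function(post, covariate, level = 0.80, min_draws = 100) {
  stopifnot(covariate %in% colnames(post$indicators),
            covariate %in% colnames(post$draws))
  alpha <- (1 - level) / 2
  sel <- post$indicators[, covariate]
  b <- post$draws[, covariate]
  rows <- lapply(post$radii, function(r) {
    idx <- sel == r
    n <- sum(idx)
    if (n < min_draws)
      return(data.frame(radius = r, n = n, mean = NA, lo = NA, hi = NA,
                        skipped = TRUE))
    q <- stats::quantile(b[idx], c(alpha, 1 - alpha), names = FALSE)
    data.frame(radius = r, n = n, mean = mean(b[idx]), lo = q[1], hi = q[2],
               skipped = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- !tab$skipped
  flag <- any(tab$lo[ok] > 0) && any(tab$hi[ok] < 0)
  list(flag = flag, table = tab)
}

#' Refit BLISS with only focal covariates carrying scale indicators
#'
#' The second stage of the scale-selection procedure: ALAN, urban cover and
#' their interaction keep their latent indicators while every other
#' landscape covariate enters at the scale selected in the first run.
#'
#' @param spec,design,y,cfg as in [run_bliss()].
#' @param focal covariates keeping indicators (plus `"interaction"`).
#' @param fixed_scales named radius labels for all non-focal covariates.
#' @return A `bliss_posterior`.
#' @export
refit_focal <- function(spec, design, y, cfg,
                        focal = c("alan", "urban", "interaction"),
                        fixed_scales = NULL) {
  run_bliss(spec, design, y, cfg, focal = focal, fixed_scales = fixed_scales)
}
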