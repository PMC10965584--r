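#' Count-model specification
#'
#' @param family likelihood family: `"negbin"` (mean-dispersion
#'   parameterization, variance mu + mu^2/k), `"poisson"`, or `"zip"`
#'   (zero-inflated Poisson with an intercept-only structural-zero
#'   probability).
#' @param terms character vector of design-column names entering the linear
#'   predictor (an intercept is always included); product terms should be
#'   precomputed columns.
#' @param priors list of prior hyperparameters: `beta_mean`, `beta_sd`
#'   (normal prior on standardized-scale coefficients), `k_shape`, `k_rate`
#'   (gamma prior on the NB dispersion), inflation prior is Uniform(0,1).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("negbin", "poisson", "zip"),
                       terms = character(),
                       priors = list()) {
  family <- match.arg(family)
  defaults <- list(beta_mean = 0, beta_sd = 2.5, k_shape = 0.1, k_rate = 0.1)
  priors <- utils::modifyList(defaults, priors)
  structure(list(family = family, terms = terms, priors = priors,
                 link = "log"),
            class = "model_spec")
}

#' MCMC chain configuration
#'
#' Retained draws = `chains * (iterations - burnin)`; no thinning is applied
#' (thinning discards information without reducing bias).
#'
#' @param chains number of chains.
#' @param iterations iterations per chain.
#' @param burnin burn-in iterations per chain (must be < `iterations`);
#'   proposal scales adapt only during burn-in.
#' @param seed integer seed; chain c uses `seed + c`.
#' @return An object of class `chain_config`.
#' @export
chain_config <- function(chains = 3L, iterations = 12000L, burnin = 3000L,
                         seed = 1L) {
  stopifnot(burnin < iterations, chains >= 1)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burnin = as.integer(burnin), seed = as.integer(seed),
                 retained = as.integer(chains) *
                   (as.integer(iterations) - as.integer(burnin))),
            class = "chain_config")
}

# per-observation log-likelihood at linear predictor eta
loglik_eta <- function(family, y, eta, k = NULL, pi = NULL) {
  mu <- exp(eta)
  if (family == "poisson")
    return(stats::dpois(y, mu, log = TRUE))
  if (family == "negbin") {
    if (is.null(k) || k <= 0) stop("negbin requires dispersion k > 0")
    return(stats::dnbinom(y, size = k, mu = mu, log = TRUE))
  }
  if (is.null(pi) || pi < 0 || pi >= 1)
    stop("zip requires inflation pi in [0, 1)")
  ll <- log1p(-pi) + stats::dpois(y, mu, log = TRUE)
  z <- y == 0
  if (any(z)) ll[z] <- log(pi + (1 - pi) * exp(-mu[z]))
  ll
}

#' Per-observation log-likelihood of a count model
#'
#' @param spec a [model_spec()].
#' @param params list with `beta` (named: `(Intercept)` plus `spec$terms`),
#'   `k` (NB dispersion), `pi` (ZIP inflation) as the family requires.
#' @param design design data.frame holding `spec$terms`.
#' @param y nonnegative integer response.
#' @return Numeric vector of per-observation log-likelihoods.
#' @export
loglik <- function(spec, params, design, y) {
  X <- design_matrix(design, spec$terms)
  beta <- params$beta[colnames(X)]
  if (any(is.na(beta))) stop("params$beta missing entries for: ",
                             paste(colnames(X)[is.na(beta)], collapse = ", "))
  eta <- drop(X %*% beta)
  loglik_eta(spec$family, y, eta, params$k, params$pi)
}

design_matrix <- function(design, terms) {
  miss <- setdiff(terms, names(design))
  if (length(miss)) stop("terms missing from design: ",
                         paste(miss, collapse = ", "))
  X <- cbind("(Intercept)" = rep(1, nrow(design)))
  if (length(terms))
    X <- cbind(X, as.matrix(design[terms]))
  X
}

log_prior_beta <- function(b, priors)
  stats::dnorm(b, priors$beta_mean, priors$beta_sd, log = TRUE)

#' Fit a count model by adaptive Metropolis-within-Gibbs MCMC
#'
#' Random-walk Metropolis updates of each coefficient in turn (the linear
#' predictor is maintained incrementally), then of log dispersion (NB) or
#' logit inflation (ZIP). Proposal standard deviations adapt toward a
#' 20-40% acceptance rate during burn-in only, so the retained chain is a
#' valid fixed-kernel Markov chain.
#'
#' @param spec a [model_spec()].
#' @param design standardized design data.frame.
#' @param y nonnegative integer response vector.
#' @param cfg a [chain_config()].
#' @return An object of class `posterior_samples`: list with `draws`
#'   (retained draws x parameters matrix), `loglik` (per-draw total),
#'   `chain` (chain label per draw), `accept` (acceptance rates), `spec`,
#'   `cfg`.
#' @export
run_mcmc <- function(spec, design, y, cfg) {
  stopifnot(inherits(spec, "model_spec"), inherits(cfg, "chain_config"))
  if (any(y < 0) || any(y != round(y))) stop("y must be nonnegative integers")
  X <- design_matrix(design, spec$terms)
  res <- lapply(seq_len(cfg$chains), function(ch)
    mcmc_chain(spec, X, y, cfg, ch))
  draws <- do.call(rbind, lapply(res, `[[`, "draws"))
  out <- structure(list(
    draws = draws,
    loglik = unlist(lapply(res, `[[`, "loglik")),
    chain = rep(seq_len(cfg$chains), each = cfg$iterations - cfg$burnin),
    accept = Reduce(`+`, lapply(res, `[[`, "accept")) / cfg$chains,
    spec = spec, cfg = cfg),
    class = "posterior_samples")
  stopifnot(nrow(out$draws) == cfg$retained)
  out
}

mcmc_chain <- function(spec, X, y, cfg, ch) {
  set.seed(cfg$seed + ch)
  p <- ncol(X)
  pri <- spec$priors
  has_k <- spec$family == "negbin"
  has_pi <- spec$family == "zip"
  beta <- rep(0, p)
  beta[1] <- log(mean(y) + 0.1)
  logk <- 0
  lpi <- stats::qlogis(0.1)
  k <- if (has_k) exp(logk) else NULL
  pi <- if (has_pi) stats::plogis(lpi) else NULL
  eta <- drop(X %*% beta)
  llsum <- sum(loglik_eta(spec$family, y, eta, k, pi))
  n_extra <- has_k + has_pi
  step <- rep(0.15, p + n_extra)
  acc <- numeric(p + n_extra)
  keep <- cfg$iterations - cfg$burnin
  nm <- c(colnames(X), if (has_k) "k", if (has_pi) "pi")
  draws <- matrix(NA_real_, keep, p + n_extra, dimnames = list(NULL, nm))
  ll_out <- numeric(keep)
  for (it in seq_len(cfg$iterations)) {
    gam <- if (it <= cfg$burnin) min(0.25, 2 / sqrt(it)) else 0
    for (j in seq_len(p)) {
      prop <- beta[j] + stats::rnorm(1, 0, step[j])
      eta_p <- eta + X[, j] * (prop - beta[j])
      llp <- sum(loglik_eta(spec$family, y, eta_p, k, pi))
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
      llp <- sum(loglik_eta(spec$family, y, eta, kp, pi))
      la <- llp - llsum +
        stats::dgamma(kp, pri$k_shape, pri$k_rate, log = TRUE) -
        stats::dgamma(k, pri$k_shape, pri$k_rate, log = TRUE) +
        prop - logk  # Jacobian of the log transform
      a <- min(1, exp(la))
      if (is.finite(la) && stats::runif(1) < a) {
        logk <- prop; k <- kp; llsum <- llp
        acc[p + 1] <- acc[p + 1] + 1
      }
      if (gam > 0) step[p + 1] <- step[p + 1] * exp(gam * (a - 0.3))
    }
    if (has_pi) {
      j <- p + n_extra
      prop <- lpi + stats::rnorm(1, 0, step[j])
      pip <- stats::plogis(prop)
      llp <- sum(loglik_eta(spec$family, y, eta, k, pip))
      la <- llp - llsum +
        log(pip * (1 - pip)) - log(pi * (1 - pi))  # uniform prior + Jacobian
      a <- min(1, exp(la))
      if (is.finite(la) && stats::runif(1) < a) {
        lpi <- prop; pi <- pip; llsum <- llp
        acc[j] <- acc[j] + 1
      }
      if (gam > 0) step[j] <- step[j] * exp(gam * (a - 0.3))
    }
    if (it > cfg$burnin) {
      i <- it - cfg$burnin
      draws[i, ] <- c(beta, if (has_k) k, if (has_pi) pi)
      ll_out[i] <- llsum
    }
  }
  list(draws = draws, loglik = ll_out,
       accept = stats::setNames(acc / cfg$iterations, nm))
}

#' Deviance information criterion of a fitted count model
#'
#' `DIC = Dbar + pD` with `D = -2 log L`, `Dbar` the posterior mean
#' deviance and, by default, `pD = Dbar - D(theta_bar)` evaluated at the
#' posterior mean of the parameters (Spiegelhalter form). The half-variance
#' alternative `pD = var(D)/2` is available via `pd_form`.
#'
#' @param samples a `posterior_samples`.
#' @param spec,design,y the model inputs used for the fit.
#' @param pd_form `"spiegelhalter"` or `"variance"`.
#' @return list with `dic`, `pd`, `dbar`, `dhat`.
#' @export
compute_dic <- function(samples, spec, design, y,
                        pd_form = c("spiegelhalter", "variance")) {
  pd_form <- match.arg(pd_form)
  X <- design_matrix(design, spec$terms)
  dbar <- mean(-2 * samples$loglik)
  bcols <- colnames(X)
  beta_bar <- colMeans(samples$draws[, bcols, drop = FALSE])
  k_bar <- if ("k" %in% colnames(samples$draws))
    mean(samples$draws[, "k"]) else NULL
  pi_bar <- if ("pi" %in% colnames(samples$draws))
    mean(samples$draws[, "pi"]) else NULL
  eta <- drop(X %*% beta_bar)
  dhat <- -2 * sum(loglik_eta(spec$family, y, eta, k_bar, pi_bar))
  if (!is.finite(dhat)) stop("deviance at the posterior mean is not finite")
  pd <- if (pd_form == "spiegelhalter") dbar - dhat
  else stats::var(-2 * samples$loglik) / 2
  list(dic = dbar + pd, pd = pd, dbar = dbar, dhat = dhat)
}

#' Split-chain potential scale reduction factor
#'
#' Each chain is split in half and the standard between/within-variance
#' ratio computed per parameter. Values near 1 indicate mixing; a constant
#' parameter yields `NA` rather than an error.
#'
#' @param samples a `posterior_samples` (>= 2 chains).
#' @return Named numeric vector of R-hat values.
#' @export
rhat <- function(samples) {
  ch <- samples$chain
  if (length(unique(ch)) < 2) stop("rhat requires at least 2 chains")
  vapply(colnames(samples$draws), function(pm) {
    x <- samples$draws[, pm]
    halves <- list()
    for (c0 in unique(ch)) {
      v <- x[ch == c0]
      h <- length(v) %/% 2
      halves <- c(halves, list(v[seq_len(h)], v[h + seq_len(h)]))
    }
    n <- min(lengths(halves))
    halves <- lapply(halves, function(v) v[seq_len(n)])
    m <- length(halves)
    means <- vapply(halves, mean, 0)
    vars <- vapply(halves, stats::var, 0)
    W <- mean(vars)
    B <- n * stats::var(means)
    if (!is.finite(W) || W == 0) return(NA_real_)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, 0)
}

#' Maximum-likelihood Poisson / negative-binomial GLM with AIC
#'
#' Thin wrapper over [stats::glm()] and [MASS::glm.nb()] (whose AIC counts
#' the dispersion parameter). Used for the preliminary geographic-predictor
#' screen and the Poisson-vs-NB form comparison.
#'
#' @param family `"poisson"` or `"negbin"`.
#' @param design design data.frame.
#' @param y response.
#' @param terms design columns; empty for intercept-only.
#' @return list with `coefficients`, `aic`, `family`, `fit`.
#' @export
fit_glm_ml <- function(family = c("poisson", "negbin"), design, y,
                       terms = character()) {
  family <- match.arg(family)
  dat <- if (length(terms)) cbind(.y = y, design[terms])
  else data.frame(.y = y)
  fml <- stats::as.formula(
    paste(".y ~", if (length(terms))
      paste(sprintf("`%s`", terms), collapse = " + ") else "1"))
  fit <- if (family == "poisson")
    stats::glm(fml, data = dat, family = stats::poisson())
  else MASS::glm.nb(fml, data = dat)
  if (!fit$converged && family == "poisson")
    warning("GLM did not converge (possible separation or singular design)")
  list(coefficients = stats::coef(fit), aic = stats::AIC(fit),
       family = family, fit = fit)
}

#' All-subsets AIC screen of candidate terms
#'
#' Fits every subset of the candidate terms up to `max_terms` predictors
#' (including the empty model), ranks them by AIC, and reports the
#' competitive set with delta AIC < 2. Quadratic columns are treated as
#' independent candidates (a model may carry `latitude_sq` without
#' `latitude`).
#'
#' @param candidate_terms character vector of design columns (<= 20).
#' @param design,y data.
#' @param family `"poisson"` or `"negbin"`.
#' @param max_terms maximum predictors per candidate model.
#' @return list with `table` (data.frame: `model`, `n_terms`, `aic`,
#'   `delta`, AIC-sorted), `best` (list of term vectors with delta < 2),
#'   `top` (term vector of the single best model).
#' @export
dredge_terms <- function(candidate_terms, design, y,
                         family = "poisson", max_terms = 4) {
  if (length(candidate_terms) > 20)
    stop("more than 20 candidate terms; refusing the combinatorial blow-up")
  subsets <- list(character())
  for (k in seq_len(min(max_terms, length(candidate_terms))))
    subsets <- c(subsets, utils::combn(candidate_terms, k, simplify = FALSE))
  aic <- vapply(subsets, function(tr)
    fit_glm_ml(family, design, y, tr)$aic, 0)
  ord <- order(aic)
  tab <- data.frame(
    model = vapply(subsets, function(tr)
      if (length(tr)) paste(tr, collapse = " + ") else "(intercept only)", ""),
    n_terms = lengths(subsets), aic = aic)[ord, ]
  tab$delta <- tab$aic - tab$aic[1]
  rownames(tab) <- NULL
  list(table = tab, best = subsets[ord][tab$delta < 2],
       top = subsets[[ord[1]]])
}

#' Serialize posterior samples to CSV + JSON metadata
#'
#' @param samples a `posterior_samples`.
#' @param path CSV path for the draw matrix; metadata goes to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_posterior <- function(samples, path) {
  utils::write.csv(
    data.frame(chain = samples$chain, samples$draws, check.names = FALSE),
    path, row.names = FALSE)
  jsonlite::write_json(
    list(family = samples$spec$family, terms = samples$spec$terms,
         priors = samples$spec$priors,
         chains = samples$cfg$chains, iterations = samples$cfg$iterations,
         burnin = samples$cfg$burnin, accept = as.list(samples$accept)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
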