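# Shared fixtures: small designs and independent oracles, built in code.

# multi-scale design: one covariate measured at K radii with controlled
# inter-scale correlation rho (standardized columns)
gen_multiscale_design <- function(seed, n = 800, rho = 0.6,
                                  radii = c(400, 1600, 6400),
                                  covariate = "alan") {
  set.seed(seed)
  K <- length(radii)
  R <- matrix(rho, K, K)
  diag(R) <- 1
  X <- matrix(stats::rnorm(n * K), n, K) %*% chol(R)
  d <- as.data.frame(X)
  names(d) <- paste(covariate, radii, sep = "_")
  standardize_design(d)
}

# two correlated landscape covariates at one shared scale plus a temporal
# covariate; the shape of the final-abundance fitting problem
gen_abundance_design <- function(seed, n = 400, rho = 0.6) {
  set.seed(seed)
  z <- matrix(stats::rnorm(n * 2), n, 2) %*%
    chol(matrix(c(1, rho, rho, 1), 2))
  d <- data.frame(alan_1600 = z[, 1], urban_1600 = z[, 2],
                  sun_angle = stats::rnorm(n))
  standardize_design(d)
}

# deterministic 1-D quadrature over the posterior of a Poisson
# intercept-only model with the package's default Normal(0, 2.5^2) prior;
# independent oracle for the MCMC engine
quadrature_poisson_intercept <- function(y, lo = -4, hi = 4, m = 8001) {
  g <- seq(lo, hi, length.out = m)
  lp <- vapply(g, function(b)
    sum(stats::dpois(y, exp(b), log = TRUE)) +
      stats::dnorm(b, 0, 2.5, log = TRUE), 0)
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  list(mean = sum(g * w), sd = sqrt(sum(g^2 * w) - sum(g * w)^2))
}

# Monte-Carlo standard error of a chain mean by consecutive batch means,
# respecting chain boundaries
batch_mean_se <- function(x, chain, batches_per_chain = 30) {
  bm <- unlist(lapply(unique(chain), function(c0) {
    v <- x[chain == c0]
    nb <- batches_per_chain
    tapply(v, rep(seq_len(nb), each = ceiling(length(v) / nb),
                  length.out = length(v)), mean)
  }))
  stats::sd(bm) / sqrt(length(bm))
}

# tiny degenerate posterior for the prediction/summary functions
degenerate_fit <- function(b0 = 0, b_alan = 0, b_urban = NULL,
                           b_int = NULL, k = 2, n_draws = 1) {
  cols <- c("(Intercept)" = b0, alan = b_alan)
  if (!is.null(b_urban)) cols <- c(cols, urban = b_urban)
  if (!is.null(b_int)) cols <- c(cols, alan_x_urban = b_int)
  cols <- c(cols, k = k)
  draws <- matrix(rep(cols, each = n_draws), nrow = n_draws,
                  dimnames = list(NULL, names(cols)))
  as_abundance_fit(draws, alan_col = "alan",
                   urban_col = if (!is.null(b_urban)) "urban",
                   interaction_col = if (!is.null(b_int)) "alan_x_urban")
}
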