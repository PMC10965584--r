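test_that("conditional ALAN caps follow the nearest-rank rule", {
  d <- data.frame(alan_1600 = as.numeric(1:100),
                  urban_1600 = rep(c(0.1, 0.9), each = 50))
  attr(d, "scaling") <- data.frame(column = c("alan_1600", "urban_1600"),
                                   mean = 0, sd = 1)
  fit <- degenerate_fit(b_alan = -0.1, b_urban = 0.1)
  fit$design <- d
  fit$alan_col <- "alan_1600"
  fit$urban_col <- "urban_1600"
  fit$scaling <- attr(d, "scaling")
  # urban <= 0.5 keeps values 1..50: 99th percentile nearest-rank = 50
  expect_equal(alan_cap(fit, 0.5), 50)
  # qualifying values 1..100 -> 99
  expect_equal(alan_cap(fit, 1), 99)
  # all-zero qualifying ALAN -> 0
  d0 <- d
  d0$alan_1600 <- 0
  fit$design <- d0
  expect_equal(alan_cap(fit, 1), 0)
  # non-decreasing in the urban level
  fit$design <- d
  caps <- vapply(c(0.1, 0.5, 1), function(u) alan_cap(fit, u), 0)
  expect_true(all(diff(caps) >= 0))
  expect_error(alan_cap(fit, -5), "no surveys")
})

test_that("prediction curves reduce to closed forms on degenerate draws", {
  # all slopes zero in every draw: flat curve at mean(exp(intercept))
  set.seed(1)
  b0s <- rnorm(200, 0.3, 0.2)
  draws <- cbind("(Intercept)" = b0s, alan = 0, k = 2)
  fit <- as_abundance_fit(draws, alan_col = "alan")
  pc <- predict_curve(fit, alan_grid = c(0, 1, 2))
  expect_equal(pc$mean, rep(mean(exp(b0s)), 3))
  expect_true(all(pc$lo <= pc$mean & pc$mean <= pc$hi))
  # single draw: mean = exp(eta), zero-width interval
  f1 <- degenerate_fit(b0 = 0.5, b_alan = -0.2)
  p1 <- predict_curve(f1, alan_grid = c(0, 1))
  expect_equal(p1$mean, exp(0.5 - 0.2 * c(0, 1)))
  expect_equal(p1$lo, p1$hi)
  # negative ALAN coefficient in all draws, no interaction: decreasing
  set.seed(2)
  dr <- cbind("(Intercept)" = rnorm(100), alan = -abs(rnorm(100, 0.3, 0.1)),
              k = 2)
  f2 <- as_abundance_fit(dr, alan_col = "alan")
  p2 <- predict_curve(f2, alan_grid = seq(0, 3, by = 0.5))
  expect_true(all(diff(p2$mean) < 0))
  # cap enforcement
  expect_error(predict_curve(f1, alan_grid = c(0, 5), cap = 2), "cap")
  expect_silent(predict_curve(f1, alan_grid = c(0, 5), cap = 2,
                              force = TRUE))
})

test_that("percent change matches hand-computed posterior summaries", {
  # identical endpoints: exactly zero with a zero-width interval
  f <- degenerate_fit(b_alan = -0.32)
  pc0 <- percent_change(f, 1.0, 1.0)
  expect_equal(pc0$mean, 0)
  expect_equal(pc0$lo, 0)
  expect_equal(pc0$hi, 0)
  # degenerate posterior carrying the published poorwill ALAN coefficient
  # over the printed ALAN range: 100*(exp(-0.32*1.23)-1)
  pc <- percent_change(f, 0, 1.23)
  expect_equal(pc$mean, 100 * (exp(-0.32 * 1.23) - 1), tolerance = 1e-10)
  # two-draw posterior: mean of per-draw ratios, not ratio of means
  dr <- cbind("(Intercept)" = c(0, 0), alan = c(-0.2, -0.4), k = c(2, 2))
  f2 <- as_abundance_fit(dr, alan_col = "alan")
  pc2 <- percent_change(f2, 0, 1)
  expect_equal(pc2$mean, 100 * ((exp(-0.2) + exp(-0.4)) / 2 - 1))
  # invariance to standardization constants (natural-unit contract)
  sc <- data.frame(column = "alan", mean = 3, sd = 2.5)
  f3 <- as_abundance_fit(cbind("(Intercept)" = 0, alan = -0.32 * 2.5,
                               k = 2),
                         alan_col = "alan", scaling = sc)
  pc3 <- percent_change(f3, 0, 1.23)
  expect_equal(pc3$mean, pc$mean, tolerance = 1e-10)
})

test_that("the interaction sign-switch threshold is the coefficient ratio", {
  f <- degenerate_fit(b_alan = 0.2, b_urban = 0.1, b_int = -1.0)
  sw <- sign_switch(f)
  expect_equal(sw$mean, 0.2)
  expect_equal(sw$lo, 0.2)
  # beta_ALAN = 0 in all draws: threshold exactly 0
  f0 <- degenerate_fit(b_alan = 0, b_urban = 0.1, b_int = -1.0)
  expect_equal(sign_switch(f0)$mean, 0)
  # interaction-free fit is a typed error, never a number
  expect_error(sign_switch(degenerate_fit(b_alan = -0.3)), "interaction")
  # standardized-to-natural mapping
  sc <- data.frame(column = c("alan", "urban", "alan_x_urban"),
                   mean = c(0, 0.10, 0), sd = c(1, 0.2, 1))
  fz <- as_abundance_fit(cbind("(Intercept)" = 0, alan = 0.5, urban = 0,
                               alan_x_urban = -1, k = 2),
                         alan_col = "alan", urban_col = "urban",
                         interaction_col = "alan_x_urban", scaling = sc)
  expect_equal(sign_switch(fz)$mean, 0.10 + 0.2 * 0.5)
})

test_that("posterior coefficient correlations flag collinear pairs", {
  set.seed(4)
  x <- rnorm(27000)
  draws <- cbind(a = x, b = rnorm(27000), c = -x)
  f <- as_abundance_fit(cbind("(Intercept)" = 0, draws, k = 1))
  out <- posterior_coef_correlation(f, list(c("a", "b")))
  expect_lt(abs(out$r), 0.05)
  expect_equal(suppressMessages(
    posterior_coef_correlation(f, list(c("a", "a"))))$r, 1)
  expect_message(
    out2 <- posterior_coef_correlation(f, list(c("a", "c"))),
    "multicollinearity")
  expect_equal(out2$r, -1)
  expect_true(out2$advisory)
  expect_error(posterior_coef_correlation(f, list(c("a", "zzz"))),
               "unknown parameter")
})

test_that("final fits recover generating coefficients and support refits", {
  d <- gen_abundance_design(21, n = 400)
  d$station_id <- rep(sprintf("S%02d", 1:40), each = 10)
  tr <- true_params(intercept = log(1.5), coefs = list(
    alan = list(beta = -0.3, scale = 1600),
    urban = list(beta = 0.3, scale = 1600)),
    interaction = list(beta = -0.25, scale_alan = 1600, scale_urban = 1600),
    temporal = c(sun_angle = 0.15), dispersion = 2)
  tab <- simulate_counts(d, tr, seed = 22)
  cc <- chain_config(3, 1500, 500, seed = 7)
  fit <- fit_final(d, tab$count_true,
                   terms = c("alan_1600", "urban_1600", "sun_angle"),
                   alan_col = "alan_1600", urban_col = "urban_1600",
                   interaction = TRUE, cfg = cc)
  expect_s3_class(fit, "abundance_fit")
  expect_true("k" %in% colnames(fit$samples$draws))
  truth <- c("(Intercept)" = log(1.5), alan_1600 = -0.3, urban_1600 = 0.3,
             sun_angle = 0.15, alan_1600_x_urban_1600 = -0.25)
  rep <- recovery_report(fit, truth)
  expect_gte(rep$coverage, 3 / 5)
  # interaction-free variant drops exactly one coefficient
  fit0 <- fit_final(d, tab$count_true,
                    terms = c("alan_1600", "urban_1600", "sun_angle"),
                    alan_col = "alan_1600", urban_col = "urban_1600",
                    interaction = FALSE, cfg = cc)
  expect_equal(ncol(fit$samples$draws) - ncol(fit0$samples$draws), 1)
  # determinism of the DIC under an identical refit
  fit_b <- fit_final(d, tab$count_true,
                     terms = c("alan_1600", "urban_1600", "sun_angle"),
                     alan_col = "alan_1600", urban_col = "urban_1600",
                     interaction = TRUE, cfg = cc)
  expect_equal(fit$dic$dic, fit_b$dic$dic)
  # duplicate columns rejected
  expect_error(fit_final(d, tab$count_true,
                         terms = c("alan_1600", "alan_1600"), cfg = cc),
               "duplicate")

  # dropping stations: a no-op drop reproduces the fit; survey accounting
  drop2 <- drop_stations_refit(fit, c("S01", "S02"))
  expect_equal(drop2$n_removed, 20)
  expect_equal(nrow(drop2$fit$design), 380)
  drop0 <- drop_stations_refit(fit, character())
  expect_equal(max(abs(drop0$deltas$delta)), 0)
  expect_error(drop_stations_refit(fit, "S99"), "unknown")
})

test_that("dual-scale fits decompose a shared-column effect", {
  # identical columns at both scales: the coefficient sum matches the
  # single-column coefficient (reparameterization identity)
  set.seed(31)
  n <- 300
  x <- rnorm(n)
  d <- data.frame(alan_1600 = x, alan_6400 = x, other = rnorm(n))
  attr(d, "scaling") <- data.frame(column = names(d), mean = 0, sd = 1)
  y <- rpois(n, exp(0.4 + 0.5 * x))
  cc <- chain_config(3, 1500, 500, seed = 3)
  dual <- dual_scale_marginal(d, y, "alan", c(1600, 6400),
                              other_terms = "other", cfg = cc)
  single <- fit_final(d, y, terms = c("alan_1600", "other"), cfg = cc)
  sum_means <- sum(dual$summary$mean)
  single_mean <- coef_summary(single)$mean[2]
  expect_equal(sum_means, single_mean, tolerance = 0.1)
  # the filter contract
  d2 <- gen_multiscale_design(32, n = 200)
  y2 <- rpois(200, 1.5)
  flt <- dual_scale_marginal(d2, y2, "alan", c(1600, 6400),
                             filter = d2$alan_400 < 0,
                             cfg = chain_config(2, 400, 100, seed = 1))
  expect_true(all(flt$fit$design$alan_400 < 0))
  expect_error(dual_scale_marginal(d2, y2, "alan", c(1600, 6400),
                                   filter = rep(FALSE, 200)),
               "every survey")
})
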