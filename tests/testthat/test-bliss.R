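test_that("single-radius BLISS degenerates to the fixed-scale fit", {
  d <- gen_multiscale_design(1, n = 200, radii = 1600)
  tr <- true_params(intercept = log(2), coefs = list(
    alan = list(beta = 0.4, scale = 1600)), dispersion = 2)
  tab <- simulate_counts(d, tr, seed = 2)
  cc <- chain_config(3, 1500, 500, seed = 4)
  bs <- bliss_spec(multiscale_terms("alan", 1600))
  post_b <- run_bliss(bs, d, tab$count_true, cc)
  post_m <- run_mcmc(model_spec("negbin", "alan_1600"), d, tab$count_true, cc)
  expect_true(all(post_b$indicators == "1600"))
  # subsample to near-independent draws before the distributional test
  # (KS assumes independence; raw MCMC draws are autocorrelated)
  idx <- seq(1, nrow(post_b$draws), by = 15)
  ks <- suppressWarnings(
    stats::ks.test(post_b$draws[idx, "alan"], post_m$draws[idx, "alan_1600"]))
  expect_gt(ks$p.value, 0.01)
})

test_that("indicator draw accounting matches the chain configuration", {
  d <- gen_multiscale_design(2, n = 120)
  tr <- true_params(intercept = log(2), coefs = list(
    alan = list(beta = 0.4, scale = 1600)), dispersion = 2)
  tab <- simulate_counts(d, tr, seed = 3)
  cc <- chain_config(3, 300, 100, seed = 5)
  post <- run_bliss(bliss_spec(multiscale_terms("alan", c(400, 1600, 6400))),
                    d, tab$count_true, cc)
  expect_equal(nrow(post$indicators), cc$retained)
  expect_equal(nrow(post$draws), cc$retained)
  # proportions normalize per covariate
  props <- scale_selection_table(post)
  expect_equal(sum(as.numeric(props[1, -1])), 1, tolerance = 1e-12)
})

test_that("modal-scale selection applies the argmax and tie rules", {
  fake <- structure(list(
    proportions = data.frame(covariate = c("alan", "urban", "single"),
                             "400" = c(0.1, 0.5, 1), "1600" = c(0.2, 0.5, 0),
                             "6400" = c(0.7, 0, 0), check.names = FALSE),
    indicators = NULL, radii = c("400", "1600", "6400")),
    class = c("bliss_posterior", "posterior_samples"))
  expect_equal(select_scale(fake, "alan"), 6400)
  expect_warning(s <- select_scale(fake, "urban"), "tie")
  expect_equal(s, 400)
  expect_equal(select_scale(fake, "single"), 400)
  expect_error(select_scale(fake, "nope"), "unknown")
})

test_that("sign conflicts across scales are flagged by the interval rule", {
  mk <- function(means, n_each = 500, sd = 0.05) {
    draws <- cbind(alan = unlist(lapply(means, function(m)
      stats::rnorm(n_each, m, sd))))
    ind <- cbind(alan = rep(c("400", "6400"), each = n_each))
    structure(list(draws = draws, indicators = ind,
                   radii = c("400", "1600", "6400")),
              class = c("bliss_posterior", "posterior_samples"))
  }
  set.seed(6)
  conflicted <- sign_conflict(mk(c(0.4, -0.4)), "alan")
  expect_true(conflicted$flag)
  agreeing <- sign_conflict(mk(c(0.4, 0.6)), "alan")
  expect_false(agreeing$flag)
  # the under-sampled middle scale is skipped with a note, not an error
  expect_true(any(conflicted$table$skipped))
  # opposite-sign local/landscape urban effects (the territorial-nighthawk
  # configuration) flag on constructed draws
  set.seed(7)
  urb <- mk(c(-0.6, 0.5))
  colnames(urb$draws) <- "urban"
  colnames(urb$indicators) <- "urban"
  expect_true(sign_conflict(urb, "urban")$flag)
})

test_that("scale selection recovers the generating radius", {
  # single-seed smoke check; the 10-replicate version is an acceptance run
  d <- gen_multiscale_design(3, n = 800, rho = 0.6)
  tr <- true_params(intercept = log(1.5), coefs = list(
    alan = list(beta = 0.5, scale = 1600)), dispersion = 2)
  tab <- simulate_counts(d, tr, seed = 103)
  post <- run_bliss(bliss_spec(multiscale_terms("alan", c(400, 1600, 6400))),
                    d, tab$count_true, chain_config(3, 1000, 300, seed = 3))
  expect_equal(select_scale(post, "alan"), 1600)
})

test_that("permuting the radius order permutes selection proportions", {
  d <- gen_multiscale_design(4, n = 300, rho = 0.5)
  tr <- true_params(intercept = log(2), coefs = list(
    alan = list(beta = 0.4, scale = 1600)), dispersion = 2)
  tab <- simulate_counts(d, tr, seed = 9)
  cc <- chain_config(2, 600, 200, seed = 8)
  fwd <- multiscale_terms("alan", c(400, 1600, 6400))
  rev_ms <- list(alan = rev(fwd$alan))
  p1 <- run_bliss(bliss_spec(fwd), d, tab$count_true, cc)$proportions
  p2 <- run_bliss(bliss_spec(rev_ms), d, tab$count_true, cc)$proportions
  # same sampler randomness, mirrored labels: proportions agree closely
  expect_equal(as.numeric(p1[1, c("400", "1600", "6400")]),
               as.numeric(p2[1, c("400", "1600", "6400")]),
               tolerance = 0.05)
})

test_that("interaction parents carry their own scale indicators", {
  set.seed(10)
  n <- 400
  z <- matrix(rnorm(n * 6), n, 6)
  d <- as.data.frame(z)
  names(d) <- c(paste("alan", c(400, 1600, 6400), sep = "_"),
                paste("urban", c(400, 1600, 6400), sep = "_"))
  d <- standardize_design(d)
  tr <- true_params(intercept = log(2), coefs = list(
    alan = list(beta = 0.3, scale = 1600),
    urban = list(beta = 0.3, scale = 6400)),
    interaction = list(beta = -0.4, scale_alan = 1600, scale_urban = 1600),
    dispersion = 2)
  tab <- simulate_counts(d, tr, seed = 11)
  bs <- bliss_spec(multiscale_terms(c("alan", "urban"), c(400, 1600, 6400)),
                   interaction = c("alan", "urban"))
  post <- run_bliss(bs, d, tab$count_true, chain_config(2, 800, 300, seed = 1))
  expect_setequal(colnames(post$indicators),
                  c("alan", "urban", "int.alan", "int.urban"))
  expect_equal(nrow(post$proportions), 4)
})

test_that("focal refits hold non-focal covariates at fixed scales", {
  d <- gen_multiscale_design(5, n = 300)
  d2 <- gen_multiscale_design(6, n = 300, covariate = "urban")
  d <- standardize_design(cbind(d, d2))
  tr <- true_params(intercept = log(2), coefs = list(
    alan = list(beta = 0.4, scale = 1600),
    urban = list(beta = -0.3, scale = 6400)), dispersion = 2)
  tab <- simulate_counts(d, tr, seed = 12)
  bs <- bliss_spec(multiscale_terms(c("alan", "urban"), c(400, 1600, 6400)))
  cc <- chain_config(2, 600, 200, seed = 2)
  post <- refit_focal(bs, d, tab$count_true, cc, focal = "alan",
                      fixed_scales = c(urban = "6400"))
  expect_true(all(post$indicators[, "urban"] == "6400"))
  expect_gt(length(unique(post$indicators[, "alan"])), 0)
  expect_error(
    refit_focal(bs, d, tab$count_true, cc, focal = "alan"),
    "missing fixed scale")
  # all-focal refit has the run_bliss contract
  post_all <- refit_focal(bs, d, tab$count_true, cc,
                          focal = c("alan", "urban"))
  expect_equal(nrow(post_all$draws), cc$retained)
})

test_that("spec validation rejects inconsistent radius sets", {
  bad <- list(alan = c("400" = "alan_400", "1600" = "alan_1600"),
              urban = c("400" = "urban_400"))
  expect_error(bliss_spec(bad), "radius sets differ")
  expect_error(
    bliss_spec(multiscale_terms("alan", c(100, 200, 400, 800))),
    "radii")
  expect_error(
    bliss_spec(multiscale_terms("alan", c(400, 1600)),
               interaction = c("alan", "urban")),
    "interaction parents")
})
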