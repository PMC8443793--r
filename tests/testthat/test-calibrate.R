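test_that("urinary deposition rates from voids", {
  ur <- data.frame(time = c(2, 4), volume = c(200, 100),
                   conc_OH = c(0.5, 0.2), conc_cx = c(0, 0.1))
  r <- urine_rates(ur)
  expect_equal(r$rate_OH[1], 0.05)       # 0.5 mg/L * 0.2 L / 2 h
  expect_equal(r$rate_cx[1], 0)
  expect_equal(r$rate_cx[2], 0.1 * 0.1 / 2)
  ## merging two consecutive voids conserves the excreted mass
  merged <- data.frame(time = 4, volume = 300,
                       conc_OH = (0.5 * 200 + 0.2 * 100) / 300,
                       conc_cx = (0 * 200 + 0.1 * 100) / 300)
  rm_ <- urine_rates(merged)
  expect_equal(rm_$rate_OH * 4, sum(r$rate_OH * diff(c(0, r$time))))
  expect_error(urine_rates(data.frame(time = c(3, 2), volume = c(1, 1),
                                      conc_OH = 0, conc_cx = 0)),
               "increasing")
  expect_error(urine_rates(data.frame(time = c(1, 2), volume = c(0, 1),
                                      conc_OH = 0, conc_cx = 0)), "> 0")
})

test_that("zero-truncated normal log-density matches the closed form", {
  ld <- dphpk:::.ztnorm_logdens
  expect_equal(ld(1, 1, 1), -0.5 * log(2 * pi) - log(1 - pnorm(-1)),
               tolerance = 1e-12)
  expect_equal(ld(1, 1, 1), -0.7462, tolerance = 1e-4)
  ## flat improper tail: density -> 0 as sigma grows
  expect_lt(ld(1, 1, 1e6), ld(1, 1, 1))
  ## truncation renormalises: integrates to one over [0, Inf)
  f <- function(y) exp(sapply(y, ld, mu = 0.3, sigma = 0.7))
  expect_equal(integrate(f, 0, Inf)$value, 1, tolerance = 1e-6)
})

test_that("log-likelihood is additive over subjects and streams", {
  ds <- small_dataset()
  sig <- c(OH = 0.01, cx = 0.001, DPHP = 0.02, MPHP = 0.02)
  one <- ds; one$subjects <- ds$subjects[1]
  two <- ds; two$subjects <- ds$subjects[1:2]
  ll1 <- bm_log_likelihood(one, theta = small_truth, sigmas = sig)
  ll2 <- bm_log_likelihood(two, theta = small_truth, sigmas = sig)
  lld <- bm_log_likelihood(two, theta = small_truth, sigmas = sig) -
    bm_log_likelihood(one, theta = small_truth, sigmas = sig)
  ## duplicating a subject's data doubles its contribution exactly
  dup <- ds
  dup$subjects <- list(ds$subjects[[1]],
                       modifyList(ds$subjects[[1]], list(id = "A2")))
  lldup <- bm_log_likelihood(dup, theta = small_truth, sigmas = sig)
  expect_equal(lldup, 2 * ll1, tolerance = 1e-10)
  expect_equal(ll2, ll1 + (ll2 - ll1))
  expect_equal(lld, ll2 - ll1)
  ## excluded subjects do not contribute
  onex <- two
  onex$subjects[[2]]$exclude <- TRUE
  expect_equal(bm_log_likelihood(onex, theta = small_truth, sigmas = sig),
               ll1)
})

test_that("with the likelihood disabled the sampler reproduces the prior", {
  spec <- calibration_spec(global = c("K1_MOH", "FracMetabOH"),
                           subject = character())
  ds <- small_dataset()
  ps <- mcmc_calibrate(spec, ds, iterations = 30000, thin = 15, seed = 8,
                       use_likelihood = FALSE)
  d <- dphpk:::.post_draws(ps)
  pk <- ps$spec$priors[ps$spec$priors$name == "K1_MOH", ]
  ## Kolmogorov-Smirnov against the uniform prior marginal
  ks <- suppressWarnings(
    ks.test(d[, "K1_MOH|global"], "punif", pk$lower, pk$upper))
  expect_gt(ks$p.value, 0.01)
  fm <- ps$spec$priors[ps$spec$priors$name == "FracMetabOH", ]
  ks2 <- suppressWarnings(
    ks.test(d[, "FracMetabOH|global"], "punif", fm$lower, fm$upper))
  expect_gt(ks2$p.value, 0.01)
})

test_that("zero iterations returns the initial state only", {
  spec <- calibration_spec(global = "K1_MOH", subject = character())
  ps <- mcmc_calibrate(spec, small_dataset(), iterations = 0,
                       use_likelihood = FALSE)
  expect_equal(nrow(ps$draws), 1)
  pk <- ps$spec$priors[1, ]
  expect_equal(ps$draws[1, "K1_MOH|global"],
               (pk$lower + pk$upper) / 2, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("posterior summaries: analytic quantiles and degenerate chains", {
  set.seed(1)
  draws <- cbind(z = rnorm(1e5), logpost = 0)
  ps <- structure(list(draws = draws, burn_in = 0, thin = 1),
                  class = "dphpk_posterior")
  sm <- posterior_summaries(ps)
  expect_equal(sm$median, 0, tolerance = 0.02)
  expect_equal(sm$lo2.5, -1.96, tolerance = 0.03)
  expect_equal(sm$hi97.5, 1.96, tolerance = 0.03)
  expect_equal(names(sm), c("parameter", "median", "lo2.5", "hi97.5"))
  ## constant chain collapses to a point
  psc <- structure(list(draws = cbind(z = rep(2, 200), logpost = 0),
                        burn_in = 0, thin = 1), class = "dphpk_posterior")
  smc <- posterior_summaries(psc)
  expect_equal(smc$lo2.5, smc$hi97.5)
  expect_equal(smc$median, 2)
})

test_that("global parameters are recovered from synthetic data", {
  ## truth at the published posterior medians for the calibrated subset;
  ## three subjects, short adaptive chain
  ds <- small_dataset()
  spec <- calibration_spec(
    global = c("K1_MOH", "K1_cx", "FracMetabOH", "FracMetabcx"),
    subject = character())
  ps <- mcmc_calibrate(spec, ds, iterations = 600, thin = 5, seed = 21)
  sm <- posterior_summaries(ps)
  for (g in spec$global) {
    row <- sm[sm$parameter == paste0(g, "|global"), ]
    rel <- abs(row$median - small_truth[[g]]) / small_truth[[g]]
    expect_lt(rel, 0.25)
  }
})

test_that("credible bands cover the central curve", {
  ds <- small_dataset()
  spec <- calibration_spec(global = c("K1_MOH", "FracMetabOH"),
                           subject = character())
  ps <- mcmc_calibrate(spec, ds, iterations = 200, thin = 5, seed = 4)
  subj <- ds$subjects[[1]]
  grid <- seq(0, 24, 1)
  band <- suppressWarnings(
    credible_band(ps, subj, "RUrineOH", grid = grid, n_draws = 20))
  expect_equal(nrow(band), length(grid))
  inside <- mean(band$centre >= band$lo - 1e-12 &
                   band$centre <= band$hi + 1e-12)
  expect_gte(inside, 0.9)
  ## a single draw collapses the band onto the curve
  ps1 <- ps
  ps1$draws <- ps1$draws[nrow(ps1$draws), , drop = FALSE]
  ps1$burn_in <- 0
  b1 <- suppressWarnings(credible_band(ps1, subj, "RUrineOH", grid = grid,
                                       n_draws = 1))
  expect_equal(b1$lo, b1$hi)
})

test_that("posterior writer emits draws and a summary table", {
  set.seed(2)
  ps <- structure(list(draws = cbind(`K1_MOH|global` = runif(120, 0.05, 0.15),
                                     logpost = rnorm(120)),
                       burn_in = 10, thin = 1),
                  class = "dphpk_posterior")
  dp <- tempfile(fileext = ".csv"); sp <- tempfile(fileext = ".csv")
  sm <- write_posterior(ps, dp, sp)
  back <- read.csv(sp)
  expect_equal(back$median, sm$median)
  expect_equal(nrow(read.csv(dp, check.names = FALSE)), 120)
})

test_that("calibration spec validation", {
  expect_error(calibration_spec(global = c("K1_MOH"), subject = c("K1_MOH")),
               "disjoint")
  expect_error(calibration_spec(global = "not_a_param",
                                subject = character()), "no prior")
})
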