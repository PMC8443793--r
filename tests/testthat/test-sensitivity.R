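test_that("prior sampling respects supports and truncation", {
  spec <- parameter_priors()
  d <- sample_priors(spec, 500, seed = 3)
  expect_equal(dim(d), c(500, nrow(spec)))
  for (j in seq_len(nrow(spec)))
    expect_true(all(d[, j] >= spec$lower[j] & d[, j] <= spec$upper[j]),
                info = spec$name[j])
  ## reproducibility is bit-for-bit
  expect_identical(sample_priors(spec, 500, seed = 3), d)
  expect_false(identical(sample_priors(spec, 500, seed = 4), d))
})

test_that("truncated-normal draws match the analytic truncated mean", {
  spec <- parameter_priors()
  bw <- spec[spec$name == "BW", ]
  d <- sample_priors(bw, 1e5, seed = 1)
  a <- (bw$lower - bw$par1) / bw$par2
  b <- (bw$upper - bw$par1) / bw$par2
  m_true <- bw$par1 + bw$par2 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  expect_equal(mean(d), m_true, tolerance = 0.005)
  expect_true(all(d >= bw$lower & d <= bw$upper))
})

test_that("maximin LHD: stratification, size, distance criterion", {
  spec <- parameter_priors()
  d <- lhd_maximin(spec, 200, seed = 1)
  expect_equal(nrow(d), 200)
  ## one point per equal-probability stratum in every dimension: check on
  ## uniform margins where strata are equal-width
  uni <- which(spec$dist == "uniform")[1:5]
  for (j in uni) {
    strat <- floor((d[, j] - spec$lower[j]) /
                     (spec$upper[j] - spec$lower[j]) * 200)
    expect_setequal(strat, 0:199)
  }
  expect_identical(lhd_maximin(spec, 200, seed = 1), d)

  ## the optimised design beats plain random LHD on min inter-point
  ## distance, on average over seeds (unit-cube uniforms so distances are
  ## comparable)
  us <- unit_spec(5)
  mind <- function(x) min(dist(x))
  gain <- sapply(1:10, function(s)
    mind(lhd_maximin(us, 40, seed = s)) -
      mind(sample_priors(us, 40, seed = s)))
  expect_gt(mean(gain), 0)
})

test_that("Morris design arithmetic and analytic elementary effects", {
  des <- morris_design(59, 5, seed = 1)
  expect_equal(nrow(des$X), 300)
  expect_true(all(des$X >= 0 & des$X <= 1))
  ## each trajectory perturbs every parameter exactly once
  expect_equal(as.vector(table(des$param[des$param > 0])), rep(5L, 59))

  ## linear function: mu* proportional to |coefficient|, sigma = 0,
  ## dummy parameter exactly zero
  f <- function(x) c(m = sum(c(3, 2, 1, 0) * x))
  m <- morris_screen(f, unit_spec(4), r = 6, seed = 2)
  expect_equal(m$n_runs, 30)
  expect_equal(unname(m$mu_star[, 1]), c(3, 2, 1, 0), tolerance = 1e-9)
  expect_equal(unname(m$sigma[, 1]), rep(0, 4), tolerance = 1e-9)
  ## constant metric warns and returns zeros
  expect_warning(m0 <- morris_screen(function(x) c(m = 1), unit_spec(3),
                                     r = 3, seed = 1), "constant")
  expect_true(all(m0$mu_star == 0))
})

test_that("retention rule keeps parameters within 0.2 of the max mu*", {
  m <- structure(list(mu_star = matrix(c(1, 0.85, 0.1), 3, 1,
                                       dimnames = list(c("a", "b", "c"), "m")),
                      sigma = matrix(0, 3, 1)),
                 class = "dphpk_morris")
  expect_equal(retain_parameters(m, 0.2), c("a", "b"))
  ## union across metrics contains each per-metric set
  m2 <- m
  m2$mu_star <- cbind(m$mu_star, m2 = c(0.1, 0.2, 1))
  expect_setequal(retain_parameters(m2, 0.2), c("a", "b", "c"))
})

test_that("eFAST design arithmetic, dummy parameter, analytic indices", {
  expect_equal(efast_design(31, 1000, seed = 1)$n_runs, 31000)
  expect_error(efast_design(5, 20), "at least")
  fq <- function(x) c(m = sum(c(2, 1, 0.5) * (x[1:3] - 0.5)^2))
  e <- efast(fq, unit_spec(4), n_per_param = 257, seed = 3)
  expect_equal(e$n_runs, 4 * 257)
  ## analytic first-order shares for an additive quadratic: a_i^2 / sum
  shares <- c(4, 1, 0.25, 0) / 5.25
  expect_equal(unname(e$Si[, 1]), shares, tolerance = 0.05)
  expect_lt(abs(sum(e$Si[, 1]) - 1), 0.05)
  ## additive: total indices match first-order; dummy is inert
  expect_equal(unname(e$STi[, 1]), unname(e$Si[, 1]), tolerance = 0.05)
  expect_lt(e$Si[4, 1], 0.01)
  ## ordering invariant
  expect_true(all(e$STi >= e$Si - 0.02))
})

test_that("batch execution is deterministic and flags spiked rows", {
  spec <- parameter_priors()
  base <- default_parameters()
  scen <- exposure_scenario(0.738, t_end = 30, dt = 0.25)
  d <- sample_priors(spec, 6, seed = 9)
  ## identical rows give identical metrics
  d2 <- d[rep(1, 3), , drop = FALSE]
  b2 <- run_batch(d2, scen, base)
  expect_true(all(b2$ok))
  expect_equal(b2$metrics[1, ], b2$metrics[2, ])
  expect_equal(b2$metrics[1, ], b2$metrics[3, ])
  ## zeroing a row's hepatic dose fraction sends its urinary metrics to
  ## the bottom of the batch
  d[3, "FracDOSEHep"] <- 1e-9
  b <- run_batch(d, scen, base)
  expect_true(all(b$ok))
  expect_lt(max(abs(b$balance), na.rm = TRUE), 1e-6)
  expect_equal(which.min(b$metrics[, "RUrineOH_t12"]), 3L)
})

test_that("plasma-binding fractions dominate blood-concentration metrics", {
  ## reduced-size Morris screen over the full 59-parameter registry
  spec <- parameter_priors()
  scen <- exposure_scenario(0.738, t_end = 20, dt = 0.25)
  fun <- pbpk_metric_fun(default_parameters(), scen)
  m <- morris_screen(fun, spec, r = 4, seed = 1)
  ## each chemical's binding fraction sits in the top three of 59
  ## parameters for that chemical's late blood metrics (ties-in-noise
  ## allowance at this reduced design size)
  expect_lte(rank(-m$mu_star[, "CBloodDPHP_t12"])[["fuDPHP"]], 3)
  expect_lte(rank(-m$mu_star[, "MplasmaDPHP_peak"])[["fuDPHP"]], 3)
  expect_lte(rank(-m$mu_star[, "CBloodMPHP_t12"])[["fuMPHP"]], 3)
  expect_lte(rank(-m$mu_star[, "MplasmaMPHP_peak"])[["fuMPHP"]], 3)
})

test_that("dose fractionation and metabolite fate dominate urinary metrics", {
  ## eFAST on a small retained-style set over urinary outputs
  spec <- parameter_priors()
  keep <- c("FracDOSEHep", "FracMetabOH", "FracMetabcx", "K1_MOH", "K1_cx",
            "BW", "QCC", "PguM")
  sub <- spec[match(keep, spec$name), ]
  scen <- exposure_scenario(0.738, t_end = 25, dt = 0.25)
  fun <- pbpk_metric_fun(default_parameters(), scen)
  e <- efast(fun, sub, n_per_param = 65, seed = 6)
  for (met in c("RUrineOH_t12", "RUrinecx_t12")) {
    top4 <- names(sort(e$STi[, met], decreasing = TRUE))[1:4]
    expect_in("FracDOSEHep", top4)
    expect_true(any(c("FracMetabOH", "FracMetabcx") %in% top4),
                info = met)
  }
  expect_true(all(e$STi >= e$Si - 0.05, na.rm = TRUE))
})
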