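test_that("subject construction: volumes, allometry, validation", {
  p <- build_subject(default_parameters(), exposure_scenario(0.717))
  expect_equal(p$derived[["Vli"]], 0.0309 * 72.3, tolerance = 1e-12)
  expect_equal(p$derived[["QC"]], 14 * 72.3^0.75, tolerance = 1e-12)
  ## flows renormalised: perfusion + shunt equals cardiac output
  pv <- p$derived
  expect_equal(pv[["Qfa"]] + pv[["Qspd"]] + pv[["Qrpd"]] + pv[["Qgu"]] +
                 pv[["QHe"]] + pv[["Qshunt"]], pv[["QC"]])
  ## BW doubling: volumes x2, flows x2^0.75
  p2 <- build_subject(default_parameters(list(BW = 144.6)),
                      exposure_scenario(0.717))
  expect_equal(p2$derived[["Vli"]] / p$derived[["Vli"]], 2)
  expect_equal(p2$derived[["Vspd"]] / p$derived[["Vspd"]], 2)
  expect_equal(p2$derived[["QC"]] / p$derived[["QC"]], 2^0.75)
  expect_equal(p2$derived[["Qgu"]] / p$derived[["Qgu"]], 2^0.75)
  expect_error(
    build_subject(default_parameters(list(FracDOSEHep = 0.9,
                                          FracDOSELymph = 0.3))),
    "FracDOSEHep")
})

test_that("derivatives vanish for zero dose and zero state", {
  p <- build_subject(default_parameters(), exposure_scenario(0))
  y0 <- setNames(numeric(31), state_names)
  d <- pbpk_derivatives(1.5, y0, p)[[1]]
  expect_equal(d, numeric(31))
})

test_that("right-hand side matches an independent ODE implementation", {
  raw <- default_parameters(list(Gutlag = 0, Lymphlag = 0, Bilelag = 0))
  p <- build_subject(raw, exposure_scenario(0.717))
  set.seed(11)
  for (i in 1:20) {
    y <- setNames(abs(rnorm(31, 0, 5)), state_names)
    t <- runif(1, 0, 24)
    a <- pbpk_derivatives(t, y, p)[[1]]
    b <- indep_ode_rhs(t, y, p$derived)[[1]]
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("zero dose simulates to identically zero concentrations", {
  p <- build_subject(default_parameters(), exposure_scenario(0, t_end = 12))
  s <- simulate_pbpk(p)
  expect_true(all(s$outputs$CBloodDPHP == 0))
  expect_true(all(abs(s$states) == 0))
})

test_that("molar mass balance is conserved (volunteer A scenario)", {
  s <- default_sim()
  dose <- s$params$extra[["DOSE"]]
  expect_lt(max(abs(s$outputs$balance)) / dose, 1e-6)
  ## residual at t=0+ is tiny: dose delivered so far is still in transit
  expect_lt(abs(s$outputs$balance[2]) / dose, 1e-6)
  ## negative control: dropping the bowel pool breaks the balance by the
  ## faecal fraction
  broken <- s$outputs$balance - s$states[, "Abw"]
  expect_gt(max(abs(broken)) / dose, 0.5)
})

test_that("solution is self-convergent under tolerance tightening", {
  p <- build_subject(default_parameters(list(BW = 83)),
                     exposure_scenario(0.717))
  s1 <- simulate_pbpk(p)
  s2 <- simulate_pbpk(p, atol = 1e-10, rtol = 1e-7)
  rel <- max(abs(s1$outputs$CBloodDPHP - s2$outputs$CBloodDPHP)) /
    max(s2$outputs$CBloodDPHP)
  expect_lt(rel, 1e-3)
})

test_that("DDE reduces to the independent ODE solution at zero lags", {
  raw <- default_parameters(list(BW = 83, Gutlag = 0, Lymphlag = 0,
                                 Bilelag = 0))
  p <- build_subject(raw, exposure_scenario(0.717, t_end = 24))
  s <- simulate_pbpk(p, atol = 1e-12, rtol = 1e-10)
  y0 <- setNames(numeric(31), state_names)
  ref <- deSolve::ode(y = y0, times = s$times, parms = p$derived,
                      func = function(t, y, pv)
                        indep_ode_rhs(t, setNames(y, state_names), pv),
                      atol = 1e-12, rtol = 1e-10)
  rel <- max(abs(s$states - ref[, -1])) / max(abs(ref[, -1]))
  expect_lt(rel, 1e-8)
})

test_that("lymphatic bypass switches off cleanly", {
  raw <- default_parameters(list(BW = 83, FracDOSELymph = 0))
  s <- simulate_pbpk(build_subject(raw, exposure_scenario(0.717)))
  expect_true(all(s$outputs$MlymphDPHP == 0))
  ## with no lymph route the lymph lag cannot matter
  raw2 <- default_parameters(list(BW = 83, FracDOSELymph = 0, Lymphlag = 5))
  s2 <- simulate_pbpk(build_subject(raw2, exposure_scenario(0.717)))
  expect_equal(s$outputs$CBloodDPHP, s2$outputs$CBloodDPHP,
               tolerance = 1e-10)
})

test_that("enterohepatic recirculation creates post-peak urinary harmonics", {
  m_on <- extract_metrics(calib_sim())
  expect_gte(length(m_on$urine_maxima$OH), 1)
  raw_off <- default_parameters(c(list(BW = 83), as.list(calibrated_medians()),
                                  list(k1_DPHP_liver = 0, k1_MPHP_liver = 0)))
  s_off <- simulate_pbpk(build_subject(raw_off, exposure_scenario(0.717)))
  expect_length(extract_metrics(s_off)$urine_maxima$OH, 0)
})

test_that("stronger plasma binding raises the DPHP plasma peak and lowers urinary recovery", {
  mk <- function(fu) {
    raw <- default_parameters(list(BW = 83, fuDPHP = fu))
    simulate_pbpk(build_subject(raw, exposure_scenario(0.717)))
  }
  lo_bind <- mk(0.01); hi_bind <- mk(0.001)   # higher FB = lower fu
  expect_gt(max(hi_bind$outputs$MplasmaDPHP), max(lo_bind$outputs$MplasmaDPHP))
  rec24 <- function(s) approx(s$times, s$states[, "UOH"] + s$states[, "Ucx"],
                              24)$y
  expect_lt(rec24(hi_bind), rec24(lo_bind))
})

test_that("lymph-only uptake yields only a shallow late urinary peak", {
  base <- c(list(BW = 83), as.list(calibrated_medians()))
  lymph_only <- default_parameters(modifyList(base,
    list(FracDOSEHep = 1e-9, FracDOSELymph = 0.02)))
  hep_only <- default_parameters(modifyList(base,
    list(FracDOSEHep = 0.1, FracDOSELymph = 1e-9)))
  sL <- simulate_pbpk(build_subject(lymph_only, exposure_scenario(0.717)))
  sH <- simulate_pbpk(build_subject(hep_only, exposure_scenario(0.717)))
  expect_lt(max(sL$outputs$RUrineOH), 0.25 * max(sH$outputs$RUrineOH))
  ## and the lymph-route peak comes later (long tail)
  expect_gt(sL$times[which.max(sL$outputs$RUrineOH)],
            sH$times[which.max(sH$outputs$RUrineOH)])
})

test_that("metric extraction: constructed series and boundary flags", {
  tt <- seq(0, 10, 0.1)
  tri <- pmax(0, 1 - abs(tt - 2))          # triangle peaking at t=2, slope -1
  m <- extract_metrics(fake_sim(tt, list(MplasmaDPHP = tri)))
  row <- m$peaks[m$peaks$output == "MplasmaDPHP", ]
  expect_equal(row$peak, 1)
  expect_equal(row$t_peak, 2)
  expect_equal(row$post_peak_rate, -1, tolerance = 1e-8)
  expect_false(row$at_boundary)
  ## monotone rising series peaks at the boundary and is flagged
  m2 <- extract_metrics(fake_sim(tt, list(MplasmaDPHP = tt)))
  expect_true(m2$peaks$at_boundary[m2$peaks$output == "MplasmaDPHP"])
  ## probe metrics read off the grid
  expect_equal(unname(m$metrics[["MplasmaDPHP_peak"]]), 1)
  expect_length(m$metrics, 18)
})

test_that("metric registry names exactly the screening metrics", {
  reg <- metric_registry()
  expect_equal(nrow(reg), 18)
  m <- extract_metrics(calib_sim())$metrics
  expect_setequal(reg$metric, names(m))
  expect_equal(sum(reg$kind == "probe"), 12)
})

test_that("simulation output writer emits tidy CSV with units", {
  s <- default_sim()
  path <- tempfile(fileext = ".csv")
  tidy <- write_simulation_csv(s, path)
  back <- read.csv(path)
  expect_equal(names(back), c("time", "variable", "value", "units"))
  expect_setequal(unique(back$variable),
                  setdiff(names(s$outputs), "time"))
  expect_equal(nrow(back), nrow(tidy))
})
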