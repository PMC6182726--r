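test_that("corrected sigmoid has the documented limits and midpoint", {
  p <- emax_params()
  expect_equal(rr_from_concentration(0, p), 995.3)
  expect_equal(rr_from_concentration(1e9, p), 500.8, tolerance = 1e-6)
  # at C = EC50 the response sits halfway: RR0 - (RR0 - RRmax)/2
  expect_equal(rr_from_concentration(0.4, p), 748.05, tolerance = 1e-12)
  # strictly decreasing and bounded in (RRmax, RR0]
  cc <- exp(seq(log(1e-4), log(100), length.out = 200))
  rr <- rr_from_concentration(cc, p)
  expect_true(all(diff(rr) < 0))
  expect_true(all(rr > p$RRmax & rr <= p$RR0))
})

test_that("the literal printed form is retained for audit only", {
  p <- emax_params()
  expect_warning(r0 <- rr_from_concentration(0, p, form = "as_printed"),
                 "audit")
  expect_equal(r0, 0)
  suppressWarnings(
    expect_equal(rr_from_concentration(0.4, p, form = "as_printed"),
                 (995.3 - 500.8) / 2))
})

test_that("parameter invariants are enforced", {
  expect_error(emax_params(RR0 = 400, RRmax = 500), "RR0 > RRmax")
  expect_error(emax_params(EC50 = 0), "EC50")
  expect_error(emax_params(n = -1), "n must")
})

test_that("noise-free data are recovered essentially exactly", {
  d <- generate_emax_dataset(noise_sd_ms = 0, seed = 1)
  f <- fit_emax(d, seed = 1)
  expect_lt(f$rmse, 0.01)
  expect_equal(f$params$RR0, 995.3, tolerance = 1e-3)
  expect_equal(f$params$RRmax, 500.8, tolerance = 1e-2)
  expect_equal(f$params$EC50, 0.4, tolerance = 1e-2)
  expect_equal(f$params$n, 1.5, tolerance = 1e-2)
})

test_that("the fitted objective never exceeds the truth objective", {
  truth <- emax_params()
  for (seed in c(2, 9, 17)) {
    d <- generate_emax_dataset(seed = seed)
    f <- fit_emax(d, seed = seed)
    rmse_truth <- sqrt(mean(
      (d$rr_ms - rr_from_concentration(d$conc_uM, truth))^2))
    expect_lte(f$rmse, rmse_truth + 1e-9)
  }
})

test_that("recovery bias shrinks as the noise shrinks", {
  med_err <- sapply(c(120.98, 40, 5), function(sd_ms) {
    errs <- sapply(1:5, function(s) {
      d <- generate_emax_dataset(noise_sd_ms = sd_ms, seed = 400 + s)
      f <- fit_emax(d, seed = 400 + s, sa_control = list(maxit = 3000))
      abs(f$params$EC50 - 0.4) / 0.4
    })
    median(errs)
  })
  expect_true(all(diff(med_err) <= 1e-9))
})

test_that("degenerate datasets are rejected", {
  d <- data.frame(conc_uM = rep(1, 10), rr_ms = rnorm(10, 900, 10))
  expect_error(fit_emax(d), "order of magnitude")
  expect_error(fit_emax(data.frame(conc_uM = 1:4, rr_ms = 1:4)),
               "8 data points")
})

test_that("case RR prediction averages the Emax curve over time", {
  m <- full_model()
  s <- simulate_pbpk(m, regimen_single(75), seq(0, 24, 0.5),
                     method = "matexp")
  # constant zero plasma returns the baseline
  s0 <- s; s0$data$at_plasma <- 0 * s0$data$at_plasma
  expect_equal(predict_rr_for_case(s0), 995.3)
  # constant plasma at EC50 returns the midpoint
  sE <- s; sE$data$at_plasma <- rep(uM_to_ngml(0.4, 277.4), nrow(sE$data))
  expect_equal(predict_rr_for_case(sE), 748.05, tolerance = 1e-9)
  # a dose-only overdose record yields one finite mean RR per twin
  rec <- list(age = 16, sex = "F", dose_mg = 750)
  ex <- exposure_for_case_group(rec, "simulated_dose_only",
                                t_grid = seq(0, 24, 0.25))
  rr <- predict_rr_for_case(ex$series)
  expect_true(is.finite(rr))
  expect_lt(rr, 995.3)
  expect_gt(rr, 500.8)
})
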