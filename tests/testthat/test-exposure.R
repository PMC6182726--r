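at <- amitriptyline_params()
nt <- nortriptyline_params()

test_that("free cardiac conversion equals the partition arithmetic", {
  expect_equal(free_cardiac_from_plasma(100, at), 100 * 11.77 * 0.0012,
               tolerance = 1e-12)
  expect_equal(free_cardiac_from_plasma(100, at), 1.4124,
               tolerance = 1e-12)
  expect_equal(free_cardiac_from_plasma(200, nt), 200 * 35.63 * 0.001,
               tolerance = 1e-12)
  expect_equal(free_cardiac_from_plasma(200, nt), 7.126,
               tolerance = 1e-12)
  expect_identical(free_cardiac_from_plasma(0, at), 0)
  # linearity
  x <- c(1, 10, 250)
  expect_equal(free_cardiac_from_plasma(3 * x, at),
               3 * free_cardiac_from_plasma(x, at))
})

test_that("metabolite imputation is exactly half the parent level", {
  expect_identical(impute_nt_plasma(300), 150)
  expect_identical(impute_nt_plasma(0), 0)
})

test_that("unit round trip ng/mL <-> uM is exact", {
  x <- c(0.001, 1, 123.4, 5000)
  expect_equal(uM_to_ngml(ngml_to_uM(x, 277.4), 277.4), x,
               tolerance = 1e-12)
  # container carries both units consistently
  e <- cardiac_exposure(0, "AT", 277.4, 277.4, "from_plasma_eq")
  expect_equal(e$free_cardiac_uM, 1, tolerance = 1e-12)
})

test_that("simulated-heart exposure applies tissue binding", {
  m <- full_model()
  s <- simulate_pbpk(m, regimen_single(75), seq(0, 24, 0.5),
                     method = "matexp")
  e <- free_cardiac_from_simulation(s, at)
  expect_equal(e$free_cardiac_ng_per_mL, s$data$at_heart * 0.0012)
  expect_identical(attr(e, "provenance"), "from_simulated_heart")
  # a zero profile yields zero exposure
  s0 <- s; s0$data$at_heart <- 0 * s0$data$at_heart
  expect_true(all(free_cardiac_from_simulation(s0, at)
                  $free_cardiac_ng_per_mL == 0))
})

test_that("group-1 methodology uses observed plasma with imputation", {
  rec <- list(age = 50, sex = "F", plasma_at_ng_ml = 500)
  ex <- exposure_for_case_group(rec, "observed_plasma")
  expect_equal(ex$AT$free_cardiac_ng_per_mL, 7.062, tolerance = 1e-12)
  expect_equal(ex$NT$free_cardiac_ng_per_mL, 8.9075, tolerance = 1e-12)
  # measured NT is passed through, not imputed
  rec2 <- c(rec, list(plasma_nt_ng_ml = 100))
  ex2 <- exposure_for_case_group(rec2, "observed_plasma")
  expect_equal(ex2$NT$free_cardiac_ng_per_mL, 100 * 35.63 * 0.001,
               tolerance = 1e-12)
})

test_that("group-2 selection time is the AT plasma argmax in the window", {
  rec <- list(age = 30, sex = "M", dose_mg = 1500,
              plasma_at_ng_ml = 400, ecg_window_h = c(2, 4))
  ex <- exposure_for_case_group(rec, "simulated_full",
                                t_grid = seq(0, 12, 0.1))
  expect_gte(ex$selection_time_h, 2)
  expect_lte(ex$selection_time_h, 4)
  win <- ex$series$data$time_h >= 2 & ex$series$data$time_h <= 4
  expect_equal(max(ex$series$data$at_plasma[win]),
               ex$series$data$at_plasma[ex$series$data$time_h ==
                                          ex$selection_time_h])
})

test_that("group-3 methodology needs only the dose", {
  rec <- list(age = 30, sex = "M", dose_mg = 1500)
  ex <- exposure_for_case_group(rec, "simulated_dose_only",
                                t_grid = seq(0, 12, 0.2))
  expect_gt(ex$AT$free_cardiac_uM, 0)
  expect_identical(attr(ex$AT, "provenance"), "from_simulated_heart")
})

test_that("mode/record mismatches fail before any simulation", {
  expect_error(exposure_for_case_group(list(), "observed_plasma"),
               "age and sex")
  rec <- list(age = 30, sex = "M", dose_mg = 1500)
  expect_error(exposure_for_case_group(rec, "simulated_full"),
               "plasma_at_ng_ml")
  rec2 <- list(age = 30, sex = "M", plasma_at_ng_ml = 200)
  expect_error(exposure_for_case_group(rec2, "simulated_dose_only"),
               "dose_mg")
})
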