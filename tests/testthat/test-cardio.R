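test_that("the resting cell is quiescent and stable", {
  # relax unpaced for 10 s, then the membrane must be essentially still
  rest <- cardiopbpk:::.tnnp_rest_cpp(
    as.numeric(tnnp_initial_state()), as.numeric(default_scalers()),
    5.4, 140, 2, 0L, 10000, 0.02)
  expect_lt(abs(rest$dvdt_end), 0.02)
  # resting drift below 1 mV over 30 s
  rest30 <- cardiopbpk:::.tnnp_rest_cpp(
    as.numeric(tnnp_initial_state()), as.numeric(default_scalers()),
    5.4, 140, 2, 0L, 30000, 0.02)
  expect_lt(abs(rest30$drift_mV), 1)
})

test_that("the RHS responds to conductance scalers at the current level", {
  y <- tnnp_initial_state()
  y["V"] <- -20  # depolarized point where IKr flows
  d_full <- tnnp_rhs(y)
  d_blocked <- tnnp_rhs(y, scalers = c(IKr = 0))
  # removing an outward current makes dV/dt less negative
  expect_gt(d_blocked["V"], d_full["V"])
  expect_error(tnnp_rhs(y, scalers = c(IFake = 0.5)), "unknown current")
  y_bad <- y; y_bad["V"] <- NaN
  expect_error(tnnp_rhs(y_bad), "non-finite")
})

test_that("control epicardial APD90 matches the published model", {
  r <- paced_qt(pacing_protocol(cl_ms = 1000, n_beats = 30))
  # published epicardial APD90 at 1 Hz pacing is ~301.5 ms
  expect_equal(r$apd90, 301.5, tolerance = 0.10)
  expect_identical(r$type, "none")
  expect_false(r$arrhythmia)
  # physiological sanity band for the single-cell QT surrogate
  expect_gt(r$qt, 300); expect_lt(r$qt, 450)
  # physiological restitution: shorter cycle length, shorter APD
  r600 <- paced_qt(fast_protocol(cl_ms = 600))
  r1000 <- paced_qt(fast_protocol(cl_ms = 1000))
  expect_lt(r600$apd90, r1000$apd90)
})

test_that("channel block scalers follow the pore-block arithmetic", {
  blocks <- list(AT = list(IKr = list(ic50_uM = 2, hill = 1)),
                 NT = list(IKr = list(ic50_uM = 4, hill = 1)))
  expect_equal(block_scalers(c(AT = 2, NT = 0), blocks)[["IKr"]], 0.5)
  expect_equal(block_scalers(c(AT = 0, NT = 0), blocks)[["IKr"]], 1)
  # both analytes at their IC50 leave a quarter of the conductance
  expect_equal(block_scalers(c(AT = 2, NT = 4), blocks)[["IKr"]], 0.25)
  # Hill steepness enters as the exponent
  b2 <- list(AT = list(IKr = list(ic50_uM = 2, hill = 2)))
  expect_equal(block_scalers(c(AT = 4), b2)[["IKr"]], 1 / (1 + 4))
  bad <- list(AT = list(IKr = list(hill = 1)))
  expect_error(block_scalers(c(AT = 1), bad), "lacks ic50")
})

test_that("APD90 grows monotonically along an IKr-block ladder", {
  apds <- sapply(c(1, 0.7, 0.4, 0.2), function(s) {
    paced_qt(fast_protocol(), scalers = c(IKr = s))$apd90
  })
  expect_true(all(diff(apds) > 0))
})

test_that("extreme combined potassium-current block flags arrhythmia", {
  r <- paced_qt(fast_protocol(), scalers = c(IKr = 0.02, IKs = 0.05,
                                             IK1 = 0.3))
  expect_true(r$arrhythmia)
  expect_true(r$type %in% c("EAD", "repolarization_failure"))
})

test_that("QT correction formulas are exact arithmetic", {
  expect_equal(qtc(400, 1000, "bazett"), 400, tolerance = 1e-12)
  expect_equal(qtc(400, 600, "bazett"), 400 / sqrt(0.6), tolerance = 1e-12)
  expect_equal(qtc(400, 600, "bazett"), 516.4, tolerance = 1e-4)
  expect_equal(qtc(400, 600, "fridericia"), 400 / 0.6^(1 / 3),
               tolerance = 1e-12)
  expect_identical(qtc(400, 600, "none"), 400)
  expect_error(qtc(-1, 600), "qt")
})

test_that("pacing protocol validators reject unphysiological settings", {
  expect_error(pacing_protocol(cl_ms = 150), "200 ms")
  expect_error(pacing_protocol(n_beats = 2), "3 beats")
  expect_error(paced_qt(fast_protocol(), scalers = c(IKr = -1)), ">= 0")
})

test_that("the seeded multi-run case protocol is bit-reproducible", {
  blocks <- example_blocks()
  a <- run_case(c(AT = 0.5, NT = 0.3), blocks, rr_ms = 800, n_runs = 4,
                seed = 1111, protocol = fast_protocol())
  b <- run_case(c(AT = 0.5, NT = 0.3), blocks, rr_ms = 800, n_runs = 4,
                seed = 1111, protocol = fast_protocol())
  expect_identical(a$runs, b$runs)
  expect_identical(a$mean_qtc, b$mean_qtc)
  # a different seed draws different conductance multipliers
  c2 <- run_case(c(AT = 0.5, NT = 0.3), blocks, rr_ms = 800, n_runs = 4,
                 seed = 2222, protocol = fast_protocol())
  expect_false(identical(a$runs$qtc, c2$runs$qtc))
})

test_that("zero exposure leaves only population variability, no arrhythmia", {
  blocks <- example_blocks()
  r <- run_case(c(AT = 0, NT = 0), blocks, rr_ms = 1000, n_runs = 4,
                seed = 1111, protocol = fast_protocol())
  expect_equal(r$arrhythmia_count, 0)
  expect_gt(r$sd_qtc, 0)   # conductance variability alone spreads QTc
  # with variability disabled the runs are identical
  r0 <- run_case(c(AT = 0, NT = 0), blocks, rr_ms = 1000, n_runs = 3,
                 seed = 1111, protocol = fast_protocol(),
                 variability_cv = 0)
  expect_equal(r0$sd_qtc, 0)
})
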