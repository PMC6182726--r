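test_that("bioavailability draws respect the truncation bounds", {
  set.seed(11)
  f <- sample_F(10000)
  expect_gte(min(f), 0.33)
  expect_lte(max(f), 0.62)
  # truncated-normal mean oracle:
  # mean = mu + sd * (phi(a) - phi(b)) / (Phi(b) - Phi(a))
  a <- (0.33 - 0.459) / 0.093
  b <- (0.62 - 0.459) / 0.093
  mu_trunc <- 0.459 + 0.093 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  expect_equal(mu_trunc, 0.4658, tolerance = 2e-4)
  set.seed(12)
  expect_equal(mean(sample_F(1e6)), mu_trunc, tolerance = 1e-3)
})

test_that("fa*Fg sampling matches the moment-matched lognormal", {
  mm <- cardiopbpk:::lnorm_moments(0.832, 0.131)
  expect_equal(mm$sdlog, sqrt(log(1 + 0.131^2)), tolerance = 1e-12)
  expect_equal(mm$sdlog, 0.13044, tolerance = 5e-5)
  expect_equal(mm$meanlog, log(0.832) - mm$sdlog^2 / 2, tolerance = 1e-12)
  expect_equal(mm$meanlog, -0.19240, tolerance = 2e-4)
  set.seed(21)
  g <- sample_faFg(1e6)
  expect_equal(mean(g), 0.832, tolerance = 1e-3)
  expect_true(any(g > 1))          # no truncation above 1
  expect_identical(sample_faFg(5, cv = 0), rep(0.832, 5))
})

test_that("lag-time draws are positive with the stated mean and CV", {
  set.seed(31)
  tl <- sample_tlag(1e6)
  expect_true(all(tl > 0))
  expect_equal(mean(tl), 1.33, tolerance = 5e-3)
  expect_equal(sd(tl) / mean(tl), 0.30, tolerance = 0.01)
  set.seed(32)
  tn <- sample_tlag(1e4, family = "truncnorm")
  expect_true(all(tn > 0))
})

test_that("seeded sampling is exactly reproducible", {
  set.seed(7); x1 <- sample_F(100)
  set.seed(7); x2 <- sample_F(100)
  expect_identical(x1, x2)
  p1 <- make_population(10, seed = 1111)
  p2 <- make_population(10, seed = 1111)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 10)
})

test_that("population draws satisfy the joint invariants for many seeds", {
  for (seed in 1:25) {
    pop <- make_population(40, seed = seed)
    expect_true(all(pop$F >= 0.33 & pop$F <= 0.62))
    expect_true(all(pop$fa_Fg > 0))
    expect_true(all(pop$t_lag > 0))
    expect_true(all(pop$F <= pop$fa_Fg))  # Fh <= 1 after the clamp
  }
})

test_that("the rejection counter matches the joint-overlap probability", {
  # brute-force Monte Carlo estimate of P(F > fa*Fg) under independence
  set.seed(99)
  n <- 2e5
  f <- sample_F(n)
  g <- sample_faFg(n)
  p_reject <- mean(f > g)
  pop <- make_population(n, seed = 123)
  observed_rate <- attr(pop, "resample_count") /
    (n + attr(pop, "resample_count"))
  expect_equal(observed_rate, p_reject, tolerance = 0.002)
  expect_gt(attr(pop, "resample_count"), 0)
})

test_that("a mean individual arises when all CVs are zero", {
  cfg <- population_config(tlag_cv = 0, F_sd = 1e-9, faFg_cv = 0)
  pop <- make_population(1, cfg, seed = 5)
  expect_equal(pop$F, 0.459, tolerance = 1e-6)
  expect_equal(pop$fa_Fg, 0.832)
  expect_equal(pop$t_lag, 1.33)
})

test_that("one lag per individual is reused across all their doses", {
  pop <- make_population(1, seed = 3)
  m <- full_model()
  ev <- cardiopbpk:::event_table(
    regimen_qd(25, 7, 8),
    absorption_params(pop$ka, pop$t_lag, pop$F, pop$fa_Fg),
    amitriptyline_params(), nortriptyline_params())
  expect_equal(ev$time_h, seq(0, by = 8, length.out = 7) + pop$t_lag)
})

test_that("virtual twins fix known covariates and sample the rest", {
  rec <- list(age = 67, sex = "F", dose_mg = 2500)
  tw <- make_virtual_twin(rec, n = 10, seed = 1111)
  expect_true(all(tw$age == 67))
  expect_true(all(tw$sex == "F"))
  expect_equal(length(unique(tw$F)), 10)      # ten distinct parameter sets
  expect_equal(length(unique(tw$t_lag)), 10)
  # recorded ions pass through exactly; missing ones default to normal
  rec2 <- list(age = 40, sex = "M", plasma_at_ng_ml = 300,
               ions = list(K = 3.1))
  tw2 <- make_virtual_twin(rec2, n = 1, seed = 1)
  expect_equal(tw2$K, 3.1)
  expect_equal(tw2$Na, normal_ions()[["Na"]])
  expect_equal(tw2$Ca, normal_ions()[["Ca"]])
})

test_that("contradictory or incomplete case records are rejected", {
  expect_error(make_virtual_twin(list(age = 50)), "age and sex")
  expect_error(make_virtual_twin(list(age = 50, sex = "F")),
               "dose and/or")
  expect_error(make_virtual_twin(list(age = 50, sex = "F", dose_mg = 500,
                                      rr_ms = -10)),
               "RR")
})
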