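test_that("model construction lays out the expected state vector", {
  m <- full_model()
  expect_true(all(c("depot_par", "depot_met") %in% m$state_names))
  expect_true("tis_heart" %in% m$state_names)
  expect_gte(sum(grepl("^tis_", m$state_names)), 2)
  expect_true(all(c("met_central", "met_rest") %in% m$state_names))

  # missing heart compartment is a configuration error
  phys <- default_physiology()
  phys$tissues <- phys$tissues[phys$tissues$name != "heart", ]
  expect_error(build_pbpk_model(phys, amitriptyline_params(),
                                nortriptyline_params(),
                                default_absorption()),
               "heart")
  # missing Kp entry is a configuration error
  at <- amitriptyline_params()
  at$Kp_map <- at$Kp_map[names(at$Kp_map) != "lung"]
  expect_error(build_pbpk_model(default_physiology(), at,
                                nortriptyline_params(),
                                default_absorption()),
               "Kp_map")
})

test_that("the empty system is at equilibrium", {
  m <- full_model()
  expect_equal(as.numeric(m$A %*% rep(0, m$n)), rep(0, m$n))
})

test_that("collapse configuration matches a hand-written 2-state RHS", {
  V <- 40; CL <- 8; ka <- 0.24
  m <- collapse_model(V = V, CL = CL, ka = ka)
  ip <- m$idx
  set.seed(42)
  for (i in 1:10) {
    depot <- runif(1, 0, 50); central <- runif(1, 0, 50)
    x <- rep(0, m$n)
    x[ip$depot_par] <- depot; x[ip$central_par] <- central
    dx <- as.numeric(m$A %*% x)
    # hand-written one-compartment model with first-order input
    expect_equal(dx[ip$depot_par], -ka * depot)
    expect_equal(dx[ip$central_par], ka * depot - CL / V * central)
  }
})

test_that("oral dosing increments both depots with the documented masses", {
  absn <- default_absorption()
  at <- amitriptyline_params(); nt <- nortriptyline_params()
  st <- c(depot_par = 0, depot_met = 0)
  st1 <- apply_oral_dose(st, dose_event(0, 75), absn, at, nt)
  expect_equal(unname(st1["depot_par"]), 0.459 * 75)
  expect_equal(unname(st1["depot_par"]), 34.425)
  nt_mass <- 263.384 / 277.4 * (1 - 0.459 / 0.832) * 0.832 * 75
  expect_equal(unname(st1["depot_met"]), nt_mass)
  expect_equal(unname(st1["depot_met"]), 26.56, tolerance = 1e-3)

  # Fh = 1 means no first-pass loss, hence no first-pass metabolite
  absn1 <- absorption_params(ka = 0.24, t_lag = 0, F = 0.6, fa_Fg = 0.6)
  st2 <- apply_oral_dose(st, dose_event(0, 75), absn1, at, nt)
  expect_equal(unname(st2["depot_met"]), 0)

  # dosing is additive
  st3 <- apply_oral_dose(st1, dose_event(1, 75), absn, at, nt)
  expect_equal(unname(st3["depot_par"]), 2 * unname(st1["depot_par"]))
  expect_equal(unname(st3["depot_met"]), 2 * unname(st1["depot_met"]))
})

test_that("simulation honours the absorption lag exactly", {
  m <- full_model()
  tg <- c(seq(0.1, 1.3, by = 0.2), seq(1.4, 12, by = 0.2))
  s <- simulate_pbpk(m, regimen_single(25), tg, method = "matexp")
  expect_true(all(s$data$at_plasma[tg < 1.33] == 0))
  expect_true(all(s$data$nt_plasma[tg < 1.33] == 0))
  expect_true(any(s$data$at_plasma[tg > 1.4] > 0))
  # a single dose gives a single maximum after the lag
  cmax_t <- tg[which.max(s$data$at_plasma)]
  expect_gt(cmax_t, 1.33)
  expect_error(simulate_pbpk(m, regimen_single(25)[0, ], tg), "regimen")
  expect_error(simulate_pbpk(m, regimen_single(25), c(1, 1, 2)),
               "increasing")
})

test_that("collapse configuration reproduces the Bateman closed form", {
  V <- 40; CL <- 8
  m <- collapse_model(V = V, CL = CL)
  tg <- seq(0.1, 48, by = 0.4)
  oracle <- bateman_ngml(tg, 75, 0.459, 0.24, CL / V, V, 1.33)
  for (method in c("matexp", "lsoda")) {
    s <- simulate_pbpk(m, regimen_single(75), tg, method = method)
    dev <- abs(s$data$at_plasma - oracle) / pmax(oracle, 1e-9)
    expect_lt(max(dev[oracle > 0]), 1e-4)
  }
})

test_that("the two integration paths agree on the full model", {
  m <- full_model()
  tg <- seq(0, 48, by = 0.5)
  s1 <- simulate_pbpk(m, regimen_qd(75, 2), tg, method = "matexp")
  s2 <- simulate_pbpk(m, regimen_qd(75, 2), tg, method = "lsoda")
  expect_equal(s1$data$at_plasma, s2$data$at_plasma,
               tolerance = 1e-6)
  expect_equal(s1$data$nt_plasma, s2$data$nt_plasma,
               tolerance = 1e-6)
})

test_that("linear model obeys dose proportionality and superposition", {
  m <- full_model()
  tg <- seq(0, 240, by = 1)
  s25 <- simulate_pbpk(m, regimen_single(25), tg, method = "matexp")
  s75 <- simulate_pbpk(m, regimen_single(75), tg, method = "matexp")
  auc <- function(s) sum(diff(tg) * (head(s$data$at_plasma, -1) +
                                       tail(s$data$at_plasma, -1)) / 2)
  expect_equal(auc(s75) / auc(s25), 3, tolerance = 0.005)

  multi <- simulate_pbpk(m, regimen_qd(75, 3), tg, method = "matexp")
  f <- approxfun(tg, s75$data$at_plasma, yleft = 0, rule = 2)
  shifted_sum <- f(tg) + f(tg - 24) + f(tg - 48)
  expect_lt(max(abs(multi$data$at_plasma - shifted_sum)) /
              max(multi$data$at_plasma), 0.005)
})

test_that("states stay non-negative across regimens", {
  m <- full_model()
  for (reg in list(regimen_single(25), regimen_qd(75, 4, 12))) {
    s <- simulate_pbpk(m, reg, seq(0, 72, 0.5), method = "matexp")
    expect_true(all(s$states >= 0))
  }
})

test_that("steady-state cycling converges and matches superposition", {
  m <- full_model()
  ss <- simulate_to_steady_state(m, regimen_single(75), tolerance = 1e-6)
  expect_gt(ss$trough_ng_per_mL, 0)
  expect_lte(ss$cycles, 60)

  # steady-state AUC over one interval equals single-dose AUC to infinity
  tg_inf <- seq(0, 1500, by = 1)
  sing <- simulate_pbpk(m, regimen_single(75), tg_inf, method = "matexp")
  auc_inf <- sum(diff(tg_inf) * (head(sing$data$at_plasma, -1) +
                                   tail(sing$data$at_plasma, -1)) / 2)
  tg_ss <- seq(0, 24, by = 0.1)
  sss <- simulate_pbpk(m, regimen_single(75), tg_ss, state0 = ss$state,
                       method = "matexp")
  auc_ss <- sum(diff(tg_ss) * (head(sss$data$at_plasma, -1) +
                                 tail(sss$data$at_plasma, -1)) / 2)
  expect_equal(auc_ss / auc_inf, 1, tolerance = 0.01)

  # fast washout converges almost immediately (fast absorption too,
  # otherwise depot carry-over dominates the trough)
  fast <- collapse_model(V = 10, CL = 500, ka = 5, t_lag = 0.1)
  ssf <- simulate_to_steady_state(fast, regimen_single(75))
  expect_lte(ssf$cycles, 3)
  expect_lt(ssf$trough_ng_per_mL, 1e-6)
  expect_error(simulate_to_steady_state(m, regimen_single(75),
                                        tolerance = 0, max_cycles = 3),
               "3 cycles")
})

test_that("mass balance closes to 1e-6 for every regimen", {
  m <- full_model()
  absn <- default_absorption()
  at <- amitriptyline_params(); nt <- nortriptyline_params()
  for (reg in list(regimen_single(75), regimen_qd(75, 3),
                   regimen_qd(25, 5, 8))) {
    s <- simulate_pbpk(m, reg, seq(0, 96, 0.5), method = "matexp")
    mb <- mass_balance(s, reg, absn, at, nt, m)
    expect_lt(mb$max_rel_par, 1e-6)
    expect_lt(mb$max_rel_met, 1e-6)
    expect_true(mb$ok)
  }
  # the first-pass metabolite mass is recovered from the depot integral
  s <- simulate_pbpk(m, regimen_single(75), seq(0, 96, 0.5),
                     method = "matexp")
  mb <- mass_balance(s, regimen_single(75), absn, at, nt, m)
  expect_equal(mb$delivered_met_mg,
               unname(263.384 / 277.4 * (0.832 - 0.459) * 75 +
                        m$r_mw * s$states[nrow(s$states), "conv_par"]),
               tolerance = 1e-9)
})

test_that("simulated heart/plasma ratio approaches Kp_ht at equilibrium", {
  m <- full_model()
  ss <- simulate_to_steady_state(m, regimen_single(75), tolerance = 1e-6)
  tg <- seq(0, 24, 0.5)
  s <- simulate_pbpk(m, regimen_single(75), tg, state0 = ss$state,
                     method = "matexp")
  i_trough <- length(tg)
  ratio <- s$data$at_heart[i_trough] / s$data$at_plasma[i_trough]
  expect_equal(ratio, amitriptyline_params()$Kp_ht, tolerance = 0.02)
})
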