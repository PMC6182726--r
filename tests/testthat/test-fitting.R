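test_that("w_rmse reduces to the expected special cases", {
  expect_equal(w_rmse(c(1, 2), c(1, 2), c(0, 1)), 0)
  expect_equal(w_rmse(5, 2, 1, weights = 1), 3)
  # uniform weights reduce to the ordinary RMSE (brute-force oracle)
  set.seed(8)
  for (i in 1:5) {
    n <- sample(3:20, 1)
    pred <- rnorm(n); obs <- rnorm(n); times <- sort(runif(n, 0, 24))
    expect_equal(w_rmse(pred, obs, times, scheme = "uniform"),
                 sqrt(mean((pred - obs)^2)))
  }
  expect_error(w_rmse(1:3, 1:2, 1:3), "equal length")
})

test_that("interval weights compensate uneven sampling", {
  times <- c(1, 2, 4, 8, 24)
  w <- cardiopbpk:::time_weights(times, "interval")
  expect_equal(w, c(1, 1.5, 3, 10, 16))
  expect_equal(cardiopbpk:::time_weights(times, "uniform"), rep(1, 5))
  expect_equal(cardiopbpk:::time_weights(times, "time"), times)
})

test_that("CRS2-LM finds the sphere optimum and stays in bounds", {
  sphere <- function(x) sum(x^2)
  vals <- sapply(1:20, function(s) {
    crs2_lm_minimize(sphere, c(-5, -5), c(5, 5), n_iter = 1500,
                     seed = s)$value
  })
  expect_lt(median(vals), 1e-3)

  # every evaluated point is inside the box
  seen <- list()
  spy <- function(x) { seen[[length(seen) + 1]] <<- x; sphere(x) }
  crs2_lm_minimize(spy, c(-2, -1), c(3, 4), n_iter = 200, seed = 1)
  pts <- do.call(rbind, seen)
  expect_true(all(pts[, 1] >= -2 & pts[, 1] <= 3))
  expect_true(all(pts[, 2] >= -1 & pts[, 2] <= 4))

  # constant objective returns an in-bounds point at the constant
  rc <- crs2_lm_minimize(function(x) 7, c(0, 0), c(1, 1),
                         n_iter = 50, seed = 2)
  expect_equal(rc$value, 7)
  expect_true(all(rc$par >= 0 & rc$par <= 1))
})

test_that("CRS2-LM beats pure random search on the Rosenbrock valley", {
  rosen <- function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2
  wins <- sapply(1:20, function(s) {
    r <- crs2_lm_minimize(rosen, c(-2, -2), c(2, 2), n_iter = 1500,
                          seed = s)
    set.seed(s + 5000)
    rand <- min(apply(matrix(runif(2 * 1500, -2, 2), ncol = 2), 1, rosen))
    r$value <= rand
  })
  expect_gte(sum(wins), 19)  # paired comparison, 20 seeds
})

test_that("bounded refinement honours box-constraint semantics", {
  bowl <- function(x) sum((x - c(1, -2))^2)
  r <- lbfgsb_refine(bowl, c(3, 3), c(-5, -5), c(5, 5))
  expect_equal(r$par, c(1, -2), tolerance = 1e-6)
  # start at a bound with inward gradient moves inward
  r2 <- lbfgsb_refine(bowl, c(5, 5), c(-5, -5), c(5, 5))
  expect_lt(r2$par[1], 5)
  # bound with outward gradient stays pinned
  r3 <- lbfgsb_refine(bowl, c(2, 0), c(2, -5), c(5, 5))
  expect_equal(r3$par[1], 2)
  expect_error(lbfgsb_refine(function(x) NaN, c(0), c(-1), c(1)),
               "non-finite")
})

test_that("two stages together match or beat each alone on a multi-basin surface", {
  # egg-carton plus bowl: many local minima, global at the origin
  multi <- function(x) sum(x^2) + 10 * sum(1 - cos(2 * pi * x))
  lo <- c(-4, -4); hi <- c(4, 4)
  res <- sapply(1:20, function(s) {
    g <- crs2_lm_minimize(multi, lo, hi, n_iter = 800, seed = s)
    two <- lbfgsb_refine(multi, g$par, lo, hi)$value
    set.seed(s)
    local_only <- lbfgsb_refine(multi, runif(2, -4, 4), lo, hi)$value
    c(two = two, global_only = g$value, local_only = local_only)
  })
  expect_lte(median(res["two", ]), median(res["global_only", ]) + 1e-9)
  expect_lte(median(res["two", ]), median(res["local_only", ]) + 1e-9)
})

test_that("noise-free absorption data are recovered within 2 percent", {
  pr <- generate_fit_problem(noise_cv = 0, noise_floor_ng_ml = 0,
                             seed = 77)
  fit <- fit_absorption(pr, seed = 77)
  expect_equal(unname(fit$estimates["ka"]), 0.24, tolerance = 0.02)
  expect_equal(unname(fit$estimates["t_lag"]), 1.33, tolerance = 0.02)
  expect_lte(fit$w_rmse_final, fit$w_rmse_initial)
})

test_that("the two-stage absorption fit is seed-deterministic and monotone", {
  pr <- generate_fit_problem(seed = 55)
  f1 <- fit_absorption(pr, seed = 55)
  f2 <- fit_absorption(pr, seed = 55)
  expect_identical(f1$estimates, f2$estimates)
  expect_lte(f1$w_rmse_final, f1$w_rmse_initial)
  # estimates respect the box
  expect_true(all(f1$estimates >= c(0.1, 0) & f1$estimates <= c(2, 2)))
})

test_that("fit problems validate their inputs", {
  expect_error(fit_problem(list()), "at least one")
  bad <- data.frame(time_h = 1, conc_ng_per_mL = 1)
  expect_error(fit_problem(list(bad)), "analyte")
  good <- data.frame(time_h = 1:3, analyte = "AT",
                     conc_ng_per_mL = c(1, 2, 1))
  expect_error(fit_problem(list(good)), "dose_mg")
  attr(good, "dose_mg") <- 25
  expect_error(fit_problem(list(good), start = c(ka = 5, t_lag = 1)),
               "start")
})
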