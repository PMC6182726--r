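#' Time-weighted root-mean-square error
#'
#' W-MSE = sum(w_i (pred_i - obs_i)^2) / sum(w_i); W-RMSE = sqrt(W-MSE).
#' Weighting schemes:
#' \describe{
#'   \item{interval}{w_i = (t_{i+1} - t_{i-1}) / 2 (trapezoid interval
#'     widths; compensates uneven sampling; the default).}
#'   \item{inv_time}{w_i = 1 / max(t_i, eps).}
#'   \item{time}{w_i = t_i.}
#'   \item{uniform}{w_i = 1 (ordinary RMSE).}
#' }
#'
#' @param pred,obs aligned prediction/observation vectors.
#' @param times observation times, h (same length).
#' @param scheme weighting scheme id.
#' @param weights explicit weights overriding the scheme.
#' @return the W-RMSE (scalar).
#' @export
w_rmse <- function(pred, obs, times, scheme = c("interval", "inv_time",
                                                "time", "uniform"),
                   weights = NULL) {
  scheme <- match.arg(scheme)
  if (length(pred) != length(obs) || length(obs) != length(times)) {
    stop("pred, obs and times must have equal length")
  }
  if (length(obs) < 1) stop("need at least one observation")
  w <- if (!is.null(weights)) weights else time_weights(times, scheme)
  sqrt(sum(w * (pred - obs)^2) / sum(w))
}

time_weights <- function(times, scheme) {
  switch(scheme,
         uniform = rep(1, length(times)),
         time = times,
         inv_time = 1 / pmax(times, 1e-6),
         interval = {
           if (length(times) == 1) return(1)
           t2 <- c(2 * times[1] - times[2], times,
                   2 * times[length(times)] - times[length(times) - 1])
           (t2[-(1:2)] - t2[seq_len(length(times))]) / 2
         })
}

#' Controlled random search with local mutation (CRS2-LM)
#'
#' Population-based stochastic global minimizer over a box. A population
#' of `pop_size` points is maintained; each iteration reflects a randomly
#' chosen simplex (the current best point plus d random others) through
#' its centroid; if the trial point is infeasible or no better than the
#' worst population member, a coordinate-wise local mutation about the
#' best point is tried instead. Accepted points replace the worst member.
#' No point outside the bounds is ever evaluated.
#'
#' @param objective function of a numeric vector returning a scalar.
#' @param lower,upper finite bound vectors.
#' @param n_iter number of search iterations (default 1500).
#' @param pop_size population size; default `10 * (d + 1)`.
#' @param seed optional integer seed.
#' @return list with `par`, `value`, `trace` (best cost per iteration),
#'   `n_eval`.
#' @export
crs2_lm_minimize <- function(objective, lower, upper, n_iter = 1500,
                             pop_size = NULL, seed = NULL) {
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(upper > lower))
  d <- length(lower)
  if (is.null(pop_size)) pop_size <- 10L * (d + 1L)
  pop_size <- max(pop_size, d + 2L)
  if (!is.null(seed)) set.seed(seed)
  pts <- matrix(stats::runif(pop_size * d, lower, upper),
                nrow = pop_size, byrow = TRUE)
  vals <- apply(pts, 1, objective)
  n_eval <- pop_size
  if (mean(!is.finite(vals)) > 0.5) {
    stop("objective non-finite at more than half of the initial population")
  }
  vals[!is.finite(vals)] <- max(vals[is.finite(vals)]) + 1
  trace <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    i_best <- which.min(vals)
    i_worst <- which.max(vals)
    others <- sample(setdiff(seq_len(pop_size), i_best), d)
    simplex <- pts[c(i_best, others), , drop = FALSE]
    centroid <- colMeans(simplex[seq_len(d), , drop = FALSE])
    trial <- 2 * centroid - simplex[d + 1L, ]
    accepted <- FALSE
    if (all(trial >= lower) && all(trial <= upper)) {
      f_trial <- objective(trial)
      n_eval <- n_eval + 1L
      if (is.finite(f_trial) && f_trial < vals[i_worst]) {
        pts[i_worst, ] <- trial
        vals[i_worst] <- f_trial
        accepted <- TRUE
      }
    }
    if (!accepted) {
      w <- stats::runif(d)
      mut <- pmin(pmax((1 + w) * pts[i_best, ] - w * trial, lower), upper)
      f_mut <- objective(mut)
      n_eval <- n_eval + 1L
      if (is.finite(f_mut) && f_mut < vals[i_worst]) {
        pts[i_worst, ] <- mut
        vals[i_worst] <- f_mut
      }
    }
    trace[it] <- min(vals)
  }
  i_best <- which.min(vals)
  list(par = pts[i_best, ], value = vals[i_best], trace = trace,
       n_eval = n_eval)
}

#' Bounded quasi-Newton refinement
#'
#' L-BFGS-B local descent from `start` within the box, with numeric
#' gradients. Defaults follow the two-stage protocol: 50 iterations and a
#' relative tolerance stop criterion of 1e-20. The returned point never
#' has a higher cost than the start.
#'
#' @param objective scalar objective.
#' @param start start vector (within bounds).
#' @param lower,upper bound vectors.
#' @param max_iter iteration cap.
#' @param rel_tol relative tolerance stop criterion.
#' @return list with `par`, `value`, `convergence`, `n_eval`.
#' @export
lbfgsb_refine <- function(objective, start, lower, upper,
                          max_iter = 50, rel_tol = 1e-20) {
  stopifnot(all(start >= lower - 1e-12), all(start <= upper + 1e-12))
  f0 <- objective(start)
  if (!is.finite(f0)) stop("objective non-finite at start")
  res <- try(stats::optim(
    pmin(pmax(start, lower), upper), objective, method = "L-BFGS-B",
    lower = lower, upper = upper,
    control = list(maxit = max_iter,
                   factr = max(rel_tol / .Machine$double.eps, 1e-10))
  ), silent = TRUE)
  if (inherits(res, "try-error") || res$value > f0) {
    return(list(par = start, value = f0, convergence = 1L,
                n_eval = 1L))
  }
  list(par = res$par, value = res$value, convergence = res$convergence,
       n_eval = unname(res$counts[1]))
}

#' Define an absorption-fitting problem
#'
#' Bundles the observation tables (one per study), the model
#' configuration used to simulate mean profiles, the parameter box and
#' starts, and the weighting scheme. Each observation table must have
#' columns `time_h`, `analyte` ("AT"/"NT"), `conc_ng_per_mL` and an
#' attribute (or column) `dose_mg`; variability is disabled during
#' fitting (mean F and fa x Fg).
#'
#' @param observations list of observation data.frames.
#' @param physiology,parent,metabolite model configuration.
#' @param base_absorption absorption parameters supplying the fixed mean
#'   F and fa x Fg.
#' @param bounds list with elements `ka`, `t_lag`, each a length-2 range
#'   (defaults ka [0.1, 2] 1/h, t_lag [0, 2] h).
#' @param start named start vector (default ka = 1, t_lag = 1).
#' @param scheme weighting scheme for [w_rmse()].
#' @return object of class `fit_problem`.
#' @export
fit_problem <- function(observations,
                        physiology = default_physiology(),
                        parent = amitriptyline_params(),
                        metabolite = nortriptyline_params(),
                        base_absorption = default_absorption(),
                        bounds = list(ka = c(0.1, 2), t_lag = c(0, 2)),
                        start = c(ka = 1, t_lag = 1),
                        scheme = "interval") {
  if (!length(observations)) stop("need at least one observation table")
  for (tb in observations) {
    if (!all(c("time_h", "analyte", "conc_ng_per_mL") %in% names(tb))) {
      stop("observation tables need time_h, analyte, conc_ng_per_mL")
    }
    if (is.null(attr(tb, "dose_mg")) && !"dose_mg" %in% names(tb)) {
      stop("each observation table needs its dose_mg")
    }
  }
  lo <- c(bounds$ka[1], bounds$t_lag[1])
  hi <- c(bounds$ka[2], bounds$t_lag[2])
  if (any(!is.finite(c(lo, hi))) || any(hi <= lo)) stop("invalid bounds")
  if (any(start < lo) || any(start > hi)) stop("start outside bounds")
  structure(list(observations = observations, physiology = physiology,
                 parent = parent, metabolite = metabolite,
                 base_absorption = base_absorption,
                 lower = lo, upper = hi, start = start, scheme = scheme),
            class = "fit_problem")
}

# pooled normalized W-MSE objective over all tables and analytes; the
# residual of each analyte is normalized by that analyte's mean observed
# concentration so the parent does not dominate the metabolite
absorption_objective <- function(problem) {
  base <- problem$base_absorption
  prep <- lapply(problem$observations, function(tb) {
    dose <- attr(tb, "dose_mg")
    if (is.null(dose)) dose <- tb$dose_mg[1]
    norm <- stats::ave(tb$conc_ng_per_mL, tb$analyte)
    # interval weights are per analyte: each analyte's sampling times
    # form their own increasing sequence
    w <- numeric(nrow(tb))
    for (an in unique(tb$analyte)) {
      sel <- tb$analyte == an
      ts <- tb$time_h[sel]
      if (is.unsorted(ts, strictly = TRUE)) {
        stop("observation times must be strictly increasing per analyte")
      }
      w[sel] <- time_weights(ts, problem$scheme)
    }
    list(tb = tb, dose = dose, norm = pmax(norm, 1e-9), w = w)
  })
  function(p) {
    ka <- p[1]; tlag <- p[2]
    if (ka <= 0) return(Inf)
    absn <- absorption_params(ka = ka, t_lag = max(tlag, 0),
                              F = base$F, fa_Fg = base$fa_Fg)
    model <- build_pbpk_model(problem$physiology, problem$parent,
                              problem$metabolite, absn)
    num <- 0; den <- 0
    for (pp in prep) {
      tb <- pp$tb
      tgrid <- sort(unique(tb$time_h))
      sim <- try(simulate_pbpk(model, regimen_single(pp$dose), tgrid,
                               method = "matexp"), silent = TRUE)
      if (inherits(sim, "try-error")) return(Inf)
      pred <- ifelse(tb$analyte == "AT",
                     sim$data$at_plasma[match(tb$time_h, tgrid)],
                     sim$data$nt_plasma[match(tb$time_h, tgrid)])
      r <- (pred - tb$conc_ng_per_mL) / pp$norm
      num <- num + sum(pp$w * r^2)
      den <- den + sum(pp$w)
    }
    num / den   # pooled W-MSE
  }
}

#' Two-stage absorption parameter fit
#'
#' Runs the global CRS2-LM search (default 1500 iterations) over
#' (ka, t_lag) within the box, then refines the solution with bounded
#' quasi-Newton descent (default 50 iterations, relative tolerance
#' 1e-20). The internal cost is the pooled, analyte-normalized W-MSE;
#' it is reported as W-RMSE.
#'
#' @param problem `fit_problem`.
#' @param seed optional integer seed (drives the global stage).
#' @param n_iter_global,n_iter_local stage budgets.
#' @return object of class `fit_result` with `estimates` (ka, t_lag),
#'   `w_rmse_initial`, `w_rmse_final`, stage results, `seed`, `scheme`.
#' @export
fit_absorption <- function(problem, seed = NULL, n_iter_global = 1500,
                           n_iter_local = 50) {
  stopifnot(inherits(problem, "fit_problem"))
  obj <- absorption_objective(problem)
  f_start <- obj(problem$start)
  if (!is.finite(f_start)) stop("objective non-finite at the start values")
  glob <- crs2_lm_minimize(obj, problem$lower, problem$upper,
                           n_iter = n_iter_global, seed = seed)
  loc <- lbfgsb_refine(obj, glob$par, problem$lower, problem$upper,
                       max_iter = n_iter_local)
  est <- loc$par
  names(est) <- c("ka", "t_lag")
  structure(list(
    estimates = est,
    w_rmse_initial = sqrt(f_start),
    w_rmse_final = sqrt(loc$value),
    global = glob, local = loc, seed = seed, scheme = problem$scheme,
    n_eval = glob$n_eval + loc$n_eval),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> ka %.4g 1/h | t_lag %.4g h | W-RMSE %.4g -> %.4g (%d evals)\n",
    x$estimates["ka"], x$estimates["t_lag"],
    x$w_rmse_initial, x$w_rmse_final, x$n_eval))
  invisible(x)
}
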