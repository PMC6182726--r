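#' Emax parameters for the concentration-RR relationship
#'
#' Four parameters of the saturating sigmoid linking total plasma
#' amitriptyline concentration (uM) to RR-interval length (ms): baseline
#' `RR0`, maximum-effect asymptote `RRmax` (< RR0: high concentrations
#' shorten RR, i.e. tachycardia), half-maximal concentration `EC50` and
#' sigmoidicity `n`. Defaults are the fitted literature estimates
#' (RR0 = 995.3 ms, RRmax = 500.8 ms, EC50 = 0.4 uM, n = 1.5).
#'
#' @param RR0 baseline RR, ms.
#' @param RRmax maximum-effect RR, ms (0 < RRmax < RR0).
#' @param EC50 half-maximal AT concentration, uM.
#' @param n sigmoidicity factor.
#' @return object of class `emax_params`.
#' @export
emax_params <- function(RR0 = 995.3, RRmax = 500.8, EC50 = 0.4, n = 1.5) {
  if (!(RR0 > RRmax && RRmax > 0)) stop("need RR0 > RRmax > 0")
  if (EC50 <= 0) stop("EC50 must be > 0")
  if (n <= 0) stop("n must be > 0")
  structure(list(RR0 = RR0, RRmax = RRmax, EC50 = EC50, n = n),
            class = "emax_params")
}

#' RR interval from plasma concentration
#'
#' The default `"corrected"` form is the decreasing sigmoid
#' `RR = RR0 - (RR0 - RRmax) * C^n / (EC50^n + C^n)`, which returns the
#' baseline RR0 at C = 0 and approaches RRmax as C grows — consistent
#' with baseline heart rate at zero drug and tachycardia in overdose. The
#' `"as_printed"` form evaluates the literal published expression
#' `RR = (RR0 - RRmax) * C^n / (EC50^n + C^n)` (which is 0 at C = 0); it
#' is retained for audit only and warns when used.
#'
#' @param c_uM total plasma AT concentration, uM (>= 0).
#' @param params `emax_params`.
#' @param form `"corrected"` (default) or `"as_printed"`.
#' @return RR interval length(s), ms.
#' @export
rr_from_concentration <- function(c_uM, params = emax_params(),
                                  form = c("corrected", "as_printed")) {
  form <- match.arg(form)
  stopifnot(inherits(params, "emax_params"), all(c_uM >= 0))
  frac <- ifelse(c_uM == 0, 0,
                 c_uM^params$n / (params$EC50^params$n + c_uM^params$n))
  if (form == "as_printed") {
    warning("as_printed form is for audit only: it returns 0 at C = 0")
    (params$RR0 - params$RRmax) * frac
  } else {
    params$RR0 - (params$RR0 - params$RRmax) * frac
  }
}

#' Fit the Emax model by simulated annealing
#'
#' Minimizes the RMSE between observed and predicted RR over
#' (RR0, RRmax, EC50, n) with the stochastic SANN annealer, followed by a
#' bounded quasi-Newton polish. Box bounds (defaults RR0 in [600, 1400],
#' RRmax in [200, 995], EC50 in [0.01, 10], n in [0.5, 5]) are enforced
#' through a penalty during annealing and exactly during the polish.
#'
#' @param data data.frame with columns `conc_uM` and `rr_ms` (>= 8 points
#'   spanning more than one order of magnitude in concentration).
#' @param seed optional integer seed.
#' @param sa_control list overriding annealer settings: `maxit`
#'   (default 10000), `temp` (10), `tmax` (10).
#' @param bounds list of length-2 numeric bounds named `RR0`, `RRmax`,
#'   `EC50`, `n`.
#' @param start numeric start vector in the same order.
#' @return list of class `emax_fit`: `params` (`emax_params`), `rmse`,
#'   `seed`, `n_points`.
#' @export
fit_emax <- function(data, seed = NULL, sa_control = list(),
                     bounds = list(RR0 = c(600, 1400), RRmax = c(200, 995),
                                   EC50 = c(0.01, 10), n = c(0.5, 5)),
                     start = c(RR0 = 1000, RRmax = 600, EC50 = 1, n = 1)) {
  stopifnot(all(c("conc_uM", "rr_ms") %in% names(data)))
  if (nrow(data) < 8) stop("need at least 8 data points")
  pos <- data$conc_uM[data$conc_uM > 0]
  if (length(unique(data$conc_uM)) < 2 ||
      max(pos) / min(pos) <= 10) {
    stop("concentrations must span more than one order of magnitude")
  }
  if (!is.null(seed)) set.seed(seed)
  ctrl <- utils::modifyList(list(maxit = 10000, temp = 10, tmax = 10),
                            sa_control)
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  obj <- function(p) {
    if (any(p < lo) || any(p > hi) || p[1] <= p[2]) return(1e10)
    pr <- emax_params(p[1], p[2], p[3], p[4])
    sqrt(mean((data$rr_ms -
                 rr_from_concentration(data$conc_uM, pr))^2))
  }
  sann <- stats::optim(start, obj, method = "SANN",
                       control = list(maxit = ctrl$maxit, temp = ctrl$temp,
                                      tmax = ctrl$tmax,
                                      parscale = c(100, 100, 0.5, 0.5)))
  polish <- stats::optim(pmin(pmax(sann$par, lo), hi), obj,
                         method = "L-BFGS-B",
                         lower = lo, upper = hi,
                         control = list(maxit = 500, factr = 10,
                                        pgtol = 1e-14))
  best <- if (polish$value <= sann$value) polish else sann
  p <- unname(best$par)
  structure(list(params = emax_params(p[1], p[2], p[3], p[4]),
                 rmse = best$value, seed = seed, n_points = nrow(data)),
            class = "emax_fit")
}

#' @export
print.emax_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<emax_fit> RR0 %.1f ms | RRmax %.1f ms | EC50 %.3g uM | n %.3g | RMSE %.2f ms\n",
    p$RR0, p$RRmax, p$EC50, p$n, x$rmse))
  invisible(x)
}

#' Predict the RR interval for a simulated case
#'
#' Converts the simulated AT plasma profile to uM, maps each time point
#' through the Emax curve, and returns the time-averaged RR over the
#' exposure window (trapezoidal average; a single-point series returns
#' that point's RR).
#'
#' @param series `conc_series` with an AT plasma channel.
#' @param params `emax_params`.
#' @param mw_at AT molecular weight, g/mol.
#' @return mean RR, ms.
#' @export
predict_rr_for_case <- function(series, params = emax_params(),
                                mw_at = 277.4) {
  stopifnot(inherits(series, "conc_series"))
  d <- series$data
  if (!nrow(d)) stop("empty concentration series")
  rr <- rr_from_concentration(ngml_to_uM(d$at_plasma, mw_at), params)
  if (nrow(d) == 1) return(rr)
  auc_trapz(d$time_h, rr) / (max(d$time_h) - min(d$time_h))
}
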