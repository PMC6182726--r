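#' Sample oral bioavailability F
#'
#' Draws from Normal(0.459, 0.093) truncated to [0.33, 0.62] by rejection.
#' Uses the current RNG state; seed with `set.seed()` for reproducibility.
#'
#' @param n number of draws.
#' @param mean,sd normal parameters.
#' @param lower,upper truncation bounds.
#' @param max_draws rejection cap (error if exceeded).
#' @return numeric vector of length `n`.
#' @export
sample_F <- function(n = 1, mean = 0.459, sd = 0.093,
                     lower = 0.33, upper = 0.62, max_draws = 1e6) {
  out <- numeric(0)
  drawn <- 0
  cap <- max(max_draws, 20 * n)   # the cap guards against degenerate bounds
  while (length(out) < n) {
    m <- max(n - length(out), 100)
    drawn <- drawn + m
    if (drawn > cap) stop("rejection cap of ", cap, " draws exceeded")
    x <- stats::rnorm(m, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

# lognormal meanlog/sdlog matched to an arithmetic mean and CV
lnorm_moments <- function(mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Sample fa x Fg
#'
#' Lognormal with arithmetic mean 0.832 and arithmetic CV 0.131, without
#' truncation, so draws above 1 are permitted (enterohepatic
#' recirculation). Moment matching gives sdlog = sqrt(log(1 + CV^2)) =
#' 0.13044 and meanlog = log(0.832) - sdlog^2/2 = -0.19240. Setting
#' `cv_is_log_sigma = TRUE` instead reads the CV as the standard deviation
#' of log(fa x Fg).
#'
#' @param n number of draws.
#' @param mean arithmetic mean.
#' @param cv arithmetic coefficient of variation (or log-sd, see above).
#' @param cv_is_log_sigma alternative parameterization switch.
#' @return numeric vector of length `n`.
#' @export
sample_faFg <- function(n = 1, mean = 0.832, cv = 0.131,
                        cv_is_log_sigma = FALSE) {
  if (cv == 0) return(rep(mean, n))
  if (cv_is_log_sigma) {
    stats::rlnorm(n, meanlog = log(mean) - cv^2 / 2, sdlog = cv)
  } else {
    p <- lnorm_moments(mean, cv)
    stats::rlnorm(n, p$meanlog, p$sdlog)
  }
}

#' Sample absorption lag time
#'
#' One draw per individual, reused across all of that individual's doses.
#' Default family is lognormal (guarantees positivity) with arithmetic
#' mean `mean_tlag` and 30% CV; a truncated-normal alternative (truncated
#' at 0) is available by flag.
#'
#' @param n number of draws.
#' @param mean_tlag arithmetic mean lag, h (> 0).
#' @param cv coefficient of variation.
#' @param family `"lognormal"` or `"truncnorm"`.
#' @return numeric vector of positive lags, h.
#' @export
sample_tlag <- function(n = 1, mean_tlag = 1.33, cv = 0.30,
                        family = c("lognormal", "truncnorm")) {
  stopifnot(mean_tlag > 0)
  family <- match.arg(family)
  if (cv == 0) return(rep(mean_tlag, n))
  if (family == "lognormal") {
    p <- lnorm_moments(mean_tlag, cv)
    stats::rlnorm(n, p$meanlog, p$sdlog)
  } else {
    out <- numeric(0)
    while (length(out) < n) {
      x <- stats::rnorm(n, mean_tlag, cv * mean_tlag)
      out <- c(out, x[x > 0])
    }
    out[seq_len(n)]
  }
}

#' Population sampling configuration
#'
#' @param ka absorption rate constant shared across the population, 1/h.
#' @param mean_tlag,tlag_cv lag-time distribution.
#' @param F_mean,F_sd,F_lower,F_upper truncated-normal bioavailability.
#' @param faFg_mean,faFg_cv lognormal fa x Fg.
#' @param age_range,weight_mean,weight_sd demographic covariates.
#' @return list of class `population_config`.
#' @export
population_config <- function(ka = 0.24, mean_tlag = 1.33, tlag_cv = 0.30,
                              F_mean = 0.459, F_sd = 0.093,
                              F_lower = 0.33, F_upper = 0.62,
                              faFg_mean = 0.832, faFg_cv = 0.131,
                              age_range = c(20, 65),
                              weight_mean = 70, weight_sd = 12) {
  if (any(age_range <= 0) || diff(age_range) < 0) {
    stop("invalid age range")
  }
  if (weight_mean <= 0 || weight_sd < 0) stop("invalid weight parameters")
  structure(as.list(environment()), class = "population_config")
}

#' Default plasma electrolyte levels (mM)
#'
#' Used for virtual individuals whose ion concentrations are not recorded;
#' missing ions are assumed normal. Configurable.
#'
#' @return named vector `K`, `Na`, `Ca` in mM.
#' @export
normal_ions <- function() c(K = 4.2, Na = 140, Ca = 2.4)

#' Sample a virtual population
#'
#' Draws `n` individuals: absorption parameters F (truncated normal),
#' fa x Fg (lognormal) and t_lag (lognormal), plus demographic covariates.
#' Joint (F, fa x Fg) pairs with F > fa x Fg (which would imply negative
#' first-pass metabolite formation) are rejected and redrawn; the number
#' of resampled pairs is recorded in the `resample_count` attribute.
#'
#' @param n number of individuals (>= 1).
#' @param config `population_config`.
#' @param seed optional integer seed for reproducibility.
#' @return data.frame (one row per individual) with columns `id`, `age`,
#'   `sex`, `weight`, `F`, `fa_Fg`, `t_lag`, `ka`, `RR_ms`, `K`, `Na`,
#'   `Ca`, `prior_treatment`; attribute `resample_count`.
#' @export
make_population <- function(n, config = population_config(), seed = NULL) {
  stopifnot(n >= 1, inherits(config, "population_config"))
  if (!is.null(seed)) set.seed(seed)
  Fv <- numeric(n); fg <- numeric(n)
  filled <- 0L
  resamples <- 0L
  while (filled < n) {
    m <- n - filled
    f_try <- sample_F(m, config$F_mean, config$F_sd,
                      config$F_lower, config$F_upper)
    g_try <- sample_faFg(m, config$faFg_mean, config$faFg_cv)
    ok <- f_try <= g_try
    resamples <- resamples + sum(!ok)
    k <- sum(ok)
    if (k) {
      Fv[filled + seq_len(k)] <- f_try[ok]
      fg[filled + seq_len(k)] <- g_try[ok]
      filled <- filled + k
    }
  }
  tl <- sample_tlag(n, config$mean_tlag, config$tlag_cv)
  out <- data.frame(
    id = seq_len(n),
    age = round(stats::runif(n, config$age_range[1], config$age_range[2])),
    sex = sample(c("F", "M"), n, replace = TRUE),
    weight = pmax(stats::rnorm(n, config$weight_mean, config$weight_sd), 35),
    F = Fv, fa_Fg = fg, t_lag = tl, ka = config$ka,
    RR_ms = NA_real_,
    K = normal_ions()[["K"]], Na = normal_ions()[["Na"]],
    Ca = normal_ions()[["Ca"]],
    prior_treatment = FALSE
  )
  attr(out, "resample_count") <- resamples
  out
}

#' Validate an overdose case record
#'
#' A record is a list with at least `age` and `sex`, and at least one of
#' `dose_mg` or `plasma_at_ng_ml`. Optional fields: `plasma_nt_ng_ml`,
#' `rr_ms`, `ions` (named K/Na/Ca, mM), `prior_treatment`,
#' `ecg_window_h` (length-2 post-ingestion window), `ingestion_time_h`.
#'
#' @param record the case list.
#' @return the record, invisibly, after validation.
#' @export
validate_case_record <- function(record) {
  if (is.null(record$age) || is.null(record$sex)) {
    stop("case record needs at least age and sex")
  }
  if (is.null(record$dose_mg) && is.null(record$plasma_at_ng_ml)) {
    stop("case record needs an estimated dose and/or an AT plasma level")
  }
  if (!is.null(record$rr_ms) && record$rr_ms <= 0) {
    stop("RR interval must be > 0")
  }
  if (!is.null(record$dose_mg) && record$dose_mg <= 0) {
    stop("dose must be > 0")
  }
  if (!is.null(record$plasma_at_ng_ml) && record$plasma_at_ng_ml < 0) {
    stop("plasma concentration must be >= 0")
  }
  if (!is.null(record$ecg_window_h)) {
    w <- record$ecg_window_h
    if (length(w) != 2 || w[2] <= w[1] || any(w < 0)) {
      stop("ecg_window_h must be an increasing non-negative pair")
    }
  }
  invisible(record)
}

#' Build virtual twins of a real case
#'
#' Known covariates (age, sex, RR, ions, prior treatment) are fixed to the
#' record; unknown quantities (the absorption parameters, and ions/RR when
#' missing) are sampled from the population distributions, ions defaulting
#' to [normal_ions()]. Each of the `n` twins receives an independent
#' absorption parameter set.
#'
#' @param record case record (see [validate_case_record()]).
#' @param n number of twins.
#' @param config `population_config`.
#' @param seed optional seed.
#' @return data.frame as in [make_population()], with record covariates
#'   fixed; attribute `record` keeps the source record.
#' @export
make_virtual_twin <- function(record, n = 1, config = population_config(),
                              seed = NULL) {
  validate_case_record(record)
  pop <- make_population(n, config, seed)
  pop$age <- record$age
  pop$sex <- record$sex
  if (!is.null(record$weight)) pop$weight <- record$weight
  if (!is.null(record$rr_ms)) pop$RR_ms <- record$rr_ms
  ions <- normal_ions()
  if (!is.null(record$ions)) {
    for (nm in intersect(names(record$ions), names(ions))) {
      ions[nm] <- record$ions[[nm]]
    }
  }
  pop$K <- ions[["K"]]; pop$Na <- ions[["Na"]]; pop$Ca <- ions[["Ca"]]
  pop$prior_treatment <- isTRUE(record$prior_treatment)
  attr(pop, "record") <- record
  pop
}
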