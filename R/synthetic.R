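#' Virtual-trial specification
#'
#' Design of one synthetic single-dose trial whose mean plasma profiles
#' are simulated from the PBPK model and perturbed with proportional plus
#' additive noise (defaults: 10% proportional CV, 0.5 ng/mL additive
#' floor).
#'
#' @param dose_mg oral dose, mg.
#' @param times sampling times, h (strictly increasing).
#' @param noise_cv proportional noise CV.
#' @param noise_floor_ng_ml additive noise SD, ng/mL.
#' @param study_id label carried into the observation table.
#' @return list of class `trial_spec`.
#' @export
trial_spec <- function(dose_mg, times = c(1, 2, 3, 4, 6, 8, 12, 16, 24),
                       noise_cv = 0.10, noise_floor_ng_ml = 0.5,
                       study_id = paste0("trial_", dose_mg, "mg")) {
  stopifnot(dose_mg > 0, all(diff(times) > 0), noise_cv >= 0,
            noise_floor_ng_ml >= 0)
  structure(list(dose_mg = dose_mg, times = times, noise_cv = noise_cv,
                 noise_floor_ng_ml = noise_floor_ng_ml,
                 study_id = study_id),
            class = "trial_spec")
}

#' Generate one synthetic trial
#'
#' Simulates the population-mean AT and NT plasma profiles at the truth
#' absorption parameters and applies the spec's noise model; negative
#' perturbed values are clipped at zero. The truth parameters are
#' attached as an attribute so recovery experiments are self-scoring.
#'
#' @param spec `trial_spec`.
#' @param truth `absorption_params` used as simulation truth.
#' @param physiology,parent,metabolite model configuration.
#' @param seed optional integer seed.
#' @return observation data.frame (`time_h`, `analyte`,
#'   `conc_ng_per_mL`, `study_id`) with attributes `dose_mg` and `truth`.
#' @export
generate_trial <- function(spec, truth = default_absorption(),
                           physiology = default_physiology(),
                           parent = amitriptyline_params(),
                           metabolite = nortriptyline_params(),
                           seed = NULL) {
  stopifnot(inherits(spec, "trial_spec"))
  if (!is.null(seed)) set.seed(seed)
  model <- build_pbpk_model(physiology, parent, metabolite, truth)
  sim <- simulate_pbpk(model, regimen_single(spec$dose_mg), spec$times,
                       method = "matexp")
  mk <- function(analyte, conc) {
    noisy <- conc * (1 + spec$noise_cv * stats::rnorm(length(conc))) +
      spec$noise_floor_ng_ml * stats::rnorm(length(conc))
    data.frame(time_h = spec$times, analyte = analyte,
               conc_ng_per_mL = pmax(noisy, 0), study_id = spec$study_id)
  }
  out <- rbind(mk("AT", sim$data$at_plasma), mk("NT", sim$data$nt_plasma))
  attr(out, "dose_mg") <- spec$dose_mg
  attr(out, "truth") <- truth
  out
}

#' Generate the three-trial absorption-recovery problem
#'
#' Builds synthetic mean-profile observations for single oral doses
#' (default 25/50/75 mg) at the truth absorption parameters and wraps
#' them into a [fit_problem()] with the standard box (ka in [0.1, 2],
#' t_lag in [0, 2], starts 1/1).
#'
#' @param doses dose per trial, mg.
#' @param times sampling times shared by the trials, h.
#' @param truth `absorption_params` simulation truth.
#' @param noise_cv proportional noise CV.
#' @param noise_floor_ng_ml additive noise SD.
#' @param seed optional integer seed.
#' @return `fit_problem` with attribute `truth`.
#' @export
generate_fit_problem <- function(doses = c(25, 50, 75),
                                 times = c(1, 2, 3, 4, 6, 8, 12, 16, 24),
                                 truth = default_absorption(),
                                 noise_cv = 0.10,
                                 noise_floor_ng_ml = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs <- lapply(doses, function(d) {
    generate_trial(trial_spec(d, times, noise_cv, noise_floor_ng_ml),
                   truth = truth)
  })
  pr <- fit_problem(obs,
                    base_absorption = absorption_params(
                      ka = truth$ka, t_lag = truth$t_lag,
                      F = truth$F, fa_Fg = truth$fa_Fg))
  attr(pr, "truth") <- truth
  pr
}

#' Generate a synthetic concentration-RR dataset
#'
#' Log-spaced concentrations over `conc_range_uM`, RR values from the
#' corrected Emax curve at the truth parameters plus Gaussian noise
#' (default SD 120.98 ms, the scale of the literature fit's residual
#' error).
#'
#' @param truth `emax_params` simulation truth.
#' @param n_points number of points (>= 8).
#' @param conc_range_uM length-2 concentration range, uM.
#' @param noise_sd_ms Gaussian noise SD, ms.
#' @param seed optional integer seed.
#' @return data.frame (`conc_uM`, `rr_ms`) with attribute `truth`.
#' @export
generate_emax_dataset <- function(truth = emax_params(), n_points = 40,
                                  conc_range_uM = c(0.01, 10),
                                  noise_sd_ms = 120.98, seed = NULL) {
  stopifnot(n_points >= 8, all(conc_range_uM > 0),
            conc_range_uM[2] > conc_range_uM[1])
  if (!is.null(seed)) set.seed(seed)
  conc <- exp(seq(log(conc_range_uM[1]), log(conc_range_uM[2]),
                  length.out = n_points))
  rr <- rr_from_concentration(conc, truth) +
    noise_sd_ms * stats::rnorm(n_points)
  out <- data.frame(conc_uM = conc, rr_ms = rr)
  attr(out, "truth") <- truth
  out
}

#' Generate a synthetic overdose case record
#'
#' Produces a record with exactly the fields each case-group methodology
#' requires: group 1 has plasma levels but no dose; group 2 has dose,
#' plasma level and an ECG window; group 3 has a dose only. Values are
#' drawn from plausible overdose ranges (doses 500-3000 mg; plasma
#' levels straddling the RR-model EC50, about 30-1000 ng/mL).
#'
#' @param template `"group1"`, `"group2"` or `"group3"`.
#' @param seed optional integer seed.
#' @return case-record list passing [validate_case_record()].
#' @export
generate_case <- function(template = c("group1", "group2", "group3"),
                          seed = NULL) {
  template <- match.arg(template)
  if (!is.null(seed)) set.seed(seed)
  rec <- list(
    age = round(stats::runif(1, 18, 80)),
    sex = sample(c("F", "M"), 1),
    prior_treatment = stats::runif(1) < 0.3
  )
  if (stats::runif(1) < 0.5) rec$rr_ms <- round(stats::runif(1, 350, 1000))
  if (stats::runif(1) < 0.4) {
    rec$ions <- list(K = round(stats::runif(1, 3.0, 5.2), 1))
  }
  if (template %in% c("group2", "group3")) {
    rec$dose_mg <- round(stats::runif(1, 500, 3000), -1)
  }
  if (template %in% c("group1", "group2")) {
    rec$plasma_at_ng_ml <- round(exp(stats::runif(1, log(30), log(1000))))
    if (stats::runif(1) < 0.5) {
      rec$plasma_nt_ng_ml <- round(rec$plasma_at_ng_ml *
                                     stats::runif(1, 0.3, 0.8))
    }
  }
  if (template == "group2") {
    start <- round(stats::runif(1, 1, 6), 1)
    rec$ecg_window_h <- c(start, start + round(stats::runif(1, 1, 4), 1))
  }
  validate_case_record(rec)
  rec
}
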