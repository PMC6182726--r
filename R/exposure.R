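#' Free cardiac concentration from total plasma concentration
#'
#' Scales a total plasma concentration by the heart tissue-to-plasma
#' partition coefficient and the unbound fraction in heart tissue:
#' `C_free,cardiac = C_total,plasma x Kp_ht x fu_ht`. With the shipped
#' constants that is x 11.77 x 0.0012 for amitriptyline and
#' x 35.63 x 0.001 for nortriptyline.
#'
#' @param c_plasma total plasma concentration(s), ng/mL (>= 0).
#' @param compound `compound_params`.
#' @return free cardiac concentration, ng/mL.
#' @export
free_cardiac_from_plasma <- function(c_plasma, compound) {
  stopifnot(inherits(compound, "compound_params"), all(c_plasma >= 0))
  c_plasma * compound$Kp_ht * compound$fu_ht
}

#' Impute a missing nortriptyline plasma level
#'
#' When a case reports only the parent (AT) plasma level, the metabolite
#' level is assumed to equal half of it. Only call this when the NT
#' measurement is genuinely missing; a measured value always passes
#' through unchanged in the case-group machinery.
#'
#' @param c_at_plasma observed AT plasma concentration, ng/mL.
#' @return imputed NT plasma concentration, ng/mL.
#' @export
impute_nt_plasma <- function(c_at_plasma) {
  stopifnot(all(c_at_plasma >= 0))
  0.5 * c_at_plasma
}

#' Cardiac exposure container
#'
#' Time-stamped free cardiac concentrations per analyte, carried in both
#' ng/mL and uM (uM = (ng/mL) / MW with MW in g/mol).
#'
#' @param times times, h.
#' @param analyte analyte id per row ("AT"/"NT").
#' @param free_ngml free cardiac concentration, ng/mL.
#' @param mw molecular weight per row, g/mol.
#' @param provenance `"from_plasma_eq"` or `"from_simulated_heart"`.
#' @return data.frame of class `cardiac_exposure` with columns `time_h`,
#'   `analyte`, `free_cardiac_ng_per_mL`, `free_cardiac_uM`.
#' @export
cardiac_exposure <- function(times, analyte, free_ngml, mw, provenance) {
  stopifnot(all(free_ngml >= -1e-12))
  free_ngml <- pmax(free_ngml, 0)
  out <- data.frame(time_h = times, analyte = analyte,
                    free_cardiac_ng_per_mL = free_ngml,
                    free_cardiac_uM = ngml_to_uM(free_ngml, mw))
  attr(out, "provenance") <- provenance
  class(out) <- c("cardiac_exposure", "data.frame")
  out
}

#' Free cardiac exposure from a simulated heart-tissue profile
#'
#' Applies the unbound fraction in heart tissue to the simulated total
#' heart-tissue concentration. At distribution equilibrium this coincides
#' with the plasma route (`plasma x Kp_ht x fu_ht`) because the simulated
#' heart/plasma ratio equals `Kp_ht`; during rapidly changing overdose
#' kinetics the tissue route is the more faithful of the two.
#'
#' @param series `conc_series` with heart-tissue channels.
#' @param compound `compound_params` for the analyte wanted
#'   ("AT" or "NT").
#' @return `cardiac_exposure` for that analyte.
#' @export
free_cardiac_from_simulation <- function(series, compound) {
  stopifnot(inherits(series, "conc_series"))
  col <- switch(compound$name, AT = "at_heart", NT = "nt_heart",
                stop("unknown analyte ", compound$name))
  if (!col %in% names(series$data)) stop("series lacks heart channel ", col)
  cardiac_exposure(series$data$time_h, compound$name,
                   series$data[[col]] * compound$fu_ht, compound$MW,
                   "from_simulated_heart")
}

#' Case-group exposure methodologies
#'
#' Implements the three overdose-case methodologies:
#' \describe{
#'   \item{observed_plasma (group 1)}{no reliable dose available; free
#'     cardiac concentrations computed from the observed plasma levels via
#'     the partition relation, with the half-AT imputation when NT was not
#'     measured.}
#'   \item{simulated_full (group 2)}{dose and plasma level(s) both
#'     reported; the twin's toxicokinetics are simulated from the dose and
#'     the cardiac concentrations are taken at the time of the simulated
#'     maximal AT plasma concentration inside the reported ECG window.}
#'   \item{simulated_dose_only (group 3)}{no plasma level; simulated from
#'     the estimated dose alone, selecting the global simulated AT plasma
#'     maximum.}
#' }
#' If the record flags prior treatment, toxic-dose ingestion is simulated
#' on top of a 75 mg q.d. steady-state background.
#'
#' @param record case record (see [validate_case_record()]).
#' @param mode one of `"observed_plasma"`, `"simulated_full"`,
#'   `"simulated_dose_only"`.
#' @param model optional `pbpk_model`; defaults to the shipped AT/NT model.
#' @param twin optional one-row twin data.frame (otherwise mean absorption
#'   parameters are used).
#' @param t_grid simulation grid, h.
#' @return list with per-analyte `cardiac_exposure` (single selected time
#'   point for the simulated modes), `selection_time_h`, `series` (for the
#'   simulated modes) and `mode`.
#' @export
exposure_for_case_group <- function(record,
                                    mode = c("observed_plasma",
                                             "simulated_full",
                                             "simulated_dose_only"),
                                    model = NULL, twin = NULL,
                                    t_grid = seq(0, 24, by = 0.1)) {
  mode <- match.arg(mode)
  validate_case_record(record)
  at <- amitriptyline_params()
  nt <- nortriptyline_params()
  if (mode == "observed_plasma") {
    if (is.null(record$plasma_at_ng_ml)) {
      stop("observed_plasma mode requires field plasma_at_ng_ml")
    }
    c_at <- record$plasma_at_ng_ml
    c_nt <- if (!is.null(record$plasma_nt_ng_ml)) {
      record$plasma_nt_ng_ml
    } else {
      impute_nt_plasma(c_at)
    }
    t0 <- if (!is.null(record$ecg_window_h)) mean(record$ecg_window_h) else 0
    return(list(
      AT = cardiac_exposure(t0, "AT", free_cardiac_from_plasma(c_at, at),
                            at$MW, "from_plasma_eq"),
      NT = cardiac_exposure(t0, "NT", free_cardiac_from_plasma(c_nt, nt),
                            nt$MW, "from_plasma_eq"),
      selection_time_h = t0, series = NULL, mode = mode))
  }
  missing_fields <- character(0)
  if (is.null(record$dose_mg)) missing_fields <- c(missing_fields, "dose_mg")
  if (mode == "simulated_full") {
    if (is.null(record$plasma_at_ng_ml)) {
      missing_fields <- c(missing_fields, "plasma_at_ng_ml")
    }
    if (is.null(record$ecg_window_h)) {
      missing_fields <- c(missing_fields, "ecg_window_h")
    }
  }
  if (length(missing_fields)) {
    stop("mode ", mode, " requires missing field(s): ",
         paste(missing_fields, collapse = ", "))
  }
  if (is.null(model)) {
    model <- build_pbpk_model(default_physiology(), at, nt,
                              default_absorption())
  }
  state0 <- NULL
  if (isTRUE(record$prior_treatment)) {
    ss <- simulate_to_steady_state(model, regimen_single(75),
                                   individual = twin)
    state0 <- ss$state
  }
  series <- simulate_pbpk(model, regimen_single(record$dose_mg),
                          t_grid, individual = twin, method = "matexp",
                          state0 = state0)
  in_win <- if (mode == "simulated_full") {
    w <- record$ecg_window_h
    which(t_grid >= w[1] & t_grid <= w[2])
  } else {
    seq_along(t_grid)
  }
  if (!length(in_win)) stop("ECG window does not intersect the time grid")
  sel <- in_win[which.max(series$data$at_plasma[in_win])]
  t_sel <- t_grid[sel]
  list(AT = cardiac_exposure(t_sel, "AT",
                             series$data$at_heart[sel] * at$fu_ht,
                             at$MW, "from_simulated_heart"),
       NT = cardiac_exposure(t_sel, "NT",
                             series$data$nt_heart[sel] * nt$fu_ht,
                             nt$MW, "from_simulated_heart"),
       selection_time_h = t_sel, series = series, mode = mode)
}

#' Export a cardiac exposure to CSV
#'
#' @param exposure `cardiac_exposure` (or a list of them).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_exposure_csv <- function(exposure, path) {
  if (inherits(exposure, "cardiac_exposure")) exposure <- list(exposure)
  rows <- do.call(rbind, lapply(exposure, function(e) {
    cbind(as.data.frame(e), provenance = attr(e, "provenance"))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
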