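#' Compound (analyte) parameter set
#'
#' Physicochemical and disposition constants for one analyte of the
#' parent/metabolite pair. The parent (amitriptyline, AT) uses a full
#' perfusion-limited tissue set described by `Kp_map`; the metabolite
#' (nortriptyline, NT) uses a minimal two-compartment leg (central + lumped
#' "rest" tissue with partition coefficient `Kp_re`).
#'
#' @param name analyte identifier, e.g. `"AT"`.
#' @param MW molecular weight, g/mol.
#' @param Kp_ht heart tissue-to-plasma partition coefficient.
#' @param fu_ht unbound fraction in heart tissue (0, 1].
#' @param Kp_map named numeric vector of tissue-to-plasma partition
#'   coefficients for the full-PBPK leg (parent); must include `"heart"`
#'   and `"lung"` when used with a full physiology.
#' @param Kp_re "rest"-compartment partition coefficient (metabolite leg).
#' @param CL_int_h hepatic intrinsic clearance, L/h (parent -> metabolite
#'   conversion pathway).
#' @param CL_other additional systemic clearance, L/h (applied to venous
#'   blood for the parent, to the central compartment for the metabolite).
#' @param BP blood-to-plasma concentration ratio.
#' @param V_central,V_rest,Q_rest minimal-PBPK leg volumes (L) and
#'   inter-compartment flow (L/h); only used for the metabolite.
#' @return object of class `compound_params`.
#' @export
compound_params <- function(name, MW, Kp_ht, fu_ht,
                            Kp_map = NULL, Kp_re = NULL,
                            CL_int_h = 0, CL_other = 0, BP = 1,
                            V_central = NULL, V_rest = NULL, Q_rest = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(MW) || MW <= 0) stop("MW must be > 0")
  if (!is.numeric(Kp_ht) || Kp_ht <= 0) stop("Kp_ht must be > 0")
  if (!is.numeric(fu_ht) || fu_ht <= 0 || fu_ht > 1) {
    stop("fu_ht must lie in (0, 1]")
  }
  if (!is.null(Kp_map)) {
    if (is.null(names(Kp_map)) || any(!nzchar(names(Kp_map)))) {
      stop("Kp_map must be a named vector")
    }
    if (any(Kp_map <= 0)) stop("all Kp values must be > 0")
  }
  if (!is.null(Kp_re) && Kp_re <= 0) stop("Kp_re must be > 0")
  if (CL_int_h < 0 || CL_other < 0) stop("clearances must be >= 0")
  if (BP <= 0) stop("BP must be > 0")
  structure(
    list(name = name, MW = MW, Kp_ht = Kp_ht, fu_ht = fu_ht,
         Kp_map = Kp_map, Kp_re = Kp_re,
         CL_int_h = CL_int_h, CL_other = CL_other, BP = BP,
         V_central = V_central, V_rest = V_rest, Q_rest = Q_rest),
    class = "compound_params"
  )
}

#' Default amitriptyline parameter set
#'
#' Heart partitioning (`Kp_ht` = 11.77, `fu_ht` = 0.0012) and MW (277.4
#' g/mol) are the literature constants for AT; the remaining tissue
#' partition coefficients and clearances are plausible defaults chosen to
#' give a lipophilic-amine disposition (systemic clearance ~45 L/h,
#' Vss ~950 L, terminal half-life ~15 h) and are fully configurable.
#'
#' @return `compound_params` for AT.
#' @export
amitriptyline_params <- function() {
  compound_params(
    name = "AT", MW = 277.4, Kp_ht = 11.77, fu_ht = 0.0012,
    Kp_map = c(adipose = 10, bone = 8, brain = 15, gut = 15,
               heart = 11.77, kidney = 30, liver = 20, lung = 40,
               muscle = 15, skin = 10, spleen = 15, rest = 10),
    CL_int_h = 40, CL_other = 5, BP = 1
  )
}

#' Default nortriptyline parameter set
#'
#' Heart partitioning (`Kp_ht` = 35.63, `fu_ht` = 0.001) and MW (263.384
#' g/mol) are the literature constants for NT; the minimal-PBPK leg
#' (central 5 L, rest 60 L with `Kp_re` 25, inter-compartment flow
#' 150 L/h, clearance 30 L/h) gives NT a terminal half-life of ~35 h.
#'
#' @return `compound_params` for NT.
#' @export
nortriptyline_params <- function() {
  compound_params(
    name = "NT", MW = 263.384, Kp_ht = 35.63, fu_ht = 0.001,
    Kp_re = 25, CL_int_h = 0, CL_other = 30, BP = 1,
    V_central = 5, V_rest = 60, Q_rest = 150
  )
}

#' Oral absorption parameter set
#'
#' First-order absorption with lag. Bioavailability factors as
#' F = (fa x Fg) x Fh, where fa is the fraction absorbed, Fg the fraction
#' escaping gut-wall metabolism and Fh the fraction escaping hepatic
#' first-pass extraction. Fh is derived as `F / fa_Fg` and must lie in
#' (0, 1]: a sampled pair with F > fa_Fg would imply negative first-pass
#' metabolite formation and is rejected.
#'
#' @param ka first-order absorption rate constant, 1/h.
#' @param t_lag absorption lag time, h.
#' @param F oral bioavailability fraction (0, 1].
#' @param fa_Fg product fa x Fg; may exceed 1 (enterohepatic recirculation).
#' @return object of class `absorption_params` with derived field `Fh`.
#' @export
absorption_params <- function(ka, t_lag, F, fa_Fg) {
  if (!is.numeric(ka) || ka <= 0) stop("ka must be > 0")
  if (!is.numeric(t_lag) || t_lag < 0) stop("t_lag must be >= 0")
  if (!is.numeric(F) || F <= 0 || F > 1) stop("F must lie in (0, 1]")
  if (!is.numeric(fa_Fg) || fa_Fg <= 0) stop("fa_Fg must be > 0")
  Fh <- F / fa_Fg
  if (Fh > 1 + 1e-12) {
    stop("F > fa_Fg implies Fh > 1 (negative first-pass formation)")
  }
  structure(list(ka = ka, t_lag = t_lag, F = F, fa_Fg = fa_Fg,
                 Fh = min(Fh, 1)),
            class = "absorption_params")
}

#' Mean absorption parameters for oral amitriptyline
#'
#' ka = 0.24 1/h and t_lag = 1.33 h (fitted estimates), F = 0.459 and
#' fa x Fg = 0.832 (population means of the sampled distributions).
#'
#' @return `absorption_params`.
#' @export
default_absorption <- function() {
  absorption_params(ka = 0.24, t_lag = 1.33, F = 0.459, fa_Fg = 0.832)
}

#' Dose event
#'
#' @param time administration time, h (>= 0).
#' @param dose_po oral dose as free base, mg (> 0).
#' @return one-row data.frame with columns `time_h`, `dose_mg`.
#' @export
dose_event <- function(time, dose_po) {
  if (!is.numeric(time) || any(time < 0)) stop("dose time must be >= 0")
  if (!is.numeric(dose_po) || any(dose_po <= 0)) stop("dose_po must be > 0")
  data.frame(time_h = time, dose_mg = dose_po)
}

#' Dosing regimens
#'
#' `regimen_single` is one dose at `time`; `regimen_qd` is once-daily
#' dosing (`interval_h` apart) for `n_doses` administrations.
#'
#' @param dose_mg dose per administration, mg free base.
#' @param time time of the single dose, h.
#' @param n_doses number of administrations.
#' @param interval_h dosing interval, h.
#' @return data.frame with columns `time_h`, `dose_mg`.
#' @export
regimen_single <- function(dose_mg, time = 0) dose_event(time, dose_mg)

#' @rdname regimen_single
#' @export
regimen_qd <- function(dose_mg, n_doses, interval_h = 24) {
  stopifnot(n_doses >= 1)
  dose_event(seq(0, by = interval_h, length.out = n_doses), dose_mg)
}

#' Physiology specification
#'
#' Tissue volumes and blood flows for the full-PBPK parent leg. The lung is
#' held separately because it sits between the venous and arterial pools
#' and carries the whole cardiac output. `collapse_physiology()` builds a
#' degenerate single-pool physiology (no tissues) in which the model
#' reduces exactly to a one-compartment system with first-order input,
#' used as an analytic oracle.
#'
#' @param tissues data.frame with columns `name`, `volume_L`, `flow_L_h`.
#' @param V_venous,V_arterial venous/arterial blood volumes, L.
#' @param cardiac_output total cardiac output, L/h.
#' @param V_lung lung tissue volume, L.
#' @param age,sex,weight demographic covariates carried for reporting.
#' @return object of class `physiology`.
#' @export
physiology_spec <- function(tissues, V_venous, V_arterial, cardiac_output,
                            V_lung, age = 35, sex = "F", weight = 70) {
  stopifnot(is.data.frame(tissues),
            all(c("name", "volume_L", "flow_L_h") %in% names(tissues)))
  if (any(tissues$volume_L <= 0) || any(tissues$flow_L_h <= 0)) {
    stop("tissue volumes and flows must be > 0")
  }
  if (V_venous <= 0 || V_arterial <= 0 || V_lung <= 0 || cardiac_output <= 0) {
    stop("blood/lung volumes and cardiac output must be > 0")
  }
  if (sum(tissues$flow_L_h) > cardiac_output + 1e-9) {
    stop("sum of tissue flows exceeds cardiac output")
  }
  if (anyDuplicated(tissues$name)) stop("duplicated tissue names")
  structure(list(tissues = tissues, V_venous = V_venous,
                 V_arterial = V_arterial, cardiac_output = cardiac_output,
                 V_lung = V_lung, collapse = FALSE,
                 age = age, sex = sex, weight = weight),
            class = "physiology")
}

#' @rdname physiology_spec
#' @export
default_physiology <- function() {
  physiology_spec(
    tissues = data.frame(
      name = c("adipose", "bone", "brain", "gut", "heart", "kidney",
               "liver", "muscle", "skin", "spleen", "rest"),
      volume_L = c(18, 10, 1.45, 1.65, 0.33, 0.31, 1.8, 29, 7.8, 0.19, 5),
      flow_L_h = c(20, 12, 46, 60, 15, 70, 90, 45, 20, 8, 10)
    ),
    V_venous = 3.6, V_arterial = 1.6, cardiac_output = 400, V_lung = 0.55
  )
}

#' @rdname physiology_spec
#' @param V_central single-pool volume, L, for the collapse configuration.
#' @export
collapse_physiology <- function(V_central = 40) {
  stopifnot(V_central > 0)
  structure(list(collapse = TRUE, V_central = V_central,
                 age = 35, sex = "F", weight = 70),
            class = "physiology")
}

#' @export
print.compound_params <- function(x, ...) {
  cat("<compound_params>", x$name, "| MW", x$MW, "g/mol | Kp_ht", x$Kp_ht,
      "| fu_ht", x$fu_ht, "\n")
  invisible(x)
}

#' @export
print.absorption_params <- function(x, ...) {
  cat(sprintf(
    "<absorption_params> ka %.4g 1/h | t_lag %.4g h | F %.4g | fa*Fg %.4g | Fh %.4g\n",
    x$ka, x$t_lag, x$F, x$fa_Fg, x$Fh))
  invisible(x)
}
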