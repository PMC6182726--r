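#' Default conductance scalers
#'
#' Multiplicative scalers applied to the main membrane currents of the
#' ventricular cell model; 1 means no block.
#'
#' @return named numeric vector over `INa`, `IKr`, `IKs`, `IK1`, `Ito`,
#'   `ICaL`, `INaCa`, `INaK`.
#' @export
default_scalers <- function() {
  c(INa = 1, IKr = 1, IKs = 1, IK1 = 1, Ito = 1, ICaL = 1,
    INaCa = 1, INaK = 1)
}

scaler_vector <- function(scalers) {
  base <- default_scalers()
  if (!is.null(scalers)) {
    unknown <- setdiff(names(scalers), names(base))
    if (length(unknown)) stop("unknown current(s): ",
                              paste(unknown, collapse = ", "))
    base[names(scalers)] <- scalers
  }
  if (any(base < 0)) stop("scalers must be >= 0")
  base
}

celltype_code <- function(cell_type) {
  switch(cell_type, epi = 0L, endo = 1L, mid = 2L,
         stop("cell_type must be epi, endo or mid"))
}

#' Initial state of the ventricular cell model
#'
#' Resting-state values of the 19 state variables (membrane potential,
#' intracellular ion concentrations, SR calcium, release gate, and the 12
#' Hodgkin-Huxley gates).
#'
#' @return named numeric vector of length 19.
#' @export
tnnp_initial_state <- function() {
  c(V = -85.23, Ki = 136.89, Nai = 8.604, Cai = 0.000126,
    CaSS = 0.00036, CaSR = 3.64, Rprime = 0.9073,
    m = 0.00172, h = 0.7444, j = 0.7045, d = 3.373e-5, f = 0.7888,
    f2 = 0.9755, fCass = 0.9953, s = 0.999998, r = 2.42e-8,
    xs = 0.0087, xr1 = 0.00621, xr2 = 0.4712)
}

#' Right-hand side of the ventricular cell model
#'
#' Time derivative of the 19-variable state with each channel conductance
#' multiplied by its scaler. With all scalers at 1 and default ions this
#' is the published epicardial model.
#'
#' @param state named numeric state (see [tnnp_initial_state()]).
#' @param t time, ms (unused; the model is autonomous between stimuli).
#' @param scalers partial or full named scaler vector.
#' @param ions extracellular concentrations `c(K=, Na=, Ca=)`, mM.
#' @param cell_type `"epi"`, `"endo"` or `"mid"`.
#' @param stim stimulus current, A/F (negative = depolarizing).
#' @return named derivative vector (per ms).
#' @export
tnnp_rhs <- function(state, t = 0, scalers = NULL,
                     ions = c(K = 5.4, Na = 140, Ca = 2),
                     cell_type = "epi", stim = 0) {
  sc <- scaler_vector(scalers)
  d <- .tnnp_derivs_cpp(as.numeric(state), as.numeric(sc),
                        ions[["K"]], ions[["Na"]], ions[["Ca"]],
                        celltype_code(cell_type), stim)
  names(d) <- names(tnnp_initial_state())
  d
}

#' IC50-based channel block scalers
#'
#' Independent pore-block model: for each current the scaler is the
#' product over analytes of `1 / (1 + (C_free / IC50)^Hill)`, so a
#' concentration equal to the IC50 (Hill 1) halves the conductance and
#' two analytes each at their IC50 leave a quarter.
#'
#' @param conc_uM named free cardiac concentrations per analyte, uM
#'   (e.g. `c(AT = 0.5, NT = 0.2)`).
#' @param blocks block specification: a named list per analyte, each a
#'   named list per current with fields `ic50_uM` and `hill` (see
#'   [load_channel_blocks()]).
#' @return named scaler vector (only the currents present in the spec;
#'   merge with [default_scalers()] happens downstream).
#' @export
block_scalers <- function(conc_uM, blocks) {
  stopifnot(!is.null(names(conc_uM)), all(conc_uM >= 0))
  currents <- unique(unlist(lapply(blocks, names)))
  out <- stats::setNames(rep(1, length(currents)), currents)
  for (an in names(blocks)) {
    if (!an %in% names(conc_uM)) next
    cfree <- conc_uM[[an]]
    for (cur in names(blocks[[an]])) {
      spec <- blocks[[an]][[cur]]
      if (is.null(spec$ic50_uM) || is.null(spec$hill)) {
        stop("current ", cur, " of analyte ", an,
             " lacks ic50_uM and/or hill")
      }
      if (spec$ic50_uM <= 0 || spec$hill <= 0) {
        stop("IC50 and Hill must be > 0")
      }
      out[cur] <- out[cur] / (1 + (cfree / spec$ic50_uM)^spec$hill)
    }
  }
  out
}

#' Load a channel-block specification from YAML
#'
#' The shipped example file `channel_blocks_synthetic.yaml` carries
#' synthetic illustrative IC50/Hill values (real potencies for these
#' analytes are not distributed with the package).
#'
#' @param path YAML file; structure `analyte -> current -> {ic50_uM, hill}`.
#' @return nested list usable by [block_scalers()].
#' @export
load_channel_blocks <- function(path) {
  if (!file.exists(path)) stop("block spec not found: ", path)
  yaml::read_yaml(path)
}

#' Pacing protocol
#'
#' @param cl_ms cycle length (RR interval), ms (> 200).
#' @param n_beats number of paced beats (>= 3); APD is read from the last.
#' @param stim_amp stimulus amplitude, A/F (negative depolarizes).
#' @param stim_dur stimulus duration, ms.
#' @param cell_type `"epi"` (default), `"endo"` or `"mid"`.
#' @param ions extracellular K/Na/Ca, mM.
#' @return list of class `pacing_protocol`.
#' @export
pacing_protocol <- function(cl_ms = 1000, n_beats = 30, stim_amp = -52,
                            stim_dur = 1, cell_type = "epi",
                            ions = c(K = 5.4, Na = 140, Ca = 2)) {
  if (cl_ms <= 200) stop("cycle length must exceed 200 ms")
  if (n_beats < 3) stop("need at least 3 beats")
  stopifnot(all(c("K", "Na", "Ca") %in% names(ions)), all(ions > 0))
  structure(list(cl_ms = cl_ms, n_beats = n_beats, stim_amp = stim_amp,
                 stim_dur = stim_dur, cell_type = cell_type, ions = ions),
            class = "pacing_protocol")
}

#' Heart-rate correction of the QT interval
#'
#' Bazett: QT / sqrt(RR in s); Fridericia: QT / (RR in s)^(1/3); none:
#' passthrough.
#'
#' @param qt_ms QT interval, ms (> 0).
#' @param rr_ms RR interval, ms (> 0).
#' @param method `"bazett"`, `"fridericia"` or `"none"`.
#' @return corrected QT, ms.
#' @export
qtc <- function(qt_ms, rr_ms, method = c("bazett", "fridericia", "none")) {
  method <- match.arg(method)
  stopifnot(all(qt_ms > 0), all(rr_ms > 0))
  switch(method,
         bazett = qt_ms / sqrt(rr_ms / 1000),
         fridericia = qt_ms / (rr_ms / 1000)^(1 / 3),
         none = qt_ms)
}

#' Paced action potential and QT surrogate
#'
#' Paces the cell for `n_beats` beats at the protocol cycle length and
#' extracts the last beat's APD90. The single-cell QT surrogate is
#' APD90 plus a fixed depolarization offset (default 40 ms); QTc uses the
#' protocol cycle length as RR. Early afterdepolarizations (sustained
#' positive dV/dt during late repolarization) and repolarization failure
#' (membrane still above -40 mV at the next stimulus) raise the
#' arrhythmia flag.
#'
#' @param protocol `pacing_protocol`.
#' @param scalers partial named scaler vector (drug block and/or
#'   variability), merged onto [default_scalers()].
#' @param qt_offset_ms depolarization offset added to APD90.
#' @param qtc_method correction method passed to [qtc()].
#' @param dt_ms integration step, ms.
#' @param init optional initial state (default [tnnp_initial_state()]).
#' @param ead_dvdt_threshold,ead_sustain_ms EAD detector settings
#'   (mV/ms and ms).
#' @return object of class `qt_result`: `apd90`, `qt`, `qtc`,
#'   `qtc_method`, `arrhythmia`, `type` (`"none"`, `"EAD"` or
#'   `"repolarization_failure"`), per-beat APDs, final state, trace.
#' @export
paced_qt <- function(protocol = pacing_protocol(), scalers = NULL,
                     qt_offset_ms = 40, qtc_method = "bazett",
                     dt_ms = 0.02, init = NULL,
                     ead_dvdt_threshold = 0.05, ead_sustain_ms = 2) {
  stopifnot(inherits(protocol, "pacing_protocol"))
  sc <- scaler_vector(scalers)
  y0 <- if (is.null(init)) tnnp_initial_state() else init
  res <- .tnnp_paced_cpp(as.numeric(y0), as.numeric(sc),
                         protocol$ions[["K"]], protocol$ions[["Na"]],
                         protocol$ions[["Ca"]],
                         celltype_code(protocol$cell_type),
                         protocol$cl_ms, protocol$n_beats,
                         protocol$stim_amp, protocol$stim_dur, dt_ms,
                         2L, 1.0, ead_dvdt_threshold, ead_sustain_ms)
  nb <- protocol$n_beats
  repol_fail <- isTRUE(res$repol_fail[nb])
  ead <- any(res$ead[max(1, nb - 2):nb])
  apd90 <- res$apd90[nb]
  type <- if (repol_fail) "repolarization_failure" else
    if (ead) "EAD" else "none"
  qt <- if (repol_fail || is.na(apd90)) NA_real_ else apd90 + qt_offset_ms
  structure(list(
    apd90 = apd90, qt = qt,
    qtc = if (is.na(qt)) NA_real_ else qtc(qt, protocol$cl_ms, qtc_method),
    qtc_method = qtc_method,
    arrhythmia = repol_fail || ead, type = type,
    apd90_beats = res$apd90, vrest = res$vrest[nb],
    dvdtmax = res$dvdtmax[nb], state = res$state,
    trace = data.frame(time_ms = res$trace_t_ms, v_mV = res$trace_v_mV),
    protocol = protocol, scalers = sc),
    class = "qt_result")
}

#' @export
print.qt_result <- function(x, ...) {
  cat(sprintf(
    "<qt_result> APD90 %.1f ms | QT %.1f ms | QTc(%s) %.1f ms | %s\n",
    x$apd90, x$qt, x$qtc_method, x$qtc, x$type))
  invisible(x)
}

#' Seeded multi-run case simulation
#'
#' Repeats the paced-cell simulation `n_runs` times for one overdose
#' case. Drug block is computed from the supplied free cardiac
#' concentrations; each run draws an independent set of lognormal
#' conductance multipliers (CV `variability_cv` across the six main
#' currents) representing between-subject electrophysiological
#' variability, so repeated runs at identical exposure still differ.
#' The full sequence is reproducible from `seed`.
#'
#' @param exposure named free cardiac concentrations in uM per analyte
#'   (e.g. `c(AT = 0.8, NT = 0.4)`), or a list of `cardiac_exposure`
#'   objects keyed by analyte from which the (single) value is taken.
#' @param blocks channel-block specification (see [block_scalers()]).
#' @param rr_ms the RR interval to pace at; defaults to 1000 ms.
#' @param n_runs number of seeded repetitions (default 10).
#' @param seed initial seed (default 1111).
#' @param protocol optional `pacing_protocol` template; its cycle length
#'   is replaced by `rr_ms`.
#' @param variability_cv lognormal CV of the per-run conductance
#'   multipliers (0 disables variability).
#' @param qtc_method correction method.
#' @param ... further arguments to [paced_qt()].
#' @return list of class `case_runs`: `runs` (per-run data.frame),
#'   `results` (list of `qt_result`), `mean_qtc`, `sd_qtc`, `mean_qt`,
#'   `arrhythmia_count`, `seed`.
#' @export
run_case <- function(exposure, blocks, rr_ms = 1000, n_runs = 10,
                     seed = 1111, protocol = NULL, variability_cv = 0.15,
                     qtc_method = "bazett", ...) {
  if (is.list(exposure) && !is.numeric(exposure)) {
    exposure <- vapply(exposure, function(e) {
      if (inherits(e, "cardiac_exposure")) max(e$free_cardiac_uM)
      else as.numeric(e)
    }, numeric(1))
  }
  drug_sc <- block_scalers(exposure, blocks)
  if (is.null(protocol)) protocol <- pacing_protocol()
  protocol$cl_ms <- rr_ms
  set.seed(seed)
  vary <- c("INa", "IKr", "IKs", "IK1", "Ito", "ICaL")
  results <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    mult <- stats::setNames(rep(1, length(vary)), vary)
    if (variability_cv > 0) {
      p <- lnorm_moments(1, variability_cv)
      mult[] <- stats::rlnorm(length(vary), p$meanlog, p$sdlog)
    }
    sc <- default_scalers()
    sc[names(drug_sc)] <- drug_sc
    sc[vary] <- sc[vary] * mult
    results[[i]] <- paced_qt(protocol, scalers = sc,
                             qtc_method = qtc_method, ...)
  }
  runs <- data.frame(
    run = seq_len(n_runs),
    apd90 = vapply(results, function(r) r$apd90, numeric(1)),
    qt = vapply(results, function(r) as.numeric(r$qt), numeric(1)),
    qtc = vapply(results, function(r) as.numeric(r$qtc), numeric(1)),
    arrhythmia = vapply(results, function(r) r$arrhythmia, logical(1)),
    type = vapply(results, function(r) r$type, character(1))
  )
  structure(list(
    runs = runs, results = results,
    mean_qt = mean(runs$qt, na.rm = TRUE),
    mean_qtc = mean(runs$qtc, na.rm = TRUE),
    sd_qtc = stats::sd(runs$qtc, na.rm = TRUE),
    arrhythmia_count = sum(runs$arrhythmia),
    seed = seed, exposure_uM = exposure, rr_ms = rr_ms),
    class = "case_runs")
}

#' @export
print.case_runs <- function(x, ...) {
  cat(sprintf(
    "<case_runs> %d runs | mean QTc %.1f +/- %.1f ms | arrhythmia %d/%d\n",
    nrow(x$runs), x$mean_qtc, x$sd_qtc, x$arrhythmia_count, nrow(x$runs)))
  invisible(x)
}
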