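#' Load a model configuration file
#'
#' Reads a YAML or JSON configuration with sections `physiology`
#' (tissues with volumes/flows, blood volumes, cardiac output),
#' `parent` / `metabolite` (compound constants) and `absorption`, and
#' builds the corresponding parameter objects. Every section is
#' validated by the respective constructor; missing sections fall back
#' to the shipped defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return list with `physiology`, `parent`, `metabolite`, `absorption`
#'   and the `pbpk_model` built from them.
#' @export
load_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml or .json: ", path)
  }
  phys <- if (is.null(cfg$physiology)) {
    default_physiology()
  } else {
    p <- cfg$physiology
    physiology_spec(tissues = as.data.frame(p$tissues),
                    V_venous = p$V_venous, V_arterial = p$V_arterial,
                    cardiac_output = p$cardiac_output, V_lung = p$V_lung)
  }
  mk_compound <- function(section, default) {
    if (is.null(section)) return(default)
    if (!is.null(section$Kp_map)) section$Kp_map <- unlist(section$Kp_map)
    do.call(compound_params, section[names(section) %in%
                                       names(formals(compound_params))])
  }
  parent <- mk_compound(cfg$parent, amitriptyline_params())
  metabolite <- mk_compound(cfg$metabolite, nortriptyline_params())
  absorption <- if (is.null(cfg$absorption)) {
    default_absorption()
  } else {
    do.call(absorption_params, cfg$absorption[c("ka", "t_lag", "F", "fa_Fg")])
  }
  list(physiology = phys, parent = parent, metabolite = metabolite,
       absorption = absorption,
       model = build_pbpk_model(phys, parent, metabolite, absorption))
}

#' Load an overdose case record from JSON
#'
#' @param path JSON file with the case fields (see
#'   [validate_case_record()]).
#' @return validated case-record list.
#' @export
load_case_record <- function(path) {
  if (!file.exists(path)) stop("case record not found: ", path)
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(rec$ecg_window_h)) {
    rec$ecg_window_h <- as.numeric(rec$ecg_window_h)
  }
  validate_case_record(rec)
  rec
}

#' Write a concentration series to CSV
#'
#' Long format: `individual_id`, `time_h`, `analyte`,
#' `matrix` (plasma/heart), `conc_ng_per_mL`.
#'
#' @param series `conc_series` or a list of them.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_series_csv <- function(series, path) {
  if (inherits(series, "conc_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, as.data.frame))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a fitting observation table from CSV
#'
#' Requires header columns `time_h`, `analyte`, `conc_ng_per_mL` and
#' either a `dose_mg` column or an explicit `dose_mg` argument; rejects
#' malformed headers with an explicit message.
#'
#' @param path CSV file.
#' @param dose_mg dose override when the file has no `dose_mg` column.
#' @return observation data.frame with attribute `dose_mg`.
#' @export
read_observations_csv <- function(path, dose_mg = NULL) {
  if (!file.exists(path)) stop("observations file not found: ", path)
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "analyte", "conc_ng_per_mL")
  miss <- setdiff(need, names(tb))
  if (length(miss)) {
    stop("malformed observations header in ", path,
         ": missing column(s) ", paste(miss, collapse = ", "))
  }
  if (!is.numeric(tb$time_h) || !is.numeric(tb$conc_ng_per_mL)) {
    stop("time_h and conc_ng_per_mL must be numeric in ", path)
  }
  if (is.null(dose_mg)) {
    if (!"dose_mg" %in% names(tb)) {
      stop("no dose_mg column in ", path, " and no dose_mg argument")
    }
    dose_mg <- tb$dose_mg[1]
  }
  attr(tb, "dose_mg") <- dose_mg
  tb
}

run_manifest <- function(outdir, kind, seed, config_digest, extras = list()) {
  man <- c(list(kind = kind, seed = seed,
                package_version = as.character(
                  utils::packageVersion("cardiopbpk")),
                config = config_digest), extras)
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' Run a virtual-trial simulation end to end
#'
#' Population sampling, PBPK simulation for every individual, free
#' cardiac exposure, and summary outputs: per-subject long CSV, mean
#' profile CSV and a reproducibility manifest. This is the
#' population-level workflow runner.
#'
#' @param config list (or path to a YAML/JSON file holding one) with
#'   fields: `n_subjects`, `dose_mg` (and optionally `n_doses`,
#'   `interval_h`), `t_grid` (or `t_max_h`/`t_step_h`), `seed`,
#'   `outdir`, optionally `model_config` (path passed to
#'   [load_model_config()]).
#' @return list with `population`, `series` (per-subject), `mean_profile`
#'   and the written file paths, invisibly.
#' @export
simulate_trial_run <- function(config) {
  cfg <- normalize_run_config(config)
  need <- c("n_subjects", "dose_mg", "outdir")
  miss <- need[!need %in% names(cfg)]
  if (length(miss)) stop("run config missing field(s): ",
                         paste(miss, collapse = ", "))
  seed <- if (is.null(cfg$seed)) 1111 else cfg$seed
  t_grid <- if (!is.null(cfg$t_grid)) cfg$t_grid else {
    seq(0, if (is.null(cfg$t_max_h)) 24 else cfg$t_max_h,
        by = if (is.null(cfg$t_step_h)) 0.25 else cfg$t_step_h)
  }
  mc <- if (!is.null(cfg$model_config)) {
    load_model_config(cfg$model_config)
  } else {
    phys <- default_physiology()
    list(physiology = phys, parent = amitriptyline_params(),
         metabolite = nortriptyline_params(),
         absorption = default_absorption(),
         model = build_pbpk_model(phys, amitriptyline_params(),
                                  nortriptyline_params(),
                                  default_absorption()))
  }
  reg <- if (!is.null(cfg$n_doses) && cfg$n_doses > 1) {
    regimen_qd(cfg$dose_mg, cfg$n_doses,
               if (is.null(cfg$interval_h)) 24 else cfg$interval_h)
  } else {
    regimen_single(cfg$dose_mg)
  }
  pop <- make_population(cfg$n_subjects, seed = seed)
  series <- lapply(seq_len(nrow(pop)), function(i) {
    s <- simulate_pbpk(mc$model, reg, t_grid, individual = pop[i, ],
                       method = "matexp")
    s$meta$individual_id <- pop$id[i]
    s
  })
  prof <- sapply(series, function(s) s$data$at_plasma)
  prof_nt <- sapply(series, function(s) s$data$nt_plasma)
  mean_profile <- data.frame(time_h = t_grid,
                             at_plasma_mean = rowMeans(prof),
                             nt_plasma_mean = rowMeans(prof_nt))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  f_subj <- file.path(cfg$outdir, "subjects.csv")
  write_series_csv(series, f_subj)
  f_mean <- file.path(cfg$outdir, "mean_profile.csv")
  utils::write.csv(mean_profile, f_mean, row.names = FALSE)
  f_man <- run_manifest(cfg$outdir, "simulate_trial", seed,
                        cfg[setdiff(names(cfg), "outdir")],
                        list(n_subjects = cfg$n_subjects))
  invisible(list(population = pop, series = series,
                 mean_profile = mean_profile,
                 files = c(subjects = f_subj, mean = f_mean,
                           manifest = f_man)))
}

#' Run the two-stage absorption fit from a run config
#'
#' @param config list or config-file path with fields `observations`
#'   (vector of CSV paths, or omitted to generate the synthetic
#'   three-trial dataset), `seed`, `outdir`, optionally `doses`.
#' @return the `fit_result`, invisibly; writes `fit_result.json`.
#' @export
absorption_fit_run <- function(config) {
  cfg <- normalize_run_config(config)
  if (is.null(cfg$outdir)) stop("run config missing field(s): outdir")
  seed <- if (is.null(cfg$seed)) 1111 else cfg$seed
  problem <- if (!is.null(cfg$observations)) {
    obs <- lapply(cfg$observations, read_observations_csv)
    fit_problem(obs)
  } else {
    generate_fit_problem(
      doses = if (is.null(cfg$doses)) c(25, 50, 75) else cfg$doses,
      seed = seed)
  }
  fit <- fit_absorption(problem, seed = seed)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(cfg$outdir, "fit_result.json")
  jsonlite::write_json(
    list(estimates = as.list(fit$estimates),
         w_rmse_initial = fit$w_rmse_initial,
         w_rmse_final = fit$w_rmse_final,
         seed = seed, scheme = fit$scheme, n_eval = fit$n_eval),
    out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  run_manifest(cfg$outdir, "absorption_fit", seed,
               cfg[setdiff(names(cfg), "outdir")])
  invisible(fit)
}

#' Run the Emax fit from a run config
#'
#' @param config list or config-file path with fields `data` (CSV with
#'   `conc_uM`, `rr_ms`; omitted to generate a synthetic dataset),
#'   `seed`, `outdir`.
#' @return the `emax_fit`, invisibly; writes `emax_fit.json`.
#' @export
emax_fit_run <- function(config) {
  cfg <- normalize_run_config(config)
  if (is.null(cfg$outdir)) stop("run config missing field(s): outdir")
  seed <- if (is.null(cfg$seed)) 1111 else cfg$seed
  data <- if (!is.null(cfg$data)) {
    tb <- utils::read.csv(cfg$data)
    if (!all(c("conc_uM", "rr_ms") %in% names(tb))) {
      stop("malformed Emax data header in ", cfg$data)
    }
    tb
  } else {
    generate_emax_dataset(seed = seed)
  }
  fit <- fit_emax(data, seed = seed)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  p <- fit$params
  jsonlite::write_json(
    list(RR0 = p$RR0, RRmax = p$RRmax, EC50 = p$EC50, n = p$n,
         rmse = fit$rmse, seed = seed),
    file.path(cfg$outdir, "emax_fit.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  run_manifest(cfg$outdir, "emax_fit", seed,
               cfg[setdiff(names(cfg), "outdir")])
  invisible(fit)
}

#' Run a full overdose-case simulation
#'
#' Twin generation, group-appropriate exposure, RR from the record or —
#' when missing — predicted with the Emax model from the simulated AT
#' plasma profile, then the seeded ten-run paced-cell protocol. Record
#' and mode are validated before any simulation starts.
#'
#' @param config list or config-file path with fields: `record` (case
#'   list) or `record_file` (JSON path), `mode` (see
#'   [exposure_for_case_group()]), `blocks_file` (YAML channel-block
#'   spec) or `blocks` (list), `seed` (default 1111), `n_runs`
#'   (default 10), `outdir`.
#' @return list of class `case_runs` (plus `exposure` and `rr_ms`),
#'   invisibly; writes `case_summary.json`.
#' @export
case_simulation_run <- function(config) {
  cfg <- normalize_run_config(config)
  if (is.null(cfg$outdir)) stop("run config missing field(s): outdir")
  record <- if (!is.null(cfg$record)) cfg$record else {
    if (is.null(cfg$record_file)) stop("need record or record_file")
    load_case_record(cfg$record_file)
  }
  mode <- if (is.null(cfg$mode)) "observed_plasma" else cfg$mode
  validate_case_record(record)
  if (mode != "observed_plasma" && is.null(record$dose_mg)) {
    stop("mode ", mode, " needs an estimated dose in the record")
  }
  blocks <- if (!is.null(cfg$blocks)) cfg$blocks else {
    path <- if (!is.null(cfg$blocks_file)) cfg$blocks_file else {
      system.file("extdata", "channel_blocks_synthetic.yaml",
                  package = "cardiopbpk")
    }
    load_channel_blocks(path)
  }
  seed <- if (is.null(cfg$seed)) 1111 else cfg$seed
  n_runs <- if (is.null(cfg$n_runs)) 10 else cfg$n_runs
  set.seed(seed)
  twin <- make_virtual_twin(record, n = 1)
  exp_res <- exposure_for_case_group(record, mode, twin = twin)
  conc <- c(AT = max(exp_res$AT$free_cardiac_uM),
            NT = max(exp_res$NT$free_cardiac_uM))
  rr <- if (!is.null(record$rr_ms)) {
    record$rr_ms
  } else if (!is.null(exp_res$series)) {
    predict_rr_for_case(exp_res$series)
  } else {
    1000
  }
  out <- run_case(conc, blocks, rr_ms = rr, n_runs = n_runs, seed = seed)
  out$exposure <- exp_res
  out$rr_ms <- rr
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(mode = mode, seed = seed, n_runs = n_runs, rr_ms = rr,
         exposure_uM = as.list(conc),
         mean_qt = out$mean_qt, mean_qtc = out$mean_qtc,
         sd_qtc = out$sd_qtc, arrhythmia_count = out$arrhythmia_count,
         per_run = out$runs),
    file.path(cfg$outdir, "case_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  run_manifest(cfg$outdir, "case_simulation", seed,
               cfg[setdiff(names(cfg), c("outdir", "record"))])
  invisible(out)
}

normalize_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stop("run config must be a list or a file path")
  config
}
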