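#' Write and read claims-style tables
#'
#' Serializes a `raw_records` list as four (plus deaths) CSV files with a
#' JSON sidecar recording the generating parameters and seed; reading the
#' directory back reproduces the tables exactly. Dates are integer day
#' offsets from the study origin.
#'
#' @param raw A `raw_records` list.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_raw_records <- function(raw, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(raw)) {
    readr::write_csv(raw[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  params <- attr(raw, "params")
  if (!is.null(params)) {
    jsonlite::write_json(unclass(params),
                         file.path(dir, "sim_params.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

raw_schemas <- function() {
  ci <- readr::col_integer; cc <- readr::col_character
  cd <- readr::col_double; cl <- readr::col_logical
  list(
    persons = list(person_id = ci(), sex = cc(), birth_year = ci(),
                   premium_band = ci()),
    claims = list(person_id = ci(), date = ci(), icd10_code = cc(),
                  setting = cc(), revascularization = cl(),
                  brain_imaging = cl(), admission_flag = cl()),
    prescriptions = list(person_id = ci(), start_date = ci(),
                         drug_code = cc(), class = cc(),
                         daily_dose_mg = cd(), days_supplied = ci()),
    checkups = list(person_id = ci(), date = ci(), bmi = cd(), sbp = cd(),
                    dbp = cd(), fasting_glucose = cd(),
                    total_cholesterol = cd(), smoking = ci(),
                    drinking_freq = ci()),
    deaths = list(person_id = ci(), date = ci(), cause_icd10 = cc())
  )
}

#' @rdname write_raw_records
#' @export
read_raw_records <- function(dir) {
  schemas <- raw_schemas()
  out <- purrr::imap(schemas, function(cols, nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      if (nm == "deaths") {
        return(tibble(person_id = integer(), date = integer(),
                      cause_icd10 = character()))
      }
      abort(sprintf("Missing table file: %s", path),
            class = "msmcvd_io_error")
    }
    header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
    miss <- setdiff(names(cols), header)
    if (length(miss) > 0) {
      abort(sprintf("Table %s is missing column(s): %s", nm,
                    paste(miss, collapse = ", ")), class = "msmcvd_io_error")
    }
    tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                           col_types = do.call(readr::cols, cols))
    key <- names(cols)[1:2]
    bad <- which(!stats::complete.cases(tab[key]))
    if (length(bad) > 0 && nm != "persons") {
      abort(sprintf("Table %s has missing key fields at row(s) %s", nm,
                    paste(utils::head(bad, 5), collapse = ", ")),
            class = "msmcvd_io_error")
    }
    tab
  })
  structure(out, class = "raw_records")
}

#' Write/read the person-period table with a schema manifest
#'
#' @param pp Person-period tibble.
#' @param path CSV path; a `.manifest.json` sidecar lists the column types.
#' @return `path` (write) or the tibble (read).
#' @export
write_person_periods <- function(pp, path) {
  readr::write_csv(pp, path)
  jsonlite::write_json(
    list(columns = purrr::map_chr(pp, ~class(.x)[1]),
         n_rows = nrow(pp), package_version = pkg_version()),
    paste0(path, ".manifest.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_person_periods
#' @export
read_person_periods <- function(path) {
  manifest <- paste0(path, ".manifest.json")
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (file.exists(manifest)) {
    m <- jsonlite::read_json(manifest)
    miss <- setdiff(names(m$columns), names(tab))
    if (length(miss) > 0) {
      abort(sprintf("Person-period file missing column(s): %s",
                    paste(miss, collapse = ", ")), class = "msmcvd_io_error")
    }
  }
  tab
}

pkg_version <- function() {
  as.character(utils::packageVersion("msmcvd"))
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  h <- 0
  for (ch in utf8ToInt(as.character(s))) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Run configuration for the end-to-end pipeline
#'
#' Bundles every tunable of a full run: the simulation parameters, the
#' eligibility and treatment-model settings, truncation pairs and the
#' master seed. Fully serializable; [run_pipeline()] snapshots it into the
#' run directory.
#'
#' @param params [sim_params()] for the synthetic cohort.
#' @param eligibility [eligibility_config()].
#' @param trt_spec [treatment_model_spec()].
#' @param truncation_pairs Percentile pairs for the truncation sweep.
#' @param dose_response Also fit the log-dose and spline models?
#' @param seed Master seed (overrides `params$seed`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(params = sim_params(n_persons = 2000, n_intervals = 8),
                       eligibility = eligibility_config(),
                       trt_spec = treatment_model_spec(),
                       truncation_pairs = list(c(0, 100), c(1, 99),
                                               c(5, 95), c(10, 90)),
                       dose_response = TRUE,
                       seed = NULL) {
  if (!is.null(seed)) {
    params$seed <- as.integer(check_count(seed, "seed", min = 0))
  }
  structure(list(params = params, eligibility = eligibility,
                 trt_spec = trt_spec, truncation_pairs = truncation_pairs,
                 dose_response = isTRUE(dose_response)),
            class = "run_config")
}

#' End-to-end pipeline run
#'
#' Chains simulate, write/read tables, eligibility, person-period layout,
#' IPT weighting, the weighted discrete-time model, the time-fixed and
#' time-varying Cox comparators, the dose-response model, e-values and the
#' truncation sweep into one reproducible run. All artifacts (tables,
#' weights, fits, a JSON summary juxtaposing the three model estimates)
#' are written under `out_dir`; a config snapshot with its hash makes the
#' run self-describing. Identical configurations give identical summaries.
#'
#' @param config A [run_config()].
#' @param out_dir Run directory (created).
#' @param verbose Print stage progress?
#' @return The summary list, invisibly; also written as `summary.json`.
#' @export
run_pipeline <- function(config = run_config(), out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- "simulate"
  result <- tryCatch({
    say("simulating cohort (n = %d)", config$params$n_persons)
    raw <- simulate_cohort(config$params)
    write_raw_records(raw, file.path(out_dir, "raw"))
    raw <- read_raw_records(file.path(out_dir, "raw"))

    stage <- "build-cohort"
    elig <- apply_eligibility(raw, config$eligibility)
    if (nrow(elig$cohort) == 0) {
      abort("Empty cohort after eligibility.", class = "msmcvd_data_error")
    }
    pp <- build_person_periods(raw, elig$cohort)
    write_person_periods(pp, file.path(out_dir, "person_periods.csv"))

    stage <- "weights"
    mods <- fit_treatment_models(pp, config$trt_spec)
    ws <- compute_weights(pp, mods)
    readr::write_csv(ws, file.path(out_dir, "weights.csv"))
    diag <- weight_diagnostics(ws)
    readr::write_csv(diag, file.path(out_dir, "weight_diagnostics.csv"))

    stage <- "fit"
    msm <- fit_msm(pp, ws, label = "msm")
    tf <- fit_cox_time_fixed(collapse_person_periods(pp))
    tv <- fit_cox_time_varying(pp)

    dose <- NULL
    if (config$dose_response && any(pp$interval_ddd > 0)) {
      dws <- dose_exposure_weights(pp, config$trt_spec)
      dose <- fit_msm(pp, dws, exposure = "log_cum_ddd",
                      label = "msm_log_dose")
    }

    stage <- "sensitivity"
    sweep <- truncation_sweep(pp, ws, pairs = config$truncation_pairs)
    hr1 <- msm$hr[1, ]
    ev <- evalue_ci(hr1$hazard_ratio, hr1$conf_low, hr1$conf_high)

    fit_row <- function(f) {
      h <- f$hr[1, ]
      list(model = f$label, hazard_ratio = h$hazard_ratio,
           conf_low = h$conf_low, conf_high = h$conf_high,
           n_persons = f$n_persons, n_events = f$n_events)
    }
    summary <- list(
      config_hash = config_hash(config),
      package_version = pkg_version(),
      seed = config$params$seed,
      n_eligible = nrow(elig$cohort),
      exclusions = as.list(setNames(elig$exclusions$n, elig$exclusions$rule)),
      models = list(
        time_fixed_cox = fit_row(tf),
        time_varying_cox = fit_row(tv),
        msm = fit_row(msm)
      ),
      dose_response = if (!is.null(dose)) fit_row(dose),
      evalue = list(point = round_half_up(ev$evalue_point, 2),
                    ci = round_half_up(ev$evalue_ci, 2)),
      truncation_sweep = purrr::pmap(
        list(sweep$lower_pct, sweep$upper_pct, sweep$hazard_ratio,
             sweep$conf_low, sweep$conf_high),
        function(l, u, hr, lo, hi) list(lower = l, upper = u,
                                        hazard_ratio = hr,
                                        conf_low = lo, conf_high = hi))
    )
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    say("done: %s", file.path(out_dir, "summary.json"))
    summary
  }, error = function(e) {
    abort(sprintf("Pipeline failed at stage '%s': %s (artifacts so far in %s)",
                  stage, conditionMessage(e), out_dir),
          class = "msmcvd_pipeline_error", parent = e)
  })
  invisible(result)
}
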