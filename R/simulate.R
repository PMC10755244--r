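#' Simulate the latent person-period panel
#'
#' Draws the generator's longitudinal panel directly: one row per person per
#' 91-day interval while at risk, holding the latent severity process, the
#' emitted comorbidity flags, treatment, and the event indicator. This is the
#' fast path used for Monte-Carlo studies; [simulate_cohort()] renders the
#' same panel as claims-style tables for the full pipeline.
#'
#' The causal structure is: latent treatment-free severity `sev_core` follows
#' a stationary AR(1); recorded severity adds a discounted burden of past
#' treatment (`treatment_effect_on_severity`); comorbidity code flags are
#' emitted with log-odds increasing in recorded severity; treatment depends
#' on the emitted flags, prior treatment and sex; the event depends on
#' current treatment and `sev_core`. Comorbidity flags therefore confound
#' (they carry `sev_core`) while also being affected by prior treatment —
#' classic treatment-confounder feedback in which conventional regression
#' adjustment fails but IPT weighting on the flags is correctly specified.
#'
#' @param params A [sim_params()] object.
#' @param regime `"natural"` (treatment drawn from its model), `"always"` or
#'   `"never"` (deterministic regimes used by the counterfactual oracle).
#'   Random draws are aligned across regimes under the same seed.
#' @param seed Optional override of `params$seed`.
#'
#' @return A tibble with one row per person-interval at risk: identifiers,
#'   baseline covariates (`female`, `age_index`, `premium_band`), latent
#'   columns (`sev_core`, `severity`, and the true treatment probability
#'   `p_treat` — unavailable to analysis modules),
#'   comorbidity flags `cm_*`, `psych_hosp`, treatment `A`, lag `A_lag`,
#'   `ever_treated_lag`, and the event indicator `Y`.
#' @export
#' @examples
#' panel <- simulate_panel(sim_params(n_persons = 200, n_intervals = 6, seed = 7))
#' dplyr::count(panel, k)
simulate_panel <- function(params, regime = c("natural", "always", "never"),
                           seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  regime <- match.arg(regime)
  seed <- seed %||% params$seed
  n <- params$n_persons
  K <- params$n_intervals
  rho <- params$severity_autocorr
  p0 <- params$comorbidity_emission_probs
  cm_names <- paste0("cm_", names(p0))
  cm_base <- qlogis(p0)

  with_stream(seed, "panel", {
    female <- rbinom(n, 1, params$female_frac)
    age <- pmax(19, rnorm(n, params$baseline_age_mean, params$baseline_age_sd))
    premium <- sample.int(10, n, replace = TRUE)
    # per-person dispensed intensity in DDD/day (0.5, 1 or 2 times the WHO
    # reference dose); shared with the claims rendering
    dose_mult <- sample(c(0.5, 1, 2), n, replace = TRUE,
                        prob = c(0.3, 0.5, 0.2))

    sev <- rnorm(n)                 # treatment-free severity core, N(0,1)
    burden <- numeric(n)            # discounted past-treatment burden
    a_prev <- integer(n)
    ever_prev <- integer(n)
    alive <- rep(TRUE, n)
    out <- vector("list", K)

    for (k in seq_len(K) - 1L) {
      if (k > 0L) {
        sev <- rho * sev + sqrt(1 - rho^2) * rnorm(n)
        burden <- rho * burden + a_prev
      }
      severity <- sev + params$treatment_effect_on_severity * burden

      flags <- matrix(0L, n, length(p0), dimnames = list(NULL, cm_names))
      for (j in seq_along(p0)) {
        flags[, j] <- rbinom(n, 1, plogis(cm_base[j] +
                                            params$comorbidity_severity_slope * severity))
      }
      hosp <- rbinom(n, 1, plogis(-4 + 1.2 * severity))

      lp_a <- params$treatment_intercept +
        params$severity_effect_on_treatment * rowSums(flags) +
        params$treatment_persistence * a_prev +
        params$female_treatment_logit * female
      a_nat <- rbinom(n, 1, plogis(lp_a))  # drawn under every regime to keep
                                           # downstream draws aligned
      a <- switch(regime,
                  natural = a_nat,
                  always = rep(1L, n),
                  never = rep(0L, n))

      lp_y <- params$baseline_event_logit + params$causal_log_hr * a +
        params$severity_effect_on_event * sev
      u_y <- runif(n)
      y <- as.integer(u_y < plogis(lp_y))
      u_c <- runif(n)

      idx <- which(alive)
      out[[k + 1L]] <- tibble(
        person_id = idx, k = k,
        female = female[idx], age_index = age[idx],
        premium_band = premium[idx], dose_mult = dose_mult[idx],
        sev_core = sev[idx], severity = severity[idx],
        p_treat = plogis(lp_a)[idx],
        as_tibble(flags[idx, , drop = FALSE]),
        psych_hosp = hosp[idx],
        A = a[idx], A_lag = a_prev[idx], ever_treated_lag = ever_prev[idx],
        Y = y[idx]
      )

      ever_prev <- pmax(ever_prev, a)
      a_prev <- a
      alive <- alive & y == 0L & u_c >= params$censor_rate
      if (!any(alive)) {
        out <- out[seq_len(k + 1L)]
        break
      }
    }
    bind_rows(out) |> arrange(.data$person_id, .data$k)
  })
}

#' Generate a claims-style synthetic cohort
#'
#' Renders the panel drawn by [simulate_panel()] as four claims-style tables
#' (persons, diagnosis claims, prescriptions, health check-ups) plus a death
#' register, emulating the content of a national health-insurance extract:
#' a PTSD index claim (ICD-10 F43.1) defines day 0 of each person's
#' follow-up; comorbidity flags become outpatient F-code claims; psychiatric
#' hospitalizations become inpatient F-code claims with an admission flag;
#' treatment becomes antidepressant prescription rows priced in WHO defined
#' daily doses; events become inpatient/emergency MACE claims (or a
#' cardiovascular death record); and routine follow-up claims mark continued
#' enrolment so that the last claim date defines the end of follow-up.
#'
#' Each table is drawn from its own seeded random stream, so adding records
#' to one table never perturbs another. Identical `params` (and seed) give
#' byte-identical output.
#'
#' @param params A [sim_params()] object.
#' @param panel Optionally, a pre-drawn panel from [simulate_panel()] with
#'   the same params (avoids re-simulation).
#' @return An object of class `raw_records`: a list of tibbles `persons`,
#'   `claims`, `prescriptions`, `checkups`, `deaths`, with the generating
#'   `params` attached as an attribute.
#' @export
#' @examples
#' raw <- simulate_cohort(sim_params(n_persons = 50, n_intervals = 4, seed = 3))
#' names(raw)
simulate_cohort <- function(params, panel = NULL) {
  stopifnot(inherits(params, "sim_params"))
  panel <- panel %||% simulate_panel(params)
  seed <- params$seed

  index_day <- with_stream(seed, "persons", {
    sample.int(181L, params$n_persons, replace = TRUE) - 1L
  })
  person_ids <- sort(unique(panel$person_id))
  base <- panel |> filter(.data$k == 0L)
  persons <- tibble(
    person_id = base$person_id,
    sex = ifelse(base$female == 1L, "F", "M"),
    birth_year = day_to_year(index_day[base$person_id]) -
      as.integer(round(base$age_index)),
    premium_band = base$premium_band
  )

  idx <- index_day[panel$person_id]
  t0 <- idx + panel$k * 91L

  # Enrolment-marking claims: the PTSD index claim at day 0, then a routine
  # follow-up claim at the start of every at-risk interval.
  enrol <- tibble(
    person_id = panel$person_id,
    date = t0,
    icd10_code = ifelse(panel$k == 0L, "F43.1", "Z09"),
    setting = "outpatient",
    revascularization = FALSE, brain_imaging = FALSE, admission_flag = FALSE
  )

  cm_codes <- c(cm_psychotic = "F20", cm_bipolar = "F31",
                cm_depressive = "F32", cm_anxiety = "F41",
                cm_somatoform = "F45")
  cm_present <- intersect(names(cm_codes), names(panel))
  comorb <- purrr::map(seq_along(cm_present), function(j) {
    col <- cm_present[j]
    rows <- panel[[col]] == 1L
    tibble(
      person_id = panel$person_id[rows],
      date = t0[rows] + 7L + j,
      icd10_code = unname(cm_codes[col]),
      setting = "outpatient",
      revascularization = FALSE, brain_imaging = FALSE, admission_flag = FALSE
    )
  }) |> bind_rows()

  hosp_rows <- panel$psych_hosp == 1L
  hosp <- tibble(
    person_id = panel$person_id[hosp_rows],
    date = t0[hosp_rows] + 14L,
    icd10_code = "F99",
    setting = "inpatient",
    revascularization = FALSE, brain_imaging = FALSE, admission_flag = TRUE
  )

  # Events: one MACE rendering per Y = 1 row, mid-interval.
  ev_rows <- which(panel$Y == 1L)
  ev <- with_stream(seed, "events", {
    type <- sample(c("mi", "cad_revasc", "ischaemic", "haemorrhagic", "cv_death"),
                   length(ev_rows), replace = TRUE,
                   prob = c(0.20, 0.15, 0.35, 0.20, 0.10))
    tibble(row = ev_rows, type = type,
           date = t0[ev_rows] + 45L,
           person_id = panel$person_id[ev_rows])
  })
  ev_claims <- ev |>
    filter(.data$type != "cv_death") |>
    mutate(
      icd10_code = c(mi = "I21", cad_revasc = "I20", ischaemic = "I63",
                     haemorrhagic = "I61")[.data$type],
      setting = dplyr::if_else(seq_len(n()) %% 4L == 0L,
                               "emergency", "inpatient"),
      revascularization = .data$type %in% c("mi", "cad_revasc"),
      brain_imaging = .data$type %in% c("ischaemic", "haemorrhagic"),
      admission_flag = .data$setting == "inpatient"
    ) |>
    select("person_id", "date", "icd10_code", "setting",
           "revascularization", "brain_imaging", "admission_flag")
  deaths <- ev |>
    filter(.data$type == "cv_death") |>
    transmute(person_id = .data$person_id, date = .data$date,
              cause_icd10 = "I46")

  claims <- bind_rows(enrol, comorb, hosp, ev_claims) |>
    arrange(.data$person_id, .data$date, .data$icd10_code)

  ddd <- default_ddd_table()
  # Class mix loosely reflecting prescribing practice: SSRIs dominate.
  class_w <- c(SSRI = 0.55, SNRI = 0.15, TCA = 0.25, other = 0.05)
  drug_w <- unname(class_w[ddd$class]) / ave(ddd$who_ddd_mg, ddd$class,
                                             FUN = length)
  prescriptions <- with_stream(seed, "prescriptions", {
    drug_of <- ddd$drug_code[sample.int(nrow(ddd), params$n_persons,
                                        replace = TRUE, prob = drug_w)]
    mult <- numeric(params$n_persons)
    mult[base$person_id] <- base$dose_mult
    rx_rows <- which(panel$A == 1L)
    pid <- panel$person_id[rx_rows]
    tibble(
      person_id = pid,
      start_date = t0[rx_rows],
      drug_code = drug_of[pid],
      class = ddd$class[match(drug_of[pid], ddd$drug_code)],
      daily_dose_mg = mult[pid] * ddd$who_ddd_mg[match(drug_of[pid], ddd$drug_code)],
      days_supplied = 91L
    )
  }) |> arrange(.data$person_id, .data$start_date)

  last_k <- panel |> group_by(.data$person_id) |> summarise(kmax = max(.data$k))
  checkups <- with_stream(seed, "checkups", {
    n_ck <- pmax(1L, (last_k$kmax * 91L) %/% 364L + 1L)
    pid <- rep(last_k$person_id, n_ck)
    ord <- sequence(n_ck) - 1L
    tibble(
      person_id = pid,
      date = index_day[pid] - 10L + ord * 364L,
      bmi = round(rnorm(length(pid), 23.5, 3), 1),
      sbp = round(rnorm(length(pid), 120, 13)),
      dbp = round(rnorm(length(pid), 76, 9)),
      fasting_glucose = round(rnorm(length(pid), 95, 15)),
      total_cholesterol = round(rnorm(length(pid), 190, 35)),
      smoking = rbinom(length(pid), 1, 0.25),
      drinking_freq = sample.int(5L, length(pid), replace = TRUE)
    )
  }) |> arrange(.data$person_id, .data$date)

  structure(
    list(persons = persons, claims = claims, prescriptions = prescriptions,
         checkups = checkups, deaths = deaths),
    class = "raw_records", params = params
  )
}

#' @export
print.raw_records <- function(x, ...) {
  cat("<raw_records>\n")
  for (nm in names(x)) cat(sprintf("  %-13s %6d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

#' Counterfactual ground truth for the marginal treatment effect
#'
#' Monte-Carlo computation of the estimand the weighted discrete-time model
#' targets: the pooled discrete-time hazard ratio comparing the
#' deterministic regimes "always treated" and "never treated". Each regime
#' re-simulates the cohort at size `mc_n` with aligned random draws (common
#' random numbers for severity innovations and event uniforms), pools events
#' and person-intervals at risk, and forms the odds-scale hazard ratio,
#' which approximates the hazard ratio under the generator's enforced
#' rare-outcome regime. Because the treatment effect is conditional on a
#' latent severity that regimes do not move, the marginal value is close to
#' `exp(causal_log_hr)` but is computed, never assumed.
#'
#' @param params A [sim_params()] object (its `n_persons` is overridden by
#'   `mc_n`).
#' @param mc_n Monte-Carlo cohort size per regime (>= 10000).
#' @param seed Optional seed override for the oracle draws.
#' @return A list of class `truth_oracle`: `params`, `hr_always_vs_never`,
#'   `log_hr`, `mc_reps` (person-intervals simulated), and `mc_se` (SE of the
#'   log hazard ratio; the unpaired binomial form, conservative under common
#'   random numbers).
#' @export
#' @examples
#' tr <- counterfactual_truth(sim_params(seed = 2), mc_n = 20000)
#' tr$hr_always_vs_never
counterfactual_truth <- function(params, mc_n = 100000, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  mc_n <- check_count(mc_n, "mc_n", min = 10000)
  p <- params
  p$n_persons <- as.integer(mc_n)
  p <- structure(unclass(p), class = "sim_params")
  seed <- seed %||% (stream_seed(params$seed, "oracle"))

  tally <- function(regime) {
    pan <- simulate_panel(p, regime = regime, seed = seed)
    c(events = sum(pan$Y), at_risk = nrow(pan))
  }
  t1 <- tally("always")
  t0 <- tally("never")
  if (t1[["events"]] == 0 && t0[["events"]] == 0) {
    abort("Degenerate regimes: no events under either regime.",
          class = "msmcvd_estimation_error")
  }
  odds <- function(t) t[["events"]] / (t[["at_risk"]] - t[["events"]])
  log_hr <- log(odds(t1) / odds(t0))
  mc_se <- sqrt(1 / t1[["events"]] + 1 / (t1[["at_risk"]] - t1[["events"]]) +
                  1 / t0[["events"]] + 1 / (t0[["at_risk"]] - t0[["events"]]))
  structure(
    list(params = params, hr_always_vs_never = exp(log_hr), log_hr = log_hr,
         mc_reps = unname(t1[["at_risk"]] + t0[["at_risk"]]), mc_se = mc_se,
         events = c(always = unname(t1[["events"]]), never = unname(t0[["events"]]))),
    class = "truth_oracle"
  )
}

#' @export
print.truth_oracle <- function(x, ...) {
  cat(sprintf(
    "<truth_oracle> HR(always vs never) = %.4f (log %.4f, MC SE %.4f; %d events)\n",
    x$hr_always_vs_never, x$log_hr, x$mc_se, sum(x$events)))
  invisible(x)
}
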