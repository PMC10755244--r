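#' Eligibility configuration
#'
#' Settings for cohort enrolment: the cohort-defining ICD-10 code (first
#' occurrence sets the index date) and the exclusion rules applied in order:
#' (i) aged `min_age_exclusive` or younger at index, (ii) missing
#' sociodemographic data (sex, birth year or premium band), (iii) never
#' received a health check-up, (iv) prior MACE before index, (v) prior
#' antidepressant prescription before index.
#'
#' @param ptsd_code Cohort-defining ICD-10 prefix.
#' @param min_age_exclusive Persons aged this or younger at index are
#'   excluded.
#' @param require_checkup Apply rule (iii)?
#' @param code_sets [outcome_code_sets()] used for the prior-MACE screen.
#' @return A list of class `eligibility_config`.
#' @export
eligibility_config <- function(ptsd_code = "F43.1",
                               min_age_exclusive = 18,
                               require_checkup = TRUE,
                               code_sets = outcome_code_sets()) {
  if (!is.character(ptsd_code) || !nzchar(ptsd_code)) {
    abort("`ptsd_code` must be a non-empty ICD-10 string.",
          class = "msmcvd_param_error")
  }
  check_scalar(min_age_exclusive, "min_age_exclusive")
  if (min_age_exclusive < 0) {
    abort("`min_age_exclusive` must be >= 0.", class = "msmcvd_param_error")
  }
  structure(list(ptsd_code = ptsd_code,
                 min_age_exclusive = min_age_exclusive,
                 require_checkup = isTRUE(require_checkup),
                 code_sets = code_sets),
            class = "eligibility_config")
}

#' Apply enrolment eligibility filters
#'
#' Finds each person's index date (first claim matching the cohort-defining
#' code) and applies the exclusion rules sequentially, tallying exclusions
#' per rule in order (i)-(v). The retained set is order-invariant; the tally
#' attributes each excluded person to the first rule that removes them.
#'
#' @param raw A `raw_records` list (tables `persons`, `claims`,
#'   `prescriptions`, `checkups`, optionally `deaths`).
#' @param cfg An [eligibility_config()].
#' @return A list with `cohort` (tibble `person_id`, `index_date`,
#'   `age_index`, `sex`, `premium_band`) and `exclusions` (tibble `rule`,
#'   `description`, `n`).
#' @export
apply_eligibility <- function(raw, cfg = eligibility_config()) {
  claims <- as_tibble(raw$claims)
  ptsd <- claims |>
    filter(icd_prefix_match(.data$icd10_code, cfg$ptsd_code))
  if (any(is.na(ptsd$date))) {
    abort("Cohort-defining claim with missing date.",
          class = "msmcvd_data_error")
  }
  if (nrow(ptsd) == 0) {
    return(list(
      cohort = tibble(person_id = integer(), index_date = integer(),
                      age_index = numeric(), sex = character(),
                      premium_band = integer()),
      exclusions = tibble(rule = c("i", "ii", "iii", "iv", "v"),
                          description = rep("", 5), n = integer(5))
    ))
  }
  idx <- ptsd |>
    group_by(.data$person_id) |>
    summarise(index_date = min(.data$date))

  cand <- idx |>
    left_join(as_tibble(raw$persons), by = "person_id") |>
    mutate(age_index = day_to_year(.data$index_date) - .data$birth_year)

  tally <- integer(5)
  # (i) age at index <= threshold
  drop1 <- !is.na(cand$age_index) & cand$age_index <= cfg$min_age_exclusive
  tally[1] <- sum(drop1)
  cand <- cand[!drop1, , drop = FALSE]
  # (ii) missing sociodemographics
  drop2 <- is.na(cand$sex) | is.na(cand$birth_year) | is.na(cand$premium_band)
  tally[2] <- sum(drop2)
  cand <- cand[!drop2, , drop = FALSE]
  # (iii) never checked up
  if (cfg$require_checkup) {
    has_ck <- unique(raw$checkups$person_id)
    drop3 <- !(cand$person_id %in% has_ck)
    tally[3] <- sum(drop3)
    cand <- cand[!drop3, , drop = FALSE]
  }
  # (iv) prior MACE strictly before index
  prior_ev <- classify_events(claims, raw$deaths, cfg$code_sets)
  prior <- prior_ev |>
    inner_join(select(cand, "person_id", "index_date"), by = "person_id") |>
    filter(.data$event_date < .data$index_date)
  drop4 <- cand$person_id %in% prior$person_id
  tally[4] <- sum(drop4)
  cand <- cand[!drop4, , drop = FALSE]
  # (v) antidepressant prescription strictly before index
  rx <- as_tibble(raw$prescriptions) |>
    inner_join(select(cand, "person_id", "index_date"), by = "person_id") |>
    filter(.data$start_date < .data$index_date)
  drop5 <- cand$person_id %in% rx$person_id
  tally[5] <- sum(drop5)
  cand <- cand[!drop5, , drop = FALSE]

  list(
    cohort = cand |>
      select("person_id", "index_date", "age_index", "sex", "premium_band") |>
      arrange(.data$person_id),
    exclusions = tibble(
      rule = c("i", "ii", "iii", "iv", "v"),
      description = c(
        sprintf("aged %s years or younger at index", cfg$min_age_exclusive),
        "missing sociodemographic data",
        "never received a health check-up",
        "prior major cardiovascular event before index",
        "antidepressant treatment before index"
      ),
      n = tally
    )
  )
}

#' Comorbidity code groups used as time-varying covariates
#'
#' ICD-10 prefixes defining the psychiatric comorbidity indicator block:
#' psychotic disorders (F20-F25, F28, F29), manic episode/bipolar disorders
#' (F30, F31), depressive disorders (F32-F34), anxiety and related
#' disorders (F40-F43) and somatoform disorders (F45).
#'
#' @return Named list of ICD-10 prefix vectors.
#' @export
comorbidity_code_groups <- function() {
  list(
    cm_psychotic = c("F20", "F21", "F22", "F23", "F24", "F25", "F28", "F29"),
    cm_bipolar = c("F30", "F31"),
    cm_depressive = c("F32", "F33", "F34"),
    cm_anxiety = c("F40", "F41", "F42", "F43"),
    cm_somatoform = "F45"
  )
}

#' Lay out the person-period long table
#'
#' Expands each cohort member into one row per 91-day interval from the
#' index date until the first MACE or the end of records (the last claim or
#' prescription date). Per interval, computes the treatment indicator
#' (any antidepressant prescription overlapping the interval), per-class
#' indicators, interval and cumulative DDD, comorbidity code flags, the
#' psychiatric-hospitalization flag, and check-up values carried forward
#' from the most recent measurement (LOCF). Non-MACE cardiovascular
#' diagnoses do not terminate follow-up.
#'
#' @param raw A `raw_records` list.
#' @param cohort The `cohort` tibble from [apply_eligibility()].
#' @param interval_days Interval length in days (91 = one quarter).
#' @param ddd_table DDD reference from [default_ddd_table()].
#' @param code_sets [outcome_code_sets()] for event adjudication.
#' @param code_groups Comorbidity prefix groups; see
#'   [comorbidity_code_groups()].
#' @return A person-period tibble with identifiers, `k`, exposure columns
#'   (`A`, `rx_SSRI`, `rx_SNRI`, `rx_TCA`, `interval_ddd`, `cum_ddd`),
#'   covariate columns (`cm_*`, `psych_hosp`, check-up values, baseline
#'   block), `Y` and `event_type`. Persons with no post-index records get a
#'   single interval flagged `degenerate`.
#' @export
build_person_periods <- function(raw, cohort, interval_days = 91L,
                                 ddd_table = default_ddd_table(),
                                 code_sets = outcome_code_sets(),
                                 code_groups = comorbidity_code_groups()) {
  stopifnot(nrow(cohort) > 0)
  claims <- as_tibble(raw$claims) |>
    inner_join(select(cohort, "person_id", "index_date"), by = "person_id")
  rx <- as_tibble(raw$prescriptions) |>
    inner_join(select(cohort, "person_id", "index_date"), by = "person_id")

  last_claim <- bind_rows(
    claims |> transmute(.data$person_id, day = .data$date),
    rx |> transmute(.data$person_id, day = .data$start_date)
  ) |>
    group_by(.data$person_id) |>
    summarise(last_day = max(.data$day))

  events <- classify_events(claims, raw$deaths, code_sets,
                            min_date = cohort |>
                              transmute(.data$person_id,
                                        min_date = .data$index_date))

  span <- cohort |>
    left_join(last_claim, by = "person_id") |>
    left_join(events, by = "person_id") |>
    mutate(
      end_day = pmin(.data$last_day, .data$event_date, na.rm = TRUE),
      end_day = pmax(.data$end_day, .data$index_date),
      degenerate = is.na(.data$event_date) & .data$end_day <= .data$index_date,
      k_end = as.integer((.data$end_day - .data$index_date) %/% interval_days)
    )

  pp <- span |>
    mutate(k = purrr::map(.data$k_end, ~seq.int(0L, .x))) |>
    tidyr::unnest("k") |>
    transmute(
      person_id = .data$person_id, k = as.integer(.data$k),
      index_date = .data$index_date,
      t_start = .data$k * interval_days,
      t_end = (.data$k + 1L) * interval_days,
      age_index = .data$age_index,
      female = as.integer(.data$sex == "F"),
      premium_band = .data$premium_band,
      degenerate = .data$degenerate
    )

  # interval index of each claim relative to its person's index date
  claims <- claims |>
    mutate(ck = as.integer((.data$date - .data$index_date) %/% interval_days)) |>
    filter(.data$ck >= 0)

  for (g in names(code_groups)) {
    hit <- claims |>
      filter(icd_prefix_match(.data$icd10_code, code_groups[[g]])) |>
      distinct(.data$person_id, k = .data$ck) |>
      mutate(!!g := 1L)
    pp <- pp |>
      left_join(hit, by = c("person_id", "k")) |>
      mutate(!!g := ifelse(is.na(.data[[g]]), 0L, 1L))
  }
  hosp <- claims |>
    filter(grepl("^F", .data$icd10_code), .data$admission_flag) |>
    distinct(.data$person_id, k = .data$ck) |>
    mutate(psych_hosp = 1L)
  pp <- pp |>
    left_join(hosp, by = c("person_id", "k")) |>
    mutate(psych_hosp = ifelse(is.na(.data$psych_hosp), 0L, 1L))

  # exposure: prescription overlaps interval [t_k, t_{k+1})
  n_int <- span |> select("person_id", "k_end", "index_date")
  dose <- rx |>
    group_by(.data$person_id) |>
    group_split() |>
    purrr::map(function(d) {
      info <- n_int[n_int$person_id == d$person_id[1], ]
      cumulative_ddd(d, info$index_date, info$k_end + 1L, ddd_table,
                     interval_days) |>
        mutate(person_id = d$person_id[1])
    }) |>
    bind_rows()
  if (nrow(dose) > 0) {
    pp <- pp |>
      left_join(dose, by = c("person_id", "k"))
  } else {
    pp <- pp |> mutate(interval_ddd = NA_real_, cum_ddd = NA_real_)
  }
  pp <- pp |>
    mutate(interval_ddd = tidyr::replace_na(.data$interval_ddd, 0),
           cum_ddd = tidyr::replace_na(.data$cum_ddd, 0),
           A = as.integer(.data$interval_ddd > 0))
  # cum_ddd NA-fill above is only correct for untreated persons; recompute
  # running max to keep the series non-decreasing after the join
  pp <- pp |>
    group_by(.data$person_id) |>
    arrange(.data$k, .by_group = TRUE) |>
    mutate(cum_ddd = cummax(.data$cum_ddd)) |>
    ungroup()

  # per-class exposure indicators
  rx_cls <- rx |>
    mutate(class = ddd_table$class[match(.data$drug_code, ddd_table$drug_code)],
           s = .data$start_date - .data$index_date,
           e = .data$s + .data$days_supplied)
  for (cls in c("SSRI", "SNRI", "TCA")) {
    seg <- rx_cls |>
      filter(.data$class == cls) |>
      mutate(k_lo = pmax(0L, as.integer(.data$s %/% interval_days)),
             k_hi = as.integer((.data$e - 1) %/% interval_days)) |>
      mutate(k = purrr::map2(.data$k_lo, .data$k_hi, seq.int)) |>
      tidyr::unnest("k") |>
      distinct(.data$person_id, .data$k) |>
      mutate(!!paste0("rx_", cls) := 1L)
    pp <- pp |>
      left_join(seg, by = c("person_id", "k")) |>
      mutate(!!paste0("rx_", cls) :=
               ifelse(is.na(.data[[paste0("rx_", cls)]]), 0L, 1L))
  }

  # check-up values, most recent record in or before the interval (LOCF)
  ck <- as_tibble(raw$checkups) |>
    inner_join(select(cohort, "person_id", "index_date"), by = "person_id")
  ck_vars <- c("bmi", "sbp", "dbp", "fasting_glucose", "total_cholesterol",
               "smoking", "drinking_freq")
  ck_long <- ck |>
    mutate(day = .data$date - .data$index_date) |>
    select("person_id", "day", dplyr::all_of(ck_vars)) |>
    arrange(.data$person_id, .data$day)
  pp <- pp |>
    left_join(ck_long, by = dplyr::join_by("person_id", closest("t_end" > "day"))) |>
    select(-"day")

  pp |>
    mark_events(events, interval_days) |>
    arrange(.data$person_id, .data$k) |>
    add_history()
}

# Treatment-history encoding used by the weight and outcome models:
# previous-interval indicator and an ever-treated-before flag.
add_history <- function(pp) {
  pp |>
    group_by(.data$person_id) |>
    arrange(.data$k, .by_group = TRUE) |>
    mutate(
      A_lag = dplyr::lag(.data$A, default = 0L),
      ever_treated_lag = as.integer(cumsum(dplyr::lag(.data$A, default = 0L)) > 0)
    ) |>
    ungroup()
}

#' Person-period table from a simulated panel
#'
#' Adapter from the generator's latent panel ([simulate_panel()]) to the
#' analysis person-period layout, bypassing claims rendering and rebuilding.
#' Used for Monte-Carlo studies where thousands of replicates make the full
#' claims round trip wasteful; the round trip itself is validated separately.
#'
#' @param panel Output of [simulate_panel()].
#' @return Person-period tibble with the analysis columns (latent severity
#'   columns dropped).
#' @export
panel_person_periods <- function(panel) {
  panel |>
    mutate(index_date = 0L, t_start = .data$k * 91L, t_end = (.data$k + 1L) * 91L,
           event_type = ifelse(.data$Y == 1L, "MACE", "none"),
           interval_ddd = .data$A * 91 * .data$dose_mult,
           degenerate = FALSE) |>
    group_by(.data$person_id) |>
    arrange(.data$k, .by_group = TRUE) |>
    mutate(cum_ddd = cumsum(.data$interval_ddd)) |>
    ungroup() |>
    select(-dplyr::any_of(c("sev_core", "severity", "p_treat", "dose_mult")))
}
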