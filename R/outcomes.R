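#' Outcome code sets for MACE adjudication
#'
#' ICD-10 code groups defining the composite major adverse cardiovascular
#' event (MACE) and its components, with the care-setting restriction:
#' only inpatient and emergency-department diagnoses qualify, never
#' outpatient ones. Matching is by ICD-10 prefix, so "I21" covers "I21.0".
#'
#' @param mi_codes Myocardial infarction codes (qualify directly as coronary
#'   artery disease with revascularization).
#' @param other_ihd_codes Other ischaemic heart disease codes; qualify only
#'   with a revascularization procedure in the same treatment session.
#' @param ischaemic_stroke_codes,haemorrhagic_stroke_codes Stroke codes;
#'   qualify only with a brain-imaging study in the same session.
#' @param cv_death_prefix ICD-10 prefix of causes counted as cardiovascular
#'   death.
#' @param allowed_settings Care settings whose diagnoses qualify.
#' @return A list of class `outcome_code_sets`.
#' @export
outcome_code_sets <- function(mi_codes = "I21",
                              other_ihd_codes = c("I20", "I24"),
                              ischaemic_stroke_codes = "I63",
                              haemorrhagic_stroke_codes = c("I60", "I61", "I62"),
                              cv_death_prefix = "I",
                              allowed_settings = c("inpatient", "emergency")) {
  structure(list(
    mi_codes = mi_codes, other_ihd_codes = other_ihd_codes,
    ischaemic_stroke_codes = ischaemic_stroke_codes,
    haemorrhagic_stroke_codes = haemorrhagic_stroke_codes,
    cv_death_prefix = cv_death_prefix,
    allowed_settings = allowed_settings
  ), class = "outcome_code_sets")
}

icd_prefix_match <- function(codes, prefixes) {
  if (length(prefixes) == 0) return(rep(FALSE, length(codes)))
  pat <- paste0("^(", paste(gsub("\\.", "\\\\.", prefixes), collapse = "|"), ")")
  grepl(pat, codes)
}

#' Adjudicate first MACE per person
#'
#' Applies the component definitions to qualifying claims:
#' * `CAD_revasc` — myocardial infarction (I21), or other ischaemic heart
#'   disease (I20/I24) with a revascularization procedure within the same
#'   treatment session;
#' * `ischaemic_stroke` / `haemorrhagic_stroke` — the stroke code with a
#'   brain-imaging study within the same treatment session;
#' * `cv_death` — death with an ICD-10 "I" cause.
#'
#' Outpatient diagnoses never qualify. A "treatment session" is
#' operationalized as same-day claims at the same setting (for inpatient
#' claims, the admission); procedure flags are carried on the claim rows.
#' The first qualifying event (earliest date) wins; same-day qualifying
#' events of different types are resolved by the fixed precedence
#' `CAD_revasc > ischaemic_stroke > haemorrhagic_stroke > cv_death`, with a
#' warning.
#'
#' @param claims Claims tibble (`person_id`, `date`, `icd10_code`,
#'   `setting`, `revascularization`, `brain_imaging`, `admission_flag`).
#' @param deaths Death register (`person_id`, `date`, `cause_icd10`); may be
#'   `NULL` or empty.
#' @param code_sets An [outcome_code_sets()] object.
#' @param min_date Optional per-person tibble (`person_id`, `min_date`)
#'   restricting adjudication to claims on/after that date (the index).
#' @return Tibble `person_id`, `event_date`, `event_type` with one row per
#'   person having at least one qualifying event.
#' @export
classify_events <- function(claims, deaths = NULL,
                            code_sets = outcome_code_sets(),
                            min_date = NULL) {
  stopifnot(all(c("person_id", "date", "icd10_code", "setting") %in% names(claims)))
  cl <- as_tibble(claims)
  if (!is.null(min_date)) {
    cl <- cl |>
      inner_join(min_date, by = "person_id") |>
      filter(.data$date >= .data$min_date) |>
      select(-"min_date")
  }
  cl <- cl |> filter(.data$setting %in% code_sets$allowed_settings)

  cand <- cl |>
    mutate(event_type = dplyr::case_when(
      icd_prefix_match(.data$icd10_code, code_sets$mi_codes) ~ "CAD_revasc",
      icd_prefix_match(.data$icd10_code, code_sets$other_ihd_codes) &
        .data$revascularization ~ "CAD_revasc",
      icd_prefix_match(.data$icd10_code, code_sets$ischaemic_stroke_codes) &
        .data$brain_imaging ~ "ischaemic_stroke",
      icd_prefix_match(.data$icd10_code, code_sets$haemorrhagic_stroke_codes) &
        .data$brain_imaging ~ "haemorrhagic_stroke",
      TRUE ~ NA_character_
    )) |>
    filter(!is.na(.data$event_type)) |>
    select("person_id", event_date = "date", "event_type")

  if (!is.null(deaths) && nrow(deaths) > 0) {
    dd <- as_tibble(deaths)
    if (!is.null(min_date)) {
      dd <- dd |>
        inner_join(min_date, by = "person_id") |>
        filter(.data$date >= .data$min_date) |>
        select(-"min_date")
    }
    dd <- dd |>
      filter(icd_prefix_match(.data$cause_icd10, code_sets$cv_death_prefix)) |>
      transmute(person_id = .data$person_id, event_date = .data$date,
                event_type = "cv_death")
    cand <- bind_rows(cand, dd)
  }
  if (nrow(cand) == 0) {
    return(tibble(person_id = integer(), event_date = numeric(),
                  event_type = character()))
  }

  prec <- c(CAD_revasc = 1L, ischaemic_stroke = 2L,
            haemorrhagic_stroke = 3L, cv_death = 4L)
  first <- cand |>
    mutate(.prec = prec[.data$event_type]) |>
    group_by(.data$person_id) |>
    arrange(.data$event_date, .data$.prec, .by_group = TRUE) |>
    mutate(.tie = n_distinct(.data$event_type[.data$event_date == min(.data$event_date)]) > 1) |>
    slice(1) |>
    ungroup()
  if (any(first$.tie)) {
    warn(sprintf(
      "%d person(s) had same-day qualifying events of different types; fixed precedence applied.",
      sum(first$.tie)))
  }
  first |> select("person_id", "event_date", "event_type")
}

#' Mark events on the person-period table
#'
#' Sets `Y = 1` (and `event_type`) in the interval containing each person's
#' first MACE date and drops any later rows, so follow-up ends at the event.
#'
#' @param person_periods Person-period tibble with `person_id`, `k`, and an
#'   `index_date` column (or attribute) defining day 0.
#' @param events Output of [classify_events()].
#' @param interval_days Interval length in days.
#' @return The person-period tibble with `Y` and `event_type` set and
#'   post-event rows removed.
#' @export
mark_events <- function(person_periods, events, interval_days = 91L) {
  pp <- person_periods |>
    mutate(Y = 0L, event_type = "none")
  if (is.null(events) || nrow(events) == 0) return(pp)
  ev <- events |>
    inner_join(distinct(pp, .data$person_id, .data$index_date),
               by = "person_id") |>
    mutate(ev_k = as.integer((.data$event_date - .data$index_date) %/% interval_days))
  if (any(ev$ev_k < 0)) {
    abort("Event before the index date; eligibility should have excluded this person.",
          class = "msmcvd_data_error")
  }
  pp |>
    left_join(select(ev, "person_id", "ev_k", ev_type = "event_type"),
              by = "person_id") |>
    filter(is.na(.data$ev_k) | .data$k <= .data$ev_k) |>
    mutate(
      Y = as.integer(!is.na(.data$ev_k) & .data$k == .data$ev_k),
      event_type = ifelse(.data$Y == 1L, .data$ev_type, "none")
    ) |>
    select(-"ev_k", -"ev_type")
}
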