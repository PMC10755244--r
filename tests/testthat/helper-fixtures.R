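# Hand-built claims fixtures used across test files. All dates are integer
# days from the study origin (year 2004 + day/365).

# A raw-records list with full schema from compact per-table specs.
make_raw <- function(persons, claims = NULL, prescriptions = NULL,
                     checkups = NULL, deaths = NULL) {
  blank_claims <- tibble::tibble(
    person_id = integer(), date = numeric(), icd10_code = character(),
    setting = character(), revascularization = logical(),
    brain_imaging = logical(), admission_flag = logical())
  blank_rx <- tibble::tibble(
    person_id = integer(), start_date = numeric(), drug_code = character(),
    class = character(), daily_dose_mg = numeric(), days_supplied = numeric())
  blank_ck <- tibble::tibble(
    person_id = integer(), date = numeric(), bmi = numeric(), sbp = numeric(),
    dbp = numeric(), fasting_glucose = numeric(),
    total_cholesterol = numeric(), smoking = integer(),
    drinking_freq = integer())
  blank_dd <- tibble::tibble(person_id = integer(), date = numeric(),
                             cause_icd10 = character())
  structure(list(
    persons = persons,
    claims = if (is.null(claims)) blank_claims else
      dplyr::bind_rows(blank_claims, claims),
    prescriptions = if (is.null(prescriptions)) blank_rx else
      dplyr::bind_rows(blank_rx, prescriptions),
    checkups = if (is.null(checkups)) blank_ck else
      dplyr::bind_rows(blank_ck, checkups),
    deaths = if (is.null(deaths)) blank_dd else
      dplyr::bind_rows(blank_dd, deaths)
  ), class = "raw_records")
}

person_row <- function(id, sex = "F", birth_year = 1980, premium_band = 5) {
  tibble::tibble(person_id = id, sex = sex, birth_year = birth_year,
                 premium_band = premium_band)
}

claim_row <- function(id, date, code, setting = "outpatient",
                      revasc = FALSE, imaging = FALSE, admission = FALSE) {
  tibble::tibble(person_id = id, date = date, icd10_code = code,
                 setting = setting, revascularization = revasc,
                 brain_imaging = imaging, admission_flag = admission)
}

rx_row <- function(id, start, drug = "N06AB03", dose = 20, days = 30) {
  tab <- msmcvd::default_ddd_table()
  tibble::tibble(person_id = id, start_date = start, drug_code = drug,
                 class = tab$class[match(drug, tab$drug_code)],
                 daily_dose_mg = dose, days_supplied = days)
}

checkup_row <- function(id, date, bmi = 23, sbp = 120, dbp = 78,
                        glucose = 92, chol = 185, smoking = 0, drink = 1) {
  tibble::tibble(person_id = id, date = date, bmi = bmi, sbp = sbp,
                 dbp = dbp, fasting_glucose = glucose,
                 total_cholesterol = chol, smoking = smoking,
                 drinking_freq = drink)
}

# Eight-person eligibility fixture: persons 1-3 clean, 4-8 each violate one
# rule (in order i-v). Index claims on day 400 so pre-index history exists.
eligibility_fixture <- function() {
  persons <- dplyr::bind_rows(
    person_row(1), person_row(2), person_row(3),
    person_row(4, birth_year = 1987),        # age 18 at 2005 index: rule i
    person_row(5, sex = NA),                 # rule ii
    person_row(6),                           # rule iii (no checkup)
    person_row(7),                           # rule iv (prior MACE)
    person_row(8)                            # rule v (prior antidepressant)
  )
  claims <- dplyr::bind_rows(
    lapply(1:8, function(i) claim_row(i, 400, "F43.1")),
    claim_row(7, 390, "I21", setting = "inpatient")
  )
  checkups <- dplyr::bind_rows(lapply(setdiff(1:8, 6),
                                      function(i) checkup_row(i, 380)))
  rx <- rx_row(8, 300)
  make_raw(persons, claims, rx, checkups)
}

# Small simulated panel shared by several weight/model tests.
small_panel <- function(n = 600, K = 6, seed = 421, ...) {
  p <- msmcvd::sim_params(n_persons = n, n_intervals = K, seed = seed, ...)
  msmcvd::panel_person_periods(msmcvd::simulate_panel(p))
}

fit_weights_quiet <- function(pp, ...) {
  mods <- msmcvd::fit_treatment_models(pp, positivity_screen = FALSE, ...)
  msmcvd::compute_weights(pp, mods)
}
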