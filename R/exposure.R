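#' Packaged defined-daily-dose reference table
#'
#' Antidepressant reference doses in WHO ATC/DDD style: one row per drug
#' code with its medication class (SSRI, SNRI, TCA, other) and the WHO
#' defined daily dose in milligrams. The packaged table covers exemplar
#' agents of each class (e.g. fluoxetine, paroxetine, citalopram,
#' sertraline, escitalopram; venlafaxine, duloxetine, desvenlafaxine;
#' amitriptyline, clomipramine, nortriptyline, imipramine; mirtazapine,
#' trazodone). Pass a custom CSV with the same columns to cover a wider
#' formulary.
#'
#' @param path CSV with columns `drug_code,class,who_ddd_mg`; defaults to
#'   the packaged table.
#' @return A tibble with columns `drug_code`, `class`, `who_ddd_mg`.
#' @export
#' @examples
#' head(default_ddd_table())
default_ddd_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ddd_table.csv", package = "msmcvd")
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           drug_code = readr::col_character(),
                           class = readr::col_character(),
                           who_ddd_mg = readr::col_double()
                         ))
  bad <- setdiff(unique(tab$class), c("SSRI", "SNRI", "TCA", "other"))
  if (length(bad) > 0) {
    abort(paste0("Unknown medication class in DDD table: ",
                 paste(bad, collapse = ", ")), class = "msmcvd_ddd_error")
  }
  if (any(!is.finite(tab$who_ddd_mg) | tab$who_ddd_mg <= 0)) {
    abort("`who_ddd_mg` must be positive.", class = "msmcvd_ddd_error")
  }
  tab
}

#' Defined daily doses dispensed by one prescription
#'
#' `daily_dose_mg * days_supplied / who_ddd_mg`: the number of WHO defined
#' daily doses the prescription contains.
#'
#' @param daily_dose_mg Prescribed daily dose in mg (> 0).
#' @param days_supplied Days of supply (> 0).
#' @param who_ddd_mg WHO defined daily dose in mg (> 0).
#' @return DDD amount (vectorised).
#' @export
#' @examples
#' prescription_ddd(40, 30, 20) # 60 DDD
prescription_ddd <- function(daily_dose_mg, days_supplied, who_ddd_mg) {
  if (any(!is.finite(daily_dose_mg) | daily_dose_mg <= 0) ||
      any(!is.finite(days_supplied) | days_supplied <= 0) ||
      any(!is.finite(who_ddd_mg) | who_ddd_mg <= 0)) {
    abort("daily_dose_mg, days_supplied and who_ddd_mg must all be positive.",
          class = "msmcvd_ddd_error")
  }
  daily_dose_mg * days_supplied / who_ddd_mg
}

#' Per-interval and cumulative DDD for one person's prescriptions
#'
#' Allocates each prescription's dose mass to 91-day follow-up intervals
#' pro-rata by day overlap (a prescription spanning an interval boundary
#' contributes to both intervals in proportion to the days covered), then
#' accumulates: the cumulative series at interval `k` is the total DDD
#' dispensed in intervals `0..k`. Optionally restricted to one medication
#' class.
#'
#' @param prescriptions Tibble with `start_date`, `daily_dose_mg`,
#'   `days_supplied`, `drug_code` (and `class`) for one person; dates in
#'   days relative to any origin.
#' @param index_date Day of follow-up origin (interval 0 starts here).
#' @param n_intervals Number of intervals to lay out.
#' @param ddd_table Reference table from [default_ddd_table()].
#' @param interval_days Interval length in days.
#' @param class Optional class filter (`"SSRI"`, `"SNRI"`, `"TCA"`, `"other"`).
#' @return Tibble with `k`, `interval_ddd`, `cum_ddd` (`n_intervals` rows;
#'   all zero when there are no prescriptions).
#' @export
#' @examples
#' rx <- tibble::tibble(start_date = 46, drug_code = "N06AB03",
#'                      daily_dose_mg = 20, days_supplied = 91)
#' cumulative_ddd(rx, index_date = 0, n_intervals = 3)
cumulative_ddd <- function(prescriptions, index_date, n_intervals,
                           ddd_table = default_ddd_table(),
                           interval_days = 91L, class = NULL) {
  out <- tibble(k = seq_len(n_intervals) - 1L,
                interval_ddd = 0, cum_ddd = 0)
  if (is.null(prescriptions) || nrow(prescriptions) == 0) return(out)

  unknown <- setdiff(unique(prescriptions$drug_code), ddd_table$drug_code)
  if (length(unknown) > 0) {
    abort(paste0("Drug code(s) not in the DDD table: ",
                 paste(unknown, collapse = ", ")), class = "msmcvd_ddd_error")
  }
  if (any(prescriptions$start_date < index_date)) {
    abort("Prescription predates the index date; eligibility should have excluded this person.",
          class = "msmcvd_data_error")
  }
  rx <- prescriptions
  if (!is.null(class)) {
    cls <- ddd_table$class[match(rx$drug_code, ddd_table$drug_code)]
    rx <- rx[cls == class, , drop = FALSE]
    if (nrow(rx) == 0) return(out)
  }
  who <- ddd_table$who_ddd_mg[match(rx$drug_code, ddd_table$drug_code)]
  ddd_per_day <- rx$daily_dose_mg / who
  s <- rx$start_date - index_date           # day offsets from index
  e <- s + rx$days_supplied                 # half-open [s, e)

  alloc <- numeric(n_intervals)
  for (i in seq_len(nrow(rx))) {
    k_lo <- max(0L, as.integer(s[i] %/% interval_days))
    k_hi <- min(n_intervals - 1L, as.integer((e[i] - 1) %/% interval_days))
    if (k_hi < k_lo) next
    for (k in k_lo:k_hi) {
      overlap <- min(e[i], (k + 1) * interval_days) - max(s[i], k * interval_days)
      alloc[k + 1L] <- alloc[k + 1L] + overlap * ddd_per_day[i]
    }
  }
  out$interval_ddd <- alloc
  out$cum_ddd <- cumsum(alloc)
  out
}

#' Log dose transform
#'
#' `log(1 + cumulative DDD)`, so never-treated person-periods (dose 0) map
#' to 0 and the transform is monotone over the whole nonnegative range.
#'
#' @param cum_ddd Nonnegative cumulative DDD values.
#' @return `log1p(cum_ddd)`.
#' @export
#' @examples
#' log_cum_ddd(c(0, exp(1) - 1))
log_cum_ddd <- function(cum_ddd) {
  if (any(!is.finite(cum_ddd) | cum_ddd < 0)) {
    abort("`cum_ddd` must be nonnegative.", class = "msmcvd_ddd_error")
  }
  log1p(cum_ddd)
}
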