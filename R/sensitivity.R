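#' E-value for an observed risk (or rare-outcome hazard) ratio
#'
#' The minimum strength of association, on the risk-ratio scale, that an
#' unmeasured confounder would need with both exposure and outcome to fully
#' explain away an observed association:
#' `E = RR + sqrt(RR * (RR - 1))` for `RR >= 1`; ratios below 1 are
#' inverted first, so `evalue(1/RR) == evalue(RR)`. Hazard ratios are
#' accepted as risk-ratio approximations when the outcome is rare.
#'
#' @param rr Positive risk/hazard ratio (vectorised).
#' @return E-value(s) at full precision; round with [evalue_report()] for
#'   printing.
#' @export
#' @examples
#' evalue(1.34) # approximately 2.01
evalue <- function(rr) {
  if (any(!is.finite(rr) | rr <= 0)) {
    abort("`rr` must be positive.", class = "msmcvd_param_error")
  }
  rr <- ifelse(rr < 1, 1 / rr, rr)
  rr + sqrt(rr * (rr - 1))
}

#' E-value rounded for reporting
#'
#' Rounds half-up to two decimals, the printed precision used in reports;
#' full precision is retained by [evalue()].
#'
#' @param rr Positive risk/hazard ratio.
#' @param digits Decimals.
#' @return Rounded e-value(s).
#' @export
#' @examples
#' evalue_report(c(1.34, 1.45))
evalue_report <- function(rr, digits = 2) {
  round_half_up(evalue(rr), digits)
}

#' E-values for a point estimate and its confidence interval
#'
#' Computes the point-estimate e-value and the confidence-limit e-value
#' from the limit closer to the null (the lower limit when the point
#' estimate exceeds 1); when the interval contains 1 the confidence-limit
#' e-value is 1 (no unmeasured confounding is needed to explain a
#' non-significant association). Both conventions appear in applied
#' reports, so both are returned and labelled.
#'
#' @param point Point estimate of the risk/hazard ratio.
#' @param lo,hi 95% confidence limits (`lo <= point <= hi`).
#' @return A one-row tibble of class `evalue_result`: `rr_point`,
#'   `rr_ci_lower`, `rr_ci_upper`, `evalue_point`, `evalue_ci`.
#' @export
#' @examples
#' evalue_ci(1.34, 1.18, 1.53)
evalue_ci <- function(point, lo, hi) {
  check_scalar(point, "point"); check_scalar(lo, "lo"); check_scalar(hi, "hi")
  if (lo > point || point > hi) {
    abort("Require lo <= point <= hi.", class = "msmcvd_param_error")
  }
  if (any(c(point, lo, hi) <= 0)) {
    abort("Ratios must be positive.", class = "msmcvd_param_error")
  }
  ev_ci <- if (lo <= 1 && hi >= 1) {
    1
  } else if (point > 1) {
    evalue(lo)
  } else {
    evalue(hi)
  }
  structure(
    tibble(rr_point = point, rr_ci_lower = lo, rr_ci_upper = hi,
           evalue_point = evalue(point), evalue_ci = ev_ci),
    class = c("evalue_result", class(tibble())))
}

#' Weight-truncation sensitivity sweep
#'
#' Re-estimates the weighted discrete-time model under progressively
#' tighter percentile truncation of the stabilized weights — by default
#' (0,100) as the untruncated reference, then (1,99), (5,95) and (10,90) —
#' the standard probe for positivity violations: materially shifting
#' estimates under truncation indicate influential extreme weights.
#'
#' @param person_periods Person-period tibble.
#' @param weights Untruncated `weight_set`.
#' @param pairs List of `c(lower, upper)` percentile pairs.
#' @param ... Passed to [fit_msm()].
#' @return Tibble with one row per pair: bounds, hazard ratio, confidence
#'   limits, and the `msm_fit` in a list column.
#' @export
truncation_sweep <- function(person_periods, weights,
                             pairs = list(c(0, 100), c(1, 99),
                                          c(5, 95), c(10, 90)),
                             ...) {
  purrr::map(pairs, function(pr) {
    fit <- tryCatch(
      fit_msm(person_periods,
              truncate_weights(weights, pr[1], pr[2]), ...),
      error = function(e) {
        abort(sprintf("Fit failed at truncation (%g, %g): %s",
                      pr[1], pr[2], conditionMessage(e)),
              class = "msmcvd_estimation_error")
      })
    hr1 <- fit$hr[1, ]
    tibble(lower_pct = pr[1], upper_pct = pr[2],
           hazard_ratio = hr1$hazard_ratio,
           conf_low = hr1$conf_low, conf_high = hr1$conf_high,
           fit = list(fit))
  }) |> bind_rows()
}

#' Default comorbidity groups for the exclusion reanalysis
#' @return Named list of ICD-10 prefix vectors.
#' @export
default_exclusion_groups <- function() {
  g <- comorbidity_code_groups()[c("cm_psychotic", "cm_bipolar",
                                   "cm_anxiety", "cm_somatoform")]
  g$cm_anxiety <- c("F40", "F41", "F42")
  g
}

#' Comorbidity-exclusion reanalysis
#'
#' Re-runs the pipeline after dropping all persons who ever carry a claim
#' in a given psychiatric comorbidity code group (psychotic, bipolar,
#' anxiety, somatoform, ...), one group at a time, to probe whether a
#' single comorbidity stratum drives the estimate.
#'
#' @param raw A `raw_records` list.
#' @param cohort Eligible cohort from [apply_eligibility()].
#' @param groups Named list of ICD-10 prefix vectors. The default takes the
#'   psychotic, bipolar, anxiety and somatoform groups of
#'   [comorbidity_code_groups()], with the anxiety group restricted to
#'   F40-F42: the F43 block contains the cohort-defining PTSD code, so
#'   excluding it verbatim would empty the cohort.
#' @param spec Treatment-model specification.
#' @param ... Passed to [fit_msm()].
#' @return Tibble with one row per excluded group: sizes, hazard ratio,
#'   confidence limits and the fit.
#' @export
comorbidity_exclusion_reanalysis <- function(raw, cohort,
                                             groups = default_exclusion_groups(),
                                             spec = treatment_model_spec(),
                                             ...) {
  claims <- as_tibble(raw$claims)
  purrr::imap(groups, function(prefixes, gname) {
    carriers <- claims |>
      filter(icd_prefix_match(.data$icd10_code, prefixes)) |>
      distinct(.data$person_id)
    sub <- cohort |> filter(!.data$person_id %in% carriers$person_id)
    if (nrow(sub) == 0) {
      abort(sprintf("Excluding group %s empties the cohort.", gname),
            class = "msmcvd_data_error")
    }
    pp <- build_person_periods(raw, sub)
    mods <- fit_treatment_models(pp, spec)
    ws <- compute_weights(pp, mods)
    fit <- fit_msm(pp, ws, ...)
    hr1 <- fit$hr[1, ]
    tibble(excluded_group = gname,
           n_excluded = nrow(cohort) - nrow(sub),
           n_persons = nrow(sub), n_events = fit$n_events,
           hazard_ratio = hr1$hazard_ratio,
           conf_low = hr1$conf_low, conf_high = hr1$conf_high,
           fit = list(fit))
  }) |> bind_rows()
}
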