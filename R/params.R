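#' Simulation parameters for the synthetic claims generator
#'
#' Bundles and validates the parameters of the synthetic cohort generator.
#' The generator emulates a claims database of adults followed from a PTSD
#' index diagnosis: a latent, autoregressive psychiatric severity process
#' emits comorbidity diagnosis codes; recorded comorbidity burden drives
#' antidepressant dispensing; and a rare per-interval cardiovascular event
#' hazard depends on current treatment and on the treatment-free component
#' of severity. Treatment feeds back on future *recorded* severity (treated
#' patients stay engaged with psychiatric care and accrue more comorbidity
#' codes), which is what makes the comorbidity block a time-varying
#' confounder affected by prior treatment.
#'
#' @param n_persons Number of simulated persons.
#' @param n_intervals Maximum number of 91-day follow-up intervals.
#' @param baseline_age_mean,baseline_age_sd Age at index (years); draws are
#'   truncated at 19 so everyone passes the adult eligibility filter.
#' @param female_frac Proportion female.
#' @param severity_autocorr AR(1) coefficient of latent severity, in `[0, 1)`.
#' @param treatment_effect_on_severity Shift in recorded severity per unit of
#'   (exponentially discounted) past treatment. Positive values emulate
#'   surveillance: treated persons accumulate more recorded psychiatric codes.
#' @param severity_effect_on_treatment Log-odds of treatment per active
#'   comorbidity flag (the measured expression of severity).
#' @param causal_log_hr Conditional log-odds effect of current-interval
#'   treatment on the event; the marginal hazard-ratio estimand is obtained
#'   from [counterfactual_truth()], not from a formula.
#' @param severity_effect_on_event Log-odds of the event per unit of latent
#'   treatment-free severity.
#' @param baseline_event_logit Per-interval event log-odds at severity 0,
#'   untreated. Must keep the outcome rare (hazard < 0.1 under all regimes).
#' @param comorbidity_emission_probs Named probabilities of emitting each
#'   comorbidity code group in an interval at severity 0.
#' @param comorbidity_severity_slope Log-odds of each comorbidity flag per
#'   unit of recorded severity.
#' @param treatment_intercept Log-odds of treatment with no comorbidity flags
#'   and no prior treatment.
#' @param treatment_persistence Log-odds increment for treatment in the
#'   previous interval (dispensing episodes persist).
#' @param female_treatment_logit Extra treatment log-odds for women.
#' @param censor_rate Per-interval probability of administrative censoring
#'   (loss of claims activity) before the horizon.
#' @param seed Master seed; every random stream is derived from it.
#'
#' @return An object of class `sim_params` (a validated named list).
#' @export
#' @examples
#' p <- sim_params(n_persons = 500, n_intervals = 8, seed = 1)
#' p$causal_log_hr
sim_params <- function(n_persons = 5000,
                       n_intervals = 12,
                       baseline_age_mean = 39.8,
                       baseline_age_sd = 12.6,
                       female_frac = 0.61,
                       severity_autocorr = 0.7,
                       treatment_effect_on_severity = 1.2,
                       severity_effect_on_treatment = 0.3,
                       causal_log_hr = log(1.34),
                       severity_effect_on_event = 0.5,
                       baseline_event_logit = -5.0,
                       comorbidity_emission_probs = c(
                         psychotic = 0.02, bipolar = 0.04, depressive = 0.20,
                         anxiety = 0.25, somatoform = 0.08
                       ),
                       comorbidity_severity_slope = 1.0,
                       treatment_intercept = -2.8,
                       treatment_persistence = 2.2,
                       female_treatment_logit = 0.2,
                       censor_rate = 0.02,
                       seed = 1L) {
  n_persons <- check_count(n_persons, "n_persons")
  n_intervals <- check_count(n_intervals, "n_intervals")
  check_scalar(baseline_age_mean, "baseline_age_mean")
  check_scalar(baseline_age_sd, "baseline_age_sd")
  check_prob(female_frac, "female_frac")
  check_scalar(severity_autocorr, "severity_autocorr")
  if (severity_autocorr < 0 || severity_autocorr >= 1) {
    abort("`severity_autocorr` must lie in [0, 1).",
          class = "msmcvd_param_error")
  }
  check_scalar(treatment_effect_on_severity, "treatment_effect_on_severity")
  check_scalar(severity_effect_on_treatment, "severity_effect_on_treatment")
  check_scalar(causal_log_hr, "causal_log_hr")
  check_scalar(severity_effect_on_event, "severity_effect_on_event")
  check_scalar(baseline_event_logit, "baseline_event_logit")
  check_prob(comorbidity_emission_probs, "comorbidity_emission_probs")
  if (is.null(names(comorbidity_emission_probs)) ||
      any(!nzchar(names(comorbidity_emission_probs)))) {
    abort("`comorbidity_emission_probs` must be a named vector.",
          class = "msmcvd_param_error")
  }
  check_scalar(comorbidity_severity_slope, "comorbidity_severity_slope")
  check_scalar(treatment_intercept, "treatment_intercept")
  check_scalar(treatment_persistence, "treatment_persistence")
  check_scalar(female_treatment_logit, "female_treatment_logit")
  check_prob(censor_rate, "censor_rate")
  check_count(seed, "seed", min = 0)

  # Rare-outcome screen: the worst-case per-interval hazard (treated, latent
  # severity three SDs above the mean) must stay below 0.1 so that
  # discrete-time odds ratios approximate hazard ratios.
  worst <- plogis(baseline_event_logit + max(causal_log_hr, 0) +
                    abs(severity_effect_on_event) * 3)
  if (worst >= 0.1) {
    abort(sprintf(
      "Event model is not in the rare-outcome regime (worst-case per-interval hazard %.3f >= 0.1).",
      worst
    ), class = "msmcvd_param_error")
  }

  structure(
    list(
      n_persons = n_persons, n_intervals = n_intervals,
      baseline_age_mean = baseline_age_mean,
      baseline_age_sd = baseline_age_sd,
      female_frac = female_frac,
      severity_autocorr = severity_autocorr,
      treatment_effect_on_severity = treatment_effect_on_severity,
      severity_effect_on_treatment = severity_effect_on_treatment,
      causal_log_hr = causal_log_hr,
      severity_effect_on_event = severity_effect_on_event,
      baseline_event_logit = baseline_event_logit,
      comorbidity_emission_probs = comorbidity_emission_probs,
      comorbidity_severity_slope = comorbidity_severity_slope,
      treatment_intercept = treatment_intercept,
      treatment_persistence = treatment_persistence,
      female_treatment_logit = female_treatment_logit,
      censor_rate = censor_rate,
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  %d persons x up to %d intervals (91 days each), seed %d\n",
              x$n_persons, x$n_intervals, x$seed))
  cat(sprintf("  causal log-HR %.3f; feedback %.2f; censor rate %.3f\n",
              x$causal_log_hr, x$treatment_effect_on_severity, x$censor_rate))
  invisible(x)
}
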