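#' Fit the weighted marginal structural discrete-time survival model
#'
#' Pooled logistic regression of the per-interval event indicator on the
#' exposure terms, a flexible interval (baseline-hazard) term, and the
#' baseline covariate block, weighted by the IPT weights; inference uses
#' the person-clustered sandwich covariance, which accounts for repeated
#' intervals within person and for the estimated weights (conservatively).
#' Under the rare-outcome regime the exponentiated exposure coefficient
#' approximates the marginal hazard ratio.
#'
#' Exposure specifications:
#' * `"binary"` — current-interval treatment `A`;
#' * `"class"` — per-class indicators `rx_SSRI`, `rx_SNRI`, `rx_TCA`;
#' * `"log_cum_ddd"` — `log(1 + cumulative DDD)` dose-response slope;
#' * `"spline"` — degree-5 spline basis of the log cumulative dose (use
#'   [spline_dose_response()] for the fitted curve).
#'
#' @param person_periods Person-period tibble.
#' @param weights A `weight_set` aligned to `person_periods` (joined on
#'   `person_id`, `k`), a bare numeric vector, or `NULL` for unweighted.
#' @param exposure Exposure specification (see above).
#' @param baseline Baseline adjustment covariates (the models are doubly
#'   adjusted for the baseline block).
#' @param history Treatment-history adjustment terms. The stabilized-weight
#'   numerator conditions on treatment history, so the outcome model must
#'   include the same history encoding for the current-exposure coefficient
#'   to be interpretable as the marginal current-treatment effect; terms
#'   that are constant in the data (e.g. in point-exposure designs) are
#'   dropped automatically.
#' @param time_term Baseline-hazard parameterization: categorical interval
#'   term for the first `time_knot` intervals with a linear tail.
#' @param time_knot Last interval with its own categorical level.
#' @param spline_spec A [spline_spec()] when `exposure = "spline"`.
#' @param robust Use the person-clustered sandwich covariance (default)?
#'   `FALSE` falls back to the model-based covariance; point estimates are
#'   unchanged. Replicate studies that only use point estimates can skip
#'   the sandwich computation.
#' @param label Model label carried into reports.
#' @return An object of class `msm_fit`: coefficients, robust covariance,
#'   a hazard-ratio table for the exposure terms, event counts and the
#'   underlying `glm` fit.
#' @export
fit_msm <- function(person_periods, weights = NULL,
                    exposure = c("binary", "class", "log_cum_ddd", "spline"),
                    baseline = c("female", "age_index", "premium_band"),
                    history = c("A_lag", "ever_treated_lag"),
                    time_term = c("factor", "linear", "none"),
                    time_knot = 12L,
                    spline_spec = NULL,
                    robust = TRUE,
                    label = NULL) {
  exposure <- match.arg(exposure)
  time_term <- match.arg(time_term)
  pp <- person_periods
  if (sum(pp$Y) == 0) {
    abort("No events; cannot estimate a hazard model.",
          class = "msmcvd_estimation_error")
  }
  if (sum(pp$Y) < 10) {
    warn(sprintf("Only %d events; estimates will be unstable.", sum(pp$Y)))
  }

  wvec <- resolve_weights(pp, weights)

  exp_terms <- switch(
    exposure,
    binary = "A",
    class = c("rx_SSRI", "rx_SNRI", "rx_TCA"),
    log_cum_ddd = "log_dose",
    spline = "sp_basis"
  )
  if (exposure == "log_cum_ddd") pp$log_dose <- log_cum_ddd(pp$cum_ddd)
  sp <- NULL
  if (exposure == "spline") {
    sp <- spline_spec %||% spline_spec()
    basis <- dose_spline_basis(pp$cum_ddd, sp)
    pp$sp_basis <- basis$X
    sp <- basis$spec
  }

  tt <- switch(time_term,
               factor = c("factor(pmin(k, time_knot))",
                          "pmax(k - time_knot, 0)"),
               linear = "k",
               none = character())
  # drop degenerate tail term when follow-up is shorter than the knot, and
  # the whole time term for single-interval (point-exposure) data
  if (time_term == "factor" && max(pp$k) <= time_knot) {
    tt <- "factor(k)"
  }
  if (dplyr::n_distinct(pp$k) < 2) {
    tt <- character()
  }
  hist_terms <- intersect(history, names(pp))
  hist_terms <- hist_terms[purrr::map_lgl(hist_terms,
                                          ~dplyr::n_distinct(pp[[.x]]) > 1)]
  form <- build_formula("Y", c(exp_terms, tt, hist_terms,
                               intersect(baseline, names(pp))))

  env <- list2env(list(time_knot = time_knot), parent = environment())
  environment(form) <- env
  fit <- stats::glm(form, data = pp, family = quasibinomial(),
                    weights = wvec)
  if (!fit$converged) {
    abort(sprintf("Hazard model did not converge in %d IRLS iterations.",
                  fit$iter), class = "msmcvd_estimation_error")
  }
  V <- if (robust) {
    cluster_vcov_glm(fit, pp$person_id)
  } else {
    stats::vcov(fit)
  }
  beta <- coef(fit)

  keep <- if (exposure == "spline") {
    grep("^sp_basis", names(beta), value = TRUE)
  } else {
    intersect(exp_terms, names(beta))
  }
  se <- sqrt(diag(V))[keep]
  hr <- tibble(
    term = keep,
    estimate = beta[keep],
    std_error = se,
    hazard_ratio = exp(beta[keep]),
    conf_low = exp(beta[keep] - qnorm(0.975) * se),
    conf_high = exp(beta[keep] + qnorm(0.975) * se),
    p_value = 2 * pnorm(-abs(beta[keep] / se))
  )

  structure(
    list(
      label = label %||% paste0("msm_", exposure),
      exposure = exposure, exposure_terms = keep,
      coefficients = beta, vcov = V, hr = hr,
      n_persons = dplyr::n_distinct(pp$person_id),
      n_events = sum(pp$Y), n_rows = nrow(pp),
      weighted = !is.null(weights),
      spline = sp, fit = fit
    ),
    class = "msm_fit"
  )
}

# Person-clustered sandwich covariance for a (quasi)binomial glm:
# bread = (X' W X)^-1, meat = sum over clusters of outer(score sums), with
# the usual M/(M-1) cluster adjustment. Agrees with sandwich::vcovCL (the
# dispersion cancels between bread and meat); kept in-package because the
# replicate studies call it thousands of times.
cluster_vcov_glm <- function(fit, cluster) {
  X <- stats::model.matrix(fit)
  r <- fit$prior.weights * (fit$y - fit$fitted.values)
  S <- rowsum(X * r, cluster)
  p <- fit$rank
  Bp <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  piv <- fit$qr$pivot[seq_len(p)]   # undo the QR column pivoting
  k <- length(coef(fit))
  B <- matrix(0, k, k, dimnames = list(names(coef(fit)), names(coef(fit))))
  B[piv, piv] <- Bp
  M <- nrow(S)
  B %*% crossprod(S) %*% B * (M / (M - 1))
}

resolve_weights <- function(pp, weights) {
  if (is.null(weights)) return(rep(1, nrow(pp)))
  if (is.numeric(weights)) {
    stopifnot(length(weights) == nrow(pp))
    return(weights)
  }
  j <- pp |>
    select("person_id", "k") |>
    left_join(weights |> select("person_id", "k", "sw"),
              by = c("person_id", "k"))
  if (any(is.na(j$sw))) {
    abort("Weights do not cover every person-period row.",
          class = "msmcvd_data_error")
  }
  j$sw
}

#' Time-fixed Cox comparator
#'
#' Conventional Cox proportional-hazards regression (Efron ties) on one row
#' per person: ever-vs-never exposure over follow-up and baseline covariate
#' values, the "time-fixed" analysis the weighted model is compared with.
#'
#' @param person_table One row per person: `time` (days of follow-up),
#'   `event` (0/1), `exposed` (0/1) and covariate columns. Build it with
#'   [collapse_person_periods()].
#' @param covariates Covariate column names to adjust for.
#' @return An object of class `msm_fit` (Cox flavour: coefficients on the
#'   log-hazard scale, robust-free model covariance).
#' @export
fit_cox_time_fixed <- function(person_table,
                               covariates = c("female", "age_index",
                                              "premium_band")) {
  if (sum(person_table$event) == 0) {
    abort("No events; cannot fit a Cox model.",
          class = "msmcvd_estimation_error")
  }
  if (length(unique(person_table$exposed)) < 2) {
    abort("Exposure indicator is constant; no estimable coefficient.",
          class = "msmcvd_estimation_error")
  }
  form <- build_formula("survival::Surv(time, event)",
                        c("exposed", intersect(covariates,
                                               names(person_table))))
  fit <- survival::coxph(form, data = person_table, ties = "efron")
  cox_as_msm_fit(fit, "cox_time_fixed", "exposed",
                 dplyr::n_distinct(person_table$person_id),
                 sum(person_table$event))
}

#' Time-varying Cox comparator
#'
#' Cox regression in counting-process layout: each person-period
#' contributes an interval `(t_start, t_end]` with current-interval
#' treatment and time-varying covariate values, the "time-varying"
#' conventional analysis. With treatment-confounder feedback this model
#' conditions on covariates affected by prior treatment and is biased for
#' the marginal effect; it is fit as a documented comparator.
#'
#' @param person_periods Person-period tibble.
#' @param covariates Covariate column names (time-varying and baseline).
#' @param cluster Use person-clustered robust variance? (Point estimates are
#'   unchanged; disable in replicate studies that only use them.)
#' @return An object of class `msm_fit`.
#' @export
fit_cox_time_varying <- function(person_periods,
                                 covariates = c(
                                   "female", "age_index", "premium_band",
                                   "cm_psychotic", "cm_bipolar",
                                   "cm_depressive", "cm_anxiety",
                                   "cm_somatoform", "psych_hosp"
                                 ),
                                 cluster = TRUE) {
  pp <- person_periods |> arrange(.data$person_id, .data$k)
  same <- pp$person_id[-1] == pp$person_id[-nrow(pp)]
  if (nrow(pp) > 1 &&
      any(same & pp$t_start[-1] < pp$t_end[-nrow(pp)])) {
    abort("Overlapping intervals within person.", class = "msmcvd_data_error")
  }
  if (sum(pp$Y) == 0) {
    abort("No events; cannot fit a Cox model.",
          class = "msmcvd_estimation_error")
  }
  form <- build_formula("survival::Surv(t_start, t_end, Y)",
                        c("A", intersect(covariates, names(pp)),
                          if (cluster) "cluster(person_id)"))
  fit <- survival::coxph(form, data = pp, ties = "efron")
  cox_as_msm_fit(fit, "cox_time_varying", "A",
                 dplyr::n_distinct(pp$person_id), sum(pp$Y))
}

cox_as_msm_fit <- function(fit, label, exp_terms, n_persons, n_events) {
  beta <- coef(fit)
  V <- stats::vcov(fit)
  keep <- intersect(exp_terms, names(beta))
  se <- sqrt(diag(V))[keep]
  hr <- tibble(
    term = keep, estimate = beta[keep], std_error = se,
    hazard_ratio = exp(beta[keep]),
    conf_low = exp(beta[keep] - qnorm(0.975) * se),
    conf_high = exp(beta[keep] + qnorm(0.975) * se),
    p_value = 2 * pnorm(-abs(beta[keep] / se))
  )
  structure(
    list(label = label, exposure = "binary", exposure_terms = keep,
         coefficients = beta, vcov = V, hr = hr,
         n_persons = n_persons, n_events = n_events,
         n_rows = fit$n, weighted = FALSE, spline = NULL, fit = fit),
    class = "msm_fit"
  )
}

#' Collapse person-periods to one row per person
#'
#' Builds the time-fixed analysis table: ever-vs-never exposure, baseline
#' (first-interval) covariate values, total follow-up time in days and the
#' event indicator.
#'
#' @param person_periods Person-period tibble.
#' @return One-row-per-person tibble with `time`, `event`, `exposed` and
#'   baseline covariates.
#' @export
collapse_person_periods <- function(person_periods) {
  agg <- person_periods |>
    group_by(.data$person_id) |>
    summarise(exposed = as.integer(any(.data$A == 1L)),
              time = max(.data$t_end),
              event = as.integer(any(.data$Y == 1L)))
  base_cols <- intersect(
    c("person_id", "female", "age_index", "premium_band",
      "cm_psychotic", "cm_bipolar", "cm_depressive", "cm_anxiety",
      "cm_somatoform", "psych_hosp", "bmi", "sbp", "dbp",
      "fasting_glucose", "total_cholesterol", "smoking", "drinking_freq"),
    names(person_periods))
  baseline <- person_periods |>
    filter(.data$k == 0L) |>
    select(dplyr::all_of(base_cols))
  left_join(agg, baseline, by = "person_id")
}

#' Degree-5 spline specification for the dose-response model
#'
#' Polynomial spline basis of degree 5 on the log-transformed cumulative
#' dose, with interior knots at the 5th, 25th, 50th, 75th and 95th
#' percentiles of cumulative DDD among exposed (positive-dose)
#' person-periods. Duplicate knots after transformation are merged with a
#' warning. The basis is anchored so the curve is an exact hazard ratio of
#' 1 at dose 0.
#'
#' @param degree Spline degree.
#' @param knot_percentiles Interior-knot percentiles of the positive
#'   cumulative-dose distribution.
#' @return A list of class `spline_spec`.
#' @export
spline_spec <- function(degree = 5L,
                        knot_percentiles = c(5, 25, 50, 75, 95)) {
  structure(list(degree = check_count(degree, "degree"),
                 knot_percentiles = knot_percentiles, knots = NULL,
                 boundary = NULL),
            class = "spline_spec")
}

dose_spline_basis <- function(cum_ddd, spec, at = NULL) {
  x <- log_cum_ddd(cum_ddd)
  if (is.null(spec$knots)) {
    pos <- cum_ddd[cum_ddd > 0]
    if (length(pos) <= spec$degree + length(spec$knot_percentiles)) {
      abort("Too few distinct positive doses for the spline basis.",
            class = "msmcvd_estimation_error")
    }
    kn <- log1p(quantile(pos, spec$knot_percentiles / 100, names = FALSE))
    kd <- unique(kn)
    if (length(kd) < length(kn)) {
      warn(sprintf("Merged %d duplicate spline knot(s).",
                   length(kn) - length(kd)))
    }
    spec$knots <- kd
    spec$boundary <- c(0, max(x))
  }
  X <- splines::bs(if (is.null(at)) x else log_cum_ddd(at),
                   knots = spec$knots, degree = spec$degree,
                   Boundary.knots = spec$boundary, intercept = FALSE)
  attr(X, "class") <- "matrix"
  list(X = X, spec = spec)
}

#' Spline dose-response curve
#'
#' Fits the weighted discrete-time model on the degree-5 spline basis of
#' log cumulative DDD and returns the fitted hazard-ratio curve relative to
#' dose 0 with pointwise 95% confidence bands (delta method on the robust
#' covariance).
#'
#' @param person_periods Person-period tibble with `cum_ddd`.
#' @param weights Dose-response `weight_set` (or `NULL`).
#' @param spec A [spline_spec()].
#' @param grid Cumulative-DDD values at which to evaluate the curve
#'   (default: 50 points spanning the observed range).
#' @inheritParams fit_msm
#' @return A list of class `dose_response`: the `msm_fit` and a `curve`
#'   tibble (`cum_ddd`, `hazard_ratio`, `conf_low`, `conf_high`).
#' @export
spline_dose_response <- function(person_periods, weights = NULL,
                                 spec = spline_spec(), grid = NULL,
                                 baseline = c("female", "age_index",
                                              "premium_band"),
                                 time_term = "factor", time_knot = 12L) {
  fit <- fit_msm(person_periods, weights, exposure = "spline",
                 baseline = baseline, time_term = time_term,
                 time_knot = time_knot, spline_spec = spec,
                 label = "msm_spline_dose")
  grid <- grid %||% seq(0, max(person_periods$cum_ddd), length.out = 50)
  B <- dose_spline_basis(person_periods$cum_ddd, fit$spline, at = grid)$X
  keep <- fit$exposure_terms
  beta <- fit$coefficients[keep]
  V <- fit$vcov[keep, keep, drop = FALSE]
  eta <- drop(B %*% beta)
  se <- sqrt(pmax(0, rowSums((B %*% V) * B)))
  curve <- tibble(
    cum_ddd = grid,
    hazard_ratio = exp(eta),
    conf_low = exp(eta - qnorm(0.975) * se),
    conf_high = exp(eta + qnorm(0.975) * se)
  )
  structure(list(fit = fit, curve = curve), class = "dose_response")
}

#' @export
print.msm_fit <- function(x, ...) {
  cat(sprintf("<msm_fit: %s> %d persons, %d events, %d rows%s\n",
              x$label, x$n_persons, x$n_events, x$n_rows,
              if (x$weighted) ", IPT-weighted" else ""))
  print(as.data.frame(x$hr), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Tidy an MSM or Cox fit
#'
#' Broom-style coefficient table: exposure terms with log-hazard estimates,
#' robust standard errors, hazard ratios and 95% confidence limits.
#'
#' @param x An `msm_fit`.
#' @param all_terms Include non-exposure (time and baseline) terms?
#' @param ... Unused.
#' @return A tibble with one row per term.
#' @method tidy msm_fit
#' @export
tidy.msm_fit <- function(x, all_terms = FALSE, ...) {
  if (!all_terms) {
    return(x$hr |> mutate(model = x$label, .before = 1))
  }
  se <- sqrt(diag(x$vcov))
  tibble(model = x$label, term = names(x$coefficients),
         estimate = unname(x$coefficients), std_error = unname(se),
         hazard_ratio = exp(unname(x$coefficients)),
         conf_low = exp(unname(x$coefficients) - qnorm(0.975) * se),
         conf_high = exp(unname(x$coefficients) + qnorm(0.975) * se),
         p_value = 2 * pnorm(-abs(unname(x$coefficients) / se)))
}

#' Glance at an MSM fit
#'
#' @param x An `msm_fit`.
#' @param ... Unused.
#' @return One-row tibble with model label, sizes and event count.
#' @method glance msm_fit
#' @export
glance.msm_fit <- function(x, ...) {
  tibble(model = x$label, n_persons = x$n_persons, n_events = x$n_events,
         n_rows = x$n_rows, weighted = x$weighted,
         n_terms = length(x$coefficients))
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
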