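#' Treatment-model specification for IPT weighting
#'
#' Declares the covariate sets of the stabilized-weight numerator and
#' denominator models. The numerator conditions on the baseline block and
#' treatment history only; the denominator additionally conditions on the
#' time-varying covariate block, so the numerator covariates are always a
#' subset of the denominator's. History enters as the previous-interval
#' treatment indicator plus an ever-treated flag; interval index enters as
#' a categorical term by default. Both models are pooled over intervals.
#'
#' @param baseline Baseline covariate column names (block V).
#' @param time_varying Time-varying covariate column names (block L).
#' @param history History encoding columns.
#' @param time_term `"factor"` (categorical interval term), `"linear"`, or
#'   `"none"`.
#' @param per_interval Fit one model per interval instead of pooling
#'   (requires enough events per interval; off by default).
#' @return A list of class `treatment_model_spec`.
#' @export
treatment_model_spec <- function(baseline = c("female", "age_index",
                                              "premium_band"),
                                 time_varying = c(
                                   "cm_psychotic", "cm_bipolar",
                                   "cm_depressive", "cm_anxiety",
                                   "cm_somatoform", "psych_hosp"
                                 ),
                                 history = c("A_lag", "ever_treated_lag"),
                                 time_term = c("factor", "linear", "none"),
                                 per_interval = FALSE) {
  time_term <- match.arg(time_term)
  structure(list(baseline = baseline, time_varying = time_varying,
                 history = history, time_term = time_term,
                 per_interval = isTRUE(per_interval)),
            class = "treatment_model_spec")
}

time_terms <- function(spec) {
  switch(spec$time_term,
         factor = "factor(k)",
         linear = "k",
         none = character())
}

build_formula <- function(lhs, terms) {
  if (length(terms) == 0) terms <- "1"
  stats::as.formula(paste(lhs, "~", paste(terms, collapse = " + ")))
}

PROB_CLIP <- c(1e-8, 1 - 1e-8)

#' Fit the stabilized-weight numerator and denominator treatment models
#'
#' Pooled logistic regressions for the per-interval probability of
#' antidepressant treatment: the denominator model conditions on baseline
#' covariates, treatment history, the interval term and the time-varying
#' covariate block; the numerator model omits the time-varying block.
#' Returns per-row fitted probabilities of the *observed* exposure level,
#' clipped to `[1e-8, 1 - 1e-8]` before any weight product (the number of
#' clipped rows is reported in the result). Fitted probabilities of exactly
#' 0 or 1 before clipping raise a positivity error; covariate patterns with
#' no treated or no untreated rows raise a positivity warning.
#'
#' @param person_periods Person-period tibble (from
#'   [build_person_periods()] or [panel_person_periods()]).
#' @param spec A [treatment_model_spec()].
#' @param positivity_screen Warn about covariate patterns with only treated
#'   or only untreated rows? (The screen is informative on full-size runs
#'   but noisy in small replicate studies.)
#' @return List of class `treatment_models`: the two `glm` fits, the
#'   per-row observed-level probabilities `p_num` and `p_den`, and
#'   `n_clipped`.
#' @export
fit_treatment_models <- function(person_periods, spec = treatment_model_spec(),
                                 positivity_screen = TRUE) {
  pp <- person_periods
  miss <- setdiff(c(spec$baseline, spec$time_varying, spec$history, "A", "k"),
                  names(pp))
  if (length(miss) > 0) {
    abort(paste0("Missing columns in person_periods: ",
                 paste(miss, collapse = ", ")), class = "msmcvd_data_error")
  }
  if (length(unique(pp$A)) < 2) {
    abort("Treatment is constant; cannot fit a treatment model.",
          class = "msmcvd_positivity_error")
  }
  if (positivity_screen) {
    # screen on the discrete part of the denominator covariates
    strata <- interaction(pp[intersect(c(spec$time_varying, spec$history),
                                       names(pp))], drop = TRUE)
    bad <- tapply(pp$A, strata, function(a) length(unique(a)) == 1)
    if (any(bad)) {
      warn(sprintf(
        "%d covariate pattern(s) have only treated or only untreated rows; weights there rely on model smoothing.",
        sum(bad)))
    }
  }

  num_terms <- c(time_terms(spec), spec$baseline, spec$history)
  den_terms <- c(num_terms, spec$time_varying)
  # one model matrix per model, fitted with the IRLS core directly: these
  # fits run inside replicate loops, so the formula/model-frame overhead of
  # a full glm() call is skipped
  X_num <- stats::model.matrix(build_formula("A", num_terms), data = pp)
  X_den <- stats::model.matrix(build_formula("A", den_terms), data = pp)
  fit1 <- suppressWarnings(stats::glm.fit(X_num, pp$A, family = binomial()))
  fit2 <- suppressWarnings(stats::glm.fit(X_den, pp$A, family = binomial()))

  p1 <- fit1$fitted.values
  p2 <- fit2$fitted.values
  sep_tol <- 1e-10  # numerically-0/1 fitted probabilities indicate separation
  sep <- p2 < sep_tol | p2 > 1 - sep_tol
  if (any(sep)) {
    pat <- which(sep)[1]
    cols <- c(spec$time_varying, spec$history)
    abort(sprintf(
      "Separation in the treatment model: fitted probability 0 or 1 (first at row %d; covariates: %s).",
      pat, paste(sprintf("%s=%s", cols, unlist(pp[pat, cols])),
                 collapse = ", ")),
      class = "msmcvd_positivity_error")
  }
  if (!fit1$converged || !fit2$converged) {
    abort("Treatment model IRLS did not converge.",
          class = "msmcvd_estimation_error")
  }
  clip <- function(p) pmin(pmax(p, PROB_CLIP[1]), PROB_CLIP[2])
  n_clipped <- sum(p1 < PROB_CLIP[1] | p1 > PROB_CLIP[2] |
                     p2 < PROB_CLIP[1] | p2 > PROB_CLIP[2])
  obs_prob <- function(p) ifelse(pp$A == 1L, p, 1 - p)
  structure(
    list(numerator = fit1, denominator = fit2,
         p_num = obs_prob(clip(p1)), p_den = obs_prob(clip(p2)),
         n_clipped = n_clipped, spec = spec),
    class = "treatment_models"
  )
}

#' Inverse-probability-of-treatment weights
#'
#' Builds per person-period IPT weights as cumulative products over the
#' person's at-risk intervals: the non-stabilized weight is
#' `w_i(k) = prod_{j<=k} 1 / P(A_j = a_ij | history, L_j, V)` and the
#' stabilized weight replaces the numerator 1 by the history-and-baseline
#' conditional probability of the observed treatment, shrinking weight
#' variance without changing the target. Row order within person follows
#' interval index.
#'
#' @param person_periods Person-period tibble.
#' @param models A `treatment_models` fit from [fit_treatment_models()], or
#'   a list with numeric vectors `p_num` and `p_den` aligned to rows
#'   (probabilities of the observed exposure level).
#' @param stabilized Compute the stabilized weight (`sw`) as the analysis
#'   weight? Both columns are always returned.
#' @return A tibble of class `weight_set` with `person_id`, `k`, `sw`, `w`,
#'   and an attribute `truncation` (bounds applied, `NULL` here).
#' @export
compute_weights <- function(person_periods, models, stabilized = TRUE) {
  p_num <- models$p_num
  p_den <- models$p_den
  stopifnot(length(p_num) == nrow(person_periods),
            length(p_den) == nrow(person_periods))
  if (any(p_den <= 0 | p_den >= 1 | p_num <= 0 | p_num >= 1)) {
    abort(sprintf("Fitted probabilities outside (0,1) at row %d.",
                  which(p_den <= 0 | p_den >= 1 | p_num <= 0 | p_num >= 1)[1]),
          class = "msmcvd_positivity_error")
  }
  ws <- person_periods |>
    select("person_id", "k") |>
    mutate(.pn = p_num, .pd = p_den) |>
    group_by(.data$person_id) |>
    arrange(.data$k, .by_group = TRUE) |>
    mutate(
      w = cumprod(1 / .data$.pd),
      sw = cumprod(.data$.pn / .data$.pd)
    ) |>
    ungroup() |>
    select("person_id", "k", "sw", "w")
  if (any(!is.finite(ws$sw)) || any(!is.finite(ws$w))) {
    abort(sprintf("Weight underflow/overflow at row %d.",
                  which(!is.finite(ws$sw) | !is.finite(ws$w))[1]),
          class = "msmcvd_numeric_error")
  }
  structure(ws, class = c("weight_set", class(ws)),
            truncation = NULL, stabilized = stabilized)
}

#' Truncate IPT weights at percentiles
#'
#' Caps weights below the `lower_pct` percentile at that percentile and
#' above the `upper_pct` percentile at that percentile. Percentiles are
#' computed over all person-period weights with linear interpolation
#' (`quantile type 7`), separately for the stabilized and non-stabilized
#' columns. `(0, 100)` is the identity.
#'
#' @param weights A `weight_set` from [compute_weights()].
#' @param lower_pct,upper_pct Percentile bounds, `0 <= lower < upper <= 100`.
#' @return The truncated `weight_set`; attribute `truncation` records the
#'   pair.
#' @export
truncate_weights <- function(weights, lower_pct, upper_pct) {
  if (nrow(weights) == 0) {
    abort("Empty weight set.", class = "msmcvd_data_error")
  }
  check_scalar(lower_pct, "lower_pct"); check_scalar(upper_pct, "upper_pct")
  if (lower_pct < 0 || upper_pct > 100 || lower_pct >= upper_pct) {
    abort("Require 0 <= lower_pct < upper_pct <= 100.",
          class = "msmcvd_param_error")
  }
  trunc_col <- function(x) {
    q <- quantile(x, c(lower_pct, upper_pct) / 100, type = 7, names = FALSE)
    pmin(pmax(x, q[1]), q[2])
  }
  out <- weights |>
    mutate(sw = trunc_col(.data$sw), w = trunc_col(.data$w))
  attr(out, "truncation") <- c(lower = lower_pct, upper = upper_pct)
  class(out) <- class(weights)
  out
}

#' IPT weights for the ordered dose-response exposure
#'
#' Discretizes interval-level antidepressant dose into ordered levels —
#' level 0 for untreated intervals plus tertiles of the positive interval
#' DDD distribution — and builds stabilized and non-stabilized weights from
#' multinomial logistic numerator/denominator models of the level
#' probabilities (same covariate structure as the binary models). With two
#' levels the multinomial reduces to the logistic pathway of
#' [compute_weights()] and reproduces it exactly.
#'
#' @param person_periods Person-period tibble with `interval_ddd`.
#' @param spec A [treatment_model_spec()].
#' @param n_dose_levels Number of positive-dose levels (default 3 =
#'   tertiles); levels with no rows are collapsed with a warning and the
#'   models refit.
#' @return A `weight_set` tibble (as [compute_weights()]) with an extra
#'   `dose_level` column.
#' @export
dose_exposure_weights <- function(person_periods,
                                  spec = treatment_model_spec(),
                                  n_dose_levels = 3) {
  pp <- person_periods
  if (!"interval_ddd" %in% names(pp)) {
    abort("`interval_ddd` is required for dose-response weights.",
          class = "msmcvd_data_error")
  }
  pos <- pp$interval_ddd[pp$interval_ddd > 0]
  if (length(pos) == 0) {
    lev <- rep(0L, nrow(pp))
  } else {
    n_lev <- n_dose_levels
    n_collapsed <- 0L
    repeat {
      br <- unique(quantile(pos, probs = seq(0, 1, length.out = n_lev + 1),
                            type = 7, names = FALSE))
      cutlev <- cut(pp$interval_ddd, breaks = c(-Inf, 0, br[-1]),
                    labels = FALSE, right = TRUE) - 1L
      if (length(unique(cutlev)) == n_lev + 1 || n_lev == 1) break
      n_collapsed <- n_collapsed + 1L
      n_lev <- n_lev - 1
    }
    if (n_collapsed > 0) {
      warn(sprintf("%d empty dose level(s); collapsing and refitting.",
                   n_collapsed))
    }
    lev <- cutlev
  }
  pp$dose_level <- factor(lev, levels = sort(unique(lev)))

  if (nlevels(pp$dose_level) == 1) {
    # degenerate exposure: the observed level has probability 1 everywhere
    ws <- pp |>
      select("person_id", "k") |>
      mutate(sw = 1, w = 1, dose_level = pp$dose_level)
    return(structure(ws, class = c("weight_set", class(ws)),
                     truncation = NULL, stabilized = TRUE))
  }
  if (nlevels(pp$dose_level) == 2) {
    # binary collapse: same logistic pathway as the main weights, on the
    # collapsed dose indicator
    pp$A <- as.integer(pp$dose_level != levels(pp$dose_level)[1])
    mods <- fit_treatment_models(pp, spec, positivity_screen = FALSE)
    ws <- compute_weights(pp, mods)
    ws$dose_level <- pp$dose_level
    return(ws)
  }

  num_terms <- c(time_terms(spec), spec$baseline, spec$history)
  den_terms <- c(num_terms, spec$time_varying)
  fit_mn <- function(terms) {
    nnet::multinom(build_formula("dose_level", terms), data = pp,
                   trace = FALSE, maxit = 500)
  }
  m_num <- fit_mn(num_terms)
  m_den <- fit_mn(den_terms)
  obs_prob <- function(m) {
    pr <- stats::predict(m, newdata = pp, type = "probs")
    if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)
    pr[cbind(seq_len(nrow(pp)), as.integer(pp$dose_level))]
  }
  clip <- function(p) pmin(pmax(p, PROB_CLIP[1]), PROB_CLIP[2])
  mods <- list(p_num = clip(obs_prob(m_num)), p_den = clip(obs_prob(m_den)))
  ws <- compute_weights(pp, mods)
  ws$dose_level <- pp$dose_level
  ws
}

#' Per-interval log-weight diagnostics
#'
#' Mean and standard deviation of the log-transformed stabilized and
#' non-stabilized weights by interval, the standard check that stabilized
#' weights stay centred (log mean near 0) across follow-up.
#'
#' @param weights A `weight_set`.
#' @return Tibble with `k`, `n`, `mean_log_sw`, `sd_log_sw`, `mean_log_w`,
#'   `sd_log_w`, `mean_sw`.
#' @export
weight_diagnostics <- function(weights) {
  if (any(weights$sw <= 0 | weights$w <= 0)) {
    abort("Weights must be positive.", class = "msmcvd_data_error")
  }
  weights |>
    group_by(.data$k) |>
    summarise(
      n = n(),
      mean_log_sw = mean(log(.data$sw)),
      sd_log_sw = ifelse(n() > 1, stats::sd(log(.data$sw)), 0),
      mean_log_w = mean(log(.data$w)),
      sd_log_w = ifelse(n() > 1, stats::sd(log(.data$w)), 0),
      mean_sw = mean(.data$sw)
    )
}
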