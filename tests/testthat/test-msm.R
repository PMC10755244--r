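test_that("unit weights reduce the weighted model to plain pooled logistic", {
  pp <- small_panel(n = 700, K = 4, seed = 41)
  m <- fit_msm(pp, weights = rep(1, nrow(pp)))
  direct <- stats::glm(
    Y ~ A + factor(k) + A_lag + ever_treated_lag + female + age_index +
      premium_band,
    family = binomial(), data = pp)
  expect_equal(unname(m$coefficients), unname(coef(direct)),
               tolerance = 1e-8)
  # NULL weights follow the same path
  m0 <- fit_msm(pp)
  expect_equal(m0$coefficients, m$coefficients, tolerance = 1e-12)
})

test_that("point-exposure reduction: single interval equals ordinary logistic", {
  set.seed(71)
  n <- 2000
  d <- tibble::tibble(
    person_id = 1:n, k = 0L,
    A = rbinom(n, 1, 0.4), A_lag = 0L, ever_treated_lag = 0L,
    female = rbinom(n, 1, 0.5), age_index = rnorm(n, 40, 10),
    premium_band = sample(1:10, n, TRUE)
  )
  d$Y <- rbinom(n, 1, plogis(-3 + 0.5 * d$A))
  m <- fit_msm(d, weights = rep(1, n))
  direct <- stats::glm(Y ~ A + female + age_index + premium_band,
                       family = binomial(), data = d)
  expect_equal(unname(m$coefficients), unname(coef(direct)),
               tolerance = 1e-8)
})

test_that("clustered sandwich agrees with sandwich::vcovCL", {
  pp <- small_panel(n = 500, K = 4, seed = 43)
  ws <- fit_weights_quiet(pp)
  m <- fit_msm(pp, ws)
  V_ref <- sandwich::vcovCL(m$fit, cluster = pp$person_id)
  # standard errors to 0.1%; off-diagonal entries on the matrix scale
  # (near-zero covariances differ in the last working-residual update)
  expect_equal(sqrt(diag(m$vcov)), sqrt(diag(V_ref)), tolerance = 1e-3)
  expect_lt(max(abs(m$vcov - V_ref)) / max(abs(V_ref)), 0.01)
})

test_that("the clustered sandwich detects within-person correlation that
           the likelihood-based variance misses", {
  # duplicating every person-period makes rows perfectly correlated within
  # person: the ML variance halves while the clustered sandwich does not
  pp <- small_panel(n = 800, K = 5, seed = 301)
  ws <- fit_weights_quiet(pp)
  m1 <- fit_msm(pp, ws)
  pp2 <- dplyr::bind_rows(pp, pp)
  sw_aligned <- dplyr::left_join(dplyr::select(pp, "person_id", "k"), ws,
                                 by = c("person_id", "k"))$sw
  m2 <- fit_msm(pp2, weights = rep(sw_aligned, 2))
  a <- which(m2$hr$term == "A")
  ml_se2 <- sqrt(diag(summary(m2$fit)$cov.unscaled))[
    which(names(m2$coefficients) == "A")]
  # clustered SE on duplicated data stays at the original level ...
  expect_equal(m2$hr$std_error[a], m1$hr$std_error[a], tolerance = 0.02)
  # ... and clearly exceeds the ML SE, which is fooled by the duplication
  expect_gt(m2$hr$std_error[a], 1.3 * ml_se2)
})

test_that("time-fixed Cox recovers a known hazard ratio without confounding", {
  set.seed(83)
  n <- 10000
  exposed <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, rate = 0.05 * 2^exposed)
  t_c <- runif(n, 0, 30)
  d <- tibble::tibble(person_id = 1:n, exposed = exposed,
                      time = pmin(t_ev, t_c),
                      event = as.integer(t_ev <= t_c))
  f <- fit_cox_time_fixed(d, covariates = character())
  se <- f$hr$std_error[1]
  expect_lt(abs(f$hr$estimate[1] - log(2)) / se, 2.5)
  # constant exposure has no estimable coefficient
  expect_error(fit_cox_time_fixed(dplyr::mutate(d, exposed = 1L)),
               class = "msmcvd_estimation_error")
})

test_that("time-varying Cox with constant covariates equals time-fixed Cox", {
  set.seed(87)
  n <- 800
  person <- tibble::tibble(
    person_id = 1:n,
    exposed = rbinom(n, 1, 0.5),
    female = rbinom(n, 1, 0.6),
    k_end = sample(0:5, n, TRUE)
  )
  ev_k <- ifelse(runif(n) < 0.15, person$k_end, -1L)
  pp <- person |>
    dplyr::rowwise() |>
    dplyr::mutate(k = list(0:k_end)) |>
    tidyr::unnest(k) |>
    dplyr::mutate(A = exposed, t_start = k * 91, t_end = (k + 1) * 91,
                  Y = as.integer(k == ev_k[person_id]))
  tv <- fit_cox_time_varying(pp, covariates = "female")
  tf <- fit_cox_time_fixed(collapse_person_periods(pp),
                           covariates = "female")
  expect_equal(unname(tv$hr$estimate[1]), unname(tf$hr$estimate[1]),
               tolerance = 1e-8)
  # overlapping intervals are a data error
  bad <- dplyr::mutate(pp, t_start = 0)
  expect_error(fit_cox_time_varying(bad, covariates = "female"),
               class = "msmcvd_data_error")
})

test_that("discrete-time and Cox hazard ratios agree under rare outcomes", {
  p <- sim_params(n_persons = 8000, n_intervals = 6, seed = 91,
                  severity_effect_on_event = 0,
                  treatment_effect_on_severity = 0)
  pp <- panel_person_periods(simulate_panel(p))
  m <- fit_msm(pp, baseline = character(), history = character())
  tv <- fit_cox_time_varying(pp, covariates = character(), cluster = FALSE)
  expect_equal(m$hr$estimate[1], tv$hr$estimate[1], tolerance = 0.05)
})

test_that("spline dose-response basis has the documented structure", {
  pp <- small_panel(n = 1500, K = 5, seed = 97)
  sp <- spline_spec()
  dr <- suppressWarnings(spline_dose_response(pp, weights = NULL, spec = sp))
  fit <- dr$fit
  # dimension: degree + interior knots for the no-intercept construction
  n_knots <- length(fit$spline$knots)
  expect_equal(length(fit$exposure_terms), fit$spline$degree + n_knots)
  # reference level: HR exactly 1 at dose 0
  at0 <- dr$curve[dr$curve$cum_ddd == 0, ]
  expect_equal(at0$hazard_ratio, 1)
  expect_equal(at0$conf_low, 1)
  # knots strictly increasing after deduplication
  expect_true(all(diff(fit$spline$knots) > 0))
})

test_that("spline curve stays near the linear fit when the truth is linear", {
  pp <- small_panel(n = 4000, K = 6, seed = 103)
  lin <- fit_msm(pp, exposure = "log_cum_ddd")
  dr <- suppressWarnings(spline_dose_response(pp))
  grid <- dr$curve$cum_ddd
  lin_hr <- exp(lin$hr$estimate[1] * log1p(grid))
  inside <- lin_hr >= dr$curve$conf_low & lin_hr <= dr$curve$conf_high
  expect_gte(mean(inside), 0.8)
})

test_that("tidy and glance return broom-shaped tibbles", {
  pp <- small_panel(n = 400, K = 3, seed = 111)
  m <- fit_msm(pp)
  td <- tidy(m)
  expect_true(all(c("term", "estimate", "hazard_ratio", "conf_low",
                    "conf_high") %in% names(td)))
  expect_equal(td$hazard_ratio, exp(td$estimate))
  expect_true(all(td$conf_low <= td$hazard_ratio &
                    td$hazard_ratio <= td$conf_high))
  g <- glance(m)
  expect_equal(nrow(g), 1)
  expect_equal(g$n_events, sum(pp$Y))
  expect_s3_class(autoplot(m), "ggplot")
})

test_that("zero events raise an estimation error", {
  pp <- small_panel(n = 100, K = 2, seed = 113)
  pp$Y <- 0L
  expect_error(fit_msm(pp), class = "msmcvd_estimation_error")
  expect_error(fit_cox_time_varying(pp), class = "msmcvd_estimation_error")
})
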