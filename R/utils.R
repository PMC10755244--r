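#' @importFrom rlang .data abort warn .env
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom stats plogis qlogis rbinom rnorm runif quantile glm binomial
#'   quasibinomial coef vcov predict model.matrix as.formula setNames
#'   pnorm qnorm sd
NULL

# Deterministic 31-bit stream seed from a master seed and a stream label, so
# that adding a new random stream never perturbs draws in existing ones.
stream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + (abs(seed) %% 2147483647) * 2654435761) %% 2147483647)
}

with_stream <- function(seed, label, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(stream_seed(seed, label))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

# Round half-up to `digits` decimals (base round() rounds half-to-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# The simulated calendar counts integer days from a study origin; claim years
# are derived with a flat 365-day year starting in 2004.
STUDY_ORIGIN_YEAR <- 2004
day_to_year <- function(day) STUDY_ORIGIN_YEAR + day %/% 365L

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name),
          class = "msmcvd_param_error")
  }
  invisible(x)
}

check_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || (finite && !is.finite(x))) {
    abort(sprintf("`%s` must be a finite numeric scalar.", name),
          class = "msmcvd_param_error")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  check_scalar(x, name)
  if (x < min || x != as.integer(x)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min),
          class = "msmcvd_param_error")
  }
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
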