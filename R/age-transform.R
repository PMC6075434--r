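#' Calibrated age transformation for clock training
#'
#' Epigenetic clocks of the skin & blood family do not regress methylation on
#' chronological age directly: methylation at clock CpGs changes far faster
#' before adulthood than after, so chronological age is first mapped onto a
#' calibrated scale that is logarithmic below an adult-age anchor and linear
#' above it. On that scale the clock-CpG trajectories are approximately
#' linear over the whole lifespan, which is what a linear penalized model
#' needs. The transform is continuously differentiable at the anchor (both
#' one-sided slopes equal `1/(adult_age + 1)`), strictly increasing on
#' `(-1, Inf)`, and zero exactly at `adult_age`.
#'
#' For `x <= adult_age` the value is `log((x + 1)/(adult_age + 1))`
#' (natural log); for `x > adult_age` it is `(x - adult_age)/(adult_age + 1)`.
#' Ages slightly below zero are legal so that gestationally-offset cord-blood
#' ages can be represented; the domain boundary is `x > -1`.
#'
#' @param x Chronological age in years; any value greater than -1.
#' @param adult_age Anchor age in years separating the logarithmic and linear
#'   regimes. Default 20.
#' @return Transformed age (unitless), same length as `x`.
#' @examples
#' transform_age(c(0, 20, 90))
#' inverse_transform_age(transform_age(37.5))
#' @export
transform_age <- function(x, adult_age = 20) {
  check_adult_age(adult_age)
  if (!is.numeric(x)) abort("`x` must be numeric.")
  bad <- !is.na(x) & x <= -1
  if (any(bad)) {
    abort(sprintf(
      "Age must be > -1 (log-based calibration); got %s.",
      paste(format(x[bad]), collapse = ", ")
    ))
  }
  ifelse(x <= adult_age,
    log((x + 1) / (adult_age + 1)),
    (x - adult_age) / (adult_age + 1)
  )
}

#' Inverse of the calibrated age transformation
#'
#' Maps a value on the calibrated regression scale back to age in years;
#' exact inverse of [transform_age()]. Clock predictions are made on the
#' transformed scale and reported in years through this function.
#'
#' @param y Transformed age (unitless); must be finite.
#' @inheritParams transform_age
#' @return Age in years, same length as `y`.
#' @export
inverse_transform_age <- function(y, adult_age = 20) {
  check_adult_age(adult_age)
  if (!is.numeric(y)) abort("`y` must be numeric.")
  if (any(!is.finite(y) & !is.na(y))) {
    abort("Transformed age must be finite.")
  }
  ifelse(y <= 0,
    (adult_age + 1) * exp(y) - 1,
    adult_age + y * (adult_age + 1)
  )
}

check_adult_age <- function(adult_age) {
  if (!is.numeric(adult_age) || length(adult_age) != 1 ||
      !is.finite(adult_age) || adult_age <= 0) {
    abort("`adult_age` must be a single positive number.")
  }
  invisible(adult_age)
}
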