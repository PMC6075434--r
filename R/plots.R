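#' Scatter of DNAm age against chronological age
#'
#' The conventional clock-accuracy panel: DNAm age (y) versus chronological
#' age (x) with the identity line, annotated with the Pearson correlation
#' and the median absolute error.
#'
#' @param data Data frame with columns `age` and `dnam_age` (years);
#'   optionally `disease` for point colour.
#' @return A ggplot object.
#' @export
plot_dnam_age <- function(data) {
  data <- check_age_pairs(data)
  acc <- accuracy_metrics(data$age, data$dnam_age)
  lab <- sprintf("r = %.2f, error = %.2f y", acc$pearson_r, acc$median_abs_error)
  aes_pts <- if ("disease" %in% names(data)) {
    ggplot2::aes(.data$age, .data$dnam_age, colour = .data$disease)
  } else {
    ggplot2::aes(.data$age, .data$dnam_age)
  }
  ggplot2::ggplot(data, aes_pts) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Chronological age (years)", y = "DNAm age (years)",
                  subtitle = lab) +
    ggplot2::theme_minimal()
}

#' Plot an age-acceleration analysis
#'
#' Two conventional views of an [residual_acceleration()] result: the
#' DNAm-age scatter with the control reference regression (`"scatter"`), or
#' group mean acceleration with one-standard-error bars by disease label
#' (`"groups"`).
#'
#' @param object An `accel_result`.
#' @param type `"scatter"` or `"groups"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.accel_result <- function(object, type = c("scatter", "groups"), ...) {
  type <- arg_match(type)
  d <- object$samples
  if (type == "groups") {
    if (is.null(object$groups)) abort("No disease labels to group by.")
    g <- object$groups
    return(
      ggplot2::ggplot(g, ggplot2::aes(.data$disease, .data$mean_accel)) +
        ggplot2::geom_col(fill = "grey80", colour = "grey30") +
        ggplot2::geom_errorbar(ggplot2::aes(
          ymin = .data$mean_accel - .data$se_accel,
          ymax = .data$mean_accel + .data$se_accel), width = 0.2) +
        ggplot2::labs(x = NULL, y = "Mean age acceleration (years)") +
        ggplot2::theme_minimal()
    )
  }
  grid <- tibble(age = seq(min(d$age), max(d$age), length.out = 100))
  grid$dnam_age <- predict(object$reference, grid)
  aes_pts <- if ("disease" %in% names(d)) {
    ggplot2::aes(.data$age, .data$dnam_age, colour = .data$disease)
  } else {
    ggplot2::aes(.data$age, .data$dnam_age)
  }
  ggplot2::ggplot(d, aes_pts) +
    ggplot2::geom_line(data = grid, ggplot2::aes(.data$age, .data$dnam_age),
                       inherit.aes = FALSE, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Chronological age (years)", y = "DNAm age (years)") +
    ggplot2::theme_minimal()
}

#' Plot the cross-validation curve of a trained clock
#'
#' Mean cross-validated squared error (transformed-age scale) against
#' log lambda, with the selected penalty marked.
#'
#' @param object A `clock_model` trained with cross-validation.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clock_model <- function(object, ...) {
  cv <- object$meta$cv
  if (is.null(cv)) abort("This clock model carries no cross-validation curve.")
  ggplot2::ggplot(cv, ggplot2::aes(log(.data$lambda), .data$mean_cv_error)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_cv_error - .data$se_cv_error,
      ymax = .data$mean_cv_error + .data$se_cv_error), size = 0.2) +
    ggplot2::geom_vline(xintercept = log(object$lambda), linetype = 2) +
    ggplot2::labs(x = "log(lambda)", y = "Mean CV squared error") +
    ggplot2::theme_minimal()
}

#' DNAm age against cumulative population doubling
#'
#' The ex vivo tracking panel: epigenetic age of a culture over its
#' cumulative population doubling level, with the least-squares trend line
#' and slope annotation.
#'
#' @param data Data frame with columns `cum_pd` and `dnam_age`.
#' @return A ggplot object.
#' @export
plot_pd_trend <- function(data) {
  tr <- pd_age_trend(data)
  lab <- sprintf("slope = %.3f y/doubling, r = %.2f", tr$slope, tr$pearson_r)
  ggplot2::ggplot(data, ggplot2::aes(.data$cum_pd, .data$dnam_age)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = tr$slope, intercept = tr$intercept,
                         colour = "grey40") +
    ggplot2::labs(x = "Cumulative population doubling",
                  y = "DNAm age (years)", subtitle = lab) +
    ggplot2::theme_minimal()
}
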