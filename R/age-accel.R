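#' Fit a reference regression of DNAm age on chronological age in controls
#'
#' Epigenetic age acceleration is defined relative to a reference: the
#' least-squares regression line (or quadratic) of DNAm age on chronological
#' age fitted through control samples only. A sample's acceleration is then
#' its vertical distance to this reference.
#'
#' @param controls Data frame of control samples with columns `age` and
#'   `dnam_age` (years).
#' @param degree Polynomial degree of the reference, 1 (line, default) or 2.
#' @return An object of class `age_reference`: the `lm` fit plus the degree.
#' @export
fit_reference <- function(controls, degree = 1) {
  if (!degree %in% c(1, 2)) abort("`degree` must be 1 or 2.")
  controls <- check_age_pairs(controls)
  need <- if (degree == 2) 4 else 3
  if (nrow(controls) < need) {
    abort(sprintf("Need at least %d control samples for degree %d.", need, degree))
  }
  fml <- if (degree == 1) dnam_age ~ age else dnam_age ~ age + I(age^2)
  fit <- lm(fml, data = controls)
  if (anyNA(coef(fit))) {
    abort("Singular reference design (e.g. a single repeated age value).")
  }
  structure(list(fit = fit, degree = degree, n = nrow(controls)),
            class = "age_reference")
}

#' @export
print.age_reference <- function(x, ...) {
  cat(sprintf("<age_reference> degree %d, %d controls\n", x$degree, x$n))
  print(coef(x$fit))
  invisible(x)
}

#' @export
predict.age_reference <- function(object, newdata, ...) {
  if (is.numeric(newdata)) newdata <- tibble(age = newdata)
  as.numeric(predict(object$fit, newdata = newdata))
}

#' Residual epigenetic age acceleration
#'
#' Computes each sample's age acceleration as `dnam_age - reference(age)`,
#' the vertical distance to the control reference regression. By the
#' least-squares property, the mean acceleration over the reference's own
#' control samples is zero.
#'
#' @param samples Data frame with columns `age` and `dnam_age` (years);
#'   extra columns (e.g. `sample_id`, `disease`, `sex`) are carried through.
#' @param reference An [fit_reference()] object, or `NULL` to fit one from
#'   the rows of `samples` whose `disease` column equals `control_label`.
#' @param degree Reference degree when fitting internally.
#' @param control_label Disease label marking reference samples.
#'   Default `"control"`.
#' @return An object of class `accel_result`: `$samples` (input tibble plus
#'   an `accel` column, years), `$reference`, and `$groups` (mean, SE and n
#'   of acceleration by disease label, when a `disease` column exists).
#' @examples
#' d <- tibble::tibble(
#'   age = c(1, 3, 5, 7, 2, 4),
#'   dnam_age = c(1.2, 3.1, 4.8, 7.0, 6.0, 9.1),
#'   disease = c("control", "control", "control", "control", "case", "case")
#' )
#' acc <- residual_acceleration(d)
#' tidy(acc)
#' @export
residual_acceleration <- function(samples, reference = NULL, degree = 1,
                                  control_label = "control") {
  samples <- check_age_pairs(samples)
  if (is.null(reference)) {
    if (!"disease" %in% names(samples)) {
      abort("Provide `reference`, or a `disease` column to locate controls.")
    }
    ctl <- samples[samples$disease == control_label, , drop = FALSE]
    if (nrow(ctl) == 0) {
      abort(sprintf("No samples with disease == '%s' to fit the reference.",
                    control_label))
    }
    reference <- fit_reference(ctl, degree = degree)
  }
  stopifnot(inherits(reference, "age_reference"))
  samples$accel <- samples$dnam_age - predict(reference, samples)

  groups <- NULL
  if ("disease" %in% names(samples)) {
    groups <- samples %>%
      group_by(.data$disease) %>%
      summarise(n = n(), mean_accel = mean(.data$accel),
                se_accel = sd(.data$accel) / sqrt(n()), .groups = "drop")
  }
  structure(list(samples = samples, reference = reference, groups = groups,
                 control_label = control_label),
            class = "accel_result")
}

#' @export
print.accel_result <- function(x, ...) {
  cat(sprintf("<accel_result> %d samples, reference degree %d\n",
              nrow(x$samples), x$reference$degree))
  if (!is.null(x$groups)) print(x$groups)
  invisible(x)
}

#' Per-sample acceleration table
#'
#' @param x An `accel_result`.
#' @param ... Unused.
#' @return The per-sample tibble with the `accel` column (years).
#' @export
tidy.accel_result <- function(x, ...) x$samples

#' Group-level acceleration summary
#'
#' @param x An `accel_result`.
#' @param ... Unused.
#' @return Tibble of group means/SEs by disease label, or a one-row overall
#'   summary when no disease labels are present.
#' @export
glance.accel_result <- function(x, ...) {
  if (!is.null(x$groups)) return(x$groups)
  tibble(n = nrow(x$samples), mean_accel = mean(x$samples$accel),
         se_accel = sd(x$samples$accel) / sqrt(nrow(x$samples)))
}

#' Covariate-adjusted epigenetic age model
#'
#' Ordinary least squares of DNAm age on a chosen covariate set — typically
#' age, age squared, cumulative population doubling level, and a disease
#' indicator — with two-sided t-test p-values per coefficient. This is the
#' adjusted analysis used to quantify disease-associated age acceleration
#' while controlling for chronological age and culture proliferation.
#'
#' @param samples Data frame with `dnam_age` plus the covariate columns.
#'   `"age2"` is derived as `age^2`; `"disease"` becomes an indicator that
#'   is 1 for every label other than `control_label`.
#' @param covariates Character vector drawn from
#'   `c("age", "age2", "pdl", "disease")` (or any other numeric column of
#'   `samples`).
#' @param control_label Disease label coded 0 in the indicator.
#' @return A tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`.
#' @export
adjusted_acceleration <- function(samples,
                                  covariates = c("age", "age2", "pdl", "disease"),
                                  control_label = "control") {
  samples <- as_tibble(samples)
  if (!"dnam_age" %in% names(samples)) abort("`samples` needs a `dnam_age` column.")
  d <- tibble(dnam_age = samples$dnam_age)
  for (cv in covariates) {
    d[[cv]] <- switch(cv,
      age2 = {
        if (!"age" %in% names(samples)) abort("Covariate 'age2' needs an `age` column.")
        samples$age^2
      },
      disease = {
        if (!"disease" %in% names(samples)) abort("No `disease` column.")
        as.numeric(samples$disease != control_label)
      },
      {
        if (!cv %in% names(samples)) abort(sprintf("No '%s' column.", cv))
        as.numeric(samples[[cv]])
      }
    )
  }
  d <- d[complete.cases(d), , drop = FALSE]
  X <- model.matrix(~ ., data = d[, covariates, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(sprintf("Design matrix is rank deficient; collinear column(s): %s.",
                  paste(dropped, collapse = ", ")))
  }
  fit <- lm(dnam_age ~ ., data = d)
  sm <- summary(fit)$coefficients
  tibble(
    term = rownames(sm),
    estimate = unname(sm[, 1]), std_error = unname(sm[, 2]),
    statistic = unname(sm[, 3]), p_value = unname(sm[, 4])
  )
}

#' Clock accuracy: age correlation and median absolute error
#'
#' The two accuracy figures conventionally reported for DNAm age
#' estimators: the Pearson correlation between DNAm age and chronological
#' age, and the "error" — the median absolute deviation between the two,
#' in years.
#'
#' @param age,dnam_age Paired numeric vectors (years), length >= 2.
#' @return A one-row tibble with `pearson_r` (NA with a warning if either
#'   vector has zero variance), `median_abs_error`, and `n`.
#' @export
accuracy_metrics <- function(age, dnam_age) {
  ok <- !is.na(age) & !is.na(dnam_age)
  age <- age[ok]; dnam_age <- dnam_age[ok]
  if (length(age) < 2) abort("Need at least 2 paired values.")
  r <- if (sd(age) == 0 || sd(dnam_age) == 0) {
    warn("Zero variance in ages; correlation undefined.")
    NA_real_
  } else {
    cor(age, dnam_age)
  }
  tibble(pearson_r = r,
         median_abs_error = median(abs(dnam_age - age)),
         n = length(age))
}

check_age_pairs <- function(d) {
  if (!is.data.frame(d) || !all(c("age", "dnam_age") %in% names(d))) {
    abort("Expected a data frame with `age` and `dnam_age` columns.")
  }
  d <- as_tibble(d)
  if (!is.numeric(d$age) || !is.numeric(d$dnam_age)) {
    abort("`age` and `dnam_age` must be numeric (years).")
  }
  d
}
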