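#' Construct a clock model object
#'
#' A clock model is the fitted artefact of clock training: an intercept and
#' a sparse set of per-probe weights on the calibrated (transformed) age
#' scale, plus the training-set mean beta of each weighted probe (used to
#' impute probes that are missing at prediction time) and the age-transform
#' anchor. Most users obtain one from [train_clock()] or
#' [read_clock_coefficients()] rather than calling this directly.
#'
#' @param intercept Intercept on the transformed-age scale.
#' @param weights Named numeric vector of non-zero probe coefficients
#'   (per unit beta).
#' @param probe_means Named numeric vector of training mean betas for the
#'   weighted probes, or `NULL` when unknown (e.g. an externally supplied
#'   coefficient list without means — imputation is then unavailable).
#' @param adult_age Age-transform anchor in years.
#' @param alpha Elastic-net mixing parameter used in training, if known.
#' @param lambda Selected penalty, if known.
#' @param meta Named list of training metadata (sample count, candidate
#'   probe count, seed, cross-validation table, training performance).
#' @return An object of class `clock_model`.
#' @export
clock_model <- function(intercept, weights = numeric(), probe_means = NULL,
                        adult_age = 20, alpha = NA_real_, lambda = NA_real_,
                        meta = list()) {
  if (!is.numeric(intercept) || length(intercept) != 1 || !is.finite(intercept)) {
    abort("`intercept` must be a single finite number.")
  }
  weights <- weights[weights != 0]
  if (length(weights) > 0 && is.null(names(weights))) {
    abort("`weights` must be named by probe ID.")
  }
  if (anyDuplicated(names(weights))) abort("Duplicate probe IDs in `weights`.")
  if (!is.null(probe_means)) {
    missing_means <- setdiff(names(weights), names(probe_means))
    if (length(missing_means) > 0) {
      abort(sprintf("No probe_mean stored for weighted probe(s): %s.",
                    paste(head(missing_means, 3), collapse = ", ")))
    }
    probe_means <- probe_means[names(weights)]
  }
  check_adult_age(adult_age)
  structure(
    list(intercept = intercept, weights = weights, probe_means = probe_means,
         adult_age = adult_age, alpha = alpha, lambda = lambda, meta = meta),
    class = "clock_model"
  )
}

#' @export
print.clock_model <- function(x, ...) {
  cat("<clock_model>\n")
  cat(sprintf("  probes: %d, intercept: %.4f (transformed-age scale)\n",
              length(x$weights), x$intercept))
  cat(sprintf("  adult_age anchor: %g years; alpha = %s; lambda = %s\n",
              x$adult_age,
              format(x$alpha, digits = 3), format(x$lambda, digits = 4)))
  if (!is.null(x$meta$n_train)) {
    cat(sprintf("  trained on %d samples (%d candidate probes)\n",
                x$meta$n_train, x$meta$n_candidates %||% NA))
  }
  if (!is.null(x$meta$train_cor)) {
    cat(sprintf("  training fit: r = %.3f, median abs error = %.2f years\n",
                x$meta$train_cor, x$meta$train_mad))
  }
  invisible(x)
}

#' Tidy a clock model into a coefficient tibble
#'
#' @param x A `clock_model`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, and (when available)
#'   `probe_mean`; the intercept row uses term `"(Intercept)"`.
#' @export
tidy.clock_model <- function(x, ...) {
  out <- tibble(
    term = c("(Intercept)", names(x$weights)),
    estimate = c(x$intercept, unname(x$weights))
  )
  if (!is.null(x$probe_means)) {
    out$probe_mean <- c(NA_real_, unname(x$probe_means[names(x$weights)]))
  }
  out
}

#' One-row summary of a clock model
#'
#' @param x A `clock_model`.
#' @param ... Unused.
#' @return A one-row tibble: probe count, alpha, lambda, anchor, and
#'   training performance when recorded.
#' @export
glance.clock_model <- function(x, ...) {
  tibble(
    n_probes = length(x$weights),
    alpha = x$alpha,
    lambda = x$lambda,
    adult_age = x$adult_age,
    n_train = x$meta$n_train %||% NA_integer_,
    train_cor = x$meta$train_cor %||% NA_real_,
    train_mad = x$meta$train_mad %||% NA_real_
  )
}

#' Read a clock coefficient file
#'
#' Loads an externally supplied coefficient table — e.g. a published clock's
#' CpG list — as a `clock_model`. The file is a CSV with columns `term` and
#' `coefficient`; the intercept row is labelled `(Intercept)` (the label
#' `intercept`, any case, is also accepted). An optional `probe_mean` column
#' supplies training means for imputation. Exactly one intercept row is
#' required and probe rows must be unique.
#'
#' @param path Path to the CSV file.
#' @param adult_age Age-transform anchor the coefficients were trained
#'   under. Default 20.
#' @return A `clock_model`. The number of probe rows is reported via message.
#' @export
read_clock_coefficients <- function(path, adult_age = 20) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("term", "coefficient"), names(tbl))
  if (length(miss) > 0) {
    abort(sprintf("Coefficient file must have columns term, coefficient (missing: %s).",
                  paste(miss, collapse = ", ")))
  }
  is_int <- tbl$term == "(Intercept)" | tolower(tbl$term) == "intercept"
  if (sum(is_int) == 0) abort("Coefficient file has no intercept row.")
  if (sum(is_int) > 1) abort("Coefficient file has multiple intercept rows.")
  probes <- tbl[!is_int, , drop = FALSE]
  if (anyDuplicated(probes$term)) {
    abort(sprintf("Duplicate probe row(s) in coefficient file: %s.",
                  paste(unique(probes$term[duplicated(probes$term)]), collapse = ", ")))
  }
  weights <- setNames(probes$coefficient, probes$term)
  probe_means <- NULL
  if ("probe_mean" %in% names(tbl)) {
    probe_means <- setNames(probes$probe_mean, probes$term)
  }
  inform(sprintf("Loaded clock with %d probe coefficient(s).", nrow(probes)))
  clock_model(intercept = tbl$coefficient[is_int], weights = weights,
              probe_means = probe_means, adult_age = adult_age)
}

#' Write a clock model's coefficients to CSV
#'
#' Inverse of [read_clock_coefficients()] up to numeric formatting.
#'
#' @param model A `clock_model`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_clock_coefficients <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  out <- tidy(model)
  names(out)[names(out) == "estimate"] <- "coefficient"
  readr::write_csv(out, path)
  invisible(path)
}
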