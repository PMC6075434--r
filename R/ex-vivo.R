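#' Population doublings between seeding and harvest
#'
#' The number of times a cell culture doubled between seeding and harvest,
#' computed as `(log10(harvested) - log10(seeded)) * 3.32`. The printed
#' laboratory constant 3.32 approximates `1/log10(2)`; set `exact = TRUE`
#' to use the exact factor (`3.32193...`), under which doubling the cells
#' gives exactly 1.0. A harvest below the seed count yields a negative
#' value, as the formula dictates.
#'
#' @param seeded,harvested Cell counts, both > 0. Vectorized.
#' @param exact Use `1/log10(2)` instead of the conventional 3.32.
#' @return Population doublings (unitless).
#' @examples
#' population_doubling(10000, 20000)
#' @export
population_doubling <- function(seeded, harvested, exact = FALSE) {
  if (any(!is.na(seeded) & seeded <= 0) || any(!is.na(harvested) & harvested <= 0)) {
    abort("Cell counts must be positive.")
  }
  k <- if (exact) 1 / log10(2) else 3.32
  (log10(harvested) - log10(seeded)) * k
}

#' Cumulative population doubling over a passage series
#'
#' Adds per-passage population doublings along a culture series. The input
#' is one row per passage with seeding and harvest counts; passage indices
#' must be strictly increasing.
#'
#' @param records Data frame with columns `passage`, `cells_seeded`,
#'   `cells_harvested` (and optionally `sample_id` for passages where DNA
#'   was taken).
#' @inheritParams population_doubling
#' @return The input tibble with added columns `pd` (per-passage doublings)
#'   and `cum_pd` (running sum).
#' @export
cumulative_pd <- function(records, exact = FALSE) {
  if (!is.data.frame(records)) abort("`records` must be a data frame.")
  records <- as_tibble(records)
  need <- c("passage", "cells_seeded", "cells_harvested")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    abort(sprintf("Missing column(s): %s.", paste(miss, collapse = ", ")))
  }
  if (nrow(records) == 0) {
    records$pd <- numeric(0)
    records$cum_pd <- numeric(0)
    return(records)
  }
  if (any(diff(records$passage) <= 0)) {
    abort("Passage indices must be strictly increasing.")
  }
  records$pd <- population_doubling(records$cells_seeded,
                                    records$cells_harvested, exact = exact)
  records$cum_pd <- cumsum(records$pd)
  records
}

#' Trend of DNAm age over cumulative population doubling
#'
#' Quantifies epigenetic aging of cells proliferating in culture: the
#' least-squares slope of DNAm age on cumulative population doubling level
#' (years per doubling) and the Pearson correlation of the paired series.
#'
#' @param data Data frame with columns `cum_pd` and `dnam_age`, or `NULL`
#'   when the two vectors are given directly.
#' @param cum_pd,dnam_age Numeric vectors used when `data` is `NULL`.
#' @return A one-row tibble: `slope` (years/doubling), `intercept` (years),
#'   `pearson_r`, `slope_se`, `n`.
#' @export
pd_age_trend <- function(data = NULL, cum_pd = NULL, dnam_age = NULL) {
  if (!is.null(data)) {
    if (!all(c("cum_pd", "dnam_age") %in% names(data))) {
      abort("`data` needs columns `cum_pd` and `dnam_age`.")
    }
    cum_pd <- data$cum_pd
    dnam_age <- data$dnam_age
  }
  ok <- !is.na(cum_pd) & !is.na(dnam_age)
  cum_pd <- cum_pd[ok]; dnam_age <- dnam_age[ok]
  if (length(cum_pd) < 3) abort("Need at least 3 paired points.")
  if (sd(cum_pd) == 0) abort("Zero variance in cumulative population doubling.")
  fit <- lm(dnam_age ~ cum_pd)
  sm <- summary(fit)$coefficients
  tibble(
    slope = sm["cum_pd", 1],
    intercept = sm["(Intercept)", 1],
    pearson_r = cor(cum_pd, dnam_age),
    slope_se = sm["cum_pd", 2],
    n = length(cum_pd)
  )
}
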