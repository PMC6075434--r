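#' Published clock results for progeria fibroblast lines
#'
#' Skin-and-blood-clock DNAm age estimates and age-acceleration values for
#' fibroblast cell lines from Hutchinson–Gilford progeria patients (classic
#' and non-classic LMNA/ZMPSTE24 variants), as published for lines
#' distributed by The Progeria Research Foundation. The acceleration column
#' is the published residual from a control reference regression that was
#' not released, so it cannot be recomputed exactly from this table alone;
#' the table is the standard worked example for group comparisons of
#' epigenetic age acceleration (e.g. classic-progeria boys vs girls).
#'
#' @return A tibble with columns `cell_line`, `progeria`
#'   (`Classic`/`NonClassic`), `sex`, `age` (years), `dnam_age` (years),
#'   `accel` (years).
#' @examples
#' hg <- progeria_fibroblasts()
#' classic <- dplyr::filter(hg, progeria == "Classic")
#' kruskal_wallis(classic$accel, classic$sex)
#' @export
progeria_fibroblasts <- function() {
  path <- system.file("extdata", "progeria_fibroblasts.csv",
                      package = "dnamclock", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
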