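#' Kruskal–Wallis comparison of age acceleration between groups
#'
#' Nonparametric k-group comparison by ranks, the standard test for
#' differences in epigenetic age acceleration between disease groups (or
#' between sexes within a disease group). The statistic is computed from
#' rank sums with average ranks and the usual tie-correction divisor, and
#' the p-value comes from the chi-square tail with k-1 degrees of freedom.
#' The statistic depends on the data only through ranks, so it is invariant
#' under any strictly monotone transformation of the values.
#'
#' @param values Numeric vector of observations (e.g. acceleration, years).
#' @param groups Vector of group labels, same length as `values`. At least
#'   two groups, each non-empty after removing missing values.
#' @return A one-row tibble: `statistic` (H), `df`, `p_value`, `n_groups`.
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4), c("a", "a", "b", "b"))
#' @export
kruskal_wallis <- function(values, groups) {
  if (length(values) != length(groups)) {
    abort("`values` and `groups` must have the same length.")
  }
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  if (nlevels(groups) < 2) abort("Need at least 2 groups.")
  if (any(table(groups) == 0)) abort("Every group must be non-empty.")
  ht <- kruskal.test(values, groups)
  tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    n_groups = nlevels(groups)
  )
}
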