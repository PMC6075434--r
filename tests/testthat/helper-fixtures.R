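# Shared fixtures and independent oracles for the test suite.

# Small beta tibble: probes x samples, values supplied column-major.
make_beta <- function(values, probe_ids, sample_ids) {
  m <- matrix(values, nrow = length(probe_ids), ncol = length(sample_ids))
  colnames(m) <- sample_ids
  dplyr::bind_cols(tibble::tibble(probe_id = probe_ids),
                   tibble::as_tibble(m))
}

# Independent Kruskal-Wallis oracle: brute-force rank sums with the
# standard tie-correction divisor.
kw_oracle <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  rk <- rank(values)
  rs <- tapply(rk, groups, sum)
  ns <- tapply(rk, groups, length)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- h / correction
  list(h = h, p = stats::pchisq(h, df = nlevels(groups) - 1, lower.tail = FALSE))
}

# Exact elastic-net coefficient at lambda = 0 from the normal equations.
ols_oracle <- function(x, y) {
  xb <- cbind(1, x)
  as.numeric(solve(crossprod(xb), crossprod(xb, y)))
}

# Path to the CLI script: installed location first, source tree fallback.
cli_path <- function() {
  p <- system.file("exec", "dnamclock", package = "dnamclock")
  if (nzchar(p) && file.exists(p)) return(p)
  testthat::test_path("..", "..", "exec", "dnamclock")
}

run_cli <- function(...) {
  out <- suppressWarnings(system2(
    file.path(R.home("bin"), "Rscript"), c(cli_path(), ...),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  ))
  status <- attr(out, "status")
  list(output = out, status = if (is.null(status)) 0L else status)
}
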