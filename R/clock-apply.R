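#' Estimate DNAm age of samples from a clock model
#'
#' Computes each sample's linear predictor `b0 + sum_j w_j * beta_j` on the
#' calibrated transformed-age scale and maps it back to years through the
#' inverse age transform. Model probes that are absent from the matrix, or
#' missing for a sample, are imputed with the model's stored training mean
#' beta; the per-sample imputed fraction is always reported, and samples
#' whose imputed fraction exceeds `max_missing_frac` are flagged (not
#' dropped, and never silently returned as clean).
#'
#' Prediction is invariant to probe order and to extra unweighted probes in
#' the matrix.
#'
#' @param model A [clock_model()].
#' @param beta A beta tibble (see [read_beta_matrix()]).
#' @param max_missing_frac Largest acceptable fraction of imputed model
#'   probes per sample; above it the sample's `flagged` is `TRUE`.
#'   Default 0.2.
#' @return A tibble with columns `sample_id`, `dnam_age` (years),
#'   `n_imputed`, `frac_imputed`, `flagged`.
#' @examples
#' clk <- clock_model(intercept = 0, weights = c(cg1 = 2),
#'                    probe_means = c(cg1 = 0.25))
#' b <- tibble::tibble(probe_id = "cg1", s1 = 0.25)
#' estimate_dnam_age(clk, b)
#' @export
estimate_dnam_age <- function(model, beta, max_missing_frac = 0.2) {
  stopifnot(inherits(model, "clock_model"))
  if (max_missing_frac < 0 || max_missing_frac > 1) {
    abort("`max_missing_frac` must lie in [0, 1].")
  }
  m <- beta_to_matrix(beta)
  probes <- names(model$weights)
  n_probes <- length(probes)
  samples <- colnames(m)

  if (n_probes == 0) {
    lp <- rep(model$intercept, length(samples))
    return(tibble(sample_id = samples,
                  dnam_age = inverse_transform_age(lp, model$adult_age),
                  n_imputed = 0L, frac_imputed = 0, flagged = FALSE))
  }

  xm <- matrix(NA_real_, n_probes, length(samples),
               dimnames = list(probes, samples))
  present <- intersect(probes, rownames(m))
  xm[present, ] <- m[present, , drop = FALSE]
  imputed <- is.na(xm)
  if (any(imputed)) {
    if (is.null(model$probe_means)) {
      abort(paste(
        "Model probes are missing from the data but the model stores no",
        "probe means to impute with."
      ))
    }
    mu <- model$probe_means[probes]
    idx <- which(imputed, arr.ind = TRUE)
    xm[idx] <- mu[idx[, 1]]
  }

  lp <- model$intercept + as.numeric(crossprod(xm, model$weights[probes]))
  n_imp <- unname(colSums(imputed))
  frac <- n_imp / n_probes
  tibble(
    sample_id = samples,
    dnam_age = inverse_transform_age(lp, model$adult_age),
    n_imputed = as.integer(n_imp),
    frac_imputed = frac,
    flagged = frac > max_missing_frac
  )
}

#' Write DNAm age predictions to CSV
#'
#' @param predictions Tibble from [estimate_dnam_age()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dnam_age <- function(predictions, path) {
  readr::write_csv(predictions, path)
  invisible(path)
}
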