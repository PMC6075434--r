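#' Preselect candidate clock CpGs by age correlation
#'
#' Clock training does not feed every array probe to the penalized solver:
#' the candidate set is the union, per stratum (by default per tissue or
#' cell type), of the `k_pos` probes most positively and `k_neg` most
#' negatively Pearson-correlated with transformed age, plus the `k_null`
#' probes whose age correlation is least significant on the pooled data
#' (largest correlation-test p-value). The null block keeps probes with no
#' age signal available to the solver, which stabilizes the penalty path.
#'
#' Probes with zero variance within a stratum are treated as correlation 0,
#' p-value 1. Strata with fewer than 3 aged samples are skipped with a
#' warning. Tie-breaking is deterministic: equal correlations are ordered by
#' probe ID. Counts larger than the probe universe are capped.
#'
#' @param beta A beta tibble (see [read_beta_matrix()]).
#' @param ann Sample annotation with `sample_id`, `age`, and the
#'   stratification column.
#' @param k_pos,k_neg Top positively / negatively correlated probes kept per
#'   stratum. Defaults 1000 each.
#' @param k_null Least-age-associated probes kept from the pooled data.
#'   Default 500.
#' @param stratify_by Annotation column defining strata. Default
#'   `"tissue"`; if absent, all samples form one stratum.
#' @param adult_age Anchor for the age transform used in the correlations.
#' @return Character vector of selected probe IDs (in beta-matrix order).
#' @export
preselect_cpgs <- function(beta, ann, k_pos = 1000, k_neg = 1000,
                           k_null = 500, stratify_by = "tissue",
                           adult_age = 20) {
  if (k_pos < 0 || k_neg < 0 || k_null < 0 || k_pos + k_neg + k_null == 0) {
    abort("Selection counts must be >= 0 and not all zero.")
  }
  ann <- validate_annotation(ann)
  m <- beta_to_matrix(beta)
  common <- intersect(colnames(m), ann$sample_id)
  if (length(common) < 3) abort("Fewer than 3 samples shared by beta matrix and annotation.")
  m <- m[, common, drop = FALSE]
  ann <- ann[match(common, ann$sample_id), ]
  tage <- transform_age(ann$age, adult_age)

  strata <- if (stratify_by %in% names(ann)) {
    as.character(ann[[stratify_by]])
  } else {
    rep("all", length(common))
  }

  selected <- character()
  for (s in unique(strata)) {
    idx <- which(strata == s & !is.na(tage))
    if (length(idx) < 3) {
      warn(sprintf("Stratum '%s' has fewer than 3 aged samples; skipped.", s))
      next
    }
    r <- probe_age_correlation(m[, idx, drop = FALSE], tage[idx])$r
    ord_desc <- order(-r, rownames(m))
    ord_asc <- order(r, rownames(m))
    if (k_pos > 0) selected <- c(selected, rownames(m)[ord_desc[seq_len(min(k_pos, nrow(m)))]])
    if (k_neg > 0) selected <- c(selected, rownames(m)[ord_asc[seq_len(min(k_neg, nrow(m)))]])
  }
  if (k_null > 0) {
    ok <- !is.na(tage)
    pooled <- probe_age_correlation(m[, ok, drop = FALSE], tage[ok])
    ord_null <- order(-pooled$p, rownames(m))
    selected <- c(selected, rownames(m)[ord_null[seq_len(min(k_null, nrow(m)))]])
  }
  beta$probe_id[beta$probe_id %in% selected]
}

# Pearson correlation (pairwise-complete) of each probe row with a numeric
# covariate, plus the two-sided correlation-test p-value. Zero-variance
# probes: r = 0, p = 1.
probe_age_correlation <- function(m, z) {
  r <- suppressWarnings(as.numeric(cor(t(m), z, use = "pairwise.complete.obs")))
  nn <- rowSums(!is.na(m))
  r[is.na(r)] <- 0
  tstat <- r * sqrt(pmax(nn - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = pmax(nn - 2, 1))
  p[r == 0] <- 1
  list(r = r, p = p)
}

#' Train a DNAm age clock
#'
#' End-to-end clock construction: transform chronological ages onto the
#' calibrated scale, preselect candidate CpGs by age correlation
#' ([preselect_cpgs()]), mean-impute any missing betas, and fit a
#' cross-validated elastic net ([fit_elastic_net()]). The fitted support is
#' a sparse subset of the candidate set. Training-set performance (Pearson
#' correlation and median absolute error between DNAm age and chronological
#' age, in years) is recorded in the model's metadata.
#'
#' @inheritParams preselect_cpgs
#' @param alpha Elastic-net mixing; default 0.5.
#' @param folds Cross-validation folds; default 10.
#' @param lambda Optional penalty grid; default as in [fit_elastic_net()].
#' @param seed Integer seed for fold assignment (recorded in the model).
#' @param ... Further arguments passed to [fit_elastic_net()].
#' @return A [clock_model()].
#' @examples
#' sim <- simulate_methylation(n_samples = 60, n_causal = 20, n_null = 80,
#'                             seed = 7)
#' clock <- train_clock(sim$beta, sim$annotation, k_pos = 25, k_neg = 25,
#'                      k_null = 20, folds = 5)
#' glance(clock)
#' @export
train_clock <- function(beta, ann, k_pos = 1000, k_neg = 1000, k_null = 500,
                        stratify_by = "tissue", adult_age = 20, alpha = 0.5,
                        folds = 10, lambda = NULL, seed = 1, ...) {
  ann <- validate_annotation(ann)
  candidates <- preselect_cpgs(beta, ann, k_pos = k_pos, k_neg = k_neg,
                               k_null = k_null, stratify_by = stratify_by,
                               adult_age = adult_age)
  m <- beta_to_matrix(beta)
  common <- intersect(colnames(m), ann$sample_id)
  ann <- ann[match(common, ann$sample_id), ]
  keep <- !is.na(ann$age)
  ann <- ann[keep, ]
  x <- t(m[candidates, ann$sample_id, drop = FALSE])
  x <- impute_col_means(x)
  y <- transform_age(ann$age, adult_age)

  model <- fit_elastic_net(x, y, alpha = alpha, lambda = lambda,
                           folds = folds, adult_age = adult_age,
                           seed = seed, ...)
  pred <- estimate_dnam_age(model, beta, max_missing_frac = 1)
  pred <- pred[match(ann$sample_id, pred$sample_id), ]
  acc <- accuracy_metrics(ann$age, pred$dnam_age)
  model$meta$train_cor <- acc$pearson_r
  model$meta$train_mad <- acc$median_abs_error
  model$meta$candidates <- candidates
  model
}

impute_col_means <- function(x) {
  if (!anyNA(x)) return(x)
  mu <- colMeans(x, na.rm = TRUE)
  mu[is.nan(mu)] <- 0.5
  idx <- which(is.na(x), arr.ind = TRUE)
  x[idx] <- mu[idx[, 2]]
  x
}
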