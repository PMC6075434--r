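#' Simulate an array-like methylation dataset with known ground truth
#'
#' Generates a beta-value matrix whose "causal" CpGs follow monotone
#' logistic trajectories in calibrated (transformed) age — the statistical
#' structure a methylation clock exploits — together with age-independent
#' null CpGs, per-sample annotation, two overlapping platform manifests,
#' and a ground-truth record sufficient to recompute every planted effect.
#'
#' A causal probe j has mean beta
#' `plogis(a_j + b_j * z_i)` where `z_i = F(age_i) + tissue_offset +
#' disease_offset * disease_i` is the sample's true biological age on the
#' transformed scale (`F` = [transform_age()]); intercepts `a_j` and slopes
#' `b_j` are drawn from seeded ranges with balanced slope signs. Injecting
#' the disease effect on the transformed scale makes the planted offset
#' age-dependent in years — larger, in years, for young samples — which is
#' how progeroid acceleration presents. Gaussian noise (`noise_sd`, beta
#' scale) is added and values are clamped to \[0,1\]; null probes are a
#' constant mean plus the same noise.
#'
#' @param n_samples Number of samples.
#' @param n_causal,n_null Counts of age-tracking and pure-noise CpGs.
#' @param age_range Min/max of the uniform age distribution (years), or use
#'   `ages` for an explicit vector.
#' @param ages Optional explicit chronological ages.
#' @param noise_sd Beta-scale noise standard deviation. Default 0.03.
#' @param tissues Character vector of tissue labels, assigned uniformly.
#' @param tissue_offsets Named numeric vector of per-tissue offsets
#'   (transformed-age units); default 0 for every tissue.
#' @param disease_frac Fraction of samples labelled diseased.
#' @param disease_offset Disease acceleration in transformed-age units.
#' @param platform_frac Fraction of probes present on only one of the two
#'   emitted platform manifests.
#' @param slope_range Range of |b_j| for causal probes.
#' @param adult_age Age-transform anchor.
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return A list: `beta` (beta tibble), `annotation` (tibble with
#'   `sample_id`, `age`, `sex`, `tissue`, `disease`), `manifests` (list of
#'   two probe-ID vectors), `truth` (list with `causal_probes`,
#'   `probe_intercepts`, `probe_slopes`, `bio_age_transformed`, and the
#'   generator parameters).
#' @examples
#' sim <- simulate_methylation(n_samples = 10, n_causal = 5, n_null = 5)
#' dim(sim$beta)
#' @export
simulate_methylation <- function(n_samples = 100, n_causal = 50, n_null = 450,
                                 age_range = c(0, 90), ages = NULL,
                                 noise_sd = 0.03,
                                 tissues = "fibroblast", tissue_offsets = NULL,
                                 disease_frac = 0, disease_offset = 0,
                                 platform_frac = 0.1,
                                 slope_range = c(0.3, 0.8),
                                 adult_age = 20, seed = 1) {
  if (n_samples < 1 || n_causal < 0 || n_null < 0 || n_causal + n_null < 1) {
    abort("Counts must be positive (>= 1 probe, >= 1 sample).")
  }
  if (disease_frac < 0 || disease_frac > 1) abort("`disease_frac` must be in [0,1].")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (platform_frac < 0 || platform_frac > 1) abort("`platform_frac` must be in [0,1].")
  if (is.null(tissue_offsets)) tissue_offsets <- setNames(rep(0, length(tissues)), tissues)

  with_private_seed(seed, {
    n_probes <- n_causal + n_null
    probe_ids <- sprintf("cg%07d", sample.int(9999999, n_probes))
    causal <- sort(sample.int(n_probes, n_causal))
    is_causal <- seq_len(n_probes) %in% causal

    if (is.null(ages)) {
      ages <- runif(n_samples, age_range[1], age_range[2])
    } else {
      n_samples <- length(ages)
    }
    sample_ids <- sprintf("S%04d", seq_len(n_samples))
    tissue <- sample(tissues, n_samples, replace = TRUE)
    sex <- sample(c("male", "female"), n_samples, replace = TRUE)
    diseased <- as.logical(stats::rbinom(n_samples, 1, disease_frac))

    z <- transform_age(ages, adult_age) +
      unname(tissue_offsets[tissue]) +
      disease_offset * diseased

    a <- runif(n_probes, -1, 1)
    b_mag <- runif(n_probes, slope_range[1], slope_range[2])
    sign_vec <- rep_len(c(1, -1), n_causal)
    b <- numeric(n_probes)
    b[causal] <- b_mag[causal] * sample(sign_vec)
    mu_null <- runif(n_probes, 0.15, 0.85)

    mu <- matrix(rep(mu_null, n_samples), n_probes, n_samples)
    if (n_causal > 0) {
      mu[causal, ] <- stats::plogis(outer(a[causal], rep(1, n_samples)) +
                                      outer(b[causal], z))
    }
    vals <- mu + matrix(rnorm(n_probes * n_samples, 0, noise_sd),
                        n_probes, n_samples)
    vals <- pmin(pmax(vals, 0), 1)
    colnames(vals) <- sample_ids

    only_one <- runif(n_probes) < platform_frac
    on_a <- !only_one | (runif(n_probes) < 0.5)
    on_b <- !only_one | !on_a

    beta <- dplyr::bind_cols(tibble(probe_id = probe_ids), as_tibble(vals))
    annotation <- tibble(
      sample_id = sample_ids, age = ages, sex = sex, tissue = tissue,
      disease = ifelse(diseased, "case", "control")
    )
    truth <- list(
      causal_probes = probe_ids[causal],
      probe_intercepts = setNames(a[causal], probe_ids[causal]),
      probe_slopes = setNames(b[causal], probe_ids[causal]),
      bio_age_transformed = setNames(z, sample_ids),
      params = list(n_samples = n_samples, n_causal = n_causal,
                    n_null = n_null, noise_sd = noise_sd,
                    disease_frac = disease_frac,
                    disease_offset = disease_offset,
                    platform_frac = platform_frac,
                    adult_age = adult_age, seed = seed)
    )
    list(
      beta = beta,
      annotation = annotation,
      manifests = list(platform_a = probe_ids[on_a], platform_b = probe_ids[on_b]),
      truth = truth
    )
  })
}

#' Simulate an ex vivo passage series with drifting epigenetic age
#'
#' Emulates a cell culture tracked over serial passaging: each passage seeds
#' a fixed cell count, harvests a stochastic multiple of it (drawn to hit a
#' target per-passage doubling), and contributes a methylation sample whose
#' causal-probe logits drift linearly in cumulative population doubling —
#' i.e. the culture's true biological age increases by `drift` years per
#' doubling.
#'
#' @param n_passages Number of passages.
#' @param cells_seeded Cells seeded at every passage. Default 10000.
#' @param target_pd Mean population doublings per passage.
#' @param pd_sd Passage-to-passage SD of the realized doubling.
#' @param donor_age Chronological age of the donor at passage 0 (years).
#' @param drift Epigenetic aging rate in years per doubling. Default 0.15.
#' @param n_causal,n_null,noise_sd,slope_range,adult_age,seed As in
#'   [simulate_methylation()].
#' @return A list: `records` (tibble `passage`, `cells_seeded`,
#'   `cells_harvested`, `sample_id`, plus `pd`/`cum_pd` via
#'   [cumulative_pd()]), `beta` (beta tibble, one column per passage),
#'   `truth` (tibble `passage`, `cum_pd`, `bio_age` in years).
#' @export
simulate_pd_series <- function(n_passages = 20, cells_seeded = 10000,
                               target_pd = 1, pd_sd = 0.05,
                               donor_age = 0, drift = 0.15,
                               n_causal = 50, n_null = 50, noise_sd = 0.01,
                               slope_range = c(0.3, 0.8),
                               adult_age = 20, seed = 1) {
  if (n_passages < 1) abort("Need at least one passage.")
  if (cells_seeded <= 0) abort("`cells_seeded` must be positive.")
  with_private_seed(seed, {
    pd_target <- pmax(rnorm(n_passages, target_pd, pd_sd), 0.05)
    harvested <- round(cells_seeded * 10^(pd_target / 3.32))
    records <- tibble(
      passage = seq_len(n_passages),
      cells_seeded = cells_seeded,
      cells_harvested = harvested,
      sample_id = sprintf("P%03d", seq_len(n_passages))
    )
    records <- cumulative_pd(records)
    bio_age <- donor_age + drift * records$cum_pd

    n_probes <- n_causal + n_null
    probe_ids <- sprintf("cg%07d", sample.int(9999999, n_probes))
    causal <- seq_len(n_causal)
    a <- runif(n_probes, -1, 1)
    b <- runif(n_probes, slope_range[1], slope_range[2]) *
      rep_len(c(1, -1), n_probes)
    z <- transform_age(bio_age, adult_age)
    mu <- matrix(rep(runif(n_probes, 0.15, 0.85), n_passages),
                 n_probes, n_passages)
    if (n_causal > 0) {
      mu[causal, ] <- stats::plogis(outer(a[causal], rep(1, n_passages)) +
                                      outer(b[causal], z))
    }
    vals <- pmin(pmax(mu + matrix(rnorm(n_probes * n_passages, 0, noise_sd),
                                  n_probes, n_passages), 0), 1)
    colnames(vals) <- records$sample_id
    list(
      records = records,
      beta = dplyr::bind_cols(tibble(probe_id = probe_ids), as_tibble(vals)),
      truth = tibble(passage = records$passage, cum_pd = records$cum_pd,
                     bio_age = bio_age)
    )
  })
}
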