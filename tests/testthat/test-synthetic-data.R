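test_that("identical spec and seed give bitwise-identical datasets", {
  s1 <- simulate_methylation(n_samples = 25, n_causal = 8, n_null = 12,
                             disease_frac = 0.4, disease_offset = 0.3,
                             seed = 17)
  s2 <- simulate_methylation(n_samples = 25, n_causal = 8, n_null = 12,
                             disease_frac = 0.4, disease_offset = 0.3,
                             seed = 17)
  expect_identical(s1, s2)
  s3 <- simulate_methylation(n_samples = 25, n_causal = 8, n_null = 12,
                             disease_frac = 0.4, disease_offset = 0.3,
                             seed = 18)
  expect_false(identical(s1$beta, s3$beta))
})

test_that("noiseless causal probes correlate perfectly with transformed age", {
  sim <- simulate_methylation(n_samples = 40, n_causal = 10, n_null = 10,
                              noise_sd = 0, disease_frac = 0, seed = 19)
  m <- beta_to_matrix(sim$beta)
  z <- transform_age(sim$annotation$age)
  for (pr in sim$truth$causal_probes) {
    v <- m[pr, sim$annotation$sample_id]
    # the trajectory is logistic in transformed age: strictly monotone
    # (rank correlation exactly 1), Pearson near 1
    expect_equal(abs(cor(v, z, method = "spearman")), 1, tolerance = 1e-12)
    expect_gt(abs(cor(v, z)), 0.9)
  }
})

test_that("generated values respect container invariants and ground truth schema", {
  sim <- simulate_methylation(n_samples = 30, n_causal = 5, n_null = 15,
                              age_range = c(2, 80), noise_sd = 0.05,
                              platform_frac = 0.3, seed = 20)
  m <- beta_to_matrix(sim$beta)
  expect_true(all(m >= 0 & m <= 1))
  expect_true(all(sim$annotation$age >= 2 & sim$annotation$age <= 80))
  expect_setequal(names(sim$truth$probe_slopes), sim$truth$causal_probes)
  expect_setequal(names(sim$truth$probe_intercepts), sim$truth$causal_probes)
  expect_equal(names(sim$truth$bio_age_transformed), sim$annotation$sample_id)
  # slope signs balanced by construction
  expect_equal(sum(sign(sim$truth$probe_slopes) > 0), 3)  # 5 causal: 3 pos, 2 neg

  # every probe is on at least one platform; split fraction on exactly one
  both <- union(sim$manifests$platform_a, sim$manifests$platform_b)
  expect_setequal(both, sim$beta$probe_id)

  # ground truth is sufficient to recompute a planted probe mean
  pr <- sim$truth$causal_probes[1]
  mu <- stats::plogis(sim$truth$probe_intercepts[pr] +
                      sim$truth$probe_slopes[pr] *
                        sim$truth$bio_age_transformed)
  obs <- m[pr, sim$annotation$sample_id]
  expect_lt(max(abs(obs - pmin(pmax(mu, 0), 1))), 0.3)
  expect_gt(cor(obs, mu), 0.9)

  expect_error(simulate_methylation(n_samples = 0), "positive")
  expect_error(simulate_methylation(disease_frac = 1.5), "disease_frac")
})

test_that("the disease offset is injected on the transformed scale", {
  sim <- simulate_methylation(n_samples = 50, n_causal = 5, n_null = 5,
                              noise_sd = 0, disease_frac = 0.5,
                              disease_offset = 0.3, seed = 23)
  z_chrono <- transform_age(sim$annotation$age)
  offs <- sim$truth$bio_age_transformed - z_chrono
  is_case <- sim$annotation$disease == "case"
  expect_equal(unname(offs[is_case]), rep(0.3, sum(is_case)))
  expect_equal(unname(offs[!is_case]), rep(0, sum(!is_case)))
})

test_that("PD series are deterministic and a zero drift gives a flat trend", {
  s1 <- simulate_pd_series(n_passages = 15, drift = 0.2, seed = 24)
  s2 <- simulate_pd_series(n_passages = 15, drift = 0.2, seed = 24)
  expect_identical(s1, s2)

  flat <- simulate_pd_series(n_passages = 20, drift = 0, seed = 25)
  set.seed(25)
  dnam <- flat$truth$bio_age + rnorm(20, 0, 0.5)
  tr <- pd_age_trend(cum_pd = flat$truth$cum_pd, dnam_age = dnam)
  expect_lt(abs(tr$slope), 2 * tr$slope_se)

  # records honour the passage bookkeeping contract
  expect_true(all(diff(s1$records$passage) > 0))
  expect_true(all(s1$records$cells_harvested > 0))
  expect_equal(s1$records$cum_pd, cumsum(s1$records$pd))
})
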