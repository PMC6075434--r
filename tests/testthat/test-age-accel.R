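test_that("reference regression recovers exact generating coefficients", {
  ages <- c(1, 4, 9, 15, 30, 55)
  ctl <- tibble::tibble(age = ages, dnam_age = 2 + 0.9 * ages)
  ref <- fit_reference(ctl, degree = 1)
  expect_equal(unname(coef(ref$fit)), c(2, 0.9), tolerance = 1e-10)

  ctl2 <- tibble::tibble(age = ages, dnam_age = 1 + 0.5 * ages + 0.1 * ages^2)
  ref2 <- fit_reference(ctl2, degree = 2)
  # normal-equations oracle
  Xd <- cbind(1, ages, ages^2)
  oracle <- as.numeric(solve(crossprod(Xd), crossprod(Xd, ctl2$dnam_age)))
  expect_equal(unname(coef(ref2$fit)), oracle, tolerance = 1e-8)
  expect_equal(oracle, c(1, 0.5, 0.1), tolerance = 1e-8)

  expect_error(fit_reference(ctl[1:2, ]), "at least 3")
  expect_error(
    fit_reference(tibble::tibble(age = rep(5, 4), dnam_age = 1:4), degree = 1),
    "[Ss]ingular"
  )
})

test_that("control residuals average zero and on-line samples have zero residual", {
  set.seed(90)
  ctl <- tibble::tibble(age = runif(30, 0, 60),
                        dnam_age = 3 + 0.8 * runif(30, 0, 60) + rnorm(30))
  ctl$dnam_age <- 3 + 0.8 * ctl$age + rnorm(30, 0, 2)
  ctl$disease <- "control"
  res <- residual_acceleration(ctl)
  expect_lt(abs(mean(res$samples$accel)), 1e-8)

  ref <- res$reference
  on_line <- tibble::tibble(age = 25,
                            dnam_age = predict(ref, tibble::tibble(age = 25)))
  expect_equal(residual_acceleration(on_line, reference = ref)$samples$accel, 0,
               tolerance = 1e-12)
})

test_that("residual against a fixed reference matches hand arithmetic", {
  ref <- fit_reference(tibble::tibble(age = c(0, 10, 20),
                                      dnam_age = 3.5 + 0.85 * c(0, 10, 20)))
  s <- tibble::tibble(age = 8.5, dnam_age = 23.73)
  res <- residual_acceleration(s, reference = ref)
  expect_equal(res$samples$accel, 23.73 - (3.5 + 0.85 * 8.5), tolerance = 1e-10)
  expect_equal(res$samples$accel, 13.005, tolerance = 1e-10)
})

test_that("acceleration is equivariant to a constant shift of all DNAm ages", {
  set.seed(91)
  d <- tibble::tibble(
    age = runif(40, 0, 70),
    disease = rep(c("control", "case"), each = 20)
  )
  d$dnam_age <- 2 + 0.9 * d$age + rnorm(40, 0, 3) +
    5 * (d$disease == "case")
  r1 <- residual_acceleration(d)
  d2 <- d
  d2$dnam_age <- d$dnam_age + 7
  r2 <- residual_acceleration(d2)
  expect_equal(r1$samples$accel, r2$samples$accel, tolerance = 1e-10)
})

test_that("adjusted model matches control-referenced group difference on balanced data", {
  set.seed(92)
  age <- rep(runif(25, 1, 9), 2)  # identical age distribution in both groups
  disease <- rep(c("control", "case"), each = 25)
  dnam <- 1 + 1.1 * age + 4 * (disease == "case") + rnorm(50, 0, 1.5)
  d <- tibble::tibble(age = age, disease = disease, dnam_age = dnam)
  adj <- adjusted_acceleration(d, covariates = c("age", "disease"))
  res <- residual_acceleration(d)
  diff_means <- mean(res$samples$accel[disease == "case"]) -
    mean(res$samples$accel[disease == "control"])
  est <- adj$estimate[adj$term == "disease"]
  expect_equal(est, diff_means, tolerance = 0.15 * abs(diff_means))
})

test_that("rank-deficient adjusted designs fail naming the collinear column", {
  d <- tibble::tibble(age = c(1, 2, 3, 4), dnam_age = c(2, 3, 5, 6),
                      agedup = c(1, 2, 3, 4))
  expect_error(adjusted_acceleration(d, covariates = c("age", "agedup")),
               "agedup")
})

test_that("accuracy metrics match hand values and handle degenerate input", {
  perfect <- accuracy_metrics(1:10, 1:10)
  expect_equal(perfect$pearson_r, 1)
  expect_equal(perfect$median_abs_error, 0)

  m1 <- accuracy_metrics(c(0, 10, 20), c(5, 10, 30))
  expect_equal(m1$median_abs_error, 5)

  m2 <- accuracy_metrics(c(1, 2, 3), c(2, 4, 6))
  expect_equal(m2$pearson_r, 1)
  expect_equal(m2$median_abs_error, 2)

  expect_warning(m3 <- accuracy_metrics(c(5, 5, 5), c(1, 2, 3)), "variance")
  expect_true(is.na(m3$pearson_r))
  expect_error(accuracy_metrics(1, 2), "at least 2")
})
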