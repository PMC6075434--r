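test_that("beta matrix survives a write/read round trip, including missing cells", {
  b <- make_beta(c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
                 c("cg1", "cg2", "cg3"), c("s1", "s2"))
  f <- withr::local_tempfile(fileext = ".csv")
  suppressWarnings(write_beta_matrix(b, f))
  got <- suppressWarnings(read_beta_matrix(f))
  expect_equal(got, b)
  expect_false(anyNA(beta_to_matrix(got)))

  # one empty cell -> exactly one missing entry at that coordinate
  b$s2[2] <- NA
  suppressWarnings(write_beta_matrix(b, f))
  got <- suppressWarnings(read_beta_matrix(f))
  m <- beta_to_matrix(got)
  expect_equal(sum(is.na(m)), 1L)
  expect_true(is.na(m["cg2", "s2"]))
  expect_equal(got, b)

  # float precision round trip
  set.seed(5)
  b2 <- make_beta(runif(20), sprintf("cg%05d", 1:5), paste0("x", 1:4))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_beta_matrix(b2, f2)
  expect_equal(read_beta_matrix(f2), b2, tolerance = 1e-12)
})

test_that("invalid beta files are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("probe_id,s1,s2", "cg1,0.2,0.3", "cg2,1.2,0.4"), f)
  expect_error(suppressWarnings(read_beta_matrix(f)), "cg2.*s1|s1.*cg2")

  writeLines(c("probe_id,s1", "cg1,0.2", "cg1,0.4"), f)
  expect_error(suppressWarnings(read_beta_matrix(f)), "[Dd]uplicate")

  writeLines(c("probe_id,s1", "cg1,0.2", "cg2,oops"), f)
  expect_error(read_beta_matrix(f), "line 3")

  writeLines(c("probe_id,s1", "weird_probe,0.2", "cg2,0.5"), f)
  expect_warning(read_beta_matrix(f), "pattern")
})

test_that("samples-in-rows dialect reads the transposed layout", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,cg1,cg2", "s1,0.1,0.2", "s2,0.3,0.4"), f)
  got <- read_beta_matrix(f, dialect = "samples_in_rows")
  expect_equal(got$probe_id, c("cg1", "cg2"))
  expect_equal(got$s1, c(0.1, 0.2))
  expect_equal(got$s2, c(0.3, 0.4))
})

test_that("platform intersection is correct, idempotent, and order-invariant", {
  b <- make_beta(rep(0.5, 6), c("cg1", "cg2", "cg3"), c("s1", "s2"))
  m1 <- c("cg1", "cg2")
  m2 <- c("cg2", "cg3")
  got <- intersect_platforms(b, list(m1, m2))
  expect_equal(got$probe_id, "cg2")

  expect_equal(intersect_platforms(b, list(c("cg1", "cg2", "cg3"))), b)
  expect_error(intersect_platforms(b, list(c("cg99"))), "manifest")

  # idempotent and commutative in manifest order
  expect_equal(intersect_platforms(got, list(m1, m2)), got)
  expect_equal(intersect_platforms(b, list(m2, m1)), got)
})

test_that("annotation validation enforces age and pdl domains", {
  ann <- tibble::tibble(sample_id = c("a", "b"), age = c(-0.3, 40),
                        sex = c("M", "f"), pdl = c(0, 12.5))
  got <- validate_annotation(ann)
  expect_equal(got$sex, c("male", "female"))

  expect_error(validate_annotation(tibble::tibble(sample_id = "a", age = -1.5)),
               "-1")
  expect_error(validate_annotation(tibble::tibble(sample_id = "a", age = 5,
                                                  pdl = -2)), "pdl")
  expect_error(validate_annotation(tibble::tibble(sample_id = c("a", "a"),
                                                  age = c(1, 2))), "[Dd]uplicate")
  expect_error(validate_annotation(tibble::tibble(sample_id = "a")), "age")
})

test_that("clock coefficient files load, reject malformed input, and round trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("term,coefficient", "(Intercept),1.0", "cg1,0.5"), f)
  m <- suppressMessages(read_clock_coefficients(f))
  expect_s3_class(m, "clock_model")
  expect_equal(m$intercept, 1.0)
  expect_equal(m$weights, c(cg1 = 0.5))

  writeLines(c("term,coefficient", "(Intercept),1.0", "cg1,0.5", "cg1,0.2"), f)
  expect_error(suppressMessages(read_clock_coefficients(f)), "[Dd]uplicate")

  writeLines(c("term,coefficient", "cg1,0.5"), f)
  expect_error(suppressMessages(read_clock_coefficients(f)), "intercept")

  # round trip up to numeric formatting
  clk <- clock_model(intercept = -0.25, weights = c(cg10 = 1.5, cg2 = -0.75),
                     probe_means = c(cg10 = 0.4, cg2 = 0.6))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_clock_coefficients(clk, f2)
  back <- suppressMessages(read_clock_coefficients(f2))
  expect_equal(back$intercept, clk$intercept)
  expect_equal(back$weights, clk$weights)
  expect_equal(back$probe_means, clk$probe_means)
})
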