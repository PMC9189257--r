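test_that("packaged verbal-IQ table loads with its printed values", {
  m <- table2
  expect_length(m$names, 11)
  expect_identical(m$n, 215L)
  expect_equal(unname(m$sds["VIQ"]), 18.0)
  expect_equal(m$corr["VIQ", "Occ"], -0.59)
  expect_equal(m$corr["Ment", "Eth"], -0.03)
  expect_true(all(diag(m$corr) == 1))
})

test_that("write/load round trip preserves every field", {
  prefix <- file.path(tempdir(), "roundtrip")
  write_summary(table2, prefix)
  m2 <- load_summary(prefix)
  expect_equal(m2$names, table2$names)
  expect_identical(m2$n, table2$n)
  expect_equal(m2$means, table2$means, tolerance = 1e-12)
  expect_equal(m2$sds, table2$sds, tolerance = 1e-12)
  expect_equal(m2$corr, table2$corr, tolerance = 1e-12)
})

test_that("lower-triangle correlation input is mirrored", {
  prefix <- file.path(tempdir(), "lower")
  C <- table2$corr
  C[upper.tri(C)] <- NA
  utils::write.csv(data.frame(variable = table2$names, C,
                              check.names = FALSE),
                   paste0(prefix, ".corr.csv"), row.names = FALSE)
  meta <- data.frame(variable = c(table2$names, "n"),
                     mean = c(unname(table2$means), 215),
                     sd = c(unname(table2$sds), NA))
  utils::write.csv(meta, paste0(prefix, ".meta.csv"), row.names = FALSE)
  m <- load_summary(prefix)
  expect_equal(m$corr, table2$corr)
})

test_that("validation rejects malformed summaries with informative errors", {
  C <- diag(2)
  expect_s3_class(summary_moments(c("a", "b"), 10, c(0, 0), c(1, 1), C),
                  "summary_moments")
  bad <- C; bad[1, 2] <- 0.3; bad[2, 1] <- 0.1
  expect_error(summary_moments(c("a", "b"), 10, c(0, 0), c(1, 1), bad),
               "asymmetric at cell")
  expect_error(summary_moments(c("a", "b"), 10, c(0, 0), c(1, 0), C),
               "SDs must be > 0")
  expect_error(summary_moments(c("a", "b"), 2, c(0, 0), c(1, 1), C),
               "n must be")
  # strongly indefinite matrix fails
  R <- matrix(c(1, .9, .9, .9, 1, -.9, .9, -.9, 1), 3)
  expect_error(summary_moments(letters[1:3], 10, rep(0, 3), rep(1, 3), R),
               "not positive semidefinite")
  # marginally indefinite (eigenvalue in (-1e-8, 0)) warns but passes
  rho <- -0.5 - 2.5e-9
  R2 <- matrix(rho, 3, 3); diag(R2) <- 1
  expect_warning(summary_moments(letters[1:3], 10, rep(0, 3), rep(1, 3), R2),
                 "marginally indefinite")
})

test_that("moments_from_raw matches known correlations and is permutation-invariant", {
  set.seed(7)
  x <- rnorm(50)
  d <- data.frame(a = x, b = x, c = -x + 0, e = rnorm(50))
  # perfect collinearity makes the correlation matrix singular, which the
  # validator may flag as marginally indefinite
  m <- suppressWarnings(moments_from_raw(d))
  expect_equal(m$corr["a", "b"], 1.0)
  expect_equal(m$corr["a", "c"], -1.0)
  shuffled <- d[sample(nrow(d)), ]
  m2 <- suppressWarnings(moments_from_raw(shuffled))
  expect_equal(m2$corr, m$corr, tolerance = 1e-12)
  expect_equal(m2$means, m$means, tolerance = 1e-12)
  # correlation matrices from raw data are PSD
  expect_gte(min(eigen(m$corr, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-12)
  expect_error(moments_from_raw(data.frame(a = rep(1, 10), b = rnorm(10))),
               "constant column")
  expect_error(moments_from_raw(data.frame(a = 1:2, b = c(2, 1))),
               "at least 3")
  expect_error(moments_from_raw(d, "zz"), "unknown column")
})

test_that("listwise deletion drops incomplete rows with a logged count", {
  d <- data.frame(a = c(1, 2, NA, 4, 5, 3), b = c(2, 1, 3, NA, 2, 5))
  expect_error(moments_from_raw(d), "missing values")
  expect_message(m <- moments_from_raw(d, na_action = "listwise"),
                 "dropped 2 of 6")
  expect_identical(m$n, 4L)
})

test_that("center_moments extracts the hand-computed covariance block", {
  cm <- center_moments(table2, "VIQ", "Occ")
  # corr * sd_y * sd_x from the printed table
  expect_equal(unname(cm$Cxy["Occ"]), -0.59 * 18.0 * 0.400, tolerance = 1e-12)
  cm2 <- center_moments(table2, "VIQ", c("Occ", "Educ"))
  expect_equal(cm2$Cxx["Occ", "Occ"], 0.400^2, tolerance = 1e-12)
  # permuting predictors permutes, not changes, the entries
  cm3 <- center_moments(table2, "VIQ", c("Educ", "Occ"))
  expect_equal(cm3$Cxx["Occ", "Educ"], cm2$Cxx["Occ", "Educ"])
  expect_equal(cm3$Cxy["Occ"], cm2$Cxy["Occ"])
  expect_error(center_moments(table2, "VIQ", "Nope"),
               "available: VIQ")
})

test_that("raw -> moments -> exact sample -> moments is the identity", {
  samp <- exact_moment_sample(table2, seed = 11)
  m <- moments_from_raw(samp)
  expect_equal(m$means, table2$means, tolerance = 1e-8)
  expect_equal(m$sds, table2$sds, tolerance = 1e-8)
  expect_equal(m$corr, table2$corr, tolerance = 1e-8)
})
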