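test_that("normalization divides by the total and rejects degenerate input", {
  expect_equal(normalize_envelope(c(2, 1, 1)), c(0.5, 0.25, 0.25))
  expect_equal(normalize_envelope(5), 1.0)
  table2 <- c(0.527, 0.298, 0.116, 0.036, 0.000, 0.023, 0.000)
  expect_equal(normalize_envelope(table2), table2)
  expect_error(normalize_envelope(c(0, 0)), "positive")
  expect_error(normalize_envelope(c(1, -0.1)), "non-negative")
})

test_that("centroid is the intensity-weighted first moment", {
  expect_equal(envelope_centroid(1.0), 0)
  expect_equal(envelope_centroid(c(0, 1)), 1)
  # hand-summed over the classic 7-peak example:
  # 1*0.298 + 2*0.116 + 3*0.036 + 5*0.023 = 0.753
  table2 <- c(0.527, 0.298, 0.116, 0.036, 0.000, 0.023, 0.000)
  expect_equal(envelope_centroid(table2), 0.753, tolerance = 1e-12)
  # independent brute-force accumulation agrees
  acc <- 0
  for (i in seq_along(table2)) acc <- acc + (i - 1) * table2[i]
  expect_equal(envelope_centroid(table2), acc / sum(table2))
})

test_that("centroid is translation-covariant and bounded", {
  set.seed(303)
  for (i in 1:40) {
    e <- normalize_envelope(runif(sample(2:12, 1)))
    c0 <- envelope_centroid(e)
    expect_gte(c0, 0)
    expect_lte(c0, length(e) - 1)
    k <- sample(1:5, 1)
    expect_equal(envelope_centroid(c(rep(0, k), e)), c0 + k,
                 tolerance = 1e-12)
  }
})

test_that("noise-free binomial envelopes have centroid n * p", {
  for (n in c(1, 4, 7, 15, 30)) {
    for (p in seq(0, 1, by = 0.25)) {
      e <- dbinom(0:n, n, p)
      expect_equal(envelope_centroid(e), n * p, tolerance = 1e-9)
    }
  }
})

test_that("uptake subtracts the zero-timepoint centroid", {
  s <- centroid_series(1, 10, time_sec = c(0, 60), centroid = c(0.75, 2.10))
  u <- compute_uptake(s)
  expect_equal(u$time_sec, c(0, 60))
  expect_equal(u$uptake, c(0.00, 1.35))
  expect_identical(u$uptake[u$time_sec == 0], 0)
})

test_that("uptake without a zero point needs an explicit reference", {
  s <- centroid_series(1, 10, time_sec = 60, centroid = 2.10)
  expect_error(compute_uptake(s), "no 0 s timepoint.*peptide 1-10")
  u <- compute_uptake(s, zero_centroid = 0.75)
  expect_equal(u$uptake, 1.35)
})

test_that("series with duplicate times are rejected", {
  expect_error(centroid_series(1, 10, c(60, 60), c(1, 2)),
               "same time")
})

test_that("replicates missing a zero get the mean of the others' zeros", {
  a <- centroid_series(1, 10, c(0, 60), c(0.70, 2.0), rep = 0)
  b <- centroid_series(1, 10, c(0, 60), c(0.80, 2.1), rep = 1)
  d <- centroid_series(1, 10, 60, 2.2, rep = 2)
  zr <- zero_reference(list(a, b, d))
  expect_equal(zr, c("0" = 0.70, "1" = 0.80, "2" = 0.75))
  # a single replicate with a zero references itself
  expect_equal(zero_reference(list(a)), c("0" = 0.70))
  # no zero anywhere is an error
  e <- centroid_series(1, 10, 60, 2.0, rep = 0)
  g <- centroid_series(1, 10, 600, 2.4, rep = 1)
  expect_error(zero_reference(list(e, g)), "no replicate has a 0 s")
})
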