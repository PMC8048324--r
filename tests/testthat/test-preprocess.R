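test_that("the default grid has 4250 buckets and water exclusion removes 385 of them", {
  g <- bucketGrid()
  expect_identical(g$n_buckets, 4250)           # (9.0 - 0.5) / 0.002
  # brute-force enumeration of centers inside the closed water window
  expected_removed <- sum(g$centers >= 4.38 & g$centers <= 5.15)
  expect_identical(expected_removed, 385L)
  sp <- NMRSpectrum(seq(0.45, 9.05, length.out = 9000), rnorm(9000))
  bt <- buildBucketTable(list(sp, sp), g)
  bt <- excludeWater(bt)
  expect_identical(sum(!retainedBuckets(bt)), 385L)
  expect_identical(sum(retainedBuckets(bt)), 3865L)
})

test_that("constant spectra aligned to the grid give uniform bucket sums", {
  # points at exact 0.001 spacing: two per 0.002 bucket
  x <- seq(0.5, 9.0, by = 0.001)
  sp <- NMRSpectrum(x, rep(3, length(x)))
  v <- bucketSpectrum(sp, bucketGrid())
  expect_true(all(v == 6))                      # c * p = 3 * 2
})

test_that("bucket membership matches the brute-force interval oracle", {
  g <- bucketGrid()
  set.seed(31)
  pts <- c(runif(40, 0.51, 8.99), 9.0, 8.998, 0.502)
  for (p in pts) {
    x <- sort(unique(c(seq(0.45, 9.05, length.out = 500), p)),
              decreasing = TRUE)
    y <- as.numeric(abs(x - p) < 1e-12)
    v <- bucketSpectrum(NMRSpectrum(x, y), g)
    hit <- which(v != 0)
    expect_length(hit, 1)
    expect_identical(hit[[1]], as.integer(bucket_of_oracle(p, 9.0, 0.5, 0.002)))
  }
})

test_that("bucketing conserves total intensity over the grid span", {
  sp <- generateSpectrum(defaultPanel()$weight * 4, defaultPanel(),
                         n_points = 9000, ppm_range = c(0.45, 9.05),
                         noise_sd = 0.1, seed = 3)
  v <- bucketSpectrum(sp, bucketGrid())
  raw <- sum(intensity(sp)[ppm(sp) > 0.5 & ppm(sp) <= 9.0])
  expect_equal(sum(v), raw, tolerance = 1e-12)
})

test_that("a spectrum not covering the grid is rejected", {
  sp <- NMRSpectrum(seq(1, 8, length.out = 1000), rnorm(1000))
  expect_error(bucketSpectrum(sp, bucketGrid()), "does not cover")
})

test_that("water exclusion commutes with raw-axis exclusion for edge-aligned windows", {
  sp <- generateSpectrum(defaultPanel()$weight * 4, defaultPanel(),
                         n_points = 9000, ppm_range = c(0.45, 9.05),
                         noise_sd = 0.1, water_amp = 30, seed = 5)
  g <- bucketGrid()
  bt <- excludeWater(buildBucketTable(list(sp), g))
  kept <- bucketMatrix(bt)[1, ]
  # exclude on the raw axis first (the points the masked buckets cover)
  keep_pt <- !(ppm(sp) > 4.38 & ppm(sp) <= 5.15)
  x2 <- ppm(sp)[keep_pt]; y2 <- intensity(sp)[keep_pt]
  v2 <- bucketSpectrum(NMRSpectrum(x2, y2), g)
  expect_equal(unname(kept),
               unname(v2[retainedBuckets(bt)]), tolerance = 1e-12)
})

test_that("degenerate exclusion windows behave sanely", {
  sp <- NMRSpectrum(seq(0.45, 9.05, length.out = 9000), rnorm(9000))
  bt <- buildBucketTable(list(sp, sp))
  same <- excludeWater(bt, c(10, 11))           # outside the grid
  expect_identical(retainedBuckets(same), rep(TRUE, 4250))
  none <- excludeWater(bt, c(0.4, 9.1))         # whole grid
  expect_identical(sum(retainedBuckets(none)), 0L)
  X <- paretoScale(bucketMatrix(none))
  expect_error(fitOplsda(X, c("pre", "post"), n_orth = 0))
})

test_that("Pareto scaling centers and divides by sqrt of the sample SD", {
  m <- cbind(a = c(1, 1, 1), b = c(0, 4, 8))    # sd(b) = 4
  s <- paretoScale(m)
  expect_equal(unname(s[, "a"]), c(0, 0, 0))
  expect_equal(unname(s[, "b"]), c(-4, 0, 4) / 2)
  big <- matrix(rnorm(200), 20, 10)
  expect_true(all(abs(colMeans(paretoScale(big))) < 1e-12))
  expect_error(paretoScale(matrix(1, 1, 3)), "at least 2 rows")
})

test_that("alanine referencing shifts a planted doublet onto the target", {
  pan <- defaultPanel()
  conc <- pan$weight * c(6, 10, 3, 4, 3, rep(8, 10))[
    match(pan$metabolite, unique(pan$metabolite))]
  for (planted_shift in c(0.02, 0, -0.015)) {
    sp <- generateSpectrum(conc, pan, n_points = 9000,
                           ppm_range = c(0.45, 9.05), noise_sd = 0.02,
                           shift = planted_shift, seed = 1)
    # doublet sits at 1.48 + planted_shift; ask for it at 1.50
    ref <- referenceToAlanine(sp, target = 1.50)
    expect_false(ref@flags$ref_failed)
    expect_lt(abs(ref@flags$ref_shift - (0.02 - planted_shift)), 6e-4)
  }
})

test_that("referencing a flat spectrum fails gracefully", {
  sp <- NMRSpectrum(seq(0.5, 9, length.out = 4000), rep(1, 4000))
  expect_warning(ref <- referenceToAlanine(sp), "not detected")
  expect_true(ref@flags$ref_failed)
  expect_identical(ref@flags$ref_shift, 0)
  expect_identical(ppm(ref), ppm(sp))
})
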