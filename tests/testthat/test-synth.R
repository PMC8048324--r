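pan <- defaultPanel()
base_conc <- function(profile = defaultEffectProfile())
  unname(profile$baseline_conc[pan$metabolite] * pan$weight)

test_that("zero concentrations, zero noise and baseline give a flat zero spectrum", {
  sp <- generateSpectrum(rep(0, nrow(pan)), pan, n_points = 2000)
  expect_true(all(intensity(sp) == 0))
  expect_equal(length(ppm(sp)), 2000)
})

test_that("region integrals are affine in concentration with positive slope", {
  for (target in c("alanine_1.48", "lipid_1.3", "glucose_3.24")) {
    r <- which(pan$name == target)
    ints <- vapply(c(0, 1, 2, 5), function(k) {
      conc <- rep(0, nrow(pan)); conc[r] <- k
      sp <- generateSpectrum(conc, pan, n_points = 4000)
      integrateRegion(sp, pan$center[r] - pan$half_width[r],
                      pan$center[r] + pan$half_width[r])
    }, numeric(1))
    # zero intercept here (no baseline), linear in k
    expect_equal(ints[3], 2 * ints[2], tolerance = 1e-10)
    expect_equal(ints[4], 5 * ints[2], tolerance = 1e-10)
    expect_gt(ints[2], 0)
  }
})

test_that("spectrum generation is deterministic for a fixed seed", {
  a <- generateSpectrum(base_conc(), pan, noise_sd = 0.05,
                        baseline_amp = 0.2, n_points = 3000, seed = 11)
  b <- generateSpectrum(base_conc(), pan, noise_sd = 0.05,
                        baseline_amp = 0.2, n_points = 3000, seed = 11)
  expect_identical(intensity(a), intensity(b))
})

test_that("invalid generator inputs are rejected", {
  expect_error(generateSpectrum(rep(-1, nrow(pan)), pan), "nonnegative")
  expect_error(generateSpectrum(rep(1, 3), pan), "one concentration")
  expect_error(NMRSpectrum(c(1, 3, 2), c(0, 0, 0)), "monotone")
  expect_error(cohortSpec(subgroup_props = c(full = 0.5, weakA = 0.4,
                                             weakB = 0.3)), "sum to 1")
})

test_that("cohort regeneration is bit-identical and patient substreams are stable under subsetting", {
  s1 <- generateCohort(cohortSpec(n_patients = 3, seed = 5,
                                  n_points = 9000))
  s2 <- generateCohort(cohortSpec(n_patients = 3, seed = 5,
                                  n_points = 9000))
  expect_identical(lapply(s1$spectra, intensity),
                   lapply(s2$spectra, intensity))
  expect_identical(s1$clinical, s2$clinical)
  s4 <- generateCohort(cohortSpec(n_patients = 4, seed = 5,
                                  n_points = 9000))
  expect_identical(s1$concentrations,
                   s4$concentrations[s4$concentrations$patient %in%
                                       s1$concentrations$patient, ])
})

test_that("identity effect profile leaves concentrations unchanged up to technical noise", {
  expect_warning(
    prof <- defaultEffectProfile(
      effects = c(lipid_0.9 = 1, lipid_1.3 = 1, lipid_5.3 = 1,
                  alanine = 1, NAG = 1, glucose = 1),
      technical_cv = 0),
    "direction")
  coh <- suppressWarnings(
    generateCohort(cohortSpec(n_patients = 4, seed = 2, n_points = 9000),
                   prof))
  expect_equal(coh$concentrations$pre, coh$concentrations$post)
})

test_that("an all-full cohort carries the full effect for every patient", {
  coh <- generateCohort(cohortSpec(n_patients = 6, seed = 3,
                                   n_points = 9000,
                                   subgroup_props = c(full = 1, weakA = 0,
                                                      weakB = 0)))
  expect_true(all(coh$labels$subgroup == "full"))
  prof <- defaultEffectProfile()
  ratio <- coh$concentrations$post / coh$concentrations$pre
  planted <- prof$effects[coh$concentrations$metabolite]
  # log-ratio = planted log-effect + technical noise (sd 0.04)
  expect_true(all(abs(log(ratio) - log(planted)) < 4 * prof$technical_cv))
})

test_that("subgroup label proportions converge to the specification", {
  # draw many patients cheaply on a coarse grid
  coh <- generateCohort(cohortSpec(n_patients = 600, seed = 9,
                                   n_points = 1000, bucket_width = 0.02))
  pr <- table(coh$labels$subgroup) / 600
  spec_pr <- c(full = 0.64, weakA = 0.19, weakB = 0.17)
  for (g in names(spec_pr)) {
    se3 <- 3 * sqrt(spec_pr[[g]] * (1 - spec_pr[[g]]) / 600)
    expect_lt(abs(pr[[g]] - spec_pr[[g]]), se3)
  }
})

test_that("planted effect directions show up in pre/post region integrals across seeds", {
  lip <- which(pan$name == "lipid_1.3")
  ala <- which(pan$name == "alanine_1.48")
  ratios <- t(vapply(1:20, function(seed) {
    coh <- generateCohort(cohortSpec(n_patients = 5, seed = seed,
                                     n_points = 2000, bucket_width = 0.01))
    lr <- ar <- numeric(5)
    for (i in 1:5) {
      pid <- sprintf("P%03d", i)
      pre <- coh$spectra[[paste0(pid, "_pre_CPMG")]]
      post <- coh$spectra[[paste0(pid, "_post_CPMG")]]
      reg <- function(s, r) integrateRegion(s, pan$center[r] - pan$half_width[r],
                                            pan$center[r] + pan$half_width[r])
      lr[i] <- reg(post, lip) / reg(pre, lip)
      ar[i] <- reg(post, ala) / reg(pre, ala)
    }
    c(lipid = mean(lr), alanine = mean(ar))
  }, numeric(2)))
  expect_gt(mean(ratios[, "lipid"]), 1)
  expect_lt(mean(ratios[, "alanine"]), 1)
})

test_that("writeCohort produces readable spectra and tables", {
  coh <- generateCohort(cohortSpec(n_patients = 2, seed = 8,
                                   n_points = 9000))
  d <- withr::local_tempdir()
  writeCohort(coh, d)
  expect_true(file.exists(file.path(d, "clinical.csv")))
  expect_true(file.exists(file.path(d, "labels.csv")))
  f <- file.path(d, "spectra", "P001_pre_CPMG.tsv")
  expect_true(file.exists(f))
  sp <- readSpectrum(f)
  orig <- coh$spectra[["P001_pre_CPMG"]]
  expect_equal(intensity(sp), intensity(orig), tolerance = 1e-9)
})
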