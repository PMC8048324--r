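test_that("mixing strata follow the score-sign rules", {
  t1 <- c(-2, 3, -1, -0.5, 0.3, 1)
  tp <- rep(c("pre", "post"), 3)
  pid <- rep(c("a", "b", "c"), each = 2)
  tr <- detectMixing(t1, tp, pid)
  expect_identical(as.character(tr$stratum),
                   c("Grey", "Red", "Green"))
  expect_equal(tr$distance, c(5, 0.5, 0.7))
  expect_identical(tr$correct, c(TRUE, TRUE, TRUE))
})

test_that("orientation is normalized so the post class sits positive", {
  t1 <- c(-2, 3, -1, -0.5, 0.3, 1)
  tp <- rep(c("pre", "post"), 3)
  pid <- rep(c("a", "b", "c"), each = 2)
  flipped <- detectMixing(-t1, tp, pid)
  expect_identical(as.character(flipped$stratum),
                   as.character(detectMixing(t1, tp, pid)$stratum))
})

test_that("strata partition the paired cohort; incomplete patients are excluded", {
  set.seed(21)
  n <- 40L
  t1 <- rnorm(2 * n)
  tp <- rep(c("pre", "post"), n)
  pid <- rep(sprintf("P%02d", 1:n), each = 2)
  tr <- detectMixing(t1, tp, pid)
  expect_identical(nrow(tr), n)
  expect_false(any(is.na(tr$stratum)))          # exhaustive and exclusive
  expect_identical(anyDuplicated(tr$patient), 0L)
  # Red takes precedence: a patient with post < 0 AND pre > 0 is Red
  both <- detectMixing(c(0.5, -0.5, -1, 1), rep(c("pre", "post"), 2),
                       c("x", "x", "y", "y"))
  expect_identical(as.character(both$stratum[both$patient == "x"]), "Red")
  expect_warning(
    tr2 <- detectMixing(c(1, -1, 2), c("pre", "post", "pre"),
                        c("a", "a", "b")), "missing a timepoint")
  expect_identical(tr2$patient, "a")
  expect_identical(attr(tr2, "excluded"), "b")
})

test_that("trajectory distance and direction follow the definitions", {
  td <- trajectoryDistance(c(-2, 1, 2), c(3, 1, -1))
  expect_equal(td$distance, c(5, 0, 3))
  expect_identical(td$correct, c(TRUE, FALSE, FALSE))
})

test_that("median ratio matches its formula and flags non-positive medians", {
  expect_equal(medianRatio(c(2, 2, 2), c(4, 4, 4)), 50)
  expect_equal(medianRatio(1:9, 1:9), 0)
  expect_equal(medianRatio(rep(100, 3), rep(1, 3)), 99)
  bad <- medianRatio(c(-2, -2), c(1, 2))
  expect_true(is.na(bad))
  expect_true(attr(bad, "undefined"))
})

test_that("the paired battery detects planted paired effects and skips tiny groups", {
  set.seed(33)
  n <- 20
  pre <- matrix(rlnorm(2 * n, log(10), 0.2), 2, n,
                dimnames = list(c("m_up", "m_same"), NULL))
  post <- pre
  post["m_up", ] <- 2 * pre["m_up", ]           # doubled in every patient
  mt <- make_metab(pre, post)
  b <- pairedBattery(mt)
  wsr <- b[b$test == "WSR", ]
  expect_lt(wsr$p[wsr$metabolite == "m_up"], 0.001)
  expect_equal(wsr$p[wsr$metabolite == "m_same"], 1)
  expect_equal(wsr$median_ratio[wsr$metabolite == "m_up"], 50)
  expect_equal(wsr$median_ratio[wsr$metabolite == "m_same"], 0)
})

test_that("group sizes below the minimum are skipped with a reason", {
  set.seed(34)
  n <- 10
  pre <- matrix(rlnorm(n, log(5), 0.1), 1, n,
                dimnames = list("m1", sprintf("P%02d", 1:n)))
  post <- pre * 1.2
  mt <- make_metab(pre, post)
  groups <- data.frame(patient = sprintf("P%02d", 1:n),
                       stratum = c(rep("Grey", 8), "Red", "Red"),
                       sex = c(rep("M", 8), "F", "F"))
  b <- pairedBattery(mt, groups)
  red <- b[b$comparison == "pre_vs_post|Red", ]
  expect_true(all(grepl("skipped", red$note)))
  expect_true(all(is.na(red$p)))
  kwa <- b[b$test == "KWA", ]
  expect_true(all(grepl("skipped", kwa$note)))  # a stratum has n < 3
})

test_that("Kruskal-Wallis across identical strata is non-significant", {
  set.seed(35)
  n <- 15
  vals <- rep(rlnorm(5, log(8), 0.3), 3)        # three identical groups
  pre <- matrix(vals, 1, n, dimnames = list("m1", sprintf("P%02d", 1:n)))
  post <- pre * matrix(rep(c(1.1, 1.1, 1.1), each = 5), 1, n)
  mt <- make_metab(pre, post)
  groups <- data.frame(patient = sprintf("P%02d", 1:n),
                       stratum = rep(c("Grey", "Red", "Green"), each = 5))
  b <- pairedBattery(mt, groups)
  kwa_pre <- b[b$comparison == "strata|pre" & b$test == "KWA", ]
  expect_gt(kwa_pre$p, 0.9)
})

test_that("between-group rank tests are invariant under strictly monotone transforms", {
  # MWU, KWA and Spearman depend on value ranks only; the signed-rank
  # test ranks |paired differences| and is deliberately excluded
  set.seed(36)
  n <- 18
  pre <- matrix(rlnorm(2 * n, log(10), 0.3), 2, n,
                dimnames = list(c("a", "b"), sprintf("P%02d", 1:n)))
  post <- pre * rlnorm(2 * n, log(0.8), 0.15)
  groups <- data.frame(patient = sprintf("P%02d", 1:n),
                       sex = rep(c("M", "F"), each = 9),
                       stratum = rep(c("Grey", "Red", "Green"), 6))
  b1 <- pairedBattery(make_metab(pre, post), groups)
  b2 <- pairedBattery(make_metab(pre^3, post^3), groups)
  keep <- b1$test %in% c("MWU", "KWA")
  expect_true(any(keep))
  expect_equal(b1$p[keep], b2$p[keep], tolerance = 1e-12)
})

test_that("response correlation recovers an identical delta and filters by |R| and p", {
  n <- 12
  pats <- sprintf("P%02d", 1:n)
  pre <- matrix(10, 1, n, dimnames = list("m1", pats))
  delta <- seq(0.5, 6, length.out = n)
  post <- pre - matrix(delta, 1)
  mt <- make_metab(pre, post)
  clin <- data.frame(patient = pats, sex = "M",
                     cT = "3", yT = as.character(rep(0:2, 4)),
                     cN = "1", yN = "0",
                     pre_volume = 100, post_volume = 100 - delta * 10,
                     stringsAsFactors = FALSE)
  cr <- correlateResponse(mt, clin, min_n = 5)
  row <- cr[cr$split == "All" & cr$response == "regression_pct", ]
  expect_equal(row$R, 1, tolerance = 1e-12)     # delta == response rank-wise
  expect_true(row$retained)
  # constant response vectors are skipped
  expect_false(any(cr$response == "cN-yN"))
})

test_that("null deltas are retained at about the filtered false-positive rate", {
  set.seed(37)
  n <- 50
  hits <- replicate(400, {
    r <- suppressWarnings(cor.test(rnorm(n), rnorm(n),
                                   method = "spearman", exact = FALSE))
    r$p.value < 0.05 && abs(r$estimate) > 0.3
  })
  # analytic rate: P(|rho| > 0.3) ~ 2 * pnorm(-0.3 * sqrt(n - 1)) ~ 0.036
  expect_gt(mean(hits), 0.01)
  expect_lt(mean(hits), 0.07)
})
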