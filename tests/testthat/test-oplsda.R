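test_that("with no orthogonal components the fit is exactly textbook PLS1", {
  set.seed(100)
  for (i in 1:10) {
    X <- scale(matrix(rnorm(200), 10, 20), scale = FALSE)
    y <- rep(c(0, 1), each = 5)
    m <- fitOplsda(X, y, n_orth = 0)
    o <- pls1_oracle(X, y - mean(y))
    expect_lt(dev_up_to_sign(scores(m), o$t), 1e-8)
    expect_lt(dev_up_to_sign(m@loadings, o$p), 1e-8)
    expect_lt(dev_up_to_sign(m@weights, o$w), 1e-8)
  }
})

test_that("scores agree with an independent PLS implementation (mixOmics)", {
  skip_if_not_installed("mixOmics")
  set.seed(101)
  X <- scale(matrix(rnorm(300), 15, 20), scale = FALSE)
  y <- rep(c(0, 1), c(7, 8))
  m <- fitOplsda(X, y, n_orth = 0)
  ext <- mixOmics::pls(X, y, ncomp = 1, scale = FALSE, mode = "regression")
  expect_equal(abs(cor(scores(m), ext$variates$X[, 1])), 1,
               tolerance = 1e-8)
})

test_that("a column proportional to the class vector has p(corr) 1", {
  set.seed(5)
  y <- rep(c(0, 1), each = 6)
  yc <- y - mean(y)
  # noise columns residualized against y so the predictive score is
  # exactly proportional to the class contrast
  noise <- matrix(rnorm(12 * 5, sd = 3), 12, 5)
  noise <- noise - yc %*% (crossprod(yc, noise) / sum(yc^2))
  X <- scale(cbind(yc, noise), scale = FALSE)
  m <- fitOplsda(X, y, n_orth = 0)
  expect_equal(abs(as.numeric(m@pcorr[1])), 1, tolerance = 1e-8)
  expect_true(all(abs(m@pcorr) <= 1 + 1e-12))
})

test_that("predictive scores are orthogonal to every orthogonal score", {
  set.seed(6)
  for (i in 1:5) {
    X <- scale(matrix(rnorm(30 * 15), 30, 15), scale = FALSE)
    y <- rep(c(0, 1), each = 15)
    m <- fitOplsda(X, y, n_orth = 3)
    ips <- crossprod(scores(m), orthoScores(m)) /
      sqrt(sum(scores(m)^2))
    expect_true(all(abs(ips) < 1e-8))
    expect_lte(m@R2X + sum(m@R2Xo), 1 + 1e-8)
  }
})

test_that("re-predicting the training data reproduces the training scores", {
  d <- separable_classes()
  m <- fitOplsda(d$X, d$y, n_orth = 2)
  pr <- predict(m, d$X)
  expect_equal(pr$tPS, scores(m), tolerance = 1e-10)
  expect_true(all(pr$class == d$y))
  expect_identical(misclassificationTable(pr$class, d$y)$correct_pct,
                   c(100, 100))
})

test_that("degenerate fits are rejected", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(fitOplsda(X, rep("a", 10)), "two classes")
  expect_error(fitOplsda(X, rep(c("a", "b"), 5), n_orth = 9), "rank")
  m <- fitOplsda(scale(X, scale = FALSE), rep(c("a", "b"), 5), n_orth = 1)
  expect_error(predict(m, X[, 1:3]), "columns")
})

test_that("cross-validated Q2 is high for separable data and near zero for symmetric duplicates", {
  d <- separable_classes()
  expect_gt(crossValidate(d$X, d$y, n_orth = 0)$Q2, 0.9)
  # every row duplicated with the opposite label: no signal by symmetry
  set.seed(9)
  B <- matrix(rnorm(14 * 6), 14, 6)
  X2 <- rbind(B, B)
  y2 <- rep(c("a", "b"), each = 14)
  expect_lte(crossValidate(scale(X2, scale = FALSE), y2, n_orth = 0)$Q2,
             0.05)
})

test_that("Q2 is invariant to swapping the class labels", {
  d <- separable_classes()
  q1 <- crossValidate(d$X, d$y, n_orth = 1)$Q2
  y_swapped <- ifelse(d$y == "a", "b", "a")
  q2 <- crossValidate(d$X, y_swapped, n_orth = 1)$Q2
  expect_equal(q1, q2, tolerance = 1e-12)
})

test_that("Q2 is negative in expectation when labels are independent of X", {
  set.seed(12)
  q <- replicate(30, {
    X <- scale(matrix(rnorm(20 * 10), 20, 10), scale = FALSE)
    crossValidate(X, rep(c(0, 1), each = 10), n_orth = 0)$Q2
  })
  expect_lt(mean(q), 0)
})

test_that("permutation testing is seeded, reproducible and attains the minimal p on strong data", {
  d <- separable_classes()
  p1 <- permutationTest(d$X, d$y, n_orth = 0, n_perm = 199, seed = 7,
                        statistics = "R2Y")
  p2 <- permutationTest(d$X, d$y, n_orth = 0, n_perm = 199, seed = 7,
                        statistics = "R2Y")
  expect_identical(p1$null$R2Y, p2$null$R2Y)
  expect_equal(p1$p[["R2Y"]], 1 / 200)          # minimum attainable
  p3 <- permutationTest(d$X, d$y, n_orth = 0, n_perm = 99, seed = 8)
  expect_equal(p3$p[["Q2"]], 1 / 100)
  expect_error(permutationTest(d$X, d$y, n_perm = 50, seed = 1), ">= 99")
  expect_error(permutationTest(d$X, d$y, n_perm = 99), "seed")
})

test_that("CV-ANOVA follows the F distribution logic at its extremes", {
  # residuals equal to the total variation: nothing explained, not significant
  y <- rep(c(0, 1), each = 10)
  resid_null <- y - mean(y)
  a <- cvAnova(resid_null, ss = sum(resid_null^2), n_components = 3)
  expect_gte(a$p, 0.3)
  # near-zero cross-validated residuals: overwhelming significance
  b <- cvAnova(rep(1e-9, 20), ss = 5, n_components = 3)
  expect_lt(b$p, 1e-6)
  # exhausted degrees of freedom
  expect_error(cvAnova(rnorm(4), ss = 3, n_components = 3), "degrees")
  # zero-residual flag
  z <- cvAnova(rep(0, 20), ss = 5, n_components = 2)
  expect_true(z$zero_residual)
  expect_lt(z$p, 1e-300)
})

test_that("misclassification table counts per class", {
  expect_identical(
    misclassificationTable(c("x", "x", "y", "y"),
                           c("x", "x", "y", "y"))$correct_pct, c(100, 100))
  expect_identical(
    misclassificationTable(c("y", "x"), c("x", "y"))$correct_pct, c(0, 0))
  t3 <- misclassificationTable(c("x", "x", "x", "y", "y"),
                               c("x", "x", "x", "x", "y"))
  expect_equal(t3$correct_pct[t3$class == "x"], 75)
  expect_error(misclassificationTable(c("z", "x"), c("x", "x")), "absent")
})

test_that("zero-variance variables get p(corr) 0 with a flag", {
  set.seed(13)
  X <- cbind(matrix(rnorm(40), 10, 4), 0)
  y <- rep(c(0, 1), each = 5)
  m <- fitOplsda(X, y, n_orth = 0)
  expect_identical(as.numeric(m@pcorr[5]), 0)
  expect_identical(attr(m@pcorr, "zero_variance"), 5L)
})

test_that("model JSON serialization round-trips the key quantities", {
  d <- separable_classes()
  m <- fitOplsda(d$X, d$y, n_orth = 1)
  f <- withr::local_tempfile(fileext = ".json")
  writeOplsdaJSON(m, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(j$scores, scores(m), tolerance = 1e-12)
  expect_equal(j$diagnostics$R2Y, m@R2Y, tolerance = 1e-12)
  expect_identical(j$classes, m@classes)
})
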