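# Two-class OPLS-DA, NIPALS-style. Orthogonal components (X-variation
# uncorrelated with class membership) are stripped first, then a single
# predictive component is extracted. With a single response the per-
# component extraction is closed-form (one pass), so no iteration or random
# initialization is involved and fits are fully deterministic.

code_classes <- function(y) {
  f <- factor(y)
  if (nlevels(f) != 2)
    stop("OPLS-DA needs exactly two classes; got ", nlevels(f))
  list(y01 = as.numeric(f) - 1, classes = levels(f))
}

#' Fit a two-class OPLS-DA model
#'
#' Classes are coded 0/1 (levels in sort order). For each orthogonal
#' component the current predictive weight \code{w} is computed from the
#' X-y covariance, the loading of the corresponding score is split into
#' its y-orthogonal part, and X is deflated; the final predictive
#' component is extracted from the deflated matrix. With \code{n_orth = 0}
#' the model is exactly single-component PLS1.
#'
#' @param X numeric matrix, samples in rows. Expected centered/scaled by
#'   the caller (e.g. \code{\link{paretoScale}}) unless
#'   \code{scale = "pareto"}, in which case scaling is done internally and
#'   remembered for prediction.
#' @param y two-class vector (factor, character or 0/1).
#' @param n_orth number of orthogonal components (>= 0; the serum model
#'   uses 2).
#' @param scale \code{"none"} or \code{"pareto"}.
#' @return an \code{\linkS4class{OplsdaModel}}.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200), 10, 20)
#' y <- rep(c("a", "b"), each = 5)
#' X[y == "b", 1:3] <- X[y == "b", 1:3] + 2
#' fitOplsda(scale(X, scale = FALSE), y, n_orth = 1)
#' @export
fitOplsda <- function(X, y, n_orth = 2, scale = c("none", "pareto")) {
  scale <- match.arg(scale)
  X <- as.matrix(X)
  cc <- code_classes(y)
  if (nrow(X) != length(cc$y01)) stop("X rows must match length(y)")
  if (n_orth < 0) stop("n_orth must be nonnegative")
  if (n_orth + 1 > min(nrow(X) - 1, ncol(X)))
    stop("n_orth + 1 exceeds the maximal possible rank of X")
  scaling <- list()
  if (scale == "pareto") {
    Xs <- paretoScale(X)
    scaling <- list(center = attr(Xs, "center"), scale = attr(Xs, "scale"))
    attributes(Xs)[c("center", "scale")] <- NULL
  } else Xs <- X

  yc <- cc$y01 - mean(cc$y01)
  ssy <- sum(yc^2)
  if (ssy == 0) stop("class vector has no variation")
  ssx <- sum(Xs^2)
  p_var <- ncol(Xs)

  E <- Xs
  Wo <- matrix(0, p_var, 0)
  Po <- matrix(0, p_var, 0)
  To <- matrix(0, nrow(Xs), 0)
  r2xo <- numeric(0)
  for (k in seq_len(n_orth)) {
    w <- crossprod(E, yc) / ssy
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) stop("no class-correlated variation left in X")
    w <- w / wn
    tt <- E %*% w
    p <- crossprod(E, tt) / sum(tt^2)
    wo <- p - as.numeric(crossprod(w, p)) * w
    won <- sqrt(sum(wo^2))
    if (won < 1e-10 * sqrt(sum(p^2)))
      stop("orthogonal variation exhausted after ", k - 1,
           " component(s); lower n_orth")
    wo <- wo / won
    to <- E %*% wo
    po <- crossprod(E, to) / sum(to^2)
    E <- E - to %*% t(po)
    Wo <- cbind(Wo, w = wo)
    Po <- cbind(Po, p = po)
    To <- cbind(To, t = to)
    r2xo <- c(r2xo, sum(to^2) * sum(po^2) / ssx)
  }
  w <- crossprod(E, yc) / ssy
  wn <- sqrt(sum(w^2))
  if (wn < 1e-12) stop("no class-correlated variation left in X")
  w <- as.numeric(w / wn)
  t1 <- as.numeric(E %*% w)
  p1 <- as.numeric(crossprod(E, t1) / sum(t1^2))
  c1 <- sum(yc * t1) / sum(t1^2)

  yhat <- mean(cc$y01) + t1 * c1
  r2y <- 1 - sum((cc$y01 - yhat)^2) / ssy
  r2x <- sum(t1^2) * sum(p1^2) / ssx

  pc <- suppressWarnings(as.numeric(cor(Xs, t1)))
  zerovar <- is.na(pc)
  pc[zerovar] <- 0
  mod <- new("OplsdaModel",
             weights = w, loadings = p1, scores = t1, yloading = c1,
             orthoWeights = Wo, orthoLoadings = Po, orthoScores = To,
             yMean = mean(cc$y01), classes = cc$classes,
             R2X = r2x, R2Xo = r2xo, R2Y = r2y,
             pcorr = pc, scaling = scaling)
  attr(mod@pcorr, "zero_variance") <- which(zerovar)
  validObject(mod)
  mod
}

#' Predict new samples with a fitted OPLS-DA model
#'
#' New rows are scaled with the stored training scaling (if any), filtered
#' through the orthogonal components, then projected onto the predictive
#' weight, giving the predicted score tPS. Class calls use the 0.5
#' threshold on the predicted 0/1 response. Re-predicting the training
#' matrix reproduces the training scores.
#'
#' @param object an \code{\linkS4class{OplsdaModel}}.
#' @param newdata matrix with the training column count/order.
#' @return data.frame with \code{tPS}, \code{yhat} and \code{class}.
#' @export
setMethod("predict", "OplsdaModel", function(object, newdata) {
  En <- as.matrix(newdata)
  if (ncol(En) != length(object@weights))
    stop("newdata has ", ncol(En), " columns; model expects ",
         length(object@weights))
  if (length(object@scaling))
    En <- applyScaling(En, object@scaling$center, object@scaling$scale)
  for (k in seq_len(ncol(object@orthoWeights))) {
    to <- En %*% object@orthoWeights[, k]
    En <- En - to %*% t(object@orthoLoadings[, k])
  }
  tps <- as.numeric(En %*% object@weights)
  yhat <- object@yMean + tps * object@yloading
  data.frame(tPS = tps, yhat = yhat,
             class = object@classes[1 + (yhat >= 0.5)],
             row.names = rownames(newdata))
})

make_folds <- function(n, y01, n_folds) {
  fold <- ((seq_len(n) - 1) %% n_folds) + 1
  ok <- vapply(seq_len(n_folds), function(f)
    length(unique(y01[fold != f])) == 2, logical(1))
  if (!all(ok)) {
    # stratified reassignment: interleave within each class
    message("fold lost a class; reassigning folds stratified by class")
    fold <- integer(n)
    for (cl in unique(y01)) {
      idx <- which(y01 == cl)
      fold[idx] <- ((seq_along(idx) - 1) %% n_folds) + 1
    }
  }
  fold
}

#' Cross-validated predictive ability (Q2)
#'
#' Deterministic n-fold cross-validation with interleaved fold assignment
#' in row order (rows are assumed ordered by sample id); folds that would
#' lose a class are reassigned stratified by class. Q2 = 1 - PRESS/SS with
#' SS the corrected sum of squares of the 0/1 response. When
#' \code{scale = "pareto"} the scaling is re-estimated inside every
#' training split.
#'
#' @inheritParams fitOplsda
#' @param n_folds number of folds (default 7).
#' @return list with \code{Q2}, \code{press}, \code{ss}, per-sample
#'   cross-validated predictions (\code{yhat_cv}) and residuals, and the
#'   fold assignment.
#' @export
crossValidate <- function(X, y, n_orth = 2, n_folds = 7,
                          scale = c("none", "pareto")) {
  scale <- match.arg(scale)
  X <- as.matrix(X)
  cc <- code_classes(y)
  n <- nrow(X)
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (n_folds > n) stop("more folds than samples")
  fold <- make_folds(n, cc$y01, n_folds)
  yhat_cv <- numeric(n)
  for (f in sort(unique(fold))) {
    tr <- fold != f
    # a fold with no class-correlated variation left (degenerate PLS
    # solution) predicts the training mean
    yhat_cv[!tr] <- tryCatch(
      predict(fitOplsda(X[tr, , drop = FALSE], cc$y01[tr],
                        n_orth = n_orth, scale = scale),
              X[!tr, , drop = FALSE])$yhat,
      error = function(e) {
        if (!grepl("class-correlated", conditionMessage(e))) stop(e)
        mean(cc$y01[tr])
      })
  }
  ss <- sum((cc$y01 - mean(cc$y01))^2)
  press <- sum((cc$y01 - yhat_cv)^2)
  list(Q2 = 1 - press / ss, press = press, ss = ss,
       yhat_cv = yhat_cv, residuals = cc$y01 - yhat_cv, folds = fold,
       n_components = n_orth + 1)
}

#' Permutation test of OPLS-DA model statistics
#'
#' Refits the model under \code{n_perm} random permutations of the class
#' labels and reports empirical p-values
#' \eqn{p = (1 + \#\{stat_{perm} \ge stat_{obs}\}) / (n_{perm} + 1)}
#' for R2Y and (optionally) Q2. Reproducible for a fixed seed.
#'
#' @inheritParams crossValidate
#' @param n_perm number of permutations (>= 99; the model default is 999).
#' @param seed integer seed (mandatory).
#' @param statistics which statistics to permute; dropping \code{"Q2"}
#'   skips the per-permutation cross-validation.
#' @return list with the observed statistics, the null data.frame and the
#'   empirical p-values.
#' @export
permutationTest <- function(X, y, n_orth = 2, n_perm = 999, seed,
                            n_folds = 7, statistics = c("R2Y", "Q2"),
                            scale = c("none", "pareto")) {
  scale <- match.arg(scale)
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (n_perm < 99) stop("n_perm must be >= 99")
  statistics <- match.arg(statistics, several.ok = TRUE)
  X <- as.matrix(X)
  cc <- code_classes(y)
  do_q2 <- "Q2" %in% statistics
  obs_r2y <- fitOplsda(X, cc$y01, n_orth = n_orth, scale = scale)@R2Y
  obs_q2 <- if (do_q2)
    crossValidate(X, cc$y01, n_orth = n_orth, n_folds = n_folds,
                  scale = scale)$Q2 else NA_real_
  null_r2y <- numeric(n_perm)
  null_q2 <- rep(NA_real_, n_perm)
  with_local_seed(seed, {
    for (b in seq_len(n_perm)) {
      yp <- sample(cc$y01)
      null_r2y[b] <- fitOplsda(X, yp, n_orth = n_orth, scale = scale)@R2Y
      if (do_q2)
        null_q2[b] <- crossValidate(X, yp, n_orth = n_orth,
                                    n_folds = n_folds, scale = scale)$Q2
    }
  })
  list(observed = c(R2Y = obs_r2y, Q2 = obs_q2),
       null = data.frame(R2Y = null_r2y, Q2 = null_q2),
       p = c(R2Y = (1 + sum(null_r2y >= obs_r2y)) / (n_perm + 1),
             Q2 = if (do_q2)
               (1 + sum(null_q2 >= obs_q2)) / (n_perm + 1) else NA_real_),
       n_perm = n_perm, seed = seed)
}

#' CV-ANOVA significance of a cross-validated model
#'
#' F-test comparing the variation explained in cross-validation
#' (SS - PRESS, with one degree of freedom per model component) against
#' the cross-validated residual variation (PRESS, with the remaining
#' degrees of freedom), in the style of the CV-ANOVA diagnostic used for
#' PLS/OPLS models.
#'
#' @param cv result of \code{\link{crossValidate}}, or a numeric vector of
#'   cross-validated residuals (then \code{ss} and \code{n_components}
#'   are required).
#' @param ss corrected total sum of squares of the response.
#' @param n_components model components counted against the degrees of
#'   freedom (predictive + orthogonal).
#' @return list with \code{F}, \code{df1}, \code{df2}, \code{p} and a
#'   \code{zero_residual} flag (p reported at the machine floor when the
#'   cross-validated residuals vanish).
#' @export
cvAnova <- function(cv, ss = NULL, n_components = NULL) {
  if (is.list(cv)) {
    resid <- cv$residuals
    ss <- cv$ss
    n_components <- cv$n_components
  } else resid <- cv
  if (is.null(ss) || is.null(n_components))
    stop("ss and n_components are required with raw residuals")
  n <- length(resid)
  df1 <- n_components
  df2 <- n - 1 - n_components
  if (df2 <= 0)
    stop("not enough samples for ", n_components,
         " components (degrees of freedom exhausted)")
  press <- sum(resid^2)
  if (press <= .Machine$double.eps * ss) {
    return(list(F = Inf, df1 = df1, df2 = df2, p = .Machine$double.xmin,
                zero_residual = TRUE))
  }
  f <- ((ss - press) / df1) / (press / df2)
  list(F = f, df1 = df1, df2 = df2,
       p = pf(f, df1, df2, lower.tail = FALSE), zero_residual = FALSE)
}

#' Misclassification table
#'
#' Per-class member counts and percent correctly classified.
#'
#' @param predicted,truth equal-length class vectors; predicted labels
#'   must all occur among the true labels' levels.
#' @return data.frame with columns \code{class}, \code{members},
#'   \code{correct} and \code{correct_pct}.
#' @examples
#' misclassificationTable(c("pre", "pre", "post"), c("pre", "post", "post"))
#' @export
misclassificationTable <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  lev <- sort(unique(as.character(truth)))
  if (!all(as.character(predicted) %in% lev))
    stop("predicted contains labels absent from truth: ",
         paste(setdiff(unique(as.character(predicted)), lev),
               collapse = ", "))
  out <- do.call(rbind, lapply(lev, function(cl) {
    in_cl <- as.character(truth) == cl
    ok <- sum(as.character(predicted)[in_cl] == cl)
    data.frame(class = cl, members = sum(in_cl), correct = ok,
               correct_pct = 100 * ok / sum(in_cl))
  }))
  rownames(out) <- NULL
  out
}

#' S-line data for a fitted model
#'
#' Per-variable covariance with the predictive score (the loading-like
#' profile plotted against ppm) colored by p(corr), the basis of the
#' s-line biomarker display.
#'
#' @param model an \code{\linkS4class{OplsdaModel}}.
#' @param ppm optional per-variable ppm values (e.g.
#'   \code{bucketPPM(table)}).
#' @return data.frame with \code{ppm} (or variable index), \code{cov}
#'   and \code{pcorr}.
#' @export
sLineData <- function(model, ppm = NULL) {
  stopifnot(is(model, "OplsdaModel"))
  covv <- model@loadings * sum(model@scores^2) /
    (length(model@scores) - 1)
  if (is.null(ppm)) ppm <- seq_along(covv)
  data.frame(ppm = ppm, cov = covv, pcorr = as.numeric(model@pcorr))
}

#' Serialize a fitted model to JSON
#'
#' Writes weights, loadings, scores, orthogonal components, class coding
#' and diagnostics to a documented JSON object readable with
#' \code{jsonlite}.
#'
#' @param model an \code{\linkS4class{OplsdaModel}}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeOplsdaJSON <- function(model, path) {
  stopifnot(is(model, "OplsdaModel"))
  obj <- list(
    format = "nmrResponse-oplsda-1",
    classes = model@classes, y_mean = model@yMean,
    weights = model@weights, loadings = model@loadings,
    scores = model@scores, y_loading = model@yloading,
    ortho_weights = model@orthoWeights, ortho_loadings = model@orthoLoadings,
    ortho_scores = model@orthoScores,
    diagnostics = as.list(diagnostics(model)),
    pcorr = as.numeric(model@pcorr),
    scaling = model@scaling)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
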