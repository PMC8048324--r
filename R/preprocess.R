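# Spectral post-processing: alanine referencing, fixed-width bucketing over
# 9.0-0.5 ppm, water-region exclusion, Pareto scaling. No normalization is
# applied at any point between bucketing and scaling.

#' Bucket grid definition
#'
#' Fixed-width bucket (bin) grid over a ppm interval. Buckets are half-open
#' descending intervals anchored at the upper bound: bucket \eqn{i} covers
#' \eqn{(upper - iw,\; upper - (i-1)w]}, so the upper edge of each bucket is
#' included and the grid tiles \eqn{(lower, upper]} without overlap. The
#' bucket count is \code{floor((upper - lower)/width)}.
#'
#' @param upper,lower grid bounds in ppm (defaults 9.0 and 0.5).
#' @param width bucket width in ppm (default 0.002).
#' @param exclude list of \code{c(low, high)} ppm exclusion windows.
#' @return list of class \code{"BucketGrid"} with \code{n_buckets} and the
#'   descending bucket-center vector \code{centers}.
#' @examples
#' g <- bucketGrid()
#' g$n_buckets  # 4250
#' @export
bucketGrid <- function(upper = 9.0, lower = 0.5, width = 0.002,
                       exclude = list()) {
  if (width <= 0) stop("bucket width must be positive")
  if (upper <= lower) stop("upper bound must exceed lower bound")
  for (w in exclude)
    if (w[1] < lower - 1e-12 || w[2] > upper + 1e-12)
      stop("exclusion window outside the grid")
  n <- floor((upper - lower) / width)
  structure(list(upper = upper, lower = lower, width = width,
                 exclude = exclude, n_buckets = n,
                 centers = upper - width * (seq_len(n) - 0.5)),
            class = "BucketGrid")
}

#' Reference a spectrum to the alanine methyl doublet
#'
#' Detects the alanine CH3 doublet inside \code{window} and shifts the ppm
#' axis so the doublet center sits at \code{target} ppm; intensities are
#' unchanged. The detector smooths the window (5-point moving average),
#' collects local maxima above a prominence threshold, and takes the
#' best pair of maxima with a doublet-like separation (7 Hz at 400 MHz,
#' accepted range 0.008-0.030 ppm) and similar line heights (ratio <= 2).
#' If no such pair exists the spectrum is returned unshifted with
#' \code{flags$ref_failed = TRUE} and a warning.
#'
#' @param spectrum an \code{\linkS4class{NMRSpectrum}}.
#' @param window search interval in ppm.
#' @param target ppm value the doublet center is moved to.
#' @param prominence absolute intensity threshold for peak candidates;
#'   default \code{median + 5 * mad} of the smoothed window.
#' @return the referenced spectrum; \code{flags$ref_shift} records the
#'   applied shift.
#' @export
referenceToAlanine <- function(spectrum, window = c(1.3, 1.7),
                               target = 1.50, prominence = NULL) {
  stopifnot(is(spectrum, "NMRSpectrum"))
  in_win <- spectrum@ppm >= window[1] & spectrum@ppm <= window[2]
  fail <- function() {
    warning("alanine doublet not detected in [", window[1], ", ", window[2],
            "] ppm; spectrum passed through unshifted")
    spectrum@flags$ref_failed <- TRUE
    spectrum@flags$ref_shift <- 0
    spectrum
  }
  if (sum(in_win) < 7) return(fail())
  x <- spectrum@ppm[in_win]
  y <- spectrum@intensity[in_win]
  s <- as.numeric(stats::filter(y, rep(1 / 5, 5), sides = 2))
  s[is.na(s)] <- y[is.na(s)]
  if (is.null(prominence))
    prominence <- median(s) + 5 * stats::mad(s)
  n <- length(s)
  is_max <- c(FALSE, s[2:(n - 1)] > s[1:(n - 2)] &
                s[2:(n - 1)] >= s[3:n], FALSE) & s > prominence
  cand <- which(is_max)
  if (length(cand) < 2) return(fail())
  if (length(cand) > 12) cand <- cand[order(s[cand], decreasing = TRUE)[1:12]]
  best <- NULL
  best_h <- -Inf
  for (a in seq_along(cand))
    for (b in seq_along(cand))
      if (a < b) {
        i <- cand[a]; j <- cand[b]
        sep <- abs(x[i] - x[j])
        if (sep < 0.008 || sep > 0.030) next
        hr <- max(s[i], s[j]) / min(s[i], s[j])
        if (hr > 2) next
        h <- min(s[i], s[j])
        if (h > best_h) { best_h <- h; best <- c(i, j) }
      }
  if (is.null(best)) return(fail())
  center <- mean(x[best])
  shift <- target - center
  spectrum@ppm <- spectrum@ppm + shift
  spectrum@flags$ref_failed <- FALSE
  spectrum@flags$ref_shift <- shift
  spectrum
}

#' Bucket a spectrum
#'
#' Each bucket value is the plain sum of the intensities of the points
#' whose ppm falls in the bucket's half-open interval (see
#' \code{\link{bucketGrid}} for the edge convention). Bucketing conserves
#' total intensity over the grid span.
#'
#' @param spectrum an \code{\linkS4class{NMRSpectrum}} whose ppm range
#'   covers the grid.
#' @param grid a \code{\link{bucketGrid}}.
#' @return named numeric vector of bucket sums (names: center ppm,
#'   descending).
#' @export
bucketSpectrum <- function(spectrum, grid = bucketGrid()) {
  stopifnot(is(spectrum, "NMRSpectrum"), inherits(grid, "BucketGrid"))
  p <- spectrum@ppm
  if (max(p) < grid$upper - 1e-9 || min(p) > grid$lower + 1e-9)
    stop("spectrum ppm range [", format(min(p)), ", ", format(max(p)),
         "] does not cover the grid [", grid$lower, ", ", grid$upper, "]")
  idx <- floor((grid$upper - p) / grid$width + 1e-9) + 1
  keep <- p <= grid$upper + 1e-12 & idx >= 1 & idx <= grid$n_buckets
  v <- numeric(grid$n_buckets)
  sums <- tapply(spectrum@intensity[keep], idx[keep], sum)
  v[as.integer(names(sums))] <- as.numeric(sums)
  names(v) <- format(grid$centers, trim = TRUE)
  v
}

#' Build a bucket table from a set of spectra
#'
#' Buckets every spectrum on a common grid and assembles a
#' \code{\linkS4class{BucketTable}} (buckets as rows, samples as columns),
#' with sample annotation taken from the spectra. All buckets start
#' retained; apply \code{\link{excludeWater}} afterwards.
#'
#' @param spectra list of \code{\linkS4class{NMRSpectrum}} (single channel).
#' @param grid a \code{\link{bucketGrid}}.
#' @return a \code{\linkS4class{BucketTable}}.
#' @export
buildBucketTable <- function(spectra, grid = bucketGrid()) {
  stopifnot(length(spectra) >= 1)
  m <- vapply(spectra, bucketSpectrum, numeric(grid$n_buckets), grid = grid)
  sids <- vapply(spectra, function(s) s@sampleID, character(1))
  sids[is.na(sids)] <- paste0("S", which(is.na(sids)))
  cd <- S4Vectors::DataFrame(
    sampleID = sids,
    patientID = vapply(spectra, function(s) s@patientID, character(1)),
    timepoint = vapply(spectra, function(s) s@timepoint, character(1)),
    channel = vapply(spectra, function(s) s@channel, character(1)))
  colnames(m) <- cd$sampleID
  rownames(cd) <- cd$sampleID
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = m),
    rowData = S4Vectors::DataFrame(ppm = grid$centers,
                                   retained = rep(TRUE, grid$n_buckets)),
    colData = cd,
    metadata = list(grid = grid))
  new("BucketTable", se)
}

#' Mask the water region of a bucket table
#'
#' Marks every bucket whose center ppm lies inside the closed window as
#' not retained. The default window is the residual-water region
#' 4.38-5.15 ppm (width 0.77 ppm). Exclusion is by bucket center, not
#' interval overlap.
#'
#' @param table a \code{\linkS4class{BucketTable}}.
#' @param window \code{c(low, high)} ppm.
#' @return the table with an updated retention mask.
#' @examples
#' # on the default 4250-bucket grid the window removes 385 buckets
#' @export
excludeWater <- function(table, window = WATER_WINDOW) {
  stopifnot(is(table, "BucketTable"), length(window) == 2,
            window[1] <= window[2])
  rd <- SummarizedExperiment::rowData(table)
  hit <- rd$ppm >= window[1] & rd$ppm <= window[2]
  rd$retained <- rd$retained & !hit
  SummarizedExperiment::rowData(table) <- rd
  md <- S4Vectors::metadata(table)
  md$grid$exclude <- c(md$grid$exclude, list(window))
  S4Vectors::metadata(table) <- md
  validObject(table)
  table
}

#' Pareto scaling
#'
#' Mean-centers each column and divides it by the square root of its
#' sample standard deviation (n - 1 denominator), the usual compromise
#' between no scaling and unit-variance scaling for spectral data.
#' Zero-variance columns are set to zero after centering.
#'
#' @param x numeric matrix, samples in rows (>= 2 rows).
#' @return the scaled matrix, with attributes \code{"center"} and
#'   \code{"scale"} (the per-column mean and sqrt-SD used).
#' @examples
#' paretoScale(matrix(c(1, 5, 3, 3, 3, 3), ncol = 2))
#' @export
paretoScale <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2)
    stop("Pareto scaling needs at least 2 rows (no variance definable)")
  ctr <- colMeans(x)
  s <- apply(x, 2, sd)
  sc <- sqrt(s)
  xc <- sweep(x, 2, ctr)
  out <- sweep(xc, 2, ifelse(sc > 0, sc, 1), "/")
  out[, sc == 0] <- 0
  attr(out, "center") <- ctr
  attr(out, "scale") <- sc
  out
}

#' Apply a previously computed Pareto scaling
#'
#' Scales new samples with the training center/scale (as stored by
#' \code{\link{paretoScale}} or inside a fitted model), the operation
#' needed before predicting an external test set.
#'
#' @param x new-sample matrix (samples in rows).
#' @param center,scale training column means and sqrt-SDs.
#' @return scaled matrix.
#' @export
applyScaling <- function(x, center, scale) {
  x <- as.matrix(x)
  if (ncol(x) != length(center)) stop("column count mismatch")
  out <- sweep(sweep(x, 2, center), 2, ifelse(scale > 0, scale, 1), "/")
  out[, scale == 0] <- 0
  out
}
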