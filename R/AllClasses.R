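#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
#'   colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats cor cor.test kruskal.test median pf quantile rnorm runif
#'   sd setNames wilcox.test rbinom rlnorm var predict
#' @importFrom utils read.csv write.csv read.table
NULL

#' One-dimensional NMR spectrum
#'
#' Container for a single 1D \eqn{^1}H NMR trace: a strictly descending ppm
#' axis, matching intensities, the acquisition channel the trace emulates
#' (\code{"CPMG"} for small-metabolite spectra, \code{"DIFF"} for
#' diffusion-edited lipid spectra), and sample/patient/timepoint identifiers.
#' The \code{flags} list carries processing provenance such as the chemical
#' shift applied during referencing.
#'
#' @slot ppm numeric, strictly decreasing chemical-shift axis (ppm).
#' @slot intensity numeric, same length as \code{ppm}.
#' @slot channel character, \code{"CPMG"} or \code{"DIFF"}.
#' @slot sampleID,patientID character scalars.
#' @slot timepoint character, \code{"pre"} or \code{"post"}.
#' @slot flags list of processing flags.
#'
#' @exportClass NMRSpectrum
setClass("NMRSpectrum",
  representation(
    ppm = "numeric",
    intensity = "numeric",
    channel = "character",
    sampleID = "character",
    patientID = "character",
    timepoint = "character",
    flags = "list"
  ),
  prototype(channel = "CPMG", sampleID = NA_character_,
            patientID = NA_character_, timepoint = NA_character_,
            flags = list())
)

setValidity("NMRSpectrum", function(object) {
  msg <- character()
  if (length(object@ppm) != length(object@intensity))
    msg <- c(msg, "ppm and intensity must have the same length")
  if (length(object@ppm) >= 2 && any(diff(object@ppm) >= 0))
    msg <- c(msg, "ppm axis must be strictly decreasing")
  if (!object@channel %in% c("CPMG", "DIFF"))
    msg <- c(msg, "channel must be 'CPMG' or 'DIFF'")
  if (length(msg)) msg else TRUE
})

#' Construct an NMRSpectrum
#'
#' @param ppm numeric chemical-shift axis. Accepted ascending or descending;
#'   stored descending (the plotting convention for NMR).
#' @param intensity numeric intensities, one per ppm point.
#' @param channel \code{"CPMG"} or \code{"DIFF"}.
#' @param sampleID,patientID,timepoint sample annotation.
#' @param flags list of processing flags.
#' @return An \code{\linkS4class{NMRSpectrum}}.
#' @examples
#' sp <- NMRSpectrum(seq(9, 0.5, length.out = 100), rnorm(100))
#' sp
#' @export
NMRSpectrum <- function(ppm, intensity, channel = "CPMG",
                        sampleID = NA_character_, patientID = NA_character_,
                        timepoint = NA_character_, flags = list()) {
  ppm <- as.numeric(ppm)
  intensity <- as.numeric(intensity)
  if (length(ppm) >= 2) {
    d <- diff(ppm)
    if (all(d > 0)) {          # ascending input: flip
      ppm <- rev(ppm)
      intensity <- rev(intensity)
    } else if (!all(d < 0)) {
      stop("ppm axis must be strictly monotone")
    }
  }
  new("NMRSpectrum", ppm = ppm, intensity = intensity, channel = channel,
      sampleID = as.character(sampleID), patientID = as.character(patientID),
      timepoint = as.character(timepoint), flags = flags)
}

setMethod("show", "NMRSpectrum", function(object) {
  rng <- if (length(object@ppm)) range(object@ppm) else c(NA, NA)
  cat("NMRSpectrum [", object@channel, "] ",
      length(object@ppm), " points, ",
      format(rng[2], digits = 4), "-", format(rng[1], digits = 4), " ppm\n",
      sep = "")
  cat("  sample: ", object@sampleID, "  patient: ", object@patientID,
      "  timepoint: ", object@timepoint, "\n", sep = "")
  if (length(object@flags))
    cat("  flags: ", paste(names(object@flags), collapse = ", "), "\n",
        sep = "")
})

#' Bucketed spectral intensity table
#'
#' A \code{SummarizedExperiment} subclass holding a samples-by-buckets
#' intensity matrix (buckets as rows, following the Bioconductor
#' features-in-rows convention). \code{rowData} carries the bucket-center
#' ppm values (descending) and the logical \code{retained} mask set by
#' \code{\link{excludeWater}}; the generating \code{\link{bucketGrid}} is
#' stored in \code{metadata(x)$grid}.
#'
#' @seealso \code{\link{buildBucketTable}}, \code{\link{excludeWater}},
#'   \code{\link{bucketMatrix}}
#' @exportClass BucketTable
setClass("BucketTable", contains = "SummarizedExperiment")

setValidity("BucketTable", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  msg <- character()
  if (!all(c("ppm", "retained") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'ppm' and 'retained'")
  else {
    if (is.unsorted(rev(rd$ppm), strictly = TRUE))
      msg <- c(msg, "bucket centers must be strictly decreasing")
    grid <- S4Vectors::metadata(object)$grid
    if (!is.null(grid)) {
      win <- grid$exclude
      if (length(win) && any(vapply(win, function(w)
        any(rd$ppm[rd$retained] >= w[1] & rd$ppm[rd$retained] <= w[2]),
        logical(1))))
        msg <- c(msg, "retained bucket centers inside an exclusion window")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Panel-metabolite integral table
#'
#' A \code{SummarizedExperiment} subclass with one row per panel metabolite
#' (rowData: name, center ppm, region half-width, source channel) and one
#' column per sample, holding the "sum all points in region" integrals.
#'
#' @seealso \code{\link{quantifyPanel}}
#' @exportClass MetaboliteTable
setClass("MetaboliteTable", contains = "SummarizedExperiment")

#' Fitted OPLS-DA model
#'
#' Two-class orthogonal projections to latent structures discriminant
#' analysis. One predictive component (weights \code{w}, loadings \code{p},
#' scores \code{t[1]}, y-loading \code{c}) plus \code{nOrth} orthogonal
#' components capturing X-variation uncorrelated with class membership.
#' Diagnostics follow the usual chemometric definitions: \code{R2X} is the
#' fraction of X-variation carried by the predictive component, \code{R2Xo}
#' the per-orthogonal-component fractions, \code{R2Y} the modeled fraction
#' of class variation and \code{pcorr} the per-variable Pearson correlation
#' with the predictive score.
#'
#' @slot weights,loadings numeric, predictive weight and loading vectors.
#' @slot scores numeric, predictive scores t[1] of the training samples.
#' @slot yloading numeric scalar c.
#' @slot orthoWeights,orthoLoadings,orthoScores matrices, one column per
#'   orthogonal component.
#' @slot yMean numeric, training mean of the 0/1 class vector.
#' @slot classes character(2), the class labels coded 0 and 1.
#' @slot R2X,R2Y numeric scalars; \code{R2Xo} numeric per orthogonal component.
#' @slot pcorr numeric, per-variable p(corr).
#' @slot scaling list, optional Pareto-scaling parameters (center, scale)
#'   applied to X before fitting; empty when the caller scaled X.
#'
#' @exportClass OplsdaModel
setClass("OplsdaModel",
  representation(
    weights = "numeric", loadings = "numeric", scores = "numeric",
    yloading = "numeric",
    orthoWeights = "matrix", orthoLoadings = "matrix", orthoScores = "matrix",
    yMean = "numeric", classes = "character",
    R2X = "numeric", R2Xo = "numeric", R2Y = "numeric",
    pcorr = "numeric", scaling = "list"
  )
)

setValidity("OplsdaModel", function(object) {
  msg <- character()
  if (ncol(object@orthoScores) > 0) {
    ip <- abs(crossprod(object@scores, object@orthoScores)) /
      (sqrt(sum(object@scores^2)) *
         sqrt(colSums(object@orthoScores^2)) + .Machine$double.eps)
    if (any(ip > 1e-6))
      msg <- c(msg, "predictive score not orthogonal to orthogonal scores")
  }
  if (length(object@pcorr) && any(abs(object@pcorr) > 1 + 1e-8,
                                  na.rm = TRUE))
    msg <- c(msg, "p(corr) outside [-1, 1]")
  if (object@R2X + sum(object@R2Xo) > 1 + 1e-8)
    msg <- c(msg, "R2X + sum(R2Xo) exceeds 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "OplsdaModel", function(object) {
  cat("OplsdaModel: 1 predictive + ", ncol(object@orthoScores),
      " orthogonal component(s), ", length(object@weights),
      " variables, ", length(object@scores), " samples\n", sep = "")
  cat(sprintf("  R2X = %.4g  R2Y = %.4g", object@R2X, object@R2Y))
  if (length(object@R2Xo))
    cat("  R2X(o) =", paste(sprintf("%.4g", object@R2Xo), collapse = ", "))
  cat("\n  classes: ", object@classes[1], " (0) vs ", object@classes[2],
      " (1)\n", sep = "")
})
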