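#' Accessors for package classes
#'
#' \code{ppm} and \code{intensity} extract the axes of an
#' \code{\linkS4class{NMRSpectrum}}; \code{bucketPPM} the bucket-center ppm
#' values of a \code{\linkS4class{BucketTable}}; \code{retainedBuckets} its
#' logical retention mask; \code{bucketMatrix} the samples-by-buckets
#' intensity matrix restricted (by default) to retained buckets;
#' \code{scores} and \code{orthoScores} the predictive and orthogonal scores
#' of an \code{\linkS4class{OplsdaModel}}; \code{pCorr} its per-variable
#' correlations with the predictive score; \code{diagnostics} its R2X /
#' R2X(o) / R2Y summary.
#'
#' @param object an object of the documented class.
#' @param retained logical; drop masked (e.g. water-region) buckets.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ppm", function(object) standardGeneric("ppm"))
#' @rdname accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))
#' @rdname accessors
#' @export
setGeneric("bucketPPM", function(object, retained = TRUE)
  standardGeneric("bucketPPM"))
#' @rdname accessors
#' @export
setGeneric("retainedBuckets", function(object)
  standardGeneric("retainedBuckets"))
#' @rdname accessors
#' @export
setGeneric("bucketMatrix", function(object, retained = TRUE)
  standardGeneric("bucketMatrix"))
#' @rdname accessors
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("orthoScores", function(object) standardGeneric("orthoScores"))
#' @rdname accessors
#' @export
setGeneric("pCorr", function(object) standardGeneric("pCorr"))
#' @rdname accessors
#' @export
setGeneric("diagnostics", function(object) standardGeneric("diagnostics"))

#' @rdname accessors
setMethod("ppm", "NMRSpectrum", function(object) object@ppm)
#' @rdname accessors
setMethod("intensity", "NMRSpectrum", function(object) object@intensity)

#' @rdname accessors
setMethod("bucketPPM", "BucketTable", function(object, retained = TRUE) {
  rd <- SummarizedExperiment::rowData(object)
  if (retained) rd$ppm[rd$retained] else rd$ppm
})

#' @rdname accessors
setMethod("retainedBuckets", "BucketTable", function(object)
  SummarizedExperiment::rowData(object)$retained)

#' @rdname accessors
setMethod("bucketMatrix", "BucketTable", function(object, retained = TRUE) {
  m <- t(SummarizedExperiment::assay(object, "intensity"))
  if (retained) m[, retainedBuckets(object), drop = FALSE] else m
})

#' @rdname accessors
setMethod("scores", "OplsdaModel", function(object) object@scores)
#' @rdname accessors
setMethod("orthoScores", "OplsdaModel", function(object) object@orthoScores)
#' @rdname accessors
setMethod("pCorr", "OplsdaModel", function(object) object@pcorr)
#' @rdname accessors
setMethod("diagnostics", "OplsdaModel", function(object)
  c(R2X = object@R2X,
    setNames(object@R2Xo, if (length(object@R2Xo))
      paste0("R2Xo", seq_along(object@R2Xo)) else character()),
    R2Y = object@R2Y))
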