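# Panel-metabolite quantification by the "sum all points in region" rule:
# an integral is the plain sum of spectrum intensities inside a named ppm
# region. Lipid signals come from the diffusion-edited channel, small
# metabolites from the CPMG channel.

#' Integrate a spectral region
#'
#' Sum of the intensities of all points with ppm in the closed interval
#' \code{[low, high]}. A region containing no points is an error, kept
#' distinct from a genuine zero integral.
#'
#' @param spectrum an \code{\linkS4class{NMRSpectrum}}.
#' @param low,high region bounds in ppm, \code{low < high}.
#' @return numeric integral.
#' @examples
#' sp <- NMRSpectrum(seq(9, 0.5, length.out = 100), rep(1, 100))
#' integrateRegion(sp, 2, 3)
#' @export
integrateRegion <- function(spectrum, low, high) {
  stopifnot(is(spectrum, "NMRSpectrum"))
  if (low >= high) stop("need low < high")
  if (low < min(spectrum@ppm) || high > max(spectrum@ppm))
    stop("region [", low, ", ", high, "] outside the spectrum range")
  sel <- spectrum@ppm >= low & spectrum@ppm <= high
  if (!any(sel))
    stop("region [", low, ", ", high, "] contains no spectrum points")
  sum(spectrum@intensity[sel])
}

#' Quantify the metabolite panel for a set of samples
#'
#' For every sample, integrates each panel region (center +/- half-width)
#' on that metabolite's assigned channel. Samples missing a required
#' channel are kept but flagged incomplete (NA integrals for the affected
#' metabolites).
#'
#' @param spectra list of \code{\linkS4class{NMRSpectrum}} covering both
#'   channels; samples are matched by \code{sampleID}.
#' @param panel panel data.frame (see \code{\link{defaultPanel}}); its
#'   regions must not overlap the water window.
#' @param half_width optional override of the per-region integration
#'   half-width (single value or one per panel row).
#' @return a \code{\linkS4class{MetaboliteTable}} (metabolites as rows,
#'   samples as columns) with \code{colData} columns \code{sampleID},
#'   \code{patientID}, \code{timepoint} and \code{incomplete}.
#' @export
quantifyPanel <- function(spectra, panel = defaultPanel(),
                          half_width = NULL) {
  validatePanel(panel)
  if (!is.null(half_width)) {
    panel$half_width <- rep_len(half_width, nrow(panel))
    validatePanel(panel)
  }
  sids <- unique(vapply(spectra, function(s) s@sampleID, character(1)))
  chan <- vapply(spectra, function(s) s@channel, character(1))
  sid_of <- vapply(spectra, function(s) s@sampleID, character(1))

  m <- matrix(NA_real_, nrow = nrow(panel), ncol = length(sids),
              dimnames = list(panel$name, sids))
  incomplete <- setNames(rep(FALSE, length(sids)), sids)
  pat <- tp <- setNames(rep(NA_character_, length(sids)), sids)

  for (sid in sids) {
    mine <- which(sid_of == sid)
    pat[sid] <- spectra[[mine[1]]]@patientID
    tp[sid] <- spectra[[mine[1]]]@timepoint
    for (r in seq_len(nrow(panel))) {
      k <- mine[chan[mine] == panel$channel[r]]
      if (!length(k)) { incomplete[sid] <- TRUE; next }
      m[r, sid] <- integrateRegion(spectra[[k[1]]],
                                   panel$center[r] - panel$half_width[r],
                                   panel$center[r] + panel$half_width[r])
    }
  }
  if (any(incomplete))
    warning(sum(incomplete), " sample(s) missing a channel; ",
            "affected integrals set to NA")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(integral = m),
    rowData = S4Vectors::DataFrame(panel),
    colData = S4Vectors::DataFrame(sampleID = sids, patientID = pat,
                                   timepoint = tp, incomplete = incomplete,
                                   row.names = sids))
  new("MetaboliteTable", se)
}

#' Long-format view of a metabolite table
#'
#' @param x a \code{\linkS4class{MetaboliteTable}}.
#' @return data.frame with columns sampleID, patientID, timepoint,
#'   metabolite (region name) and integral.
#' @export
metaboliteLong <- function(x) {
  stopifnot(is(x, "MetaboliteTable"))
  m <- SummarizedExperiment::assay(x, "integral")
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  out <- data.frame(
    sampleID = rep(cd$sampleID, each = nrow(m)),
    patientID = rep(cd$patientID, each = nrow(m)),
    timepoint = rep(cd$timepoint, each = nrow(m)),
    metabolite = rep(rownames(m), times = ncol(m)),
    integral = as.numeric(m),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
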