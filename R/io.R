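# Spectrum readers/writers: two-column delimited text and a minimal
# JCAMP-DX 1D subset (AFFN, (X++(Y..Y)) form) sufficient for exchanging
# evenly sampled real spectra.

#' Read and write 1D spectra
#'
#' \code{readSpectrum}/\code{writeSpectrum} use two-column delimited text
#' (ppm, intensity; '#' comments allowed). \code{readJCAMP}/\code{writeJCAMP}
#' handle a minimal JCAMP-DX 1D profile: AFFN-encoded
#' \code{##XYDATA=(X++(Y..Y))} with \code{FIRSTX}/\code{LASTX}/
#' \code{NPOINTS}/\code{XFACTOR}/\code{YFACTOR} records and an evenly
#' spaced axis.
#'
#' @param path file path.
#' @param sep field separator for delimited text.
#' @param ... annotation passed to \code{\link{NMRSpectrum}} (channel,
#'   sampleID, patientID, timepoint).
#' @param spectrum an \code{\linkS4class{NMRSpectrum}}.
#' @param title JCAMP \code{##TITLE} record.
#' @return the spectrum (readers) or the path, invisibly (writers).
#' @examples
#' sp <- NMRSpectrum(seq(9, 0.5, length.out = 50), rnorm(50))
#' f <- tempfile(fileext = ".tsv")
#' writeSpectrum(sp, f)
#' sp2 <- readSpectrum(f)
#' all.equal(ppm(sp), ppm(sp2))
#' @name spectrum-io
NULL

#' @rdname spectrum-io
#' @export
readSpectrum <- function(path, sep = "\t", ...) {
  d <- read.table(path, sep = sep, header = FALSE, comment.char = "#",
                  col.names = c("ppm", "intensity"))
  NMRSpectrum(d$ppm, d$intensity, ...)
}

#' @rdname spectrum-io
#' @export
writeSpectrum <- function(spectrum, path, sep = "\t") {
  stopifnot(is(spectrum, "NMRSpectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ppm", sep, "intensity"), con)
  writeLines(paste(format(spectrum@ppm, digits = 12),
                   format(spectrum@intensity, digits = 12), sep = sep), con)
  invisible(path)
}

#' @rdname spectrum-io
#' @export
writeJCAMP <- function(spectrum, path, title = "spectrum") {
  stopifnot(is(spectrum, "NMRSpectrum"))
  x <- spectrum@ppm
  y <- spectrum@intensity
  n <- length(x)
  if (n >= 3) {
    dx <- diff(x)
    if (max(abs(dx - dx[1])) > 1e-6 * abs(dx[1]))
      stop("JCAMP-DX export requires an evenly spaced ppm axis")
  }
  ymax <- max(abs(y), 1e-300)
  yfac <- ymax / 1e7                     # keep mantissas modest in AFFN
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("##TITLE=", title),
    "##JCAMP-DX=5.00",
    "##DATA TYPE=NMR SPECTRUM",
    "##XUNITS=PPM",
    "##YUNITS=ARBITRARY UNITS",
    sprintf("##XFACTOR=%.10g", 1),
    sprintf("##YFACTOR=%.10g", yfac),
    sprintf("##FIRSTX=%.10g", x[1]),
    sprintf("##LASTX=%.10g", x[n]),
    sprintf("##NPOINTS=%d", n),
    sprintf("##FIRSTY=%.10g", y[1]),
    "##XYDATA=(X++(Y..Y))"), con)
  yi <- round(y / yfac)
  idx <- seq(1, n, by = 6)
  for (s in idx) {
    e <- min(s + 5, n)
    writeLines(paste(c(sprintf("%.6f", x[s]),
                       format(yi[s:e], scientific = FALSE, trim = TRUE)),
                     collapse = " "), con)
  }
  writeLines("##END=", con)
  invisible(path)
}

jcamp_field <- function(lines, key) {
  ln <- grep(paste0("^##", key, "="), lines, value = TRUE)
  if (!length(ln)) return(NA_real_)
  as.numeric(sub(paste0("^##", key, "="), "", ln[1]))
}

#' @rdname spectrum-io
#' @export
readJCAMP <- function(path, ...) {
  lines <- readLines(path)
  np <- jcamp_field(lines, "NPOINTS")
  xf <- jcamp_field(lines, "XFACTOR")
  yf <- jcamp_field(lines, "YFACTOR")
  firstx <- jcamp_field(lines, "FIRSTX")
  lastx <- jcamp_field(lines, "LASTX")
  if (is.na(xf)) xf <- 1
  if (is.na(yf)) yf <- 1
  if (anyNA(c(np, firstx, lastx)))
    stop("not a supported JCAMP-DX file: missing NPOINTS/FIRSTX/LASTX")
  start <- grep("^##XYDATA=", lines)
  if (!length(start)) stop("no ##XYDATA record")
  end <- grep("^##END", lines)
  end <- end[end > start[1]][1]
  body <- lines[(start[1] + 1):(end - 1)]
  y <- unlist(lapply(strsplit(trimws(body), "[[:space:]]+"), function(tok)
    as.numeric(tok[-1])))
  if (length(y) != np)
    stop("JCAMP-DX point count mismatch: expected ", np, ", got ",
         length(y))
  x <- seq(firstx * xf, lastx * xf, length.out = np)
  NMRSpectrum(x, y * yf, ...)
}
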