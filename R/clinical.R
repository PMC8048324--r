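# Clinical data model: TNM v7 staging (prefix "c" = pre-treatment, "y" =
# post-induction re-stage), tumor-regression and response formulas, and
# Table-1-style cohort summaries.

#' Numeric component of a TNM stage
#'
#' Sub-stage letters (2a/2b/2c, 4a/4b) map to the same numeric major
#' stage; staging differences are computed on the major stage.
#'
#' @param x stage strings ("0", "2b", "4a", ...).
#' @return integer vector (NA for missing/unparseable input).
#' @examples
#' stageNumber(c("0", "2b", "4a"))
#' @export
stageNumber <- function(x) {
  x <- as.character(x)
  out <- suppressWarnings(as.integer(sub("^([0-9]+).*$", "\\1", x)))
  out[is.na(x) | x == ""] <- NA_integer_
  out
}

#' Percent tumor regression
#'
#' \code{100 - post_volume * 100 / pre_volume}. Values are at most 100
#' (complete response); negative values indicate progression and are
#' flagged via \code{attr(, "progression")}.
#'
#' @param pre_volume pre-treatment tumor volume (> 0, cm^3).
#' @param post_volume post-treatment volume (>= 0, cm^3).
#' @return numeric percent (vectorized).
#' @examples
#' tumorRegressionPct(100, 13)  # 87
#' @export
tumorRegressionPct <- function(pre_volume, post_volume) {
  if (any(pre_volume <= 0, na.rm = TRUE))
    stop("pre-treatment volume must be positive")
  if (any(post_volume < 0, na.rm = TRUE))
    stop("post-treatment volume must be nonnegative")
  out <- 100 - post_volume * 100 / pre_volume
  attr(out, "progression") <- which(!is.na(out) & out < 0)
  out
}

#' Clinical response as stage differences
#'
#' Computes \code{cT - yT} and \code{cN - yN} on the numeric major-stage
#' components. Records missing a post-treatment stage are marked
#' unevaluable (NA difference).
#'
#' @param records data.frame with columns \code{patient}, \code{cT},
#'   \code{yT}, \code{cN}, \code{yN} (and optionally \code{sex}, carried
#'   through).
#' @return the input with added integer columns \code{dT}, \code{dN} and
#'   logical \code{progression} (a negative difference).
#' @export
clinicalResponse <- function(records) {
  need <- c("patient", "cT", "yT", "cN", "yN")
  if (!all(need %in% names(records)))
    stop("records must contain: ", paste(need, collapse = ", "))
  out <- records
  out$dT <- stageNumber(records$cT) - stageNumber(records$yT)
  out$dN <- stageNumber(records$cN) - stageNumber(records$yN)
  out$unevaluable <- is.na(out$dT) | is.na(out$dN)
  out$progression <- !out$unevaluable & (out$dT < 0 | out$dN < 0)
  out
}

round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

derive_tnm <- function(cT, cN) {
  tn <- stageNumber(cT)
  nn <- stageNumber(cN)
  ifelse(nn >= 3, "IVb",
         ifelse(tn >= 4 | nn == 2, "IVa",
                ifelse(tn == 3 | nn == 1, "III", "I-II")))
}

#' Cohort summary
#'
#' Counts and percentages (half-up rounding to one decimal) by primary
#' tumor site, sex and cTNM stage group (III / IVa / IVb plus combined
#' IV), and the age median and range. The stage group is taken from a
#' \code{cTNM} column when present, otherwise derived from cT/cN (N3 ->
#' IVb; T4 or N2 -> IVa; T3 or N1 -> III).
#'
#' @param records clinical data.frame (columns \code{sex}, \code{age},
#'   optionally \code{site}, \code{cT}, \code{cN}, \code{cTNM}).
#' @return list with data.frames \code{site}, \code{sex}, \code{stage}
#'   and the numeric \code{age} summary.
#' @export
cohortSummary <- function(records) {
  if (!nrow(records)) stop("empty cohort")
  n <- nrow(records)
  tab <- function(x) {
    t <- table(x)
    data.frame(level = names(t), n = as.integer(t),
               pct = round_half_up(100 * as.integer(t) / n, 1),
               stringsAsFactors = FALSE)
  }
  stage <- if ("cTNM" %in% names(records)) records$cTNM
           else derive_tnm(records$cT, records$cN)
  stage_tab <- tab(stage)
  n_iv <- sum(stage_tab$n[stage_tab$level %in% c("IVa", "IVb", "IV")])
  stage_tab <- rbind(stage_tab,
                     data.frame(level = "IV (combined)", n = n_iv,
                                pct = round_half_up(100 * n_iv / n, 1)))
  list(
    n = n,
    site = if ("site" %in% names(records)) tab(records$site) else NULL,
    sex = tab(records$sex),
    stage = stage_tab,
    age = c(median = median(records$age), min = min(records$age),
            max = max(records$age)))
}
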