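# Trajectory-based responder stratification on the OPLS-DA score axis and
# the univariate battery (Wilcoxon signed-rank, Mann-Whitney U,
# Kruskal-Wallis, Spearman) with median-ratio effect sizes.

#' Trajectory distance and direction
#'
#' The metabolic-response amplitude of a patient is the distance between
#' the pre- and post-treatment predictive scores; the trajectory is
#' "correct" when it runs from the pre side (negative t[1]) to the post
#' side (positive t[1]), i.e. post > pre.
#'
#' @param pre,post numeric t[1] scores (vectorized).
#' @return data.frame with \code{distance} and logical \code{correct}.
#' @examples
#' trajectoryDistance(c(-2, 1, 2), c(3, 1, -1))
#' @export
trajectoryDistance <- function(pre, post) {
  data.frame(distance = abs(post - pre), correct = post > pre)
}

#' Stratify patients by score-plot mixing
#'
#' Orientation is normalized so the post-treatment class sits at positive
#' t[1] (all scores are negated if the post class mean is negative). A
#' patient is \strong{Red} when their post sample crosses to the negative
#' (pre) side, \strong{Green} when their pre sample crosses to the
#' positive (post) side (and they are not Red; Red takes precedence), and
#' \strong{Grey} (non-mixing) otherwise. Patients missing a timepoint are
#' excluded and reported in \code{attr(, "excluded")}.
#'
#' @param t1 numeric predictive scores, one per sample.
#' @param timepoint \code{"pre"}/\code{"post"} per sample.
#' @param patient patient id per sample.
#' @return data.frame (one row per complete patient): \code{patient},
#'   \code{pre_t1}, \code{post_t1}, \code{distance}, \code{correct},
#'   \code{stratum} (factor Grey/Red/Green).
#' @export
detectMixing <- function(t1, timepoint, patient) {
  stopifnot(length(t1) == length(timepoint),
            length(t1) == length(patient))
  timepoint <- as.character(timepoint)
  if (!all(timepoint %in% c("pre", "post")))
    stop("timepoint must be 'pre' or 'post'")
  if (mean(t1[timepoint == "post"]) < 0) t1 <- -t1   # plot convention
  ids <- unique(as.character(patient))
  pre <- setNames(rep(NA_real_, length(ids)), ids)
  post <- pre
  for (i in seq_along(t1)) {
    if (timepoint[i] == "pre") pre[as.character(patient[i])] <- t1[i]
    else post[as.character(patient[i])] <- t1[i]
  }
  complete <- !is.na(pre) & !is.na(post)
  excluded <- ids[!complete]
  if (length(excluded))
    warning("excluding ", length(excluded),
            " patient(s) missing a timepoint: ",
            paste(excluded, collapse = ", "))
  ids <- ids[complete]
  pre <- pre[complete]; post <- post[complete]
  stratum <- ifelse(post < 0, "Red", ifelse(pre > 0, "Green", "Grey"))
  td <- trajectoryDistance(pre, post)
  out <- data.frame(patient = ids, pre_t1 = unname(pre),
                    post_t1 = unname(post), distance = td$distance,
                    correct = td$correct,
                    stratum = factor(stratum,
                                     levels = c("Grey", "Red", "Green")),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Median-ratio effect size
#'
#' Between-group difference of two positive-median samples expressed as
#' \code{100 - (lower median)/(higher median) * 100}, in percent.
#'
#' @param a,b numeric vectors.
#' @return percent in [0, 100]; \code{NA} with attribute
#'   \code{"undefined"} when either median is non-positive.
#' @examples
#' medianRatio(c(1, 2, 3), c(2, 4, 6))  # 50
#' @export
medianRatio <- function(a, b) {
  ma <- median(a, na.rm = TRUE)
  mb <- median(b, na.rm = TRUE)
  if (is.na(ma) || is.na(mb) || ma <= 0 || mb <= 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  100 - min(ma, mb) / max(ma, mb) * 100
}

wsr_p <- function(a, b) {
  n <- sum(stats::complete.cases(a, b))
  if (all(a == b, na.rm = TRUE))    # no nonzero differences: no effect
    return(list(statistic = c(V = 0), p.value = 1))
  suppressWarnings(wilcox.test(a, b, paired = TRUE,
                               exact = n <= 25, correct = TRUE))
}

#' Paired univariate test battery
#'
#' Runs, per panel metabolite: the Wilcoxon signed-rank test of pre vs
#' post integrals (overall and within each stratum and sex), the
#' Mann-Whitney U test of males vs females (at each timepoint), and the
#' Kruskal-Wallis test across the Grey/Red/Green strata (at each
#' timepoint and on the post/pre ratio). Each two-group comparison
#' carries the median-ratio effect size. Rank tests use average ranks for
#' ties; the signed-rank test uses the exact null for n <= 25 and the
#' continuity-corrected normal approximation otherwise. No
#' multiple-testing correction is applied (\code{p_adjust = "none"}; the
#' comparisons are reported as computed, with the 0.05 threshold left to
#' the caller).
#'
#' @param metab a \code{\linkS4class{MetaboliteTable}} with paired
#'   pre/post columns per patient.
#' @param groups data.frame with \code{patient} plus optional
#'   \code{stratum} and \code{sex} columns.
#' @param min_n groups smaller than this are skipped with a reason.
#' @param p_adjust multiplicity correction passed to
#'   \code{\link[stats]{p.adjust}} (default \code{"none"}).
#' @return data.frame, one row per test: comparison, metabolite, test
#'   (WSR/MWU/KWA), group sizes, statistic, p, median_ratio, note.
#' @export
pairedBattery <- function(metab, groups = NULL, min_n = 3,
                          p_adjust = "none") {
  long <- metaboliteLong(metab)
  wide <- merge(
    long[long$timepoint == "pre",
         c("patientID", "metabolite", "integral")],
    long[long$timepoint == "post",
         c("patientID", "metabolite", "integral")],
    by = c("patientID", "metabolite"), suffixes = c("_pre", "_post"))
  if (!is.null(groups))
    wide <- merge(wide, groups, by.x = "patientID", by.y = "patient",
                  all.x = TRUE)
  has_stratum <- "stratum" %in% names(wide)
  has_sex <- "sex" %in% names(wide)
  rows <- list()
  add <- function(comparison, metabolite, test, n1, n2, statistic, p,
                  mr, note = "") {
    rows[[length(rows) + 1]] <<- data.frame(
      comparison = comparison, metabolite = metabolite, test = test,
      n1 = n1, n2 = n2, statistic = statistic, p = p,
      median_ratio = mr, note = note, stringsAsFactors = FALSE)
  }
  wsr_row <- function(d, label, met) {
    if (nrow(d) < min_n) {
      add(label, met, "WSR", nrow(d), nrow(d), NA, NA, NA,
          sprintf("skipped: n = %d < %d", nrow(d), min_n))
    } else {
      ht <- wsr_p(d$integral_pre, d$integral_post)
      add(label, met, "WSR", nrow(d), nrow(d),
          unname(ht$statistic), ht$p.value,
          as.numeric(medianRatio(d$integral_pre, d$integral_post)))
    }
  }
  for (met in unique(wide$metabolite)) {
    d <- wide[wide$metabolite == met, ]
    wsr_row(d, "pre_vs_post|All", met)
    if (has_stratum)
      for (st in levels(factor(d$stratum)))
        wsr_row(d[!is.na(d$stratum) & d$stratum == st, ],
                paste0("pre_vs_post|", st), met)
    if (has_sex) {
      for (sx in c("M", "F"))
        wsr_row(d[!is.na(d$sex) & d$sex == sx, ],
                paste0("pre_vs_post|", sx), met)
      for (tp in c("pre", "post")) {
        v <- d[[paste0("integral_", tp)]]
        m <- v[d$sex == "M"]; f <- v[d$sex == "F"]
        lab <- paste0("M_vs_F|", tp)
        if (min(length(m), length(f)) < min_n) {
          add(lab, met, "MWU", length(m), length(f), NA, NA, NA,
              sprintf("skipped: group < %d", min_n))
        } else {
          ht <- suppressWarnings(wilcox.test(m, f, exact = FALSE,
                                             correct = TRUE))
          add(lab, met, "MWU", length(m), length(f),
              unname(ht$statistic), ht$p.value,
              as.numeric(medianRatio(m, f)))
        }
      }
    }
    if (has_stratum) {
      dd <- d[!is.na(d$stratum), ]
      for (what in c("pre", "post", "ratio")) {
        v <- switch(what,
                    pre = dd$integral_pre, post = dd$integral_post,
                    ratio = dd$integral_post / dd$integral_pre)
        sizes <- table(factor(dd$stratum))
        lab <- paste0("strata|", what)
        if (length(sizes) < 2 || any(sizes < min_n)) {
          add(lab, met, "KWA", min(sizes), max(sizes), NA, NA, NA,
              sprintf("skipped: a stratum < %d", min_n))
        } else {
          ht <- kruskal.test(v, factor(dd$stratum))
          add(lab, met, "KWA", min(sizes), max(sizes),
              unname(ht$statistic), ht$p.value, NA_real_)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p <- stats::p.adjust(out$p, method = p_adjust)
  rownames(out) <- NULL
  out
}

#' Correlate metabolic change with clinical response
#'
#' Spearman rank correlation between per-patient metabolite deltas
#' (pre minus post integral, so a treatment \emph{increase} gives a
#' negative delta and a negative R against a beneficial response) and the
#' clinical response measures (cT-yT, cN-yN, tumor regression percent),
#' computed for the whole cohort and within each sex and stratum split.
#' The filtered view retains rows with \code{p < p_max} and
#' \code{|R| > r_min}.
#'
#' @param metab a \code{\linkS4class{MetaboliteTable}}.
#' @param clinical clinical data.frame (columns \code{patient},
#'   \code{sex}, \code{cT}, \code{yT}, \code{cN}, \code{yN},
#'   \code{pre_volume}, \code{post_volume}).
#' @param strata optional data.frame \code{patient}/\code{stratum}.
#' @param p_max,r_min retention filter (defaults 0.05 and 0.3).
#' @param min_n smallest split size correlated.
#' @param retained_only return only the retained rows.
#' @return data.frame: split, metabolite, response, n, R, p, retained.
#'   Constant response vectors within a split are skipped.
#' @export
correlateResponse <- function(metab, clinical, strata = NULL,
                              p_max = 0.05, r_min = 0.3, min_n = 5,
                              retained_only = FALSE) {
  long <- metaboliteLong(metab)
  wide <- merge(
    long[long$timepoint == "pre",
         c("patientID", "metabolite", "integral")],
    long[long$timepoint == "post",
         c("patientID", "metabolite", "integral")],
    by = c("patientID", "metabolite"), suffixes = c("_pre", "_post"))
  wide$delta <- wide$integral_pre - wide$integral_post
  resp <- clinicalResponse(clinical)
  resp$regression <- tumorRegressionPct(clinical$pre_volume,
                                        clinical$post_volume)
  ann <- resp[, c("patient", "sex", "dT", "dN", "regression")]
  d <- merge(wide, ann, by.x = "patientID", by.y = "patient")
  if (!is.null(strata))
    d <- merge(d, strata[, c("patient", "stratum")],
               by.x = "patientID", by.y = "patient", all.x = TRUE)
  splits <- list(All = rep(TRUE, nrow(d)))
  for (sx in c("M", "F")) splits[[sx]] <- d$sex == sx
  if (!is.null(strata))
    for (st in levels(factor(d$stratum)))
      splits[[st]] <- !is.na(d$stratum) & d$stratum == st
  responses <- c(`cT-yT` = "dT", `cN-yN` = "dN",
                 `regression_pct` = "regression")
  rows <- list()
  for (sp in names(splits)) {
    ds <- d[splits[[sp]], ]
    for (met in unique(ds$metabolite)) {
      dm <- ds[ds$metabolite == met, ]
      for (rn in names(responses)) {
        y <- dm[[responses[[rn]]]]
        ok <- stats::complete.cases(dm$delta, y)
        if (sum(ok) < min_n || length(unique(y[ok])) < 2) next
        ct <- suppressWarnings(cor.test(dm$delta[ok], y[ok],
                                        method = "spearman",
                                        exact = FALSE))
        rows[[length(rows) + 1]] <- data.frame(
          split = sp, metabolite = met, response = rn, n = sum(ok),
          R = unname(ct$estimate), p = ct$p.value,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$retained <- !is.na(out$p) & out$p < p_max & abs(out$R) > r_min
  rownames(out) <- NULL
  if (retained_only) out[out$retained, , drop = FALSE] else out
}
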