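# In-code fixtures shared across test files.

# a small paired cohort; spectra at full grid resolution
small_cohort <- local({
  cache <- NULL
  function(n = 8, seed = 42, ...) {
    if (is.null(cache))
      cache <<- generateCohort(cohortSpec(n_patients = n, seed = seed, ...))
    cache
  }
})

# build a MetaboliteTable directly from pre/post matrices
# (rows = metabolites, cols = patients)
make_metab <- function(pre, post, metabolites = rownames(pre),
                       patients = colnames(pre)) {
  if (is.null(metabolites)) metabolites <- paste0("m", seq_len(nrow(pre)))
  if (is.null(patients)) patients <- sprintf("P%03d", seq_len(ncol(pre)))
  sids <- c(paste0(patients, "_pre"), paste0(patients, "_post"))
  m <- cbind(pre, post)
  dimnames(m) <- list(metabolites, sids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(integral = m),
    rowData = S4Vectors::DataFrame(name = metabolites),
    colData = S4Vectors::DataFrame(
      sampleID = sids,
      patientID = rep(patients, 2),
      timepoint = rep(c("pre", "post"), each = length(patients)),
      incomplete = FALSE, row.names = sids))
  new("MetaboliteTable", se)
}

# clinical table the printed cohort-characteristics table describes:
# 53 patients, site and stage group counts, 35 M / 18 F, ages 22-74
table1_like_cohort <- function() {
  site <- rep(c("oropharynx", "nasopharynx", "hypopharynx", "larynx",
                "other"), c(20, 12, 10, 9, 2))
  ctnm <- rep(c("III", "IVa", "IVb"), c(10, 32, 11))
  ages <- c(22, rep(c(45, 57, 65), c(25, 3, 23)), 74)
  data.frame(patient = sprintf("P%03d", 1:53),
             sex = rep(c("M", "F"), c(35, 18)),
             age = ages, site = site, cTNM = ctnm,
             stringsAsFactors = FALSE)
}

# deterministic separable two-class matrix
separable_classes <- function(n_per = 10, p = 12, gap = 6, seed = 7) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per * p, sd = 0.2), 2 * n_per, p)
  X[seq_len(n_per), 1:3] <- X[seq_len(n_per), 1:3] + gap
  y <- rep(c("a", "b"), each = n_per)
  list(X = scale(X, scale = FALSE), y = y)
}
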