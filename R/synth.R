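# Synthetic paired pre/post serum cohorts. The generator plants a known
# treatment effect (lipids up; alanine, glucose, NAG down), weak-responder
# subgroups, sex-dependent baselines and a male-only coupling between the
# lipid response and tumor regression, so every downstream stage can be
# validated against ground truth.

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# fixed-offset substream seeds, kept well below 2^31
substream <- function(seed, i, k = 0L) {
  (as.integer(seed) %% 100000L) * 20000L + 13L * as.integer(i) + k
}

lorentz <- function(x, center, gamma) gamma^2 / ((x - center)^2 + gamma^2)

# 7 Hz scalar coupling at 400 MHz, in ppm
ALANINE_SPLIT_PPM <- 7 / 400

#' Simulate a 1D serum NMR spectrum
#'
#' Builds a spectrum as a mixture of Lorentzian lines (one per panel-region
#' line; the alanine methyl doublet is split by 7 Hz at 400 MHz, other
#' multiplets are collapsed to singlets), plus an optional smooth baseline
#' drift, an optional residual-water hump and additive Gaussian noise.
#' Deterministic for a fixed \code{seed}.
#'
#' @param concentrations nonnegative numeric, one value per panel row
#'   (arbitrary units; peak height per line is concentration / multiplicity).
#' @param panel panel data.frame as from \code{\link{defaultPanel}}.
#' @param n_points,ppm_range axis definition; stored descending.
#' @param noise_sd additive Gaussian noise SD.
#' @param baseline_amp amplitude of a slowly varying sinusoidal baseline.
#' @param linewidth Lorentzian half-width at half-maximum per panel row
#'   (ppm); default 0.008 for lipid rows, 0.003 otherwise.
#' @param shift global ppm offset applied to all planted lines (a
#'   referencing error for \code{\link{referenceToAlanine}} to undo).
#' @param water_amp,water_center,water_gamma residual water signal.
#' @param channel,sampleID,patientID,timepoint annotation passed through.
#' @param seed integer or NULL.
#' @return An \code{\linkS4class{NMRSpectrum}}.
#' @examples
#' pan <- defaultPanel()
#' sp <- generateSpectrum(pan$weight * 5, pan, noise_sd = 0.05, seed = 7)
#' sp
#' @export
generateSpectrum <- function(concentrations, panel = defaultPanel(),
                             n_points = 10000, ppm_range = c(0.5, 9.0),
                             noise_sd = 0, baseline_amp = 0,
                             linewidth = NULL, shift = 0,
                             water_amp = 0, water_center = 4.78,
                             water_gamma = 0.10,
                             channel = "CPMG", sampleID = NA, patientID = NA,
                             timepoint = NA, seed = NULL) {
  validatePanel(panel)
  if (length(concentrations) != nrow(panel))
    stop("need one concentration per panel row")
  if (any(concentrations < 0)) stop("concentrations must be nonnegative")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (is.null(linewidth))
    linewidth <- ifelse(grepl("^lipid", panel$metabolite), 0.008, 0.003)
  linewidth <- rep_len(linewidth, nrow(panel))

  x <- seq(ppm_range[1], ppm_range[2], length.out = n_points)
  y <- numeric(n_points)
  for (r in seq_len(nrow(panel))) {
    if (concentrations[r] == 0) next
    m <- panel$multiplicity[r]
    centers <- if (m == 2)
      panel$center[r] + c(-0.5, 0.5) * ALANINE_SPLIT_PPM
    else rep(panel$center[r], m)       # multiplets collapsed to singlets
    for (cc in centers)
      y <- y + (concentrations[r] / m) *
        lorentz(x, cc + shift, linewidth[r])
  }
  if (water_amp > 0)
    y <- y + water_amp * lorentz(x, water_center, water_gamma)
  with_local_seed(seed, {
    if (baseline_amp > 0) {
      phase <- runif(1, 0, 2 * pi)
      y <- y + baseline_amp * (0.5 + 0.5 * sin(2 * pi * x / 6 + phase))
    }
    if (noise_sd > 0) y <- y + rnorm(n_points, 0, noise_sd)
  })
  NMRSpectrum(x, y, channel = channel, sampleID = sampleID,
              patientID = patientID, timepoint = timepoint)
}

# stage distributions mirroring the study cohort
sample_stage <- function(what) {
  switch(what,
    cT = sample(0:4, 1, prob = c(0.056, 0.094, 0.208, 0.434, 0.208)),
    cN = sample(c("0", "1", "2a", "2b", "2c", "3"), 1,
                prob = c(0.09, 0.09, 0.04, 0.17, 0.19, 0.42)),
    site = sample(c("oropharynx", "nasopharynx", "hypopharynx", "larynx",
                    "other"), 1,
                  prob = c(0.377, 0.226, 0.189, 0.170, 0.038)))
}

downstage_steps <- function(regression_pct) {
  if (regression_pct >= 95) 3L
  else if (regression_pct >= 75) 2L
  else if (regression_pct >= 40) 1L
  else 0L
}

#' Generate a synthetic paired pre/post cohort
#'
#' Draws one patient at a time from a fixed per-patient random substream
#' (patient \code{i} is identical in every cohort of size >= \code{i} with
#' the same master seed). Each patient gets baseline metabolite
#' concentrations (log-normal between-patient variation, sex offsets on
#' glucose and alanine, the weak-B subgroup's elevated-lipid/low-alanine
#' baseline), a post-treatment concentration vector (full multiplicative
#' effect, attenuated on the log scale for the weak subgroups), four
#' spectra (pre/post x CPMG/diffusion-edited channels) and a clinical
#' record. Tumor regression is coupled to the realized lipid response in
#' males only; in females it is drawn independently.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @param profile an \code{\link{defaultEffectProfile}} effect profile.
#' @param panel panel data.frame.
#' @return list of class \code{"NMRCohort"}: \code{spectra} (named list of
#'   \code{\linkS4class{NMRSpectrum}}), \code{clinical} (data.frame),
#'   \code{labels} (planted subgroup truth), \code{concentrations}
#'   (planted per-metabolite pre/post concentrations), plus the generating
#'   \code{spec}, \code{profile} and \code{panel}.
#' @examples
#' coh <- generateCohort(cohortSpec(n_patients = 4, n_points = 9000,
#'                                  seed = 1))
#' coh$clinical[, 1:6]
#' @export
generateCohort <- function(spec = cohortSpec(),
                           profile = defaultEffectProfile(),
                           panel = defaultPanel()) {
  stopifnot(inherits(spec, "CohortSpec"), inherits(profile, "EffectProfile"))
  validatePanel(panel)
  mets <- unique(panel$metabolite)
  if (!all(mets %in% names(profile$effects)))
    stop("profile$effects must cover every panel metabolite")
  lipid_rows <- grepl("^lipid", panel$metabolite)

  spectra <- list()
  clin <- list()
  labels <- list()
  conc_rows <- list()

  for (i in seq_len(spec$n_patients)) {
    pid <- sprintf("P%03d", i)
    drew <- with_local_seed(substream(spec$seed, i), {
      sex <- if (runif(1) < spec$male_frac) "M" else "F"
      subgroup <- sample(c("full", "weakA", "weakB"), 1,
                         prob = spec$subgroup_props)
      base <- profile$baseline_conc[mets] *
        exp(rnorm(length(mets), 0, profile$biological_cv[mets]))
      names(base) <- mets
      if (sex == "M")
        base[names(profile$sex_male)] <- base[names(profile$sex_male)] *
          profile$sex_male
      if (subgroup == "weakB")
        base[names(profile$weakB_baseline)] <-
          base[names(profile$weakB_baseline)] * profile$weakB_baseline
      a <- switch(subgroup, full = 1,
                  weakA = profile$attenuation[["weakA"]],
                  weakB = profile$attenuation[["weakB"]])
      post <- base * profile$effects[mets]^a *
        exp(rnorm(length(mets), 0, profile$technical_cv))
      shifts <- runif(2, -0.004, 0.004)      # pre, post referencing error
      age <- max(22, min(74, round(rnorm(1, 55, 11))))
      cT <- sample_stage("cT")
      cN <- sample_stage("cN")
      site <- sample_stage("site")
      regimen <- sample(c("TPF", "PF", "PC"), 1,
                        prob = c(23, 28, 2) / 53)
      cycles <- sample(1:4, 1, prob = c(9, 6, 36, 2) / 53)
      ctcae <- c(anemia = sample(0:2, 1, prob = c(0.45, 0.40, 0.15)),
                 leukopenia = sample(0:4, 1,
                                     prob = c(0.51, 0.20, 0.14, 0.10, 0.05)),
                 neutropenia = sample(0:4, 1,
                                      prob = c(0.59, 0.08, 0.07, 0.16, 0.10)),
                 thrombocytopenia = sample(0:3, 1,
                                           prob = c(0.73, 0.15, 0.08, 0.04)))
      lip_logratio <- log(post[["lipid_1.3"]] / base[["lipid_1.3"]])
      regression <- if (sex == "M")
        100 * min(1, max(0, 0.55 + 2.2 * lip_logratio + rnorm(1, 0, 0.10)))
      else
        100 * min(1, max(0, rnorm(1, 0.72, 0.15)))
      pre_vol <- rlnorm(1, log(25), 0.6)
      list(sex = sex, subgroup = subgroup, base = base, post = post,
           shifts = shifts, age = age, cT = cT, cN = cN, site = site,
           regimen = regimen, cycles = cycles, ctcae = ctcae,
           regression = regression, pre_vol = pre_vol)
    })

    post_vol <- drew$pre_vol * (1 - drew$regression / 100)
    down <- downstage_steps(drew$regression)
    yT <- max(drew$cT - down, 0L)
    yN <- max(stageNumber(drew$cN) -
                max(0L, down - (i %% 2L)), 0L)

    for (tp in c("pre", "post")) {
      conc_m <- if (tp == "pre") drew$base else drew$post
      reg_conc <- conc_m[panel$metabolite] * panel$weight
      sh <- drew$shifts[if (tp == "pre") 1 else 2]
      k_base <- if (tp == "pre") 1L else 3L
      sid <- paste0(pid, "_", tp)
      spectra[[paste0(sid, "_CPMG")]] <- generateSpectrum(
        reg_conc, panel, n_points = spec$n_points,
        ppm_range = spec$ppm_range, noise_sd = profile$noise_sd,
        baseline_amp = profile$baseline_amp, shift = sh,
        water_amp = 30, channel = "CPMG", sampleID = sid,
        patientID = pid, timepoint = tp,
        seed = substream(spec$seed, i, 1000L + k_base))
      diff_conc <- ifelse(lipid_rows, reg_conc, 0)
      spectra[[paste0(sid, "_DIFF")]] <- generateSpectrum(
        diff_conc, panel, n_points = spec$n_points,
        ppm_range = spec$ppm_range, noise_sd = profile$noise_sd,
        baseline_amp = 2 * profile$baseline_amp, shift = sh,
        linewidth = ifelse(lipid_rows, 0.02, 0.003),
        water_amp = 10, channel = "DIFF", sampleID = sid,
        patientID = pid, timepoint = tp,
        seed = substream(spec$seed, i, 1000L + k_base + 1L))
    }

    clin[[i]] <- data.frame(
      patient = pid, sex = drew$sex, age = drew$age, site = drew$site,
      cT = as.character(drew$cT), cN = drew$cN, cM = "0",
      yT = as.character(yT), yN = as.character(yN),
      pre_volume = drew$pre_vol, post_volume = post_vol,
      regimen = drew$regimen, cycles = drew$cycles,
      ctcae_anemia = drew$ctcae[["anemia"]],
      ctcae_leukopenia = drew$ctcae[["leukopenia"]],
      ctcae_neutropenia = drew$ctcae[["neutropenia"]],
      ctcae_thrombocytopenia = drew$ctcae[["thrombocytopenia"]],
      stringsAsFactors = FALSE)
    labels[[i]] <- data.frame(patient = pid, subgroup = drew$subgroup,
                              stringsAsFactors = FALSE)
    conc_rows[[i]] <- data.frame(
      patient = pid, metabolite = mets,
      pre = as.numeric(drew$base[mets]), post = as.numeric(drew$post[mets]),
      stringsAsFactors = FALSE)
  }

  structure(list(spectra = spectra,
                 clinical = do.call(rbind, clin),
                 labels = do.call(rbind, labels),
                 concentrations = do.call(rbind, conc_rows),
                 spec = spec, profile = profile, panel = panel),
            class = "NMRCohort")
}

#' Write a synthetic cohort to disk
#'
#' Spectra as two-column tab-delimited text (ppm, intensity), one file per
#' sample and channel; clinical table and truth labels as CSV.
#'
#' @param cohort an \code{"NMRCohort"} from \code{\link{generateCohort}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "NMRCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec_dir <- file.path(dir, "spectra")
  dir.create(spec_dir, showWarnings = FALSE)
  paths <- vapply(names(cohort$spectra), function(nm) {
    p <- file.path(spec_dir, paste0(nm, ".tsv"))
    writeSpectrum(cohort$spectra[[nm]], p)
    p
  }, character(1))
  clin_path <- file.path(dir, "clinical.csv")
  lab_path <- file.path(dir, "labels.csv")
  write.csv(cohort$clinical, clin_path, row.names = FALSE)
  write.csv(cohort$labels, lab_path, row.names = FALSE)
  invisible(c(paths, clin_path, lab_path))
}
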