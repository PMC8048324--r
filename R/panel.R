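#' Water exclusion window
#'
#' The residual-water chemical-shift region removed from serum spectra
#' before multivariate analysis, in ppm.
#' @export
WATER_WINDOW <- c(4.38, 5.15)

#' Serum metabolite panel
#'
#' The panel of NMR signals discriminating pre- from post-chemotherapy
#' serum: three lipid signals (0.9, 1.3 and 5.3 ppm, quantified on
#' diffusion-edited spectra), alanine (1.48 ppm methyl doublet),
#' N-acetyl-glycoprotein (NAG, 2.07 ppm) and ten glucose signals
#' (3.24-3.90 and 5.20 ppm), the small metabolites quantified on
#' CPMG-type spectra.
#'
#' Each row is one panel region: \code{name}, the parent \code{metabolite}
#' (the ten glucose regions share one underlying concentration),
#' \code{center} ppm, \code{half_width} of the integration region,
#' Lorentzian line \code{multiplicity} (2 for the alanine doublet, 1
#' otherwise), the expected \code{direction} of the post-treatment change
#' (+1 increase, -1 decrease), the quantification \code{channel}, and the
#' relative line \code{weight} used by the synthetic generator (signal
#' intensity per unit of parent-metabolite concentration).
#'
#' @param lipid_half_width,small_half_width integration half-widths (ppm)
#'   for the broad lipid signals and the sharp small-metabolite signals.
#'   The region boundaries are configuration, not measurements: the
#'   defaults (0.05 / 0.01 ppm) are documented assumptions.
#' @return data.frame, one row per panel region.
#' @examples
#' defaultPanel()
#' @export
defaultPanel <- function(lipid_half_width = 0.05, small_half_width = 0.01) {
  glc_ppm <- c(3.24, 3.42, 3.44, 3.51, 3.56, 3.72, 3.76, 3.83, 3.90, 5.20)
  glc_w   <- c(0.60, 0.80, 0.80, 0.70, 0.70, 0.90, 0.80, 0.90, 0.60, 0.40)
  pan <- data.frame(
    name = c("lipid_0.9", "lipid_1.3", "lipid_5.3", "alanine_1.48",
             "NAG_2.07", paste0("glucose_", sprintf("%.2f", glc_ppm))),
    metabolite = c("lipid_0.9", "lipid_1.3", "lipid_5.3", "alanine", "NAG",
                   rep("glucose", length(glc_ppm))),
    center = c(0.90, 1.30, 5.30, 1.48, 2.07, glc_ppm),
    half_width = c(rep(lipid_half_width, 3), rep(small_half_width, 12)),
    multiplicity = c(1L, 1L, 1L, 2L, 1L, rep(1L, length(glc_ppm))),
    direction = c(1L, 1L, 1L, -1L, -1L, rep(-1L, length(glc_ppm))),
    channel = c(rep("DIFF", 3), rep("CPMG", 12)),
    weight = c(1, 1, 1, 1, 1, glc_w),
    stringsAsFactors = FALSE
  )
  validatePanel(pan)
  pan
}

#' Read a metabolite panel from file
#'
#' Reads a panel definition from CSV or YAML (a list of records with the
#' columns of \code{\link{defaultPanel}}) and validates it, including the
#' no-water-overlap rule.
#'
#' @param path a \code{.csv}, \code{.yaml} or \code{.yml} file.
#' @return validated panel data.frame.
#' @export
readPanel <- function(path) {
  pan <- if (grepl("\\.ya?ml$", path)) {
    do.call(rbind, lapply(yaml::read_yaml(path), as.data.frame))
  } else {
    read.csv(path, stringsAsFactors = FALSE)
  }
  pan$multiplicity <- as.integer(pan$multiplicity)
  pan$direction <- as.integer(pan$direction)
  validatePanel(pan)
  pan
}

#' Planted signal support of the panel regions
#'
#' The ppm interval over which each panel region actually carries signal:
#' the multiplet half-span plus five Lorentzian half-widths, never less
#' than the integration half-width. Used to judge whether
#' model-selected buckets fall on planted signal (line tails extend
#' beyond the integration windows).
#'
#' @param panel panel data.frame.
#' @param linewidth per-row Lorentzian half-widths; defaults to the
#'   CPMG-channel values (0.008 ppm lipids, 0.003 ppm small metabolites).
#' @return data.frame with \code{name}, \code{low}, \code{high} (ppm).
#' @export
signalRegions <- function(panel = defaultPanel(), linewidth = NULL) {
  if (is.null(linewidth))
    linewidth <- ifelse(grepl("^lipid", panel$metabolite), 0.008, 0.003)
  span <- ifelse(panel$multiplicity == 2, 7 / 400 / 2, 0)
  pad <- pmax(panel$half_width, span + 5 * linewidth)
  data.frame(name = panel$name, low = panel$center - pad,
             high = panel$center + pad, stringsAsFactors = FALSE)
}

validatePanel <- function(panel) {
  need <- c("name", "metabolite", "center", "half_width", "multiplicity",
            "direction", "channel", "weight")
  if (!all(need %in% names(panel)))
    stop("panel is missing columns: ",
         paste(setdiff(need, names(panel)), collapse = ", "))
  if (any(panel$half_width <= 0)) stop("panel half_width must be positive")
  if (any(panel$center < 0.5 | panel$center > 9.0))
    stop("panel centers must lie within [0.5, 9.0] ppm")
  lo <- panel$center - panel$half_width
  hi <- panel$center + panel$half_width
  if (any(hi > WATER_WINDOW[1] & lo < WATER_WINDOW[2]))
    stop("panel region overlaps the water window [",
         WATER_WINDOW[1], ", ", WATER_WINDOW[2], "] ppm")
  invisible(panel)
}

#' Default treatment-effect profile for the synthetic cohort
#'
#' The multiplicative post/pre concentration changes planted by
#' \code{\link{generateCohort}}, together with the subgroup, sex, and
#' noise structure. Defaults encode the qualitative serum response to
#' induction chemotherapy — lipids up, alanine/glucose/NAG down — with
#' magnitudes proportional (3x on the log scale) to the observed
#' whole-group median ratios (lipids ~3-9\% up, small metabolites
#' ~9-14\% down). The group-level ratios pool full and weak responders
#' and do not determine the per-patient full-responder effect; the
#' default magnitude is calibrated once so that the planted subgroup
#' structure is clearly recoverable by score-sign stratification (see
#' the methods vignette).
#'
#' Weak-responder subgroups attenuate the effect on the log scale
#' (multiplier\eqn{^a}, \code{a} in [0, 1]): subgroup \code{weakA}
#' ("Red"-like, minimal response, indistinguishable baseline) and
#' \code{weakB} ("Green"-like, attenuated response with a distinct
#' baseline). The weak-B baseline places those patients, for the lipid
#' and alanine axes, at the full-responder treatment endpoint — they
#' start treatment where full responders end it, the defining property
#' of the mixing pre-treatment samples. Males carry elevated baseline
#' glucose and alanine.
#'
#' @param effects named post/pre multipliers per metabolite
#'   (> 1 increase, < 1 decrease).
#' @param attenuation named log-scale attenuation factors in [0, 1] for
#'   \code{weakA} and \code{weakB}.
#' @param weakB_baseline named baseline multipliers applied to weak-B
#'   patients before treatment.
#' @param sex_male named baseline multipliers applied to male patients.
#' @param biological_cv named between-patient log-normal coefficients of
#'   variation of baseline concentrations.
#' @param technical_cv log-normal within-patient technical variation of
#'   the post sample.
#' @param noise_sd spectral (additive Gaussian) noise standard deviation,
#'   in the same arbitrary intensity units as peak heights (2-10).
#' @param baseline_amp amplitude of the smooth baseline drift.
#' @param baseline_conc named baseline concentrations (arbitrary units).
#' @return list with class \code{"EffectProfile"}.
#' @examples
#' str(defaultEffectProfile())
#' @export
defaultEffectProfile <- function(
    effects = c(lipid_0.9 = 1.087, lipid_1.3 = 1.309, lipid_5.3 = 1.259,
                alanine = 0.631, NAG = 0.753, glucose = 0.754),
    attenuation = c(weakA = 0.10, weakB = 0.30),
    weakB_baseline = c(lipid_0.9 = 1.087, lipid_1.3 = 1.309,
                       lipid_5.3 = 1.259, alanine = 0.631),
    sex_male = c(glucose = 1.18, alanine = 1.25),
    biological_cv = c(lipid_0.9 = 0.15, lipid_1.3 = 0.15, lipid_5.3 = 0.15,
                      alanine = 0.12, NAG = 0.12, glucose = 0.08),
    technical_cv = 0.04,
    noise_sd = 0.05,
    baseline_amp = 0.15,
    baseline_conc = c(lipid_0.9 = 6, lipid_1.3 = 10, lipid_5.3 = 3,
                      alanine = 4, NAG = 3, glucose = 8)) {
  if (any(effects <= 0)) stop("effects must be positive multipliers")
  if (any(attenuation < 0 | attenuation > 1))
    stop("attenuation factors must lie in [0, 1]")
  lip <- grep("^lipid", names(effects))
  if (any(effects[lip] <= 1) ||
      any(effects[c("alanine", "glucose", "NAG")] >= 1))
    warning("default-direction check: lipids should increase and ",
            "alanine/glucose/NAG decrease post treatment")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(effects = effects, attenuation = attenuation,
                 weakB_baseline = weakB_baseline, sex_male = sex_male,
                 biological_cv = biological_cv, technical_cv = technical_cv,
                 noise_sd = noise_sd, baseline_amp = baseline_amp,
                 baseline_conc = baseline_conc),
            class = "EffectProfile")
}

#' Synthetic cohort specification
#'
#' Size and composition of a synthetic paired pre/post cohort. Defaults
#' mirror the study scale: ~50 patients, two thirds male, roughly
#' 64/19/17\% full / weak-A / weak-B responders.
#'
#' @param n_patients number of patients (one pre and one post sample each).
#' @param male_frac fraction of male patients.
#' @param subgroup_props named proportions (\code{full}, \code{weakA},
#'   \code{weakB}); must sum to 1.
#' @param n_points points per spectrum; must be at least twice the number
#'   of buckets implied by \code{bucket_width} over [0.5, 9] ppm.
#' @param ppm_range spectral window, ppm.
#' @param bucket_width target bucket width used for the point-density check.
#' @param seed master seed; per-patient substreams are derived from it by
#'   fixed offsets, so patient \code{i} is identical across cohort sizes.
#' @return list with class \code{"CohortSpec"}.
#' @examples
#' cohortSpec(n_patients = 10, seed = 1)
#' @export
cohortSpec <- function(n_patients = 50, male_frac = 0.66,
                       subgroup_props = c(full = 0.64, weakA = 0.19,
                                          weakB = 0.17),
                       n_points = 10000, ppm_range = c(0.45, 9.05),
                       bucket_width = 0.002, seed = 1L) {
  if (abs(sum(subgroup_props) - 1) > 1e-8)
    stop("subgroup proportions must sum to 1")
  if (!all(c("full", "weakA", "weakB") %in% names(subgroup_props)))
    stop("subgroup_props must be named full/weakA/weakB")
  n_buckets <- floor(diff(range(ppm_range)) / bucket_width)
  if (n_points < 2 * n_buckets)
    stop("n_points must be at least twice the implied bucket count (",
         2 * n_buckets, ")")
  if (is.null(seed)) stop("a seed is mandatory")
  structure(list(n_patients = as.integer(n_patients),
                 male_frac = male_frac, subgroup_props = subgroup_props,
                 n_points = as.integer(n_points), ppm_range = ppm_range,
                 bucket_width = bucket_width, seed = as.integer(seed)),
            class = "CohortSpec")
}
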