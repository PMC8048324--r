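# nmrResponse

Serum NMR metabolomics of the response to induction chemotherapy.

Patients with locally advanced head-and-neck cancer often receive
induction chemotherapy before definitive radio(chemo)therapy. Serum
^1^H NMR spectroscopy captures the systemic metabolic response to that
treatment: the characteristic signature is an **increase of the serum
lipid signals** (0.9, 1.3, 5.3 ppm) with simultaneous **decreases of
alanine (1.48 ppm), glucose (3.2–3.9, 5.2 ppm) and
N-acetyl-glycoprotein (NAG, 2.07 ppm)**, with sex-dependent baselines
and a subset of patients whose metabolic response is markedly weaker.
`nmrResponse` is for analysts who want to run — or study — this kind of
paired pre/post serum NMR analysis end to end, including on fully
synthetic cohorts with known ground truth.

The package implements:

* **Preprocessing** exactly in the standard serum protocol: referencing
  to the alanine methyl doublet, bucketing at 0.002 ppm over
  9.0–0.5 ppm (4250 buckets), removal of the water region
  4.38–5.15 ppm (385 buckets), *no normalization*, Pareto scaling
  (center, then divide by √SD).
* **OPLS-DA** (orthogonal projections to latent structures discriminant
  analysis), written here as a closed-form NIPALS sequence for a single
  two-class response: orthogonal components `t_o = X w_o` capturing
  class-uncorrelated variation are deflated before one predictive
  component `t[1] = X w` with `w ∝ Xᵀy`. Diagnostics follow the usual
  chemometric definitions — R2X, R2X(o), R2Y, `p(corr)` (per-variable
  correlation with `t[1]`) — and validation uses deterministic 7-fold
  cross-validation (`Q2 = 1 − PRESS/SS`), label-permutation testing
  with empirical p-values `(1 + #{perm ≥ obs})/(n_perm + 1)`, CV-ANOVA
  (F-test of `SS − PRESS` against `PRESS`), external-set prediction
  (`tPS`) and misclassification tables.
* **Metabolite quantification** by the "sum all points in region" rule
  on named panel regions (lipids from diffusion-edited spectra, small
  metabolites from CPMG-type spectra).
* **Responder stratification** from score trajectories: after orienting
  the score axis so the post-treatment class is positive, a patient is
  *Red* if their post sample falls on the negative (pre) side, *Green*
  if their pre sample falls on the positive (post) side, *Grey*
  (non-mixing) otherwise; the per-patient trajectory distance
  `|t[1]_post − t[1]_pre|` measures response amplitude.
* **Univariate battery**: Wilcoxon signed-rank (pre vs post),
  Mann–Whitney U (male vs female), Kruskal–Wallis (across strata), the
  median-ratio effect size `100 − (lower median)/(higher median)·100`,
  and Spearman correlation of metabolite deltas (pre − post) with
  clinical response (cT−yT, cN−yN, tumor regression
  `100 − 100·V_post/V_pre`), filtered at `p < 0.05`, `|R| > 0.3`.
* **A synthetic-cohort generator** producing paired pre/post spectra
  (Lorentzian mixtures on both acquisition channels) with planted
  treatment effects, two weak-responder subgroups, sex-dependent
  baselines and a male-only lipid↔regression coupling, so every claim
  the pipeline makes can be checked against ground truth.

## Worked example

Simulate a 20-patient paired cohort, preprocess, fit and validate the
model, and stratify the patients:

```r
library(nmrResponse)

coh  <- generateCohort(cohortSpec(n_patients = 20, seed = 4))
cpmg <- Filter(function(s) s@channel == "CPMG", coh$spectra)
cpmg <- lapply(cpmg, referenceToAlanine, target = 1.48)
bt   <- excludeWater(buildBucketTable(cpmg, bucketGrid()))
X    <- paretoScale(bucketMatrix(bt))
tp   <- SummarizedExperiment::colData(bt)$timepoint

model <- fitOplsda(X, tp, n_orth = 2)
model
#> OplsdaModel: 1 predictive + 2 orthogonal component(s), 3865 variables, 40 samples
#>   R2X = 0.1384  R2Y = 0.5827  R2X(o) = 0.2941, 0.17
#>   classes: post (0) vs pre (1)

cv <- crossValidate(X, tp, n_orth = 2)
round(cv$Q2, 3)        # cross-validated predictive ability
#> [1] 0.235
signif(cvAnova(cv)$p, 3)
#> [1] 0.0207

traj <- detectMixing(cv$yhat_cv - 0.5, tp,
                     SummarizedExperiment::colData(bt)$patientID)
table(traj$stratum)
#> Grey   Red Green
#>   11     5     4
```

The predictive component explains ~14% of the spectral variation
(R2X) while the two orthogonal components absorb patient-level
variation; Q2 ≈ 0.24 says the class distinction survives 7-fold
cross-validation, and CV-ANOVA puts a p-value on that. Eleven patients
respond fully (Grey); nine weak responders mix across the class
boundary (Red/Green).

The paired test battery then quantifies the planted signature
(signed-rank p-values and median ratios, pre vs post, whole cohort):

```r
metab <- quantifyPanel(coh$spectra)
groups <- merge(traj[, c("patient", "stratum")],
                coh$clinical[, c("patient", "sex")], by = "patient")
b <- pairedBattery(metab, groups)
b[b$comparison == "pre_vs_post|All" &
  b$metabolite %in% c("lipid_1.3", "alanine_1.48",
                      "NAG_2.07", "glucose_3.72"),
  c("metabolite", "p", "median_ratio")]
#>    metabolite       p median_ratio
#>  alanine_1.48 2.7e-05         21.1
#>  glucose_3.72 1.3e-05         23.1
#>     lipid_1.3 5.7e-06         20.0
#>      NAG_2.07 5.7e-06         15.2
```

`runPipeline()` chains all of this (simulate or load → reference →
bucket → exclude water → Pareto scale → fit/validate → quantify →
stratify → correlate) from a single YAML/list configuration and writes
every stage output plus a checksummed run manifest;
`inst/scripts/run_pipeline.R` is a thin command-line wrapper.

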