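---
title: "Methods: paired serum NMR analysis of chemotherapy response"
author: "nmrResponse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired serum NMR analysis of chemotherapy response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its methods: the models
and rules implemented, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the numerical and design choices made where the design
was genuinely open. It states no empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## The analysis problem

Paired serum samples are drawn from each patient before and after
induction chemotherapy and measured by 1D ^1^H NMR on two channels: a
CPMG-type spectrum emphasizing small metabolites and a
diffusion-edited spectrum retaining only broad lipid/macromolecule
signals. The questions the pipeline answers are: (i) does treatment
systematically shift the serum metabolic profile, and through which
signals; (ii) which patients respond weakly; and (iii) does the
magnitude of a patient's metabolic change track their clinical
response (TNM downstaging, radiological tumor regression)?

## Preprocessing

The bucket pipeline follows the standard serum protocol, with every
step deliberately minimal:

* **Referencing.** The chemical-shift axis is anchored on the alanine
  methyl doublet. The detector smooths the search window (default
  1.3–1.7 ppm) with a 5-point moving average, collects local maxima
  above `median + 5·MAD`, and picks the best pair with doublet-like
  separation (7 Hz at 400 MHz ± tolerance: 0.008–0.030 ppm) and height
  ratio ≤ 2; the axis is shifted so the pair midpoint sits on the
  target. The target defaults to 1.50 ppm (the conventional quoting of
  the alanine doublet position); the synthetic pipeline anchors at
  1.48 ppm, where the panel places alanine, so that panel regions line
  up exactly. Detection failure leaves the spectrum unshifted with a
  warning flag rather than stopping the run.
* **Bucketing.** Fixed 0.002 ppm buckets over 9.0–0.5 ppm, hence
  `floor(8.5/0.002) = 4250` buckets. Buckets are half-open descending
  intervals anchored at 9.0 (upper edge included); this convention is
  not dictated by the protocol, but anchoring at the stated upper
  bound makes bucket counts and edge behavior deterministic, and the
  test suite checks membership against a brute-force interval oracle.
  A bucket value is the plain *sum* of point intensities, so bucketing
  conserves total intensity.
* **Water exclusion.** Buckets whose *center* lies in the closed
  window 4.38–5.15 ppm (width 0.77 ppm) are masked — 385 buckets,
  leaving 3865. Exclusion by center rather than overlap is the
  simplest rule consistent with "the region was removed"; for windows
  aligned to bucket edges the two rules coincide, and the suite checks
  that exclusion commutes with raw-axis exclusion in that case.
* **No normalization.** There is deliberately no probabilistic
  quotient, integral or any other between-sample normalization between
  bucketing and scaling.
* **Pareto scaling.** Each bucket column is mean-centered and divided
  by the square root of its sample SD (n−1 denominator); zero-variance
  columns become zero. Pareto scaling keeps intense signals dominant
  while lifting mid-intensity metabolites, the usual compromise for
  spectral data. Only X is scaled, never the class vector.

Phasing, baseline correction and apodization are acquisition-side
steps assumed already applied to the input spectra.

## OPLS-DA

For a two-class response there is a closed-form NIPALS sequence — no
iteration and no random initialization, so fits are exactly
reproducible. With classes coded 0/1 (levels in sort order) and
`y_c = y − ȳ`:

1. `w = Xᵀy_c / ‖·‖`, `t = Xw`, `p = Xᵀt/tᵀt`;
2. the orthogonal weight is the part of `p` orthogonal to `w`:
   `w_o ∝ p − (wᵀp)w`; `t_o = Xw_o`, `p_o = Xᵀt_o/t_oᵀt_o`, and X is
   deflated by `t_o p_oᵀ`;
3. after `n_orth` such deflations (default 2, the standard final model
   for this kind of serum data) the predictive component is extracted
   from the deflated matrix.

With `n_orth = 0` this is exactly textbook single-component PLS1; the
test suite asserts score/loading agreement with an independent oracle
implementation to 1e-8 and cross-checks against `mixOmics::pls`.
Diagnostics: `R2X = (tᵀt)(pᵀp)/‖X‖²` per component, `R2Y` from the
fitted response, `p(corr)` as the Pearson correlation of each column
with `t[1]` (zero-variance columns get 0, flagged). Class calls
threshold the predicted response at 0.5; the coding is symmetric under
label swap, which the tests verify for Q2.

**Cross-validation.** Deterministic interleaved assignment in row
order into 7 folds (the conventional default; the fold count is
configurable). Folds that would lose a class are reassigned stratified
by class. `Q2 = 1 − PRESS/SS`. A degenerate training split with no
class-correlated variation left (possible in adversarial symmetric
inputs) predicts the training mean rather than failing.

**Permutation testing.** Class labels are permuted `n_perm` times
(default 999, seeded and mandatory); empirical p-values use the
add-one rule `(1 + #{stat_perm ≥ stat_obs})/(n_perm + 1)`, so the
smallest attainable p is `1/(n_perm+1)`. R2Y permutes cheaply; Q2
permutation re-runs the full cross-validation and can be switched off
per call.

**CV-ANOVA.** The package uses the F-formulation on cross-validated
residuals: `F = ((SS − PRESS)/A) / (PRESS/(N − 1 − A))` with `A` the
number of model components (predictive + orthogonal), `p` from the F
distribution. The literature names this test without fixing every
degree-of-freedom convention; the choice here — one DF per extracted
component — is documented rather than claimed canonical. When the
cross-validated residuals vanish the p-value is reported at the
machine floor with a `zero_residual` flag.

## Quantification

Panel integrals are plain sums of the points inside
`center ± half_width`, lipids from the diffusion-edited channel and
small metabolites from the CPMG channel. The exact integration
boundaries the protocol used are not recoverable, so the half-widths
are configuration with documented defaults: ±0.01 ppm for sharp small
metabolites, ±0.05 ppm for broad lipid signals. Glucose is reported
per region (ten regions share one underlying concentration in the
generator); panel regions may not overlap the water window, which the
constructor enforces.

## Stratification and univariate battery

Weak responders are read off the score axis. After orienting scores so
the post-treatment class mean is positive (the score-plot convention),
**Red** patients have their post sample at `t < 0` (still in pre
territory), **Green** patients have their pre sample at `t > 0`
(already in post territory); Red takes precedence if both hold, a case
the visual definition leaves open. Everyone else is **Grey**
(non-mixing). Sign crossing is the one reproducible reading of the
visual "mixing cloud" definition. The per-patient trajectory distance
`|t_post − t_pre|` measures response amplitude and its direction is
"correct" when it runs pre→post.

The pipeline feeds this rule with **cross-validated predicted scores**
(`yhat_cv − 1/2`) rather than training scores: a training score is
biased toward the sample's own class label — precisely the bias that
masks mixing — while the cross-validated score places each sample with
a model that never saw it. `detectMixing()` itself is agnostic to
which scores it receives.

The battery runs, per panel metabolite: Wilcoxon signed-rank pre vs
post (whole cohort, per stratum, per sex; exact null for n ≤ 25,
continuity-corrected normal approximation above; all-zero difference
vectors report p = 1), Mann–Whitney U for male vs female at each
timepoint, Kruskal–Wallis across Grey/Red/Green (levels, and the
post/pre ratio), each two-group comparison with the median-ratio
effect size. Groups below 3 observations are skipped with an explicit
reason. No multiple-testing correction is applied by default
(`p_adjust = "none"`), mirroring the single-comparison convention of
this analysis style; the switch exists and its absence is a documented
limitation. Note that monotone transforms of the data leave MWU, KWA
and Spearman results unchanged but *not* the signed-rank test, which
ranks the magnitudes of paired differences.

Spearman correlations of metabolite deltas (pre − post) against cT−yT,
cN−yN and tumor regression percent are computed per split (all, M, F,
Grey, Red, Green) and filtered at `p < 0.05` and `|R| > 0.3`. With
deltas defined pre − post, a treatment *increase* yields a negative
delta, so a beneficial lipid response appears as negative R against
regression. Under the null this filter retains a row with probability
≈ `2Φ(−0.3√(n−1))` (≈ 3.6% at n = 50), which the acceptance script
measures by simulation.

## The synthetic cohort generator

The generator exists so that every downstream claim can be tested
against ground truth; it emulates the statistical structure the
analysis assumes, not NMR physics.

**What it emulates.** Paired pre/post samples per patient sharing the
patient's baseline; two acquisition channels (all panel signals with
sharp lines on the CPMG-like channel, broadened lipid signals only on
the diffusion-edited-like channel); Lorentzian line shapes (half-width
0.003 ppm for small metabolites, 0.008/0.02 ppm for lipids per
channel; the alanine methyl doublet split by 7 Hz at 400 MHz, other
multiplets collapsed to singlets); a smooth sinusoidal baseline drift
with random phase; a large residual water hump (removed again by the
water mask); additive Gaussian point noise; small per-spectrum
referencing errors (±0.004 ppm) for the referencing step to undo;
log-normal between-patient variation; sex offsets (male glucose ×1.18,
alanine ×1.25); three responder subgroups; and clinical records whose
tumor regression is coupled to the realized lipid-1.3 response in
males only (females draw regression independently), with TNM
downstaging derived from regression.

**Default effect profile.** The full-responder post/pre multipliers
are proportional on the log scale to the observed whole-group
median-ratio signature (lipids up ~3–9%, alanine/glucose/NAG down
~9–14%), scaled ×3. The scaling is a calibration, made once and
documented here: group-level median ratios pool full and weak
responders and compare pooled group medians, so they do not determine
the per-patient effect size; the free magnitude is set so that the
planted subgroup structure lies clearly inside the regime the
stratification rule can recover (the generator's whole purpose). The
weak subgroups attenuate the effect on the log scale: weak-A
("Red"-like) keeps 10% of it and is indistinguishable at baseline;
weak-B ("Green"-like) keeps 30% and *starts treatment at the
full-responder endpoint for the lipid and alanine axes* — the defining
property of pre-treatment samples that sit in post territory.
Between-patient CVs (lipids 0.15, alanine 0.12, NAG 0.12, glucose
0.08), technical CV 0.04, point noise SD 0.05 (peak heights 2–10) and
drift amplitude 0.15 are fixed realistic choices. One master seed
drives fixed per-patient substreams, so patient *i* is identical in
every cohort size — cohorts are reproducible under subsetting.

**What it does not emulate.** Pulse sequences, relaxation, phase
errors, 2D J-resolved tilting, lipoprotein subclasses, peak-shape
distortions, chemical-shift dependence on pH/temperature, or any
correlation structure beyond the planted one. Passing tests therefore
demonstrate that the *pipeline* recovers known structure of this kind;
they say nothing about instrument artifacts real data may add.
Concentrations are in arbitrary units throughout — defensible because
every pipeline stage up to Pareto scaling is scale-covariant.

## Problem sizes and numerical choices

The validation simulations use deliberately modest sizes: 50-patient
default cohorts (10 000 points per spectrum) for structure recovery,
10×20 matrices for the PLS1 oracle equivalence (50 replicates),
200 replicates × 99 permutations for p-value calibration, 100 null
draws for the sign of Q2, and 500 replicates for the correlation
filter's false-retention rate. These sizes give stable checks in
seconds to a couple of minutes each. Recovery rates on 50-pair cohorts
carry ~0.05 binomial noise (≈18 weak responders per cohort), so the
balanced-accuracy check averages four seeded cohorts rather than
trusting a single draw.

Other numerical choices: bucket-edge membership uses a 1e-9 ppm guard
against floating-point edge jitter; score orthogonality is enforced to
1e-8 (relative) in the model validity check; the NIPALS orthogonal
extraction stops with an error when the orthogonal weight norm
collapses (n_orth too large for the rank of X); `R2X + ΣR2X(o) ≤ 1` is
asserted on every fit.

## Known limitations

* The weak-responder stratification threshold (score sign) inherits
  the model's estimation noise; patients near the boundary are
  assigned unstably, and on 50-pair cohorts the recovery rate
  fluctuates by several percentage points between seeds.
* The CV-ANOVA degrees-of-freedom convention is one choice among the
  published variants; p-values should be compared across software with
  that in mind.
* The signed-rank test is not invariant under monotone transforms of
  the integrals (only the between-group rank tests are).
* No multiple-testing correction is applied by default across the
  battery's many comparisons.
* The JCAMP-DX reader supports only the evenly-spaced AFFN
  `(X++(Y..Y))` profile this package writes.
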