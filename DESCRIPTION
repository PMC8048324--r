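Package: nmrResponse
Title: Serum NMR Metabolomics of Induction-Chemotherapy Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the serum metabolic response to induction
    chemotherapy with 1H NMR spectroscopy. Implements the standard
    bucket-based preprocessing of 1D serum spectra (alanine referencing,
    0.002 ppm bucketing over 9.0-0.5 ppm, water-region exclusion, Pareto
    scaling), region-integral metabolite quantification, a NIPALS OPLS-DA
    classifier with cross-validation, permutation testing and CV-ANOVA,
    score-trajectory stratification of weak treatment responders, the
    paired nonparametric test battery with median-ratio effect sizes, and
    Spearman correlation of metabolic change with clinical tumor response.
    A synthetic-cohort generator produces paired pre/post spectra with
    planted treatment effects, sex structure and weak-responder subgroups
    so that the whole pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
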