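Package: ldlrflow
Title: Functional Characterization Pipeline for LDLR Variants from Flow
    Cytometry and Western Densitometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for heterologous-cell functional assays of
    low-density lipoprotein receptor (LDLR) variants: simulation of
    event-level flow-cytometry data (transfection reporter, surface
    antibody label, pH-sensitive LDL uptake label, viability dye) and
    Western-blot band volumes; singlet/viability/positivity gating with
    fluorescence-minus-one thresholds; per-experiment normalization to a
    benign reference variant; Dixon's Q outlier screening and ANOVA with
    Dunnett's many-to-one post hoc test; four-level severity grading of
    surface expression, LDL internalization and receptor maturation;
    rule-based inference of LDLR variant classes; and assignment of the
    ACMG/AMP PS3/BS3 functional-evidence criteria used in familial
    hypercholesterolemia variant curation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mvtnorm,
    multcomp
Config/testthat/edition: 3
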