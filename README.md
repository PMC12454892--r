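# ldlrflow

Functional characterization of LDL receptor (*LDLR*) variants from
flow-cytometry and Western-blot readouts.

Pathogenic *LDLR* variants are the most common cause of familial
hypercholesterolemia (FH). Their effect is measured in receptor-deficient
CHO cells transiently transfected with a single receptor variant, via three
assays: cell-surface receptor expression (anti-LDLR antibody, flow
cytometry), LDL internalization (pH-sensitive LDL label, flow cytometry) and
receptor maturation (160 kDa mature vs 120 kDa precursor band on a Western
blot). `ldlrflow` implements the full analysis chain for that experimental
design, for lab scientists and variant curators who need reproducible,
testable processing of such assays:

* an **event-level simulator** of cytometer wells and densitometry lanes
  (log-normal channel mixtures with doublets, dead cells, 10–25%
  transfection efficiency, variant-specific effect sizes, day effects);
* the **gating chain** — singlets by `fsc_h/fsc_a`, viable cells by dye
  valley, transfected cells by a fluorescence-minus-one (FMO) quantile
  threshold on the reporter — and median fluorescence intensity (MFI)
  extraction;
* **normalization and statistics**: percent of the benign reference variant
  p.(Ala391Thr) within each experiment, Dixon's Q outlier screen
  (two-sided, α = 0.05), cross-experiment mean ± SD, and one-way ANOVA with
  Dunnett's many-to-one test against wild type, where the adjusted p-value
  is the two-sided multivariate-t probability with product correlations
  ρᵢⱼ = √(nᵢnⱼ/((nᵢ+n₀)(nⱼ+n₀))) computed by deterministic quadrature;
* **severity grading** into normal / gray zone / moderate / severe per assay
  (surface: >90 / 70–90 / 10–<70 / <10 %; internalization: >95 / 80–95 /
  40–<80 / <40 %; maturation ratio: >2.0 / — / 0.2–2.0 / <0.2);
* **class inference** combining the grades into LDLR variant classes
  (1, 2a, 2b/5, 3/4, reduced-protein, no defect) and **PS3/BS3**
  functional-evidence assignment (PS3 if either flow assay < 70%, BS3 if
  both > 90%);
* a built-in 26-variant panel (16 studied + 10 class controls) with
  published severities and percentages for fixture-mode classification.

## Worked example

Simulate a three-day experiment for a maturation-defective variant
(one-third surface expression, 12% mature protein — the profile of a
well-known class 2b/5 missense variant) alongside the benign reference and
wild type, then run the pipeline:

```r
library(ldlrflow)

panel <- list(
  variant_effect_profile("p.(Ala391Thr)"),   # benign reference
  variant_effect_profile("WT"),
  variant_effect_profile("p.(Val523Met)", surface_factor = 0.33,
                         mature_fraction = 0.12)
)
sim <- simulate_experiment(panel, n_experiments = 3, n_events = 10000, seed = 20)
run <- pipeline_run(sim$events, sim$densitometry)

run$results[, c("variant_id", "assay", "mean_percent", "sd_percent", "n_experiments")]
#>      variant_id           assay mean_percent sd_percent n_experiments
#> 1 p.(Ala391Thr)         surface        100.0      0.000             3
#> 2 p.(Val523Met)         surface         33.5      0.973             3
#> 3            WT         surface        100.1      1.453             3
#> 4 p.(Ala391Thr) internalization        100.0      0.000             3
#> 5 p.(Val523Met) internalization         73.7      1.669             3
#> 6            WT internalization        101.4      1.501             3
```

Surface expression comes back at 33.5% of the reference (the configured
factor was 0.33); internalization is markedly higher than surface (73.7%),
the saturating-uptake behavior this assay system shows. The reference has
exactly zero SD — it is 100% in every run by construction, which is why
Dunnett's test uses wild type as control:

```r
run$dunnett$surface
#>      variant_id estimate_diff t_value adjusted_p stars
#> 1 p.(Val523Met)         -66.6     -66   3.16e-07   ***
```

The maturation ratio recovers the configured 0.12/0.88 odds and grades
severe, and the combined call is a partial transport defect with strong
pathogenic functional evidence:

```r
run$maturation[run$maturation$variant_id == "p.(Val523Met)", c("ratio_mean", "ratio_sd")]
#>               ratio_mean ratio_sd
#> p.(Val523Met)       0.14    0.014

call <- run$calls[[which(sapply(run$calls, `[[`, "variant_id") == "p.(Val523Met)")]]
call[c("surface", "internalization", "maturation", "classes")]
#> $surface          "MODERATE"
#> $internalization  "MODERATE"
#> $maturation       "SEVERE"
#> $classes          "CLASS_2B_5"
run$assessments[[1]]$criterion
#> [1] "PS3"
```

Fixture mode skips the cytometry and classifies the built-in panel directly
from recorded values:

```r
res <- classify_printed_panel(ldlr_panel("studied"))
res$summary[c("n_both_defect", "n_class2", "n_deleterious", "n_ps3", "n_bs3")]
#> 13, 11, 14, 13, 1
```

## Package layout

* `R/simulate.R` — event-level and densitometry simulator, archetype
  profiles, CSV event-table I/O
* `R/gating.R` — singlet/viability/positivity gates, FMO thresholds, well
  summaries
* `R/statistics.R` — normalization, aggregation, Dixon's Q, Dunnett
* `R/densitometry.R` — band ratios and semiquantitative expression calls
* `R/classify.R` — severity grading, class inference, PS3/BS3, panel fixture
* `R/pipeline.R` — end-to-end driver, two-gate comparison, YAML config and
  JSON reports
* `vignettes/ldlrflow-methods.Rmd` — the model, its assumptions, parameter
  choices and limitations
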