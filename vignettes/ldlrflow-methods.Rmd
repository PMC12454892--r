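---
title: "Methods: simulating and analyzing LDLR functional assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing LDLR functional assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldlrflow)
```

## The assay system

Pathogenic variants in the LDL receptor gene (*LDLR*) are the most common
cause of familial hypercholesterolemia. Their functional impact is
conventionally assessed in a receptor-deficient heterologous cell line
(CHO-ldlA7) transiently transfected with a plasmid carrying one receptor
variant, using three readouts:

* **surface expression** — flow cytometry with a fluorophore-conjugated
  anti-LDLR antibody on live, non-permeabilized cells;
* **LDL internalization** — flow cytometry with LDL particles carrying a
  pH-sensitive dye that fluoresces only after endocytosis;
* **maturation** — Western blotting, comparing the ~160 kDa mature
  (Golgi-glycosylated) receptor band with the ~120 kDa ER precursor band.

Transfected cells are identified by a monomeric GFP-type reporter fused to
the receptor; gating on the reporter rather than on the antibody signal is
what lets the analysis see transfected cells that fail to deliver any
receptor to the surface. `ldlrflow` implements the complete analysis chain
for this design, plus an event-level simulator so that every stage is
testable without instrument data.

## The simulator

`simulate_events()` draws each event of a well as a mixture:

* a doublet with probability `doublet_fraction` (0.10): forward-scatter area
  about twice the height-matched singlet value, so its `fsc_h/fsc_a` ratio
  falls near 0.5, outside the singlet band;
* dead with probability `dead_fraction` (0.10): viability dye drawn from the
  high log-normal mode;
* transfected with probability `transfected_fraction` (0.15, the middle of
  the 10–25% efficiency range typical of PEI transfection of CHO cells).

All fluorescence populations are log-normal — the standard working model for
cytometry channels; the true distributions for this assay are not published.
For a transfected live cell in a surface well, the surface-label median
scales with `expression_factor × surface_factor` and a shared per-experiment
day factor (log-normal, `experiment_scale_sd` = 0.15 — day-to-day variation
in absolute intensity is a stated feature of the assay, with no published
magnitude; the pipeline must cancel it regardless of its size). With
probability `surface_negative_fraction` a transfected cell instead shows
background only, producing the bimodal phenotype observed for one
binding-domain variant where up to 45% of transfected cells carried no
surface receptor.

The surface-label spread among transfected cells is `sdlog = 1.0`. This
value is pinned by the published two-gate comparison: with 45% of
transfected cells at background, the mixture median sits at roughly the 9th
percentile of the positive subpopulation, and reproducing the observed
reporter-gated median (about a quarter of the benign control) requires a
log-SD near 1. A spread this large is also what transient transfection
produces in practice, because per-cell plasmid copy number varies over
orders of magnitude.

Uptake in an internalization well follows

$$\mathrm{rel}(s) \;=\; u_b + (1 - u_b)\, b \,
  \frac{1 - e^{-k s}}{1 - e^{-k}},$$

where \(s\) is the cell's surface-receptor level relative to the reference,
\(b\) the binding/internalization efficiency, \(u_b\) = `uptake_background`
(0.20) the receptor-independent uptake, and \(k\) = `uptake_saturation_k`
(3.0). Two observed features motivate this form. First, variants with
near-zero surface receptor still internalized 10–37% of the reference —
receptor-independent uptake is one published explanation, and it is the one
modeled; the alternative compensatory mechanisms that have been hypothesized
are not. Second, internalization percentages systematically exceed surface
percentages; a saturating response reproduces this (k = 3 makes a variant
with ~33% surface show ~66% relative uptake, matching the printed pair 33%
surface / 67% internalization for one well-characterized missense variant).

Nonspecific antibody binding is a 1.3× multiplier on the surface-background
median for stained cells without receptor; under the default 0.999 FMO
quantile this leaves ~0.5% of viable singlets of a receptor-free well above
the surface threshold, consistent with the observed "<1% of cells in the
LDLR+ gate".

Densitometry lanes scale a base volume by `expression_factor` with a large
total-volume noise (`sdlog` 0.25: lysate amount and transfection efficiency
vary, and cancel in the band ratio) and split it into mature and precursor
bands by `mature_fraction` with a tighter partition noise (`sdlog` 0.08,
giving a ratio CV near the printed 1.33 ± 0.14). A truncated product appears
as a single band.

What the simulator does **not** emulate: spectral spillover (channels are
assumed compensated), instrument noise beyond the log-normal model,
autofluorescence correlations between channels, cell-cycle or size effects
on expression, and any image-level features of blots. Tests passing on
simulated data therefore validate the analysis logic and its calibration
behavior, not instrument-specific artifacts.

## The gating chain

`summarize_well()` applies singlets → viable → reporter-positive and takes
the median of the analysis channel:

* **singlets**: `fsc_h/fsc_a` within `[0.75, 1.25]` (the published analysis
  shows only the plot type; the band is symmetric around the singlet line
  and excludes area-doubled doublets); zero-area events are excluded as
  undefined.
* **viability**: events below the valley between the two largest modes of
  the dye distribution (no threshold value is published); a unimodal well is
  left intact, and a manual threshold in `gating_config()` is honored
  exactly.
* **positivity**: strictly above the 0.999 quantile of the gated FMO
  control (`derive_fmo_threshold()`). The FMO design is published, the
  quantile is not; 0.999 keeps the expected false-positive fraction at 0.1%
  of gated events. Ties at the threshold are negative, matching "gate for
  positivity" semantics.

The median is the exact sample median (mean of the central pair for an even
count). For surface wells the summary also records the MFI under the
alternate gate (positivity on the surface label itself) and the fraction of
reporter-positive cells that are surface-positive; `fig4_comparison()`
packages the two-gate contrast that explains why antibody-based gating hides
a surface-negative subpopulation.

## Normalization and statistics

Within an experiment, replicate wells are averaged per variant and converted
to percent of the benign reference p.(Ala391Thr) measured in the same run
(`percent_of_reference()`); absolute MFIs are never compared across days.
Per-experiment percentages are screened per variant and assay with Dixon's Q
test (`dixon_q()`, two-sided α = 0.05, at most one removal), then averaged
across ≥3 experiments with a sample SD (`aggregate_experiments()`).

Because the reference is exactly 100% in every experiment, it carries no
variance and cannot serve as the statistical control; the wild-type receptor
fills that role. `anova_dunnett()` pools the error variance across all
variants of an assay (mirroring the per-assay presentation of the published
analysis) and adjusts the many-to-one comparisons with the two-sided Dunnett
distribution: the multivariate t with product correlations
\(\rho_{ij} = \sqrt{n_i n_j / ((n_i+n_0)(n_j+n_0))}\) (½ when balanced),
evaluated by conditioning on the common normal factor (48-node
Gauss–Hermite) and the chi-distributed scale (adaptive quadrature). The
integration is deterministic; the test suite cross-checks it against an
independent multivariate-t implementation, the single-comparison t-test
degeneracy, and a Monte Carlo familywise-error simulation.

Dixon's Q uses the conventional statistic ladder (r10 for n ≤ 7, r11 for
8–10, r21 for 11–13, r22 for 14–30) with the two-sided α = 0.05 critical
values embedded as constants.

## Severity grading and class inference

Each assay is graded into four levels (`grade_surface()`,
`grade_internalization()`, `grade_ratio()`):

| assay | normal | gray zone | moderate | severe |
|---|---|---|---|---|
| surface (%) | > 90 | 70–90 | 10–<70 | < 10 |
| internalization (%) | > 95 | 80–95 | 40–<80 | < 40 |
| maturation ratio | > 2.0 | — | 0.2–2.0 | < 0.2 |

Boundary conventions matter clinically and are fixed as: exactly 90% surface
is gray (a variant at exactly 90% was denied the benign-evidence criterion);
exactly 70% is not a functional defect (the criterion reads "below 70%");
the internalization moderate band is closed at 40 and open at 80. The
published 1.0–2.0 ratio range is acknowledged as hard to interpret; this
package deliberately does not subdivide the 0.2–2.0 band.

`infer_classes()` combines the grades in a fixed rule order: truncated-only
protein → class 1 (with an NMD caveat: intron-less expression constructs
cannot trigger nonsense-mediated decay, so in vivo the protein would likely
not be made at all); faint/absent protein with a surface defect → reduced
protein levels (not a transport class); severe surface defect with normal
protein → class 2a, moderate → class 2b/5 (maturation and recycling defects
are not separable by these assays); internalization at least one severity
rank worse than surface adds class 3/4 (binding vs internalization is not
separable either — location-based arguments may be recorded as notes but
never change the call). The gray zone ranks 0.5 so that a gray-surface,
normal-internalization variant neither triggers the class-3/4 rule nor
counts as defective. One known consequence: a control variant curated in the
literature as class 2b+5 but showing <10% surface in this assay system comes
out class 2a — the rules classify what the assays measure, not the
literature consensus.

`assign_ps3_bs3()` applies the functional-evidence cutoffs: PS3 if either
flow assay is below 70%, BS3 if both are above 90% (surface) / above 90%
(internalization); exactly at a cutoff qualifies for neither, and the two
criteria are mutually exclusive by construction. Whether the maturation
ratio alone could trigger PS3 is not specified by the criterion text, so it
does not here. Final clinical classification is out of scope: it requires
evidence beyond the functional study, so the result carries an advisory
only.

## The built-in panel

`ldlr_panel()` ships 26 variants: 16 studied plus 10 class controls, with
severity levels, semiquantitative expression calls, prior classifications,
and percent values. Percentages that were individually published are tagged
`reported` in the source columns; the remainder are mid-band placeholders
tagged `estimated`, chosen once to be consistent with the reported severity
level and never used where a published number exists.
`classify_printed_panel()` reruns grading, class inference and criterion
assignment on this panel; on the 16 studied variants it reproduces the
published tallies (2 without defect, 13 defective in both flow assays, 11 in
class 2a/2b5 of which 4 also flagged class 3/4, 14 deleterious overall,
13 PS3 / 1 BS3 / 2 below thresholds).

## Problem sizes and numerical choices

The test suite runs the full pipeline — simulate, gate, normalize, screen,
grade, infer — on 20 simulated variants per class archetype (benign, 1, 2a,
2b/5, 3/4) at 4,000 events per well and 3 experiments; 4,000 events keep a
five-archetype sweep comfortably interactive while leaving ~500 gated
transfected cells per well, enough for a median SE of a few percent.
Production-scale wells (40,000 events) are used where single wells are
simulated, e.g. the nonspecific-binding calibration and the two-gate
comparison. The Dunnett familywise-error simulation uses 1,000 replicated
null panels of five groups of three.

Degenerate inputs are handled explicitly: empty event tables error; an
all-dead well returns an empty gate with a warning; a well with zero gated
events yields a flagged measurement that is excluded downstream; a zero
range defeats Dixon's Q (no outlier); a zero precursor band makes the ratio
undefined (`NaN`) rather than infinite; groups without variance make the
Dunnett p-value exactly 0 or 1 by the sign of the mean difference.

## Known limitations

* Class 3 cannot be distinguished from class 4, nor 2b from 5, by these
  assays; the package never pretends otherwise.
* The severity-to-class rules are deterministic and do not propagate the
  replicate SD; a variant whose mean sits near a band edge can flip levels
  between reruns of a noisy experiment (the gray zones exist precisely to
  absorb most of this).
* The simulator's defaults are calibration choices where no published value
  exists (fluorophore distributions, day-effect magnitude, the mechanism of
  background internalization); conclusions about real instruments require
  real FMO and control wells.
* Splicing effects, polarized targeting, and structure-based adjudication
  are out of scope.
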