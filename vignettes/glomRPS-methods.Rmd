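---
title: "Methods: glomerular morphometrics and rule-based RPS classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glomerular morphometrics and rule-based RPS classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glomRPS)
```

## The problem

Diabetic nephropathy (DN) is graded pathologically from glomerular lesions.
The Renal Pathology Society (RPS) scheme assigns classes I, IIa, IIb, III and
IV from, essentially, three observable quantities: the fraction of globally
sclerosed glomeruli (GS), the presence of Kimmelstiel–Wilson (KW) nodular
lesions, and the width of the mesangial region. In routine practice these are
estimated visually and semi-quantitatively. glomRPS implements the
computational counterpart: given per-glomerulus lesion labels and
intraglomerular measurements (mesangial area, counts of the three intrinsic
cell types — mesangial cells, endothelial cells, podocytes), it aggregates
them per patient, derives data-driven mesangial cutoffs by ROC analysis, and
applies a fixed decision tree to produce RPS classes, together with the
statistics needed to evaluate such a system against pathologists and against
clinical outcome.

Because real annotated biopsy cohorts are not freely distributable, the
package also contains a synthetic-data module that generates every input the
pipeline consumes. All tests and the acceptance report run on synthetic data;
what that does and does not establish is discussed at the end.

## Morphometrics

A labeled glomerulus is an integer mask (0 background, 1 Bowman capsule,
2 tuft, 3 mesangial region, with region 3 a subset of the tuft) plus a table
of cell centroids typed as mesangial / endothelial / podocyte. Definitions:

* **Glomerular area** = (pixels coded 2 or 3) × `pixel_size_um`². The Bowman
  capsule ring is excluded. This same area is the denominator of every cell
  *density*. The source material never pins down the density denominator;
  tuft area is the natural reading and is used throughout.
* **Mesangial area fraction** `Mf` = mesangial pixels / tuft pixels.
* **Counts, densities, ratios**: counts are tallies of the centroid table;
  ratios are fractions of all intrinsic cells; *mesangial area per mesangial
  cell* is mesangial area / mesangial cell count.
* Quantities with a zero denominator are `NA` ("undefined"), never 0 — a
  glomerulus with no counted mesangial cells has an undefined area-per-cell,
  not a zero one.
* Areas are pixel counts; no sub-pixel contour integration. Coordinates are
  1-based `(row, col)`, the R convention.

A profile is a **midsection** cut when it shows ≥ 50 intrinsic cells in
total. Patient-level aggregation computes lesion-type percentages over *all*
glomeruli but intraglomerular means only over midsection KW and NOA ("none of
the above") glomeruli, each weighted equally; whether equal or area weighting
was used upstream is not documented, so equal weighting is implemented and
flagged here. A patient with no midsection KW/NOA glomerulus gets explicit
`NA` means and is excluded from cutoff fitting and reported unclassifiable
(never silently defaulted) if the early-class rule would need the feature.
**Mild mesangial expansion** is `Mf < 0.2596`, the 95th-percentile bound of
early-class expansion; the inequality is strict.

## Classification

The decision order is fixed:

1. percent GS **> 50 %** → class IV (exactly 50 % falls through);
2. otherwise, any KW glomerulus → class III;
3. otherwise one mesangium feature `x` (patient-level mean mesangial area,
   mesangial area fraction, or mesangial area per mesangial cell — the three
   features with the strongest early-class AUCs) decides:
   `x < c1` → I, `x < c2` → IIa, else IIb.

`c1` and `c2` come from ROC curves on pathologist-classed patients restricted
to classes I–IIb. Three early classes cannot be split by one threshold, so
two splits are fitted; the default is one-vs-rest on the ordinal scale
(I vs IIa∪IIb, and I∪IIa vs IIb), with adjacent-pair splits selectable. Each
cutoff maximises Youden's J = TPR − FPR ("optimal cutoff" is not otherwise
specified in the source material; Youden is the standard reading), placed
midway between the two score values it separates, ties broken toward the
smaller cutoff. If the two cutoffs violate the ordinal order they are swapped
with a warning; an AUC ≤ 0.55 triggers a degenerate-cutoff warning. The
fitted AUC here equals the Mann–Whitney probability of correct ranking (ties
half-weighted) — an identity the tests verify against a brute-force pairwise
count.

## Evaluation metrics

Per-class metrics are one-vs-rest on the confusion matrix — only that reading
yields a distinct accuracy, specificity and precision per class
simultaneously, which is how published DN evaluation tables are laid out. F1
is the harmonic mean of precision and recall; undefined ratios propagate as
`NA`. Report output is conventionally rounded to 3 decimals (round half to
even). Dice is `2|A∩B|/(|A|+|B|)` with the both-empty case defined as 1
(perfect agreement on absence). `mean_dice()` reports both the pooled
per-pair mean and the unweighted mean of per-group means, because an overall
average over unequal groups depends on that choice and published overall
values are not always consistent with either reading.

## Agreement and prognosis statistics

* **Cohen's kappa**: unweighted (no weighting is ever specified upstream; a
  linear-weighted variant would be a different statistic). Both raters
  constant and equal gives `pe = 1` and an explicit undefined kappa.
* **Spearman correlation**: Pearson on average ranks; two-sided p from the
  t approximation on n − 2 degrees of freedom.
* **Comparing two dependent overlapping correlations** (one indicator
  correlated with two raters' classes on the same patients): the default is
  Dunn & Clark's z computed with the *backtransformed average* of the two
  Fisher-transformed correlations — the variant method-comparison work since
  the early 2000s recommends and that reference implementations label after
  that work. Plain Steiger averaging and Meng's method are selectable. The
  citation trail upstream names a methods-comparison paper, not a formula, so
  the chosen variant is pinned by simulation instead: its type-I error over
  5000 null replicates at n = 150 must lie in [0.04, 0.06] at α = 0.05
  (asserted in the acceptance suite).
* **eGFR slope**: OLS of eGFR on time, per patient, ml/min/1.73 m²/year.
* **Time-averaged proteinuria (TA-P)**: trapezoidal AUC of serial proteinuria
  divided by the span from first to last proteinuria measurement (the
  "follow-up period" is read per-indicator).
* **ESRD**: eGFR < 15 ml/min/1.73 m² or dialysis sustained ≥ 3 months, or
  transplantation (immediate). At visit resolution "sustained" means the
  criterion holds from a visit through a visit ≥ 0.25 years later, or holds
  at the final visit (censoring-adjacent — it cannot be contradicted). The
  event is dated to the first qualifying visit. Prognostic analyses retain
  patients with follow-up ≥ 1 month and baseline eGFR ≥ 30; ESRD enters the
  correlation table as a 0/1 indicator (time-to-event modelling is out of
  scope). Time is in years; 1 month = 1/12 year.

## The synthetic-data module

The generator states a world and the tests measure against it; its defaults
were fixed before the test outcomes were seen and are not tuned.

**Glomerulus images.** Disc tuft + annular Bowman capsule; the mesangial
region grows as random blobs inside the tuft, trimmed so the realized pixel
count equals `round(target × tuft pixels)` exactly (well within the ±0.05
contract). KW glomeruli plant one large nodular blob near the centre first
and default to fewer podocytes and more mesangium than NOA. Cells are points
(type + centroid) rejection-sampled at ≥ 2 px separation — all downstream
mathematics uses counts and locations only, so segmented cell bodies would
add nothing. `perturb_mask()` removes `round(f·s)` class pixels and adds the
same number from border dilations, making the perturbed-vs-original Dice
exactly `1 − f` — a closed-form oracle for the Dice machinery. Not emulated:
PAS stain texture, anything photorealistic, whole-slide mosaics.

**Cohorts.** Each patient draws a planted class (default mix I .08, IIa .12,
IIb .15, III .45, IV .20 — biopsy-referred DN is late-class-heavy, and the
source cohort's mild-expansion accounting implies III+IV dominate), a
biopsy of ~62 glomeruli (Poisson), lesion types from a class-dependent
mixture (class IV GS-dominated; KW present only from class III), and
morphometric rows: patient-level `Mf` means (0.16, 0.22, 0.30, 0.36, 0.42 by
class, SD 0.02 between patients, 0.04 between glomeruli — the intra-patient
correlation of glomerular features is not documented anywhere, so the split
is an exposed parameter, not an assumption baked in), mesangial cell counts
rising with class (45→90), podocytes falling (60→28), endothelial flat (70).
17 % of glomeruli are "off-midsection" cuts with scaled-down counts, which
reproduces a realistic midsection yield (~83 % of KW/NOA).

Trajectories: baseline plus visits every 0.25–0.5 years (jittered) to a
uniform 0.25–4.9-year follow-up (mean ≈ 2.6 years); eGFR = class-dependent
baseline (105…55, SD 12) + planted slope × t + N(0, 4) noise, floored at 2;
proteinuria log-normal around a patient level drawn around the class median.
The planted class-wise eGFR-slope medians and TA-P medians are the published
class-wise values (−1.89, −1.65, −3.34, −11.60, −13.75 ml/min/1.73 m²/year;
0.73, 1.41, 1.60, 3.92, 5.08 g/24 h), with normal/log-normal spreads matched
to the published IQRs (SD = IQR/1.349). Note the published slope medians are
themselves *not* monotone (I vs IIa inverted by 0.24 against SDs of ~3–7),
and III vs IV differ by 2.15 against SDs > 11: no finite cohort of a few
hundred patients can reliably order those pairs, so ordering assertions treat
them as near-ties and require only early-block > IIb-floor > late-block. ESRD
arises mechanically when the simulated eGFR path crosses 15 and stays there.

**What a green test establishes.** That the measurement, classification and
statistical machinery recovers planted structure (kappa ≥ 0.8 end-to-end at
n = 300 with the default separation; monotone feature trends; calibrated
tests; exact oracle identities). It does *not* establish segmentation or
classification accuracy on real PAS histology — there is no texture, no
stain variation, no annotation noise — nor the published dataset-dependent
agreement (kappa 0.624) or Table-4 correlations, which require the original
cohort.

## Numerical choices and degenerate inputs

* All randomness flows from one user seed through a documented
  linear-congruential splitting scheme (`derive_seed`), so generators are
  bit-reproducible and mutually independent; the pipeline is byte-identical
  under identical config + seed (asserted).
* ROC thresholds are the unique score values plus a `+Inf` sentinel;
  reported cutoffs are midpoints so `score ≥ cutoff` reproduces the chosen
  operating point.
* Undefined statistics (kappa at pe = 1, Spearman on a constant vector,
  F1 at P + R = 0, slope with < 2 distinct times, TA-P with < 2
  measurements) are explicit `NA`s or typed errors, never silent defaults.
* Exact Mann–Whitney p-values for two untied groups of ≤ 20; normal
  approximation with continuity correction otherwise.
* CSV output is written at fixed precision (6 significant digits) so reruns
  diff clean.

## Known limitations

* The early-class cutoff fit requires every early class present; tiny cohorts
  can legitimately fail that precondition.
* Percent-type denominators include GS/SS/C glomeruli (all detected
  glomeruli), matching published percentage breakdowns that sum to ~100; if
  an upstream system restricted denominators, percentages would differ.
* Class III is "any KW glomerulus"; no minimum KW count is applied.
* The ESRD final-visit clause counts a criterion met at censoring as an
  event; with sparse visits this slightly over-calls events relative to a
  strict 3-month confirmation.
* eGFR is an input; no creatinine-based eGFR equation is included.
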