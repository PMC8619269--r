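---
title: "Screening alpha- vs beta-thalassaemia trait from reticulocyte cell population data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening alpha- vs beta-thalassaemia trait from reticulocyte cell population data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalscreen)
```

## The screening problem

Alpha- and beta-thalassaemia traits are heterozygous carrier states of the
alpha- and beta-globin genes. Both present as a mild microcytic,
hypochromic blood picture, and in regions where both are prevalent a
screening programme must decide which confirmatory route a microcytic
sample should take: beta-trait is confirmed by haemoglobin analysis
(elevated HbA2), while alpha-trait usually needs DNA testing. Routine
red-cell indices alone do not separate the two reliably.

Haematology analyzers additionally report cell population data (CPD):
per-population medians of cell volume, conductivity and light scatter at
several angles. The reticulocyte population's lower-median-angle light
scatter (MN-LMALS-RET) reflects the optical properties of the youngest red
cells and differs systematically between the two carrier states.

## The composite score and its classification rule

The package's central quantity is

$$ S = \text{MN-LMALS-RET} \times \text{RDW} - \text{MCH}. $$

The two factors elevated in beta-trait relative to alpha-trait
(MN-LMALS-RET, in analyzer channel units, and RDW, in %) multiply; the
index depressed in beta-trait (MCH, in pg) subtracts. `classify_score()`
calls beta-thalassaemia trait **strictly above** the cutoff (default
1742.5) and alpha-thalassaemia trait at or below. The tie at exactly the
cutoff goes to alpha because the cutoff table assigns beta only to values
strictly above the threshold; this is covered by a test. The score is
dimensionless in the sense that the channel units are arbitrary: calls are
invariant under a common positive rescaling of scores and cutoff.

Subjects enter the screening pathway through a red-cell-index pre-screen
(MCH < 27 pg, MCV < 80 fL, RDW > 14 %). The source list of criteria is
comma-separated and ambiguous between conjunction and disjunction;
`screening_config()` defaults to `"any"` (OR), the conservative reading
that misses fewer carriers, with `"all"` available. By default the
pipeline scores everyone and reports `screened_in` alongside, rather than
gating scoring on the pre-screen, so no subject silently disappears.

Seven classical discriminant indices (Mentzer, Shine & Lal, England &
Fraser, Ehsani, Srivastava, Green & King, RDW Index; formulas from the
original literature) are computed for comparison output only — their
published cutoffs target thalassaemia-vs-iron-deficiency, not
alpha-vs-beta, so they never drive calls here.

## ROC machinery

`empirical_roc()` uses candidate thresholds at the midpoints between
consecutive distinct score values, plus infinite sentinels; every
achievable operating point appears exactly once and the published cutoff
style (a half-unit between observed scores) arises naturally. The AUC is
the Mann–Whitney statistic — the probability that a random beta-trait
score exceeds a random alpha-trait score, ties half-credited — computed
from midranks, and equals the trapezoidal area under the ROC polygon
exactly (tie segments become diagonal chords that the trapezoid rule
bisects just as half-credit does; a property test asserts equality to
1e−12). If a marker runs the other way the orientation is flipped so the
reported AUC is at least 0.5, and the flip is recorded.

Confidence intervals come from DeLong's placement-based variance
(deterministic, the default) or a seeded within-class percentile bootstrap
(2000 replicates by default). A perfect separator has zero DeLong variance
and returns a flagged zero-width interval. Cutoff selection offers the
Youden rule (maximise sensitivity + specificity − 1) and
closest-to-top-left; ties are broken toward higher specificity, then
toward the lower threshold, so selection is deterministic. Tie detection
uses a 1e−12 tolerance so floating-point noise cannot mask a mathematically
exact tie.

Parameter shortlisting pairs each candidate channel's AUC with a two-sided
Welch t-test p-value and keeps parameters with p < 0.05 and AUC > 0.8.
Welch's unequal-variance form is used because the carrier groups have
visibly unequal spreads. No multiple-testing correction is applied — the
procedure mirrors a shortlisting step that applied none — and this is a
documented limitation rather than a recommendation.

## Diagnostic accuracy

`build_contingency()` cross-tabulates calls against condition with
beta-trait as the positive class; subjects whose calls are not evaluable
are excluded from the table but always counted in an exclusion report.
Sensitivity, specificity, PPV and NPV are exact ratios; display
percentages are rounded half-up to two decimals. The default interval is
the Wilson score interval, with Clopper–Pearson (via beta quantiles) and
Wald as alternatives; a dedicated test inverts the score test by grid
search at 1e−6 resolution for every numerator/denominator pair up to
n = 100 and confirms the closed form. Published intervals for these
statistics came from a web calculator whose method is not identifiable, so
the package compares point estimates only and treats its own intervals as
the reproducible ones.

## The synthetic cohort generator

No subject-level data are deposited for this problem; what is published
are per-group summary tables (n, mean, SD, median, min, max). The
generator turns those summaries into cohorts:

* **Marginal family.** Each parameter is drawn from a truncated normal.
  Two refinements matter. First, the printed min/max are finite-sample
  extremes, not distribution bounds, so truncation is applied one SD
  beyond them (`bound_pad = 1`): clipping exactly at the observed extremes
  biases the moments, and for some printed rows no distribution confined
  to the observed range can even attain the printed SD (the beta-trait MCV
  SD of 6.24 exceeds the uniform-limit SD, 5.95, of its printed range).
  Second, the parent mean and SD are *moment-matched* by a two-parameter
  Nelder–Mead solve so the truncated distribution reproduces the printed
  mean and SD essentially exactly; where a printed SD sits at the edge of
  what a truncated normal can reach, the closest fit is accepted provided
  the combined relative moment error stays below about 3 %. Printed
  medians are not matched — several parameters are visibly right-skewed —
  and this is an acknowledged approximation of shape, not of moments.
* **Score mode vs component mode.** The published summaries give no
  covariances, so independently drawn components would produce a composite
  score with the wrong spread. Score mode therefore draws the composite
  score directly from its published group distribution and back-fills
  components (RDW and MCH from their marginals, then
  `mn_lmals_ret = (score + mch) / rdw`), which makes `ab_score()`
  reproduce the drawn score to machine precision — the construction is
  covered by an identity test at 1e−9. Component mode draws all channels
  independently for workflows that need full records, with scores
  emergent.
* **Synthetic channel marginals.** The source publishes no distributions
  for the CPD channels themselves, only each channel's ROC cutoff and AUC.
  For the primary-cohort preset the alpha/beta `mn_lmals_ret` means
  (109.68 / 114.49) are derived from consistency with the published group
  score means, with a common SD of 3.04 chosen so the binormal AUC equals
  the published 0.868; the remaining channels are centred on their
  published cutoffs with SDs implied by their published AUCs. These
  marginals are synthetic and labelled as such; healthy-group channel
  values are placeholders that never enter the alpha-vs-beta analyses.
  Likewise, the RDW/MCH back-fill marginals for the HbE-trait, IDA and ID
  groups of the validation preset are not published; the preset uses
  realistic microcytic-spectrum values (HbE: MCH 25 ± 2 pg, RDW 15 ± 1.5 %;
  IDA: MCH 19.5 ± 2.5, RDW 18.5 ± 2.5; ID: MCH 26 ± 2, RDW 14.5 ± 1.5),
  chosen once and not tuned.
* **Data oddities.** The alpha-trait RBC row of the published summary
  prints SD 5.08 and median 0.59 against a mean of 5.15; the two cells
  are evidently transposed and the preset stores SD 0.59, median 5.08.

`binormal_auc()` supplies the closed-form oracle
$\Phi\!\left((\mu_+-\mu_-)/\sqrt{\sigma_+^2+\sigma_-^2}\right)$ used to
check the empirical ROC: score-mode cohorts drawn from the alpha/beta
score parameters with *untruncated* tails recover it to within ±0.01 at
n = 1000 per class averaged over 20 seeds. Truncated draws concentrate the
alpha tail and push the empirical AUC up to ≈ 0.90, which is why the
oracle comparison is defined on the untruncated parameters.

What passing these tests shows — and does not show. The generator
reproduces group-wise first and second moments and the composite-score
distributions, so ROC, cutoff and accuracy machinery are exercised under
realistic separations and sample sizes. It does not reproduce
inter-parameter correlation (beyond the score-mode construction), skewness,
analyzer drift, or pre-analytic effects (CPD channels are sensitive to
sample ageing), so passing tests here says nothing about performance on a
particular laboratory's instrument without local validation.

## Numerical and degenerate-input choices

* Quartiles use the type-7 (linear interpolation) convention throughout;
  the interquartile overlap report is plain interval arithmetic on
  [Q1, Q3] per group pair.
* Sample SDs use the n − 1 denominator; a single-value group reports an
  undefined SD with a note rather than an error.
* Parsing is locale-independent (decimal point); missing values are empty
  cells or `NA`, never 0 — zero is a legal channel reading.
* Out-of-bound rows are flagged at parse time but retained; each operation
  decides whether to exclude them (scoring excludes by default and reports
  the exclusions).
* All-identical scores yield a degenerate ROC (AUC 0.5, warning) and a
  median threshold from cutoff selection, with a warning.
* RNG: every stochastic function takes a `seed` and restores the caller's
  RNG state, so pipelines are reproducible without global side effects.
  Fixed seed implies byte-identical output tables; metadata sidecars carry
  no timestamps for the same reason.

## Problem sizes used by the test suite

The suite exercises the pair-count oracle on a thousand random instances
with class sizes up to 30, the binormal oracle at 1000 + 1000 subjects over
20 seeds, parameter recovery at 5000 per group, Wilson-interval inversion
for all numerators up to n = 100, and full five-group validation runs at
the published group sizes (310 subjects). These sizes give Monte-Carlo
error comfortably inside each stated tolerance while keeping a full test
run under a minute on a laptop.

## Known limitations

* The original development cohort (1394 healthy, 155 alpha-trait, 48
  beta-trait subjects) is not deposited, and its published per-parameter
  sensitivities/specificities imply denominators inconsistent with the
  stated class sizes; the package therefore re-derives cutoffs on
  synthetic or user cohorts rather than asserting those table cells.
* Interlaboratory validation text reports 65 alpha / 30 beta recruited
  while the 2×2 margins imply 67 / 28; the table is taken as
  authoritative because the four accuracy statistics reproduce from it
  exactly.
* MAF (microcytic anaemia factor) is treated as an input column and never
  recomputed; its defining formula is not published.
* The score's behaviour under concurrent iron deficiency is a known
  confound: the IDA score range overlaps beta-trait substantially (the
  overlap report quantifies this), and the screening pathway relies on
  routing suspected IDA down a different diagnostic branch.
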