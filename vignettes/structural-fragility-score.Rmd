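---
title: "The structural fragility score: model, assumptions, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The structural fragility score: model, assumptions, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfscore)
```

## The problem

Postmenopausal bone loss is global: unbalanced remodeling simultaneously
increases cortical porosity and decreases trabecular density. The absolute
value of either trait mixes this age-related deterioration with
growth-related peak structure, and an isolated deficit in one compartment
(high porosity with preserved trabecular density, or the reverse) is more
often a consequence of region-of-interest positioning or growth-assembled
canal void than of bone loss. A femoral-neck BMD T-score at the -2.5 SD
osteoporosis cut is highly specific but misses most women who fracture,
because most of them sit in the osteopenic or "normal" BMD range.

The structural fragility score (SFS) addresses this by measuring how far a
subject's *pair* of traits has moved from the premenopausal mean in the
direction that joint cortical-and-trabecular deterioration moves it.

## The geometric model

Work in the plane of cortical porosity $x$ (% of cortical volume) against
trabecular density $y$ (mg HA/cm^3^). Three reference objects are fitted:

* **O**, the centroid: the arithmetic means $(\bar x, \bar y)$ of a healthy
  premenopausal reference sample, with sample SDs $(s_x, s_y)$
  (n-1 denominator, the standard choice for reference work).
* **U**, the deterioration axis: the line through O whose slope is the
  *average of the per-subject slopes* from O to each member of a
  fracture-derivation cohort (postmenopausal women with fragility
  fractures). It points into quadrant IV — porosity up, density down.
* **Z**, the maximum-deterioration point: the point on U at the largest
  orthogonal projection of any fracture-derivation subject, i.e. the
  maximal observed deterioration.

A subject's coordinates decompose into the perpendicular distance $A \ge 0$
to U and the along-axis coordinate $\ell$ (projection onto U). With
$B = 100 - \ell$ the remaining distance to Z in score units,

$$\mathrm{SFS} = 100 - (A + B) = \ell - A,$$

so a subject at O scores 0, a subject at Z scores 100, and off-axis
displacement (trait dissociation, not bone loss) *lowers* the score. The
score is deliberately not clamped: values below 0 (better than reference,
or strongly dissociated traits) and above 100 (beyond Z) preserve the
ordering of severity. The sign of the perpendicular residual (cortical- vs
trabecular-dominant deficit) is returned as a `side` diagnostic but does
not enter the score.

### Standardization

Porosity (%) and density (mg HA/cm^3^) are not commensurable, so all
geometry — slopes, projections, the distances $A$ and $B$ — is computed
after centering at O and dividing by the premenopausal SDs. This is the
package's convention, adopted because it makes $A$ and $B$ unit-free and
the whole score invariant to affine unit changes of either trait (a
property the test suite checks to 1e-9); raw-unit geometry would make the
score depend on the arbitrary choice of units. The score scale is fixed by
mapping the standardized distance $|OZ| = \ell_Z$ to 100 score units.

### Numerical choices

* Per-point slopes $z_y/z_x$ with $|z_x| \le 10^{-8}$ (near-vertical rays)
  are excluded from the axis average and counted in a diagnostics record;
  at least two usable points are required.
* A fitted slope $\ge 0$ is an error rather than a warning: the method
  presumes quadrant-IV displacement of the fracture cohort, and a
  non-negative average slope means the derivation sample does not carry
  the deterioration signal the construction needs.
* Quadrant ties (a trait exactly at its reference mean) fall to the "low"
  side, so O itself is in quadrant III.
* Percentile thresholds use the linear-interpolation quantile at index
  $p/100\,(n-1)$ (R's `type = 7`), documented and fixed so cuts are
  reproducible across implementations.
* Frames serialize to YAML with 17 significant digits, making reloads
  bit-exact.

## Diagnostic evaluation

Subjects are classified positive in the deterioration direction of each
trait: porosity $\ge$ its cut (90th reference centile by default), density
$\le$ its cut (5th centile), BMD T-score $\le -2.5$ SD, SFS $\ge$ its cut
(90th reference centile). The reference population for percentile cuts is
the premenopausal sample; this is configurable. From the 2x2 table against
fracture status the package reports:

* sensitivity and specificity with exact (Clopper–Pearson) 95% CIs in the
  beta-quantile formulation;
* the cross-product odds ratio with the Woolf log-normal CI,
  $\exp(\ln \mathrm{OR} \pm 1.96\,\sqrt{\sum 1/n_{ij}})$, and a two-sided
  Wald p-value; an optional Haldane–Anscombe 0.5 correction handles zero
  cells;
* logistic regressions (`logistic_fit()`), used both as the crude-OR
  cross-check (a single binary predictor reproduces the cross-product OR)
  and for covariate adjustment.

"After accounting for the contribution of" the other predictor is
implemented two ways, because published summaries are consistent with
either reading: a joint logistic model containing both binary indicators
(`adjusted_logistic`), and reclassification, in which a subject positive on
the accounted-for trait is removed from the index trait's positives
(`adjusted_reclassified`). Reports label which was used. Published
before/after sensitivities and specificities behave like the
reclassification reading, and `reconstruct_table()` exists precisely to
invert such printed summaries (with half-away-from-zero rounding) back to
integer counts so the odds ratios can be recomputed exactly.

Replicate measurement precision is summarized as the root-mean-square
coefficient of variation across subjects (`rms_cv()`), the standard
precision metric for repeated HR-pQCT acquisitions.

## The synthetic cohort generator

No subject-level cohort is distributed with the package, so validation
rests on a generator whose structure makes the method's own assumption
literally true: deterioration is drift along a latent axis of slope
`axis_slope_true` in standardized space, plus orthogonal noise.

* **Premenopausal reference**: bivariate Gaussian, truncated to the
  physical ranges by redraw. Defaults — porosity mean 36%, SD 4; density
  mean 112, SD 30 mg HA/cm^3^; correlation -0.2 — are free parameters (no
  reference means are published for these traits); they were chosen so
  that, combined with the default drift, the *evaluation control arm*
  lands near published control medians (porosity ~39.5%, density
  ~86 mg HA/cm^3^): with drift 1 standardized unit/decade after 50 and
  ages uniform on 50–75, the median subject (62.5 y) drifts
  $1.25/\sqrt2 \approx 0.88$ SD in each trait.
* **Fracture-derivation cohort**: points *on* the latent axis at along-axis
  distance `fracture_ref_shift` (default 3) plus the age drift (ages
  50–90), with only orthogonal noise (SD 0.4) around the axis — no
  premenopausal-scatter component. This makes the mean of per-point slopes
  a consistent estimator of the latent slope; adding full subject scatter
  to a displaced cloud biases the ratio mean by $-\sigma^2/a^2$ (where $a$
  is the typical standardized $x$-offset), which at the default geometry
  would be a visible artifact of the ratio estimator rather than of the
  data.
* **Evaluation cohort**: premenopausal-style scatter plus age drift (with
  subject-level SD 0.5) plus orthogonal noise, a declining T-score
  correlated with the drift, and fracture assigned by
  $\Pr(\text{fracture}) = \operatorname{logit}^{-1}(\beta_0 + \beta_1
  \cdot \mathrm{SFS})$ with defaults $\beta_0 = -2.5$,
  $\beta_1 = 0.04$ per score unit (~12% base rate, a clearly positive
  association). Case–control studies sample without replacement to the
  99/105 quotas from batched draws.

Seeding uses one master seed with per-cohort derived streams, so each
cohort is independently reproducible and the generator never perturbs the
caller's RNG state.

### What the generator does and does not emulate

It reproduces the *statistical geometry* the method assumes — a coherent
deterioration axis, age-correlated drift, logistic fracture risk in the
score — so passing recovery tests shows the implementation is faithful to
the model, not that the model is true of real bone. It does not emulate
measurement error beyond one orthogonal noise term, longitudinal
trajectories, matching structure, or the skewness of real trait
distributions. One consequence of the standardized-SD geometry is that
synthetic SFS magnitudes sit lower than published cohort medians (~52 in
controls): with reference scatter of 1 SD and $\ell_Z \approx 7$
standardized units, typical evaluation subjects score well below 50, and
the perpendicular penalty makes the premenopausal *median* SFS negative
(about $-\mathrm{scale} \cdot 0.67$), not 0 — an unavoidable property of
$\mathrm{SFS} = \ell - A$ with $A \ge 0$. Cohort-level score medians are
therefore not calibration targets; the control-arm porosity and density
medians are.

## A worked example

```{r example}
cfg <- generator_config()
study <- generate_case_control(cfg, seed = 42)
study$frame

pre_scored <- cbind(as.data.frame(study$premeno),
                    score_cohort(study$premeno, study$frame)[-1])
ev_scored <- cbind(as.data.frame(study$evaluation),
                   score_cohort(study$evaluation, study$frame)[-1])
th <- thresholds_from_reference(pre_scored)
report <- evaluate_cohort(ev_scored, th, correction = TRUE)
report$sfs$odds_ratio
```

## Problem sizes used in validation

The shipped validation suite uses 5000/2000 reference draws for axis
recovery (slope within 0.05 of truth), 10^4^ subjects for logistic
recovery of the fracture slope (within 2 SE), 100 replicated 99/105
case–control studies for the power-style check (the SFS odds-ratio CI
excludes 1 in at least 90% of replicates under a strong effect,
$\beta_1 = 0.08$), and 10^4^ random frame/point pairs for the geometric
identities at 1e-9. These sizes keep every check comfortably inside
interactive run times while leaving Monte-Carlo error far below the
asserted tolerances.

## Known limitations

* The axis estimator is a mean of ratios, chosen as the most literal
  reading of "the average of all the slopes"; angle- or vector-averaging
  and total-least-squares alternatives are deliberately not the default
  and are not implemented.
* Z is the maximal *observed* projection of the derivation cohort, so
  `ell_z` (and with it the score scale) grows with derivation-sample
  extremes; a fixed anatomical bound would be an alternative reading.
* Matched-design (conditional) logistic regression and incident-fracture
  (survival) modeling are out of scope; the evaluation battery is
  unconditional.
* The score consumes already-extracted porosity and density values; image
  acquisition and segmentation are upstream of this package.
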