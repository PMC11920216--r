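---
title: "Fixation instability scoring from pupil-center plots: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixation instability scoring from pupil-center plots: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fixstab)
```

## The measurement problem

During excimer-laser refractive surgery the eye tracker samples the pupil
center (PC) at high frequency and steers each laser pulse accordingly. After
treatment the device prints a summary plot: every sampled PC offset is drawn
as a small blue square on a 6 x 6 mm tracking grid centered on the fixation
point. A calm, steadily fixating patient produces a tight blob of marks near
the center; an anxious, poorly fixating patient produces a large, scattered,
decentered pattern. The raw time-resolved trajectory is not exported, so the
plot's spatial mark pattern is the only tracker-derived signal available.

`fixstab` turns that pattern into numbers. Three morphometrics summarize a
plot:

* **SA (sum area)** — the union area of all marks, in pixels. Overlapping
  squares are counted once: SA is the number of mark pixels.
* **SP (sum perimeter)** — the summed boundary length of the connected
  *clusters* of marks (confluent squares form one cluster).
* **ACD (average centroid deviation)** — each cluster centroid's Euclidean
  distance to the grid center, weighted by cluster area and averaged:
  `sum(area_i * dist_i) / sum(area_i)`. Large clusters dominate, so ACD
  measures where the bulk of fixation actually sat.

These combine linearly into the **Fixation Instability Score**

```
FIS = 0.005 * SA + 0.027 * SP + 0.213 * ACD + 4.458
```

banded on a 0–90 scale: **normal** for FIS <= 12, **borderline** for
12 < FIS <= 36, **case** for FIS > 36 (integer bands 0–12 / 13–36 / 37–90).
The coefficients are a fixed calibration against the anxiety sub-scale of the
Hospital Anxiety and Depression Scale (HADS: seven items scored 0–3, summed
to 0–21, banded <= 7 / 8–10 / 11–21) and are stored as configuration
constants (`fis_coefficients()`), not literals, so the score can be
recalibrated on another device.

```{r fis-basics}
compute_fis(plot_params(sa = 490.5, sp = 110, acd = 12.08))
score_hads(c(1, 1, 1, 1, 1, 1, 2))
```

## Image measurement pipeline

`detect_marks()` classifies pixels against a configurable hue/saturation/
value band (default: saturated blue, hue in [0.5, 0.83], s >= 0.5,
v >= 0.3). The device's exact mark RGB is not published and it is unknown
whether marks carry borders in a second color, so the band is a parameter
rather than a constant; anything matching the band *outside* the tracking
square (axis labels, legends) is discarded. An image with zero mark pixels
is a valid plot — perfect fixation — and returns an empty mask with a
warning flag rather than an error; its FIS is the intercept 4.458 (normal),
the most conservative reading.

`extract_clusters()` labels connected components. The default connectivity
is 8 (diagonally touching squares visually read as one island), switchable
to 4. Perimeter is the **boundary-edge count**: the number of pixel edges
separating mark from non-mark. This city-block contour makes fixtures
analytic — an s x s square has perimeter exactly 4s for every s — whereas a
polygonal arc length would not; no published contour metric exists to match,
so the exactly testable one is used. Centroids are unweighted means of
member pixel coordinates; coordinates are image row/column with origin
top-left.

### Units and the reference scale

SA, SP and ACD are pixel quantities, and published score magnitudes (SA in
the hundreds to thousands over a 6 mm square, ACD up to ~98) are only
consistent with a plot rasterized at roughly 100 px/mm. The device's native
resolution is not stated, so the package fixes a **reference scale** of
100 px/mm (`reference_px_per_mm()`, configurable via
`options(fixstab.reference_px_per_mm = ...)`); images at other resolutions
should be rescaled to the reference before measurement so scores are
comparable. The tracking grid itself is described by a `tracking_grid`
(center pixel, px/mm, half-extent 3 mm), supplied per image via a sidecar
CSV (`ingest_directory()`).

## The synthetic cohort generator

No real plots can be redistributed, so every downstream stage is exercised
against synthetic cohorts with analytic ground truth (`sample_cohort()`).
The generative model:

* **Dwell model.** Each subject has a number of dwell positions; each dwell
  is rendered as one mark square (default side 5 px). Dwell centers are
  drawn i.i.d. from an isotropic Gaussian with class-specific dispersion and
  a mean offset, truncated to the tracking square. Because the device plot
  discards time ordering, only the spatial distribution of marks matters —
  a time-correlated trajectory would change nothing measurable here, which
  is why independent draws suffice (saccade dynamics, microsaccades and
  tracker latency are deliberately out of scope).
* **Class conditions** (chosen once, as study conditions): dwell counts
  20–40 / 30–60 / 50–100, dispersions 10 / 18 / 26 px and bias vectors
  (6,−4) / (12,−8) / (18,−12) px for normal / borderline / case. These place
  default cohorts in the order-of-magnitude ranges observed on real plots
  (SA medians ~500–1700 px², SP ~100–1200 px, ACD ~13–38 px) with the
  dispersion ordering that drives every class-monotone property. Laterality
  alternates right/left, and the horizontal bias is mirrored for left eyes
  to emulate the nasal/temporal asymmetry of real decentration maps.
* **Covariates.** HADS items are uniform on {0..3} rejected into the
  subject's class band; cooperation VAS and five heart-rate time points
  (baseline, start, flap, ablation, end) are Gaussian with class-conditional
  means following the monotone severity ordering of real cohorts (ablation
  peak in the case group); break counts are Poisson with class-increasing
  rates. Exact covariate parameters are free choices — they only need the
  qualitative ordering.

Ground truth is **analytic**: `analytic_parameters()` computes (SA, SP, ACD)
from the square corner coordinates alone, clustering squares by
rectangle-interval adjacency and enumerating each cluster's pixel union
exactly — no rendering, detection or component labeling involved. The
invariant `image pathway == analytic oracle, bit-exactly` is asserted per
subject in the test suite and over 201 subjects in the acceptance checks.

What passing these tests does **not** show: robustness to anti-aliased or
JPEG-compressed marks, gridline colors inside the mark band, borders drawn
around mark squares, or non-square marks. Real plots exercised through this
package should be visually spot-checked against the detected masks
(`write_mask_png()`).

```{r cohort}
cfg <- synthetic_config(n_per_class = 30, seed = 1)
tab <- score_subjects(cohort_table(sample_cohort(cfg)))
aggregate(cbind(sa, sp, acd, fis_raw) ~ class, tab, median)
```

## Evaluation machinery

`evaluate_all()` reproduces the evaluation battery on a scored cohort:

* **Per-parameter classifiers.** Each of SA, SP, ACD and FIS is a scalar
  feature; a soft-margin linear SVM on the standardized feature (a threshold
  rule, in effect) is trained on a stratified 70 % partition and scored on
  the remaining 30 %. All four features share one split so their test scores
  are paired. The kernel is configurable but linear by design: a 1-D margin
  is what a single-parameter classifier is.
* **One-vs-one ROC.** For each unordered class pair, AUC is reported with
  each class as positive plus the pair mean; the macro-mean averages pair
  means. AUC is computed by the Mann–Whitney equivalence with tie kernel
  1/2, and its standard error by the Hanley–McNeil formula
  (`Q1 = A/(2−A)`, `Q2 = 2A²/(1+A)`).
* **DeLong comparison.** Paired AUC differences use DeLong structural
  components (per-positive and per-negative means of the concordance
  kernel), an unbiased component covariance, `z = ΔAUC/SE` and a two-sided
  normal p — two-sided because no directional hypothesis is stated for any
  pair. Identical scores are reported as a degenerate comparison with
  `ΔAUC = 0, p = 1` rather than 0/0. The tie kernel (1/2) matches the
  midrank ROC so `delong_compare` and `roc_auc` agree identically.
* **Youden cutoffs.** `youden_cutoff()` scans midpoints of adjacent distinct
  scores plus sentinels beyond the extremes, maximizing
  `J = sensitivity + specificity − 1` under the rule "positive when
  score > threshold", ties broken toward the lower threshold. Cutoffs for
  normal-vs-borderline and borderline-vs-case are computed on raw
  (unrounded) FIS; on integers the two conventions agree.
* **Spearman matrix.** Tie-corrected rank correlations with two-sided
  p-values and a significance-filtered copy (entries with p > 0.05 masked);
  constant columns yield masked, not raised, correlations.

The published clinical AUCs, correlations and cutoff values depend on the
original (unavailable) patient cohort and are *not* targets: the synthetic
defaults reproduce orderings and structure (FIS macro-AUC dominating each
single parameter, strong FIS–HADS rank correlation, monotone class medians),
not the clinical point estimates.

## Average position maps

`average_class_map()` averages the binary masks of a class/eye-side group
into a per-pixel frequency map; brighter pixels are more commonly occupied
PC positions, and the map's area-weighted centroid offset summarizes group
decentration. The plain frequency map is the primary estimator.
`pca_denoise()` is an optional interpretation — masks projected onto the
top-k principal components before averaging — because the role PCA played in
producing the original maps is under-specified; with full rank it reproduces
the frequency map (asserted to 1e-8), and its reconstruction error is
non-increasing in k. Maps are written as lossless PNGs with the 16-bit
frequency split across two 8-bit channels (`write_map_png()` /
`read_map_png()`).

## Numerical choices and degenerate inputs

* `fis_scale` rounds half-up before clipping to [0, 90]; published integer
  scores state no rounding rule, and half-up keeps band boundaries aligned
  with the inequality convention.
* Class boundaries use the inequality form (<= 12, <= 36) rather than the
  integer phrasing; the two agree on integers and the inequality form is
  what the cutoff analysis states.
* Empty plots: SA = SP = ACD = 0 by convention, flagged, FIS = intercept.
* Constant features, single-class partitions, mismatched score lengths and
  mixed mask geometries raise immediate, specific errors; a zero-variance
  DeLong difference is flagged degenerate instead of dividing by zero.
* One open question is left open: real plots report a FIS minimum of 0
  although the formula's minimum is its intercept 4.458, implying some
  upstream truncation or rescaling that is not documented; the package
  reports the formula value and does not guess.

## Problem sizes

The test suite and acceptance checks run on deliberately modest sizes chosen
as sufficient for the properties asserted: bit-exact parameter recovery over
201 rendered subjects, cohort-level orderings at 100 subjects per class,
Monte-Carlo chance-level checks at n = 900–2000, a 10^5-resample bootstrap
oracle for the DeLong variance on a 6+6 instance, and exhaustive enumeration
of all 4^7 HADS item vectors.

## Limitations

* The pixel↔mm scale behind published score magnitudes is an inference;
  cross-device comparability requires rescaling to the reference resolution.
* The FIS coefficients are taken as given; they cannot be re-derived here
  because the calibration cohort is unavailable.
* The synthetic generator models spatial dispersion only; it is not a
  simulator of oculomotor behavior and carries no cyclotorsion, which the
  device plots themselves omit.
* HADS depression items, group-comparison hypothesis testing of baseline
  tables, and parsing of proprietary PDF treatment reports are out of scope;
  the supported interface is raster plots plus a CSV sidecar.
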