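---
title: "Methods: CT texture analysis of solid pulmonary nodules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT texture analysis of solid pulmonary nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noduletex)
```

## The problem

A solitary pulmonary nodule (SPN) is a mass of at most 3 cm surrounded by
normal lung. Many SPNs found incidentally on chest CT are *indeterminate*:
neither clearly benign (calcified, fat-containing) nor clearly malignant
(spiculated, growing). For such nodules the practical benign label is
radiological stability — essentially no growth over years, operationalised
through the volume doubling time (VDT): a nodule is considered stable when
it does not grow or its VDT exceeds 2,000 days.

`noduletex` implements a first-order texture analysis of the nodule's CT
density histogram that asks whether the *distribution* of Hounsfield-unit
(HU) values over the segmented nodule volume separates stable-benign from
malignant nodules: malignant nodules tend to concentrate density in a
narrow soft-tissue band around 0–100 HU (a histogram "peak"), while stable
benign nodules spread density more evenly (a "plateau").

The pipeline is: seeded 3D region-growing segmentation → subtraction of
attached structures → HU histogram of the nodule volume → first-order
statistics (mean, variance, skewness, excess kurtosis) → peak/plateau
shape classification → diagnostic evaluation (ROC/AUC, cut-offs, 2×2
table, two-reader ICC). A calibrated synthetic phantom generator stands in
for patient data so that every stage is testable end to end.

## Segmentation model

`region_grow_3d()` grows the maximal connected set of voxels reachable
from a seed voxel through voxels whose HU lies in the inclusion interval,
by default $[-450, +1500]$ HU with **both endpoints inclusive** (the
interval is stated without openness in the protocol it reproduces;
inclusivity is documented and tested). The lower bound excludes aerated
lung (≈ −800 HU), so growth stops at the nodule boundary; the upper bound
admits soft tissue and calcification.

Numerical and design choices:

* **Connectivity** defaults to 6 (face-adjacent). The source protocol does
  not state a connectivity; face adjacency is the conservative choice with
  the fewest leak paths. 26-connectivity is available by flag.
* **Coordinates** are 0-based $(x, y, z)$ with $z$ the slice axis; masks
  share the source lattice frame.
* **`slice_range`** is half-open $[\mathrm{first}, \mathrm{last})$ in
  slice indices, matching a "number of slices" dialog while avoiding
  off-by-one ambiguity. It must contain the seed slice.
* **Structure subtraction** takes an explicit exclusion lattice (vessels,
  bronchi, scars) rather than reproducing an interactive editor; after
  subtraction only the connected component containing the seed survives.
  An optional morphological opening (6-neighbour ball, radius 1 voxel) can
  shave thin attachments automatically; it is off by default because the
  workflow it mirrors is interactive, not algorithmic.
* Determinism: the grown mask is a set union over BFS layers, so the
  result is independent of visit order.

Volumetry is plain counting: $V = N \cdot d_x d_y d_z$ mm³, and
$\mathrm{VDT} = \Delta t \cdot \ln 2 / \ln(V_2/V_1)$ days, reported as
infinite (stable) when $V_2 \le V_1$.

## First-order statistics

The nodule histogram uses unit-width HU bins over the inclusion interval,
half-open $[e, e+w)$ except the last bin, which includes its upper edge.
For integer HU at unit width, the bin representative equals the HU value,
so the histogram route and the direct voxel route (`stats_from_voxels()`)
agree *exactly*; this dual-path identity is tested. With $H(i)$ the
normalised frequency and $c_i$ the bin representative:

$$\mathrm{MEN} = \sum_i c_i H(i), \qquad
  \mathrm{VAR} = \sum_i (c_i - \mathrm{MEN})^2 H(i)$$

$$\mathrm{SKW} = \frac{\sum_i (c_i - \mathrm{MEN})^3 H(i)}{\mathrm{VAR}^{3/2}},
  \qquad
  \mathrm{KUR} = \frac{\sum_i (c_i - \mathrm{MEN})^4 H(i)}{\mathrm{VAR}^{2}} - 3$$

Variance is the population form — the sums run over the complete voxel
population of the nodule, so no small-sample correction applies. KUR is
*excess* kurtosis: 0 for a Gaussian, positive for a peaked, heavy-tailed
(leptokurtic) distribution, negative for a flat-topped (platykurtic) one,
with the universal bounds $\mathrm{KUR} \ge \mathrm{SKW}^2 - 2 \ge -2$.
Typeset versions of these formulas sometimes show the denominators as
$\mathrm{VAR}^3$/$\mathrm{VAR}^4$; we read that as corruption of the
standard standardised moments (the verbal description — positive KUR means
a peak with heavy tails, negative a flatter-than-Gaussian peak — is
exactly excess kurtosis). The literal printed exponents remain available
behind `skewness(h, literal = TRUE)` / `kurtosis(h, literal = TRUE)` for
audit. Zero-variance nodules raise an error rather than returning NaN,
so degenerate inputs fail loudly and testably.

## Peak versus plateau

The original dichotomy was assigned visually. To make it reproducible the
package uses an explicit rule (`classify_shape()`): smooth the frequencies
over the occupied HU range with a centred moving average (default window 5
bins, reflection padding so edge bins are not deflated), then compute

$$\mathrm{peakedness} = \frac{\max(\text{smoothed})}{\text{mean}(\text{smoothed})} \ge 1,$$

and label the histogram *peak* iff peakedness ≥ threshold. The threshold
default of **5.0** was chosen by calibrating on the default phantom
cohorts so that the induced 2×2 table reproduces the reference operating
point (84% sensitivity, 74% specificity) of the visual classification; it
is exposed as a parameter, and the decision is monotone (raising the
threshold can only move labels from peak to plateau). An alternative rule
(`rule = "kurtosis-sign"`: peak iff KUR > 0) is provided because the
dichotomy is sometimes equated with leptokurtic/platykurtic; on realistic
cohorts both classes are leptokurtic on average, so that rule labels
nearly everything peak — one reason the explicit ratio rule is the
default. The two rules bracket the plausible readings of the visual
protocol.

## Diagnostic evaluation

* **ROC** places thresholds at the distinct observed scores; tied scores
  shared by both classes produce diagonal segments. The trapezoidal area
  equals the tie-corrected Mann–Whitney statistic (tied pairs count ½);
  the suite verifies this identity on a thousand random tied instances and
  against an independent ROC implementation.
* **Cut-off selection** maximises the Youden index; exact ties are broken
  toward higher specificity (a benign-sparing screen — the clinical cost
  of a false malignant call on a stable nodule is an unnecessary invasive
  work-up). The published reference cut-offs (KUR > 6, SKW > 3.1, strict
  inequalities) are stored separately (`published_cutoffs()`) and never
  conflated with data-derived cut-offs.
* **2×2 statistics** are exact integer quotients; a zero denominator
  raises an error naming the undefined ratio.
* **ICC** between two readers defaults to ICC(2,1) — two-way random
  effects, absolute agreement, single measures — because readers are
  treated as a random sample of possible readers and systematic offsets
  should count against agreement. The consistency variant ICC(3,1) is a
  flag. Agreement is called acceptable at ICC ≥ 0.85.

## The synthetic phantom generator

Phantoms replace patient data. Each phantom is a cropped ROI lattice
(default 44 × 44 × 30 voxels at 0.75 × 0.75 × 1.0 mm — the in-plane
spacing of a 512-matrix chest reconstruction, 1 mm slices):

* **Background**: Gaussian noise around −800 HU (aerated lung), clamped
  below −550 HU. Because the background can never enter the inclusion
  interval, segmentation of the phantom is exact *by construction* — the
  grown mask equals the ground-truth lattice voxel for voxel, which the
  suite asserts. This deliberately separates segmentation correctness
  from texture statistics.
* **Nodule**: a smooth ellipsoid (radius 4.5–10.5 mm in cohorts; spherical
  in mm, hence ellipsoidal in voxels). Spiculated or lobulated shapes are
  *not* generated: the study design excluded them, and the shape of the
  mask does not enter first-order statistics.
* **Vessel**: optionally (p = 0.5) a cylindrical stub of radius 1.5 mm at
  60 HU attached to the nodule surface — inside the inclusion interval,
  so region growing leaks into it and structure subtraction is genuinely
  exercised.

**Voxel-intensity family.** Nodule HU values are drawn i.i.d. from a
two-component mixture in a dimensionless frame, mapped to HU by an affine
location/scale: a symmetric generalized-Gaussian *body*
($\propto e^{-|x|^\beta}$; $\beta < 2$ peaked, $\beta > 2$ flat-topped)
plus a small upper Gaussian *tail* sub-population (weight $p$, position
$\mu_t$) representing denser tissue. All four raw moments are closed-form,
so per-nodule (SKW\*, KUR\*) targets are hit exactly at the population
level by solving for $(p, \mu_t)$, and the analytic moments serve as the
oracle for sampling tests.

A single pinned distribution family (one whose shape is a function of its
skewness and kurtosis alone, such as a sinh–arcsinh Gaussian) cannot
reproduce the study's central finding: the visual peak/plateau pattern
discriminates far better (84%/74%) than any KUR cut-off (≈ 65%/66%), so
the histogram's *body shape* must vary quasi-independently of its
tail-driven moments. In the mixture family the body shape $\beta$ carries
the peak/plateau appearance while the tail carries SKW/KUR, which
reproduces both findings simultaneously.

**Class profiles** (`class_profile()`), all frozen after a one-time
Monte-Carlo calibration:

* Per-nodule SKW\* from a truncated Gaussian with the published cohort
  SDs (benign 0.94, malignant 1.01); KUR\* as the moment-feasibility
  floor $\mathrm{SKW}^{*2} - 2 + 0.3$ plus an exponential excess (an
  always-admissible draw whose calibrated mean responds linearly; a
  lower-truncated Gaussian saturates through its mills-ratio tail and
  cannot be calibrated down to the benign mean).
* Hyper-means calibrated so the *sample* cohort means of segmented
  phantoms reproduce the published cohort statistics (benign KUR
  3.37 / SKW 1.73, malignant KUR 5.88 / SKW 2.07), absorbing truncation
  effects and the finite-sample bias of moment estimators. The implied
  cohort SDs come out near the published 3.88/5.11 and 0.94/1.01 without
  further tuning. Calibration used cohorts of 500 per class across
  several master seeds; cohort means at that size reproduce the targets
  within about ±0.3 (KUR) and ±0.05 (SKW).
* Body shape $\beta$ log-normal per class (benign median 5.5 — broad
  flat-topped plateau; malignant median 1.15 — peaked), spread 0.38,
  calibrated together with the shape threshold so the 50 + 50 cohort
  lands near the 84%/74% operating point. Malignant location/scale
  (45 ± 8 HU, scale ≈ 16) concentrates mass in the 0–100 HU soft-tissue
  band; benign (25 ± 10 HU, scale ≈ 40) spreads it.
* **Seeding** is counter-based: each phantom's geometry and texture draw
  their own substreams split deterministically from the master seed, so
  cohorts are reproducible independent of generation order.

**What the phantoms do and do not emulate.** They emulate the cohort
moment structure, the peak/plateau dichotomy, HU band placement, vessel
attachment, background lung density and growth (via `generate_growth_pair`,
which scales the follow-up radius to encode a target VDT). They do *not*
emulate scanner physics (beam hardening, reconstruction kernels, noise
texture), partial-volume averaging beyond voxelisation, spatially
correlated intra-nodule texture (voxels are i.i.d. given the nodule), or
anatomy around the nodule. Passing phantom tests therefore demonstrates
correctness of the algorithms and the internal consistency of the
statistical design, not clinical performance on patient images.

## Problem sizes and runtime choices

The calibration-check cohorts use 500 phantoms per class (cohort-mean
standard errors ≈ 0.2 for KUR, 0.04 for SKW — comfortably inside the
±0.5/±0.15 acceptance bands); the study-sized analyses use 50 + 50; the
segmentation oracle suite uses 500 random lattices up to 10³ voxels; the
moment oracle suite uses 1,000 random voxel sets up to 10⁴. These sizes
were chosen so the whole suite runs in about a minute while keeping
Monte-Carlo error a small fraction of every tolerance it is checked
against.

## DICOM and archive I/O

Volumes interchange as single-frame explicit-VR little-endian CT series
(one file per axial slice; rescale slope/intercept map stored values to
HU; slices are ordered by the image-position coordinate along the slice
normal, never by file name; inter-slice spacing must be uniform within
0.01 mm — metadata jitter tolerance). Enhanced multi-frame objects and
compressed transfer syntaxes are out of scope. Intermediate rescale
results are rounded half away from zero — deterministic across platforms,
unlike round-half-even on exact .5 values. `quantize_12bit()` clamps onto
the 4,096 integer HU levels of $[-1024, 3071]$. A lossless two-file
archive (JSON sidecar + gzipped int32 lattice) provides fast fixtures;
DICOM remains the canonical interchange format. Conformance of written
files is cross-checked against an independent DICOM implementation in the
suite.

## Known limitations

* The voxel model is i.i.d. within a nodule; real nodules have spatial
  texture (that is what second-order radiomics measures, out of scope
  here).
* The peak/plateau threshold is calibrated on phantoms, not learned from
  labelled patient data; on real images it would need re-calibration.
* The published real-data operating points (AUC ≈ 0.709/0.705, ICC
  0.87/0.91) are not reproducible without the patient images; the package
  verifies its diagnostic machinery against exact oracles and checks
  directional separation on phantoms instead.
* Display windowing (width 1,500 HU, centre −700 HU) is treated as
  display-only; no analysis step depends on it.
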