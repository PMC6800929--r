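# noduletex

First-order CT texture analysis of solid pulmonary nodules in R.

Indeterminate solitary pulmonary nodules (masses ≤ 3 cm surrounded by
normal lung) are common incidental CT findings. When a nodule is neither
clearly benign nor clearly malignant, the practical benign label is
*radiological stability* — no growth, or a volume doubling time (VDT)
above 2,000 days, over years of follow-up. `noduletex` implements a
non-invasive texture analysis that separates such stable nodules from
malignant ones using nothing but the distribution of Hounsfield-unit (HU)
values over the segmented nodule volume, plus a calibrated synthetic
phantom generator so the whole pipeline is testable without patient data.

The pipeline: seeded 3D region growing within an HU inclusion interval
(default [−450, +1500]) → subtraction of attached vessels/bronchi → HU
density histogram of the nodule volume → first-order statistics

- MEN = Σᵢ cᵢ H(i)  (mean, HU)
- VAR = Σᵢ (cᵢ − MEN)² H(i)  (population variance, HU²)
- SKW = Σᵢ (cᵢ − MEN)³ H(i) / VAR^{3/2}  (skewness)
- KUR = Σᵢ (cᵢ − MEN)⁴ H(i) / VAR² − 3  (excess kurtosis)

→ peak/plateau histogram-shape classification (smoothed max-to-mean
ratio) → diagnostic evaluation: ROC/AUC with tie handling, Youden
cut-offs, 2×2-table statistics in exact arithmetic, and two-reader
ICC(2,1). Volume doubling time and the > 2,000-day stability rule are
included for growth assessment. CT volumes interchange as single-frame
DICOM series (minimal explicit-VR little-endian codec) or a fast lossless
archive format.

## Worked example

Simulate the study-sized cohort (50 stable-benign + 50 malignant
phantoms), run the pipeline, and evaluate:

```r
library(noduletex)
simulate_cohort(50, 50, master_seed = 20191007, out_dir = "results/cohort")
manifest <- read.csv("results/cohort/manifest.csv")
bundle <- run_pipeline(pipeline_config(out_dir = "results/run"), manifest)
```

The same steps are scripted as `analysis/01_simulate.R` …
`analysis/04_growth.R`; running them prints (among other things):

```
benign    n=50: KUR 3.03 +/- 3.16, SKW 1.60 +/- 0.81, peak rate 0.20
malignant n=50: KUR 6.34 +/- 4.94, SKW 2.17 +/- 0.93, peak rate 0.82
shape table: TP 41 FN 9 TN 40 FP 10
shape stats: sensitivity 0.82, specificity 0.80, accuracy 0.81
KUR: AUC 0.726; Youden cut-off 2.91 (sens 0.78, spec 0.64)
SKW: AUC 0.684; Youden cut-off 1.34 (sens 0.84, spec 0.48)
```

Reading: the malignant cohort is more leptokurtic (higher KUR) and more
skewed than the stable-benign cohort, but the per-feature cut-offs
separate only moderately (AUC ≈ 0.7) — while the histogram *shape*
dichotomy (peak vs plateau, "peak" predicting malignancy) does much
better: 41/50 malignant nodules show a peak, 40/50 benign a plateau.
Growth assessment on baseline/follow-up phantom pairs
(`analysis/04_growth.R`) recovers constructed doubling times within
voxelisation error and classifies stability by the > 2,000-day rule:

```
  target_vdt    v1     v2 recovered_vdt stable
1        300 904.5 2092.5         301.6  FALSE
4       2500 904.5 1003.5        2435.8   TRUE
6        Inf 904.5  904.5           Inf   TRUE
```

Single-nodule use on your own data: `read_dicom_series(dir)` →
`region_grow_3d(vol, seed)` → `build_histogram(vol, seg)` →
`stats_from_histogram(h)` / `classify_shape(h)`.

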