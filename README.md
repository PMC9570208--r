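# laurdanGP

Quantifying red blood cell (RBC) membrane fluidity from dual-channel
Laurdan confocal images.

Laurdan's emission is blue-shifted in ordered (liquid-crystalline,
"LC") lipid phases and green-shifted in fluid phases. Imaging both
bands gives the per-pixel **generalized polarization**

```
GP = (I_blue − G · I_green) / (I_blue + G · I_green)  ∈ [−1, 1]
```

with `G` an instrument calibration factor; higher GP means a more
ordered, less fluid membrane. Because mature RBC lack organelles,
Laurdan stains only the plasma membrane, so the GP map reads out the
lateral organization of the membrane: a fluid continuous phase dotted
with small high-GP LC domains. Changes in the mean GP and in the
number, size (Feret diameter) and shape (circularity = 4πA/p²) of these
domains track metabolic membrane remodeling, e.g. in type-2 diabetes
with and without peripheral artery disease.

The package implements the full analysis pipeline plus a synthetic
image generator with exact ground truth, so every stage is testable
without raw microscopy data:

* `simulate_subject()` / `simulate_cohort()` — dual-channel Laurdan-like
  RBC images for three preset groups (`group_presets()`: CTRL, DM,
  DM_PAD) with known GP fields, cell masks and domain geometry, Poisson
  photon noise, and per-subject GP offsets.
* `read_dual_tiff()` / `write_dual_tiff()`, `write_tables()` — 16-bit
  multi-page TIFF and lossless CSV I/O; `run_config()` holds the run
  parameters.
* `segment_cells()` — Otsu + morphology + area/solidity debris filters
  (or an optional random-forest pixel classifier,
  `train_pixel_classifier()`).
* `compute_gp()`, `calibrate_g()`, `subject_gp_summary()` — GP maps and
  per-subject GP indices.
* `build_reference_distribution()`, `derive_threshold()`,
  `extract_domains()` — LC domains as pixels strictly above the 75th
  percentile of a 20-cell reference GP stack.
* `measure_domains()`, `per_cell_domain_stats()` — per-domain area,
  perimeter, maximum-caliper Feret (rotating calipers, validated
  against brute force) and circularity.
* `anova_oneway()`, `posthoc_pairwise()` (Welch + Holm, or Tukey),
  `chi_square_categorical()`, `qq_report()`, `full_report()` — the
  group-comparison layer.
* `analyze_cohort()` — the end-to-end pipeline.

## Worked example

Simulate a small three-group cohort (2 subjects per group, 2 images
each, 256×256 px at 0.1 µm/px) and run the pipeline:

```r
library(laurdanGP)
co  <- simulate_cohort(n_images = 2, seed = 42,
                       n_subjects = c(CTRL = 2, DM = 2, DM_PAD = 2),
                       image_shape = c(256, 256), cells_per_image = 5)
res <- analyze_cohort(co, run_config(seed = 7), cells_per_group = 10)

res$threshold
#> <domain_threshold> GP* = 0.5990 (75th percentile of 69960 DM reference px)

aggregate(mean_gp ~ group, res$subjects, function(x) round(mean(x), 3))
#>    group mean_gp
#> 1   CTRL   0.534
#> 2     DM   0.519
#> 3 DM_PAD   0.501

compare_groups(split(res$cells$n_domains, res$cells$group), "n_domains")
#> <group_comparison> n_domains: ANOVA F = 275.317, p = 1.1e-18 (holm post-hoc)
#>   CTRL-DM: adj p = 9.74e-14 ****
#>   CTRL-DM_PAD: adj p = 5.64e-12 ****
#>   DM-DM_PAD: adj p = 0.739 ns
```

Reading the output: the LC threshold derived from the DM reference
stack lands at GP\* ≈ 0.60, between the fluid-phase GP (≈ 0.47–0.51)
and the domain cores (0.72). The recovered group mean GP matches the
simulation truth (0.534 / 0.519 / 0.501) — membranes get more fluid
from CTRL to DM to DM_PAD — and the domain counts separate the healthy
group (~20 domains/cell) from both diabetic groups (~90–100), which are
statistically indistinguishable from each other, while their domain
size and shape still differ (smaller, rounder domains with PAD).

`full_report(res$subjects, res$cells, outdir = "report")` writes
per-feature CSVs, a JSON summary and box/violin plots.

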