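---
title: "Membrane fluidity from dual-channel Laurdan images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane fluidity from dual-channel Laurdan images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laurdanGP)
```

## The measurement

Laurdan is an environment-sensitive membrane dye: its emission spectrum
is blue-shifted in ordered (tightly packed, liquid-crystalline) lipid
phases and green-shifted in disordered, fluid phases. Imaging the two
emission bands simultaneously (blue ~450 nm, green ~525 nm) gives a
per-pixel ratiometric index, the generalized polarization

$$GP = \frac{I_{blue} - G\,I_{green}}{I_{blue} + G\,I_{green}} \in [-1, 1],$$

where $G$ is an instrument calibration factor applied to the green
channel. Higher GP means a more ordered, less fluid membrane. Because
mature red blood cells (RBC) have no organelles, Laurdan stains only
the plasma membrane, and the GP map of an RBC reads out the lateral
organization of its membrane: a fluid continuous phase interrupted by
small ordered ("LC") domains of high GP.

The pipeline implemented here goes from dual-channel images to

1. per-pixel GP maps (`compute_gp()`, with optional calibration via
   `calibrate_g()`),
2. RBC masks with debris filtering (`segment_cells()`),
3. per-subject GP indices (`subject_gp_summary()`),
4. LC-domain masks by percentile thresholding against a reference cell
   stack (`build_reference_distribution()`, `derive_threshold()`,
   `extract_domains()`),
5. per-domain morphometrics — area, perimeter, Feret diameter,
   circularity (`measure_domains()`), and
6. group statistics — one-way ANOVA with Holm-adjusted pairwise
   post-hocs, chi-squared for categorical covariates, QQ reports
   (`full_report()` and friends).

The package ships a synthetic-image generator with exact ground truth,
so every stage is testable end to end without any microscopy data.

## The synthetic cohort

`group_presets()` encodes three study groups: healthy controls (CTRL),
type-2 diabetes without peripheral artery disease (DM) and with PAD
(DM_PAD). The presets are the simulation truth: target subject mean GP
(0.534 / 0.519 / 0.501), between-subject GP SD (0.018 / 0.007 / 0.026),
LC domains per cell (20.2 / 95.4 / 100.1), per-domain Feret diameter
mean ± SD in µm (1.028 ± 1.655 / 0.245 ± 0.281 / 0.183 ± 0.124),
domain elongation (3.0 / 1.2 / 1.1), and cohort sizes (10 / 12 / 15
subjects). The qualitative picture: diabetic membranes carry many
small, round ordered domains; control membranes few, large, elongated
ones; and overall fluidity increases (GP falls) from CTRL to DM to
DM_PAD.

Design choices worth knowing:

* **Cells** are non-overlapping discs (radius 3.0–3.6 µm, uniform)
  placed by rejection sampling with a 2 px guard gap; an annulus mode
  mimics membrane-only staining. GP statistics are computed over
  stained pixels either way, so the filled-disc default keeps
  segmentation simple without changing the estimand.
* **Pixel size** defaults to 0.1 µm/px — sub-diffraction sampling
  consistent with a 60×/1.4 NA objective. At this scale DM/DM_PAD
  domains are only 2–4 px across; the generator guarantees every
  domain at least 2 rasterized pixels, because sub-grid domains cannot
  be represented (a stated limitation, not a bug: the printed Feret
  presets sit at the resolution limit).
* **Per-domain Feret** is lognormal with the preset mean/SD, truncated
  at 1.4× the cell radius. The heavy CTRL tail is therefore clipped in
  realized fields; realized CTRL Feret means sit below the nominal
  preset, which is why recovery tests for Feret check orderings and
  direct-measurement tolerances rather than the nominal mean.
* **Domain GP profile.** Each domain's GP falls linearly from
  `gp_lc_core` (0.72) at its centre to `gp_lc_edge` (0.60) at the
  nominal rim, then continues into a soft "skirt" out to 1.15× the
  nominal radius. This models the transition zone between phases, and
  it makes the quartile threshold self-stabilizing: with DM LC area
  fractions near 25–30%, the 75th percentile of a DM reference stack
  always lands inside the rim band — above every group's fluid level
  (so fluid shot noise does not create speckle domains) and below the
  domain cores (so no domain vanishes). The derived threshold
  typically comes out near GP ≈ 0.58–0.60.
* **Exact per-cell means.** Given the realized domain geometry, the
  fluid-phase GP level of each cell is solved so that the cell's mean
  GP equals the subject target exactly; the subject offset then shifts
  the whole field. Consequently noise-free recovery of group GP is
  exact by construction and noisy recovery is limited only by photon
  statistics.
* **Subject effects** are a single additive GP offset per subject,
  Normal(0, `subject_sd_gp`). `simulate_cohort()` re-centres the drawn
  offsets within each group by default (conditional simulation): the
  simulated cohort's group mean then equals the preset target exactly
  while preserving the between-subject spread that the ANOVA layer
  needs. Unconditional draws are available via
  `center_subject_effects = FALSE`.
* **Noise** is independent Poisson noise per channel on an expected
  total of 10,000 counts per membrane pixel (and a dark level of 10);
  there is no read noise and no PSF blur by default. At these counts
  the per-pixel GP standard error is ≈ 0.005, small against the
  fluid-to-core GP gap of ≈ 0.2.

What the generator does **not** emulate: optical sectioning and PSF
physics, hemoglobin absorption, photobleaching, cell motion, touching
or overlapping cells, and real between-cell heterogeneity of domain
chemistry. Passing recovery tests therefore demonstrates that the
pipeline measures what the model generates — not that it would be
unbiased on real confocal data.

## Segmentation

The default segmentation is unsupervised: Otsu threshold on the summed
channels, hole filling, connected components, then object filters —
area within 20–120 µm² (typical RBC projected area ~50 µm²) and
solidity ≥ 0.85, which removes debris and aggregates; border-touching
objects can optionally be rejected. Every rejection is logged with its
reason. A supervised per-pixel random-forest classifier
(`train_pixel_classifier()`) on Gaussian-smoothed intensity and
gradient-magnitude features at scales 1/2/4 px can replace the Otsu
step for images where a global threshold fails. Touching cells are not
split (the generator never produces them; a watershed would be the
natural extension for real data).

## LC domains and morphometry

The threshold follows the reference-stack recipe: pool the defined GP
pixels of 20 cells sampled (seed-deterministically) from the reference
group (default DM), take the 75th percentile (linear interpolation
between order statistics), and call pixels **strictly** above it
liquid-crystalline. The same global threshold is applied to all groups,
including CTRL; a per-cell variant (`per_cell = TRUE`) re-derives the
percentile within each cell for sensitivity analyses. Components
smaller than `min_domain_px = 2` pixels are discarded; connectivity
defaults to 8, matching ImageJ particle analysis.

Morphometrics per domain:

* **Area** = pixel count × pixel area.
* **Feret diameter** = maximum caliper: the largest pairwise distance
  between pixel-corner coordinates, computed by rotating calipers on
  the convex hull (an all-pairs-on-hull variant must and does agree).
  Using pixel corners means a 1-px domain has Feret √2·pixel size, not
  zero, and a digitized disc of radius r measures ≈ 2r + 1.3 px.
* **Perimeter** has two estimators, and the choice matters for
  circularity = 4πA/p² (capped at 1):
  * `"traced"` (default in `measure_domains()`): the pixel-edge
    outline with the ImageJ corner correction (axial steps weight 1,
    staircase corners reduce 2 to √2). This reproduces the semantics
    of ImageJ's Analyze Particles — including its saturation of
    circularity at 1 for particles a few pixels across. Group
    comparisons of sub-resolution domains (DM vs DM_PAD) are driven by
    exactly this behaviour, so the pipeline defaults to it.
  * `"hull"`: the convex-hull-polygon perimeter of the pixel-corner
    outline. It is exact for axis-aligned rectangles (a 10×10 px
    square gives p = 40, circularity π/4) and multigrid-convergent for
    discs (circularity 0.96 at r = 20 px, 0.98 at r = 40, monotonically
    approaching 1), which makes it the right estimator for validating
    shape accuracy on analytic figures. For markedly concave particles
    it underestimates the perimeter.
  No corner-corrected chain estimator can do both jobs: the traced
  chain overestimates smooth perimeters by ~6% (discs plateau at
  circularity ≈ 0.89), while any estimator exact on rectangles cannot
  inflate few-pixel particles to circularity 1. Providing both, each
  with its stated domain of validity, was the deliberate resolution.

## Statistics

The subject is the unit for GP (n = 10/12/15); the cell is the unit for
domain morphometrics (n = 20 cells per group). Continuous features get
classic one-way ANOVA plus pairwise Welch t tests with Holm step-down
adjustment (Tukey HSD available); categorical tables get Pearson
chi-squared without continuity correction, flagged when expected counts
drop below 5; normality is assessed visually via QQ reports, with no
automatic rejection. Significance stars follow the usual convention
(\*\*\*\* < 0.0001, \*\* < 0.01, \* < 0.05). Degenerate ANOVA inputs
are resolved explicitly (zero between-group variance → F = 0, p = 1;
zero within-group variance → F = ∞ with the smallest positive double
as p, never NaN).

`gp_power_replicates()` checks the design's detectability at the
subject level: with the preset effect sizes and cohort sizes, the DM vs
DM_PAD GP comparison reaches Holm-adjusted p < 0.05 in roughly 60% of
replicates — the observed contrast is detectable but not comfortably
powered, which is worth knowing before reading too much into any single
simulated cohort.

## Problem sizes and reproducibility

The acceptance script (`scripts/acceptance.R`) and the heavier tests
simulate the full 37-subject cohort at 5 images per subject on reduced
256×256 px frames with 5 cells per image; `simulate_subject()`
defaults to the full study geometry (512×512 px, ~20 cells per image,
~100 cells per subject over 5 images). All randomness flows from
explicit seeds; identical seeds give bitwise-identical images, masks
and tables.

## Known limitations

* Sub-resolution domains saturate circularity at 1 under the traced
  estimator and are floored at 2 px by the generator; Feret estimates
  for such domains carry a +1–1.5 px corner bias.
* The pooled per-subject GP index weights cells by pixel count; the
  cell-averaged alternative is emitted alongside but not used as the
  default estimand.
* The hull perimeter underestimates concave particle boundaries;
  merged (overlapping) domains are the main source of concavity.
* No mixed-effects modeling of the image→cell→subject hierarchy: the
  statistical layer mirrors a two-level design (subjects for GP, cells
  for morphometry).
* A linear-regression R² between GP and a clinical covariate (e.g.
  HbA1c) can be computed on synthetic covariates, but no claim about
  real covariate structure is implied.
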