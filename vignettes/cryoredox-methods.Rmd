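---
title: "Quantifying organ redox state from two-channel cryo-imaging stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying organ redox state from two-channel cryo-imaging stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryoredox)
```

## The measurement

Mitochondria carry two intrinsically fluorescent electron carriers: NADH
(feeding complex I of the electron transport chain) and FAD (the oxidized
flavin at complex II). Their fluorescence intensity ratio, the **redox ratio**

$$\mathrm{RR}(i,j,k) = \frac{\mathrm{NADH}(i,j,k)}{\mathrm{FAD}(i,j,k)},$$

is a label-free index of mitochondrial metabolic state: a lower RR means a
more oxidized NADH pool. Serial block-face cryo-imaging acquires this signal
in 3D — a microtome inside a −40&nbsp;°C freezer alternates 25&nbsp;µm cuts
with two-channel surface snapshots (NADH ~350/460&nbsp;nm,
FAD ~437/537&nbsp;nm excitation/emission), yielding on the order of 150
16-bit slices per organ. Snap-freezing fixes the metabolic state at harvest,
so cohorts of organs (e.g. wild-type vs fatty-acid-oxidation-deficient
newborn rat hearts and kidneys) can be compared quantitatively.

The per-sample summary statistic is the volumetric mean of the ratio volume,

$$\overline{\mathrm{RR}} = \frac{1}{N}\sum_{i}\sum_{j}\sum_{k}
  \mathrm{RR}(i,j,k),$$

followed by group statistics over the per-sample means.

## Pipeline stages and the choices behind them

### Segmentation

The organ sits in a dark embedding medium, so tissue is separable by
intensity. Each slice is thresholded independently (`segment_slice()`), the
2D masks are stacked (`build_mask_volume()`), and small components are
removed (4-connectivity, default minimum 64 voxels), holes filled, and the
largest in-plane component kept. The threshold criterion is Otsu's
between-class-variance maximisation by default, searched exhaustively over
the observed gray levels with ties broken toward the lower level; `fixed`
and `quantile` criteria are available for reproducibility experiments. Otsu
was chosen because it is parameter-free: nothing in the acquisition pins an
absolute intensity scale, so a hand-tuned constant would not transfer across
samples.

Two guards make the per-slice policy safe:

* A slice whose thresholding image is *constant* is treated as pure
  embedding medium (threshold recorded as `Inf`).
* A slice whose best Otsu split has **effectiveness** (between-class variance
  over total variance) below 0.8 is likewise treated as background. Splitting
  unimodal noise cannot exceed ~0.64 (Gaussian) or ~0.75 (uniform), while a
  slice containing genuine tissue against a dark medium scores close to 1,
  so the guard separates the two regimes by closed-form bounds rather than a
  fitted constant. Without it, per-slice Otsu happily bisects the read noise
  of an organ-free slice and admits speckle.

The thresholding image is the FAD channel by default — under the phantom's
forward model it is the structurally flattest channel — with `NADH` and a
`combined` (mean of min–max-normalised channels) option, since nothing in
the acquisition dictates which channel drives segmentation. Connectivity is
fixed (4-neighbour in-plane, 6-neighbour for the optional 3D
largest-component step) so component counts are reproducible.

### Ratio volume and summaries

`ratio_volume()` divides NADH by FAD voxel-wise inside the mask. A voxel is
valid only if its (optionally background-subtracted) FAD intensity exceeds a
floor — by default three read-noise standard deviations (at least one
count) — because the ratio at a signal-free voxel is noise divided by noise.
Invalid voxels are `NA`, never zero, and are counted.

The volumetric mean is taken over *valid* voxels by default. Averaging over
the full grid would make the statistic depend on how much embedding medium
the field of view happens to contain, which contradicts the magnitude of the
reported per-organ means (~0.75–1.43); a `denominator = "grid"` audit mode
implements the literal full-grid normalisation anyway. Histograms
(`rr_histogram()`, default 100 bins on [0, 3]) report relative voxel
frequencies; out-of-range values are counted in explicit overflow fields,
and the attached mean is always computed from voxels, never from bins.

Background handling deserves a note. The generic `ratio_volume()` performs
no subtraction unless asked. The *pipeline* configuration, however, knows
its detector model, and by default subtracts the configured constant
background offset from both channels before dividing (exactly as its FAD
floor is defined relative to that offset). An uncorrected offset $b$ biases
the mean ratio by roughly $(b/F)(1-\mathrm{RR})$ for in-tissue FAD level
$F$ — with the defaults, up to ±0.03 at the cohort's RR extremes, larger
than everything else in the error budget combined. Constant-offset
subtraction from dark-region calibration is standard practice in
ratiometric fluorescence work; with it the pipeline's per-sample error is
dominated by quantization and shot noise (≲0.003 at the default settings).

### Cohort statistics

`compare_cohort()` summarises each group's per-sample means, screens
normality with a one-sample Kolmogorov–Smirnov check against a
moments-fitted normal (with the documented caveat that estimating the
parameters makes the p-value conservative — the Lilliefors effect), and
runs the design-appropriate test: a two-sided two-sample *t* test (pooled
variance by default, Welch optional) with a 95% confidence interval and the
percent decrease
$100\,(\bar x_{\mathrm{ref}} - \bar x_{\mathrm{test}})/\bar x_{\mathrm{ref}}$
for two-group designs, or one-way ANOVA followed by Tukey HSD
(Tukey–Kramer standard errors for unequal group sizes) for three-genotype
designs. The statistics are computed in closed form on base R's
distribution functions, which pins down the degenerate cases a cohort can
produce (zero pooled variance with equal means gives p = 1 and CI [0, 0];
with unequal means it is an error, not a number). The test suite checks
every statistic against `t.test()`, `ks.test()`, `aov()`/`TukeyHSD()` to
1e-6, and verifies the type-I error of the two-group test by simulation.
Significance is flagged at α = 0.05 throughout.

## The synthetic phantom

No raw imaging data are publicly deposited for this kind of study, so the
package ships a generator whose defaults *are* the study conditions, giving
every stage a parameter-recovery test surface.

* **Geometry.** Organs are ellipsoids in voxel space; kidneys nest a second
  ellipsoid (scale 0.45) whose interior is the medulla, preserving the
  cortex/medulla topology that matters for regional summaries. The z
  semi-axis is snapped to an integer so polar slice cross-sections stay
  well above the small-object cleanup size.
* **Ground truth.** A per-animal mean RR is drawn from
  `Normal(rr_mean, rr_between_sd)` (rejection-truncated below 0.05), a
  smooth spatial field (white noise low-pass filtered at a 10-voxel cutoff
  wavelength, standardised to SD `rr_within_sd` = 0.1) is added, and kidney
  medullas receive an additive offset. The smooth field gives per-sample
  histograms a realistic unimodal spread rather than pure voxel noise.
* **Group parameters.** Control mean 1.185 and severe mean 0.835 — the
  midpoints of the reported per-group ranges (0.943–1.427 and 0.75–0.92) —
  at the reported cohort sizes: hearts 6 control vs 11 severe, kidneys 5 vs
  12. The between-animal SDs are back-derived from those printed ranges via
  the expected range of a normal sample ($\text{range} \approx d_2(n)\,
  \sigma$, the range-to-sigma constant of control charts): 0.19 and 0.054
  for hearts, 0.208 and 0.052 for kidneys. The ranges are read as ranges of
  per-sample volumetric means, which is consistent with their bracketing
  the reported group means. Kidney groups default to medullary offsets of
  +0.15 (control) and +0.30 (severe), encoding the reported pattern of a
  depressed cortical RR with relatively preserved medulla.
* **Forward model.** FAD is held at a constant in-tissue base level (1000
  counts) and NADH is RR × FAD, which makes the ground-truth ratio exactly
  controllable. Noise follows the standard CCD chain: Poisson shot noise on
  the signal, a constant 50-count background, Gaussian read noise
  (SD 10), clipping to the 16-bit range, integer quantization. The
  acquisition reports no per-channel intensity statistics, so these levels
  are conventional CCD values, not fitted ones; the rendering refuses
  settings that would saturate more than rarely.

What the phantom deliberately does **not** model: optics (PSF, depth
attenuation, spectral bleed-through, photobleaching), vascular or chamber
anatomy, slice-to-slice misregistration, or intensity drift. Consequences:
segmentation here faces a sharp tissue/medium edge, so near-perfect Dice
scores on phantoms say the thresholding machinery is correct, not that any
real organ segments this cleanly; and ratio recovery is tested against a
forward model whose only corruptions are the noise chain — real data add
flat-field and registration error the pipeline does not correct.

## Reproducibility and numerics

Every generator operation is a pure function of its configuration and an
integer seed; cohort samples use `master_seed + sample index` so extending
a cohort never reshuffles existing draws. Stacks travel as multi-page
grayscale TIFF (integer at native bit depth; ratio volumes as 32-bit IEEE
float with NaN invalids, written by a minimal uncompressed writer and read
back through libtiff). Slice 1 is the first cut face; arrays are indexed
`[row, col, slice]`, 1-based, origin top-left.

The validation suite runs replicate studies at 40 × 40 × 20 voxels and
single-sample checks at up to 48 × 48 × 24 — reduced stand-ins chosen so a
full 100-replicate cohort study remains a desk-scale computation while
preserving every structural feature (polar slices, two-compartment
kidneys, the full noise chain, the reported cohort sizes). Full-resolution
128 × 128 × 60 (or 150-slice) volumes are available through the
configuration and differ only in voxel count.

Known limitations, beyond the phantom realism above: the volumetric mean
weights every valid voxel equally, so differential segmentation loss at
organ boundaries shifts it; the KS screen at n = 5–12 has little power;
pooled-variance *t* is the default even though group SDs derived from the
printed ranges differ, so the Welch variant is one switch away; and the
histogram default range [0, 3] silently relegates pathological ratios
above 3 to the overflow counter rather than the bins.
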