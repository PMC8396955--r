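# cryoredox

Volumetric NADH/FAD redox-ratio analysis for 3D optical cryo-imaging of
whole organs.

Mitochondria fluoresce through two endogenous electron carriers — NADH
(complex I substrate, ~350/460 nm) and FAD (the oxidized flavin at complex
II, ~437/537 nm). Their intensity ratio, the redox ratio

```
RR(i,j,k) = NADH(i,j,k) / FAD(i,j,k)
```

indexes the mitochondrial metabolic state label-free: lower RR means a more
oxidized tissue. Serial block-face cryo-imaging acquires both channels in
3D (25 µm microtome slices, ~150 slices per organ, 16-bit CCD), and
cohorts — e.g. wild-type newborn rat hearts against littermates carrying a
fatty-acid-oxidation-deficient mutation — are compared through the
per-sample volumetric mean

```
mean RR = (1/N) * sum_i sum_j sum_k RR(i,j,k)
```

followed by group statistics over the per-sample means.

`cryoredox` is for researchers who need that analysis chain as tested,
scriptable R: per-slice threshold segmentation of tissue from the frozen
embedding medium, voxel-wise ratio volumes with explicit validity handling,
per-sample histograms and volumetric means, regional (kidney
cortex/medulla) summaries, and cohort statistics (Kolmogorov–Smirnov
normality screen, pooled/Welch *t* tests with 95% CIs and percent
differences, one-way ANOVA with Tukey HSD). Because raw cryo-imaging
cohorts of this kind are not publicly deposited, the package also ships a
synthetic phantom generator with known ground-truth redox fields and a
CCD noise model, so every stage is validated by parameter recovery.

## Worked example

Simulate the default heart study (6 control vs 11 severe animals, control
mean RR 1.185, severe 0.835), push every sample through segmentation →
ratio → histogram → volumetric mean, and compare the groups:

```r
library(cryoredox)

acq <- acquisition_spec(n_slices = 24, slice_shape = c(48, 48))
cfg <- pipeline_config("heart", acq = acq, master_seed = 42,
                       output_root = file.path(tempdir(), "demo"))
study <- run_study(cfg)

study$summaries[, c("sample_id", "group", "true_mean_rr", "mean_rr")]
#> # A tibble: 17 × 4
#>   sample_id   group   true_mean_rr mean_rr
#>   <chr>       <chr>          <dbl>   <dbl>
#> 1 control_s01 control         1.18    1.18
#> 2 control_s02 control         1.31    1.31
#> 3 control_s03 control         1.25    1.25
#> 4 control_s04 control         1.01    1.01
#> 5 control_s05 control         1.56    1.57
#> # ℹ 12 more rows

study$result
#> <cohort_result> ttest_pooled, alpha = 0.05
#> # A tibble: 2 × 4
#>   group       n group_mean group_sd
#>   <chr>   <int>      <dbl>    <dbl>
#> 1 control     6      1.26    0.181
#> 2 severe     11      0.831   0.0530
#> # A tibble: 1 × 10
#>   group_a group_b mean_diff ci95_low ci95_high statistic   dof    p_value
#>   <chr>   <chr>       <dbl>    <dbl>     <dbl>     <dbl> <dbl>      <dbl>
#> 1 control severe      0.427    0.304     0.549      7.43    15 0.00000210
```

Reading the output: each sample's `mean_rr` is the pipeline's estimate of
its volumetric mean redox ratio, sitting next to the generator's ground
truth (`true_mean_rr`) — here they agree to ~0.003. The comparison row says
the severe group's mean RR is 0.427 lower than control (95% CI
[0.304, 0.549], pooled *t*(15) = 7.43, p ≈ 2 × 10⁻⁶), a 33.9% decrease
(`study$result$comparisons$percent_decrease`). `tidy(study$result)` and
`glance(study$result)` return the comparison and summary tibbles;
`plot_group_means()`, `plot_rr_histograms()` and `plot_rr_slice()` draw the
standard figures.

Artifacts land in `cfg$output_root`: per-sample NADH/FAD stacks, the
segmentation mask (8-bit TIFF), the ratio volume (32-bit float TIFF, NaN =
invalid voxel), histogram CSV and summary JSON, plus `manifest.csv`,
`comparisons.csv` and `report.json` for the cohort. A thin command-line
front-end over the same functions lives at `inst/cli/cryoredox.R`
(`simulate|process|compare|report`, YAML-configured — see
`inst/extdata/heart_default.yaml`).

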