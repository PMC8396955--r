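# Default synthetic heart study: wild-type control vs severe mutant cohort
# at the reported sample sizes, desk-scale 128 x 128 x 60 voxel volumes.
organ: heart
design: two_group
master_seed: 1
acquisition:
  slice_thickness_um: 25
  n_slices: 60
  slice_shape: [128, 128]
  bit_depth: 16
  pixel_size_um: 25
groups:
  - name: control
    n_samples: 6
    rr_mean: 1.185
    rr_between_sd: 0.19
    rr_within_sd: 0.1
  - name: severe
    n_samples: 11
    rr_mean: 0.835
    rr_between_sd: 0.054
    rr_within_sd: 0.1
noise:
  fad_base_intensity: 1000
  background_offset: 50
  read_noise_sd: 10
  shot_noise: true
segmentation:
  method: otsu
  channel: FAD
  min_object_voxels: 64
  fill_holes: true
  keep_largest_component: true
histogram:
  min: 0
  max: 3
  n_bins: 100
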