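# Shared fixture builders. All phantoms here are generated in code at test
# time; sizes are desk-scale stand-ins for full 150-slice acquisitions.

tiny_acq <- function(n_slices = 20L, shape = 40L) {
  acquisition_spec(n_slices = n_slices, slice_shape = c(shape, shape))
}

# A heart sample with every stochastic term switched off and a spatially
# constant redox field: the sharpest possible ground truth.
flat_heart <- function(rr = 1, acq = tiny_acq(), seed = 1L,
                       fad_base = 1000) {
  geom <- default_geometry(acq, "heart")
  grp <- group_spec("g", 1, rr_mean = rr, rr_between_sd = 0, rr_within_sd = 0)
  simulate_sample(geom, grp, noiseless_spec(fad_base), acq, seed = seed)
}

# Build a volume_pair directly from two voxel arrays (16-bit range).
manual_pair <- function(nadh_vox, fad_vox, sample_id = "manual") {
  dims <- dim(nadh_vox)
  acq <- acquisition_spec(n_slices = dims[3], slice_shape = dims[1:2])
  pair_channels(channel_stack(nadh_vox, "NADH", acq, sample_id),
                channel_stack(fad_vox, "FAD", acq, sample_id))
}

# Naive between-class-variance search: the brute-force Otsu oracle.
otsu_brute_force <- function(pixels) {
  v <- sort(unique(pixels))
  best_t <- NA_real_
  best_bcv <- -Inf
  for (t in v[-1]) {
    bg <- pixels[pixels < t]
    fg <- pixels[pixels >= t]
    w0 <- length(bg) / length(pixels)
    w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(bg) - mean(fg))^2
    if (bcv > best_bcv) {  # strict: ties keep the lower threshold
      best_bcv <- bcv
      best_t <- t
    }
  }
  best_t
}

# Triple-loop accumulation oracle for the volumetric mean.
triple_loop_mean <- function(rr, valid) {
  d <- dim(rr)
  s <- 0
  n <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (valid[i, j, k]) {
      s <- s + rr[i, j, k]
      n <- n + 1L
    }
  }
  s / n
}

# Random masked rr_volume for oracle tests.
random_rr_volume <- function(dims = c(16, 16, 8), p_valid = 0.6, seed = 1) {
  withr::with_seed(seed, {
    valid <- array(stats::runif(prod(dims)) < p_valid, dim = dims)
    if (!any(valid)) valid[1] <- TRUE
    rr <- array(NA_real_, dim = dims)
    rr[valid] <- stats::rlnorm(sum(valid), 0, 0.3)
    structure(list(rr = rr, valid = valid, n_valid = sum(valid),
                   fad_floor = 0, sample_id = "random"),
              class = "rr_volume")
  })
}
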