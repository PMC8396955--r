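# Synthetic two-channel cryo-stack phantoms with known ground-truth redox
# structure. Forward model: the FAD channel is flat inside tissue at a base
# intensity; NADH = RR x FAD, so the ground-truth ratio field is exactly
# controllable. Noise follows the usual CCD chain (shot + read + offset).

# Ellipsoid membership over the full grid, vectorised via outer sums of
# squared normalised coordinates along each axis.
ellipsoid_mask <- function(dims, center, semi) {
  u2 <- lapply(1:3, function(a) ((seq_len(dims[a]) - center[a]) / semi[a])^2)
  d2 <- outer(outer(u2[[1]], u2[[2]], "+"), u2[[3]], "+")
  d2 <= 1
}

# Smooth zero-mean random field: white Gaussian noise low-pass filtered in the
# frequency domain with a Gaussian transfer function whose cutoff wavelength
# is `cutoff_vox` voxels, then standardised to unit SD over `where`.
smooth_field <- function(dims, cutoff_vox = 10, where) {
  white <- array(stats::rnorm(prod(dims)), dim = dims)
  fr <- lapply(dims, function(n) {
    k <- c(seq_len(ceiling(n / 2)) - 1L, -rev(seq_len(floor(n / 2))))
    (k / n)^2
  })
  f2 <- outer(outer(fr[[1]], fr[[2]], "+"), fr[[3]], "+")
  transfer <- exp(-0.5 * f2 * cutoff_vox^2)
  sm <- Re(stats::fft(stats::fft(white) * transfer, inverse = TRUE)) / prod(dims)
  s <- stats::sd(sm[where])
  if (!is.finite(s) || s == 0) return(array(0, dim = dims))
  (sm - mean(sm[where])) / s
}

# Per-animal mean: Normal(mean, sd) with reject-and-resample below `floor`
# so the redox field can never go nonpositive through the animal draw.
draw_animal_mean <- function(mean, sd, floor = 0.05) {
  if (sd == 0) return(mean)
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= floor) return(x)
  }
}

#' Generate a ground-truth redox-ratio field for one synthetic organ
#'
#' Builds the voxel-wise true redox ratio (RR = NADH/FAD) for one animal: a
#' per-animal mean drawn from `Normal(rr_mean, rr_between_sd)` (truncated
#' below 0.05 by rejection), plus a smooth zero-mean spatial field with SD
#' `rr_within_sd` (low-pass filtered Gaussian noise, cutoff wavelength 10
#' voxels), plus, for kidney geometries, `medulla_rr_offset` added inside the
#' inner (medullary) ellipsoid.
#'
#' @param geometry An [organ_geometry()]; must fit the volume with a 2-voxel
#'   margin.
#' @param group A [group_spec()] supplying the RR distribution parameters.
#' @param acq An [acquisition_spec()] fixing the volume dimensions.
#' @param seed Integer seed; identical seeds give identical fields.
#' @return An object of class `ground_truth`: list with `rr_field` (numeric
#'   array, NA outside tissue), `tissue_mask` (logical array),
#'   `region_labels` (integer array: 0 background, 1 cortex/tissue,
#'   2 medulla), `animal_mean_rr`, and `sample_true_mean_rr` (mean of
#'   `rr_field` over the tissue mask).
#' @examples
#' acq <- acquisition_spec(n_slices = 16, slice_shape = c(24, 24))
#' g <- group_spec("control", 6, rr_mean = 1.185, rr_between_sd = 0.19)
#' truth <- generate_rr_field(default_geometry(acq, "heart"), g, acq, seed = 1)
#' truth$sample_true_mean_rr
#' @export
generate_rr_field <- function(geometry, group, acq, seed) {
  stopifnot(inherits(geometry, "organ_geometry"), inherits(group, "group_spec"))
  validate_geometry_fits(geometry, acq)
  dims <- acq_dims(acq)
  tissue <- ellipsoid_mask(dims, geometry$center_vox, geometry$semi_axes_vox)
  labels <- array(0L, dim = dims)
  labels[tissue] <- 1L
  if (geometry$kind == "kidney" && geometry$medulla_fraction > 0) {
    medulla <- ellipsoid_mask(dims, geometry$center_vox,
                              geometry$semi_axes_vox * geometry$medulla_fraction)
    labels[medulla] <- 2L
  }
  drawn <- withr::with_seed(seed, {
    mu <- draw_animal_mean(group$rr_mean, group$rr_between_sd)
    field <- array(mu, dim = dims)
    if (geometry$kind == "kidney") {
      field[labels == 2L] <- field[labels == 2L] + group$medulla_rr_offset
    }
    if (group$rr_within_sd > 0) {
      field <- field + group$rr_within_sd * smooth_field(dims, 10, tissue)
    }
    list(field = field, mu = mu)
  })
  rr <- drawn$field
  if (any(rr[tissue] <= 0)) {
    rlang::abort("Redox field is nonpositive inside tissue; reduce `rr_within_sd` or the medulla offset.",
                 class = "cryoredox_param_error")
  }
  rr[!tissue] <- NA_real_
  structure(
    list(rr_field = rr, tissue_mask = tissue, region_labels = labels,
         animal_mean_rr = drawn$mu,
         sample_true_mean_rr = mean(rr[tissue]),
         geometry = geometry, acq = acq, seed = as.integer(seed)),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  d <- dim(x$rr_field)
  cat(sprintf("<ground_truth> %s, %dx%dx%d, %d tissue voxels, true mean RR %.4f\n",
              x$geometry$kind, d[1], d[2], d[3], sum(x$tissue_mask),
              x$sample_true_mean_rr))
  invisible(x)
}

#' Render noisy NADH and FAD channel stacks from a ground-truth field
#'
#' Forward model: `FAD_true = fad_base_intensity` inside tissue and 0 outside;
#' `NADH_true = rr_field * FAD_true`. Optional Poisson shot noise is applied
#' to the fluorescence signal, then the constant background offset and
#' additive Gaussian read noise are added, and the result is clipped to the
#' detector range and rounded to integer counts.
#'
#' @param truth A `ground_truth` from [generate_rr_field()].
#' @param noise A [noise_spec()].
#' @param acq An [acquisition_spec()] matching the truth's dimensions.
#' @param seed Integer seed for the noise draws; defaults to `noise$seed`.
#' @param sample_id Sample identifier stamped on both stacks.
#' @return A `volume_pair` (see [pair_channels()]) with integer-valued
#'   `channel_stack` members for NADH and FAD.
#' @export
render_channels <- function(truth, noise, acq, seed = noise$seed,
                            sample_id = "sample") {
  stopifnot(inherits(truth, "ground_truth"), inherits(noise, "noise_spec"))
  dims <- acq_dims(acq)
  if (!identical(dim(truth$rr_field), as.integer(dims))) {
    rlang::abort("Ground truth and acquisition spec disagree on volume shape.",
                 class = "cryoredox_dim_error")
  }
  if (is.null(seed)) {
    rlang::abort("A seed is required (argument or `noise$seed`).",
                 class = "cryoredox_param_error")
  }
  maxval <- 2^acq$bit_depth - 1
  rr_max <- max(truth$rr_field[truth$tissue_mask])
  peak <- rr_max * noise$fad_base_intensity + noise$background_offset
  if (peak + 3 * sqrt(peak + noise$read_noise_sd^2) >= maxval) {
    rlang::abort("Expected intensities would saturate the detector more than rarely; lower `fad_base_intensity`.",
                 class = "cryoredox_param_error")
  }
  fad_true <- ifelse(truth$tissue_mask, noise$fad_base_intensity, 0)
  rr0 <- truth$rr_field
  rr0[is.na(rr0)] <- 0
  nadh_true <- rr0 * fad_true
  n <- prod(dims)
  quantize <- function(signal) {
    x <- if (noise$shot_noise) stats::rpois(n, signal) else signal
    x <- x + noise$background_offset
    if (noise$read_noise_sd > 0) x <- x + stats::rnorm(n, 0, noise$read_noise_sd)
    array(round(pmin(pmax(x, 0), maxval)), dim = dims)
  }
  rendered <- withr::with_seed(seed, {
    list(nadh = quantize(nadh_true), fad = quantize(fad_true))
  })
  pair_channels(
    channel_stack(rendered$nadh, "NADH", acq, sample_id),
    channel_stack(rendered$fad, "FAD", acq, sample_id)
  )
}

#' Simulate one phantom sample end to end (in memory)
#'
#' Convenience wrapper chaining [generate_rr_field()] and [render_channels()].
#'
#' @inheritParams render_channels
#' @inheritParams generate_rr_field
#' @return List with `truth` (`ground_truth`) and `pair` (`volume_pair`).
#' @export
simulate_sample <- function(geometry, group, noise, acq, seed,
                            sample_id = "sample") {
  truth <- generate_rr_field(geometry, group, acq, seed = seed)
  pair <- render_channels(truth, noise, acq, seed = seed + 1L,
                          sample_id = sample_id)
  list(truth = truth, pair = pair, sample_id = sample_id)
}

#' Generate a full synthetic cohort on disk
#'
#' Writes, per sample, the NADH and FAD stacks (16-bit multi-page TIFF), the
#' ground-truth tissue mask and region labels (8-bit multi-page TIFF), and a
#' cohort `manifest.csv` with one row per sample. Per-sample seeds are derived
#' as `master_seed + sample index` (across the whole cohort, 1-based), so
#' extending a cohort never reshuffles existing samples.
#'
#' @param groups List of [group_spec()] objects.
#' @param geometry An [organ_geometry()] shared by all samples.
#' @param noise A [noise_spec()].
#' @param acq An [acquisition_spec()].
#' @param out_dir Output directory (created if missing).
#' @param master_seed Integer master seed.
#' @return The cohort manifest as a tibble (columns `sample_id`, `group`,
#'   `seed`, `true_mean_rr`, `organ`), invisibly also written to
#'   `manifest.csv`.
#' @export
generate_cohort <- function(groups, geometry, noise, acq, out_dir,
                            master_seed = 1L) {
  if (inherits(groups, "group_spec")) groups <- list(groups)
  stopifnot(length(groups) >= 1)
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    rlang::abort(sprintf("Cannot create output directory '%s'.", out_dir),
                 class = "cryoredox_io_error")
  }
  idx <- 0L
  rows <- list()
  for (g in groups) {
    for (i in seq_len(g$n_samples)) {
      idx <- idx + 1L
      seed <- as.integer(master_seed) + idx
      sample_id <- sprintf("%s_s%02d", g$name, i)
      sim <- simulate_sample(geometry, g, noise, acq, seed = seed,
                             sample_id = sample_id)
      write_stack(sim$pair$nadh, file.path(out_dir, paste0(sample_id, "_NADH.tif")))
      write_stack(sim$pair$fad, file.path(out_dir, paste0(sample_id, "_FAD.tif")))
      write_mask(sim$truth$tissue_mask, file.path(out_dir, paste0(sample_id, "_truthmask.tif")))
      write_labels(sim$truth$region_labels, file.path(out_dir, paste0(sample_id, "_labels.tif")))
      rows[[idx]] <- tibble::tibble(
        sample_id = sample_id, group = g$name, seed = seed,
        true_mean_rr = sim$truth$sample_true_mean_rr, organ = geometry$kind)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
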