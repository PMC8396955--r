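# Voxel-wise redox ratio (RR = NADH/FAD), its per-sample distribution, and
# the volumetric mean summary statistic. The per-sample statistic is the
# arithmetic mean of RR over valid voxels; group statistics are then taken
# over the per-sample means.

#' Compute the voxel-wise redox-ratio volume for one sample
#'
#' Divides NADH by FAD voxel by voxel inside the tissue mask. A voxel is
#' valid when the mask is true, the (optionally background-subtracted) FAD
#' intensity exceeds `fad_floor`, and the NADH intensity is nonnegative;
#' everywhere else the ratio is NA. Background subtraction is off by default;
#' when given, it is applied per channel and clamped at zero.
#'
#' @param pair A `volume_pair`.
#' @param mask A `mask_volume` (or a logical array of the same shape).
#' @param fad_floor Minimum FAD intensity (post-subtraction) for a valid
#'   ratio; guards the division. Default 0. See [default_fad_floor()].
#' @param background Optional `c(nadh = , fad = )` per-channel constants to
#'   subtract before dividing.
#' @return An object of class `rr_volume`: list with `rr` (numeric array,
#'   NA at invalid voxels), `valid` (logical array), `n_valid`, `fad_floor`,
#'   and `sample_id`.
#' @export
ratio_volume <- function(pair, mask, fad_floor = 0, background = NULL) {
  stopifnot(inherits(pair, "volume_pair"))
  m <- if (inherits(mask, "mask_volume")) mask$mask else mask
  stopifnot(is.logical(m))
  if (!identical(dim(m), dim(pair$nadh$voxels))) {
    rlang::abort("Mask shape does not match the channel stacks.",
                 class = "cryoredox_dim_error")
  }
  if (fad_floor < 0) {
    rlang::abort("`fad_floor` must be nonnegative.",
                 class = "cryoredox_param_error")
  }
  nadh <- pair$nadh$voxels
  fad <- pair$fad$voxels
  if (!is.null(background)) {
    nadh <- pmax(nadh - background[["nadh"]], 0)
    fad <- pmax(fad - background[["fad"]], 0)
  }
  valid <- m & (fad > fad_floor) & (nadh >= 0)
  n_valid <- sum(valid)
  if (n_valid == 0) {
    rlang::abort("No valid voxels: the ratio volume is empty.",
                 class = "cryoredox_empty_ratio")
  }
  rr <- array(NA_real_, dim = dim(nadh))
  rr[valid] <- nadh[valid] / fad[valid]
  structure(
    list(rr = rr, valid = valid, n_valid = n_valid, fad_floor = fad_floor,
         sample_id = pair$sample_id),
    class = "rr_volume"
  )
}

#' @export
print.rr_volume <- function(x, ...) {
  d <- dim(x$rr)
  cat(sprintf("<rr_volume> '%s': %dx%dx%d, %d valid voxels, mean RR %.4f\n",
              x$sample_id, d[1], d[2], d[3], x$n_valid, volumetric_mean(x)))
  invisible(x)
}

#' Default FAD division floor for a given noise model
#'
#' The background offset plus three read-noise SDs (at least one count): a
#' FAD voxel below this carries essentially no fluorescence signal and its
#' ratio would be noise-dominated.
#'
#' @param noise A [noise_spec()].
#' @return A nonnegative scalar threshold on FAD counts.
#' @export
default_fad_floor <- function(noise) {
  noise$background_offset + max(3 * noise$read_noise_sd, 1)
}

#' Volumetric mean of the redox-ratio volume
#'
#' The per-sample summary statistic: the arithmetic mean of RR over the voxel
#' grid. By default the grid is the set of valid (segmented) voxels, so the
#' statistic does not depend on how much embedding medium surrounds the
#' organ. `denominator = "grid"` instead divides the same sum by the full
#' `Nx * Ny * Nz` voxel count of the volume, for audits of the literal
#' full-grid normalisation.
#'
#' @param vol An `rr_volume`.
#' @param denominator `"valid"` (default) or `"grid"`.
#' @return The mean redox ratio (a single number).
#' @export
volumetric_mean <- function(vol, denominator = c("valid", "grid")) {
  stopifnot(inherits(vol, "rr_volume"))
  denominator <- match.arg(denominator)
  if (vol$n_valid == 0) {
    rlang::abort("Empty ratio volume.", class = "cryoredox_empty_ratio")
  }
  s <- sum(vol$rr[vol$valid])
  s / switch(denominator, valid = vol$n_valid, grid = length(vol$rr))
}

#' Relative-frequency histogram of a redox-ratio volume
#'
#' Bins the valid voxels over `[e_i, e_{i+1})` (last bin closed). Values
#' falling outside the edge range are counted in `n_below`/`n_above`, never
#' silently dropped; `rel_freq` is normalised by the in-range count. The
#' attached `mean_rr` is always computed from the voxels themselves, not
#' from the bins.
#'
#' @param vol An `rr_volume`.
#' @param bin_edges Strictly increasing numeric vector of bin edges. Default
#'   100 bins over `[0, 3]`.
#' @return An object of class `rr_histogram`: list with `bin_edges`,
#'   `rel_freq`, `counts`, `n_below`, `n_above`, `mean_rr`, `n_valid`,
#'   `sample_id`.
#' @export
rr_histogram <- function(vol, bin_edges = seq(0, 3, length.out = 101)) {
  stopifnot(inherits(vol, "rr_volume"))
  if (length(bin_edges) < 2 || any(diff(bin_edges) <= 0)) {
    rlang::abort("`bin_edges` must be at least two strictly increasing values.",
                 class = "cryoredox_param_error")
  }
  x <- vol$rr[vol$valid]
  if (length(x) == 0) {
    rlang::abort("Empty ratio volume.", class = "cryoredox_empty_ratio")
  }
  nb <- length(bin_edges) - 1L
  idx <- findInterval(x, bin_edges, rightmost.closed = TRUE)
  n_below <- sum(idx == 0L)
  n_above <- sum(idx > nb)
  counts <- tabulate(idx[idx >= 1L & idx <= nb], nbins = nb)
  in_range <- sum(counts)
  if (in_range == 0) {
    rlang::abort("All ratio values fall outside the histogram range.",
                 class = "cryoredox_param_error")
  }
  structure(
    list(bin_edges = bin_edges, rel_freq = counts / in_range, counts = counts,
         n_below = n_below, n_above = n_above,
         mean_rr = mean(x), n_valid = length(x), sample_id = vol$sample_id),
    class = "rr_histogram"
  )
}

#' @export
print.rr_histogram <- function(x, ...) {
  cat(sprintf("<rr_histogram> '%s': %d bins on [%g, %g], mean RR %.4f (n = %d)\n",
              x$sample_id, length(x$rel_freq), min(x$bin_edges),
              max(x$bin_edges), x$mean_rr, x$n_valid))
  invisible(x)
}

#' Tidy a redox-ratio histogram into a tibble
#'
#' @param x An `rr_histogram`.
#' @param ... Unused.
#' @return Tibble with columns `bin_left`, `bin_right`, `rel_freq`, plus the
#'   sample id.
#' @export
tidy.rr_histogram <- function(x, ...) {
  nb <- length(x$rel_freq)
  tibble::tibble(
    sample_id = x$sample_id,
    bin_left = x$bin_edges[seq_len(nb)],
    bin_right = x$bin_edges[seq_len(nb) + 1L],
    rel_freq = x$rel_freq
  )
}

#' Mean redox ratio per labelled region
#'
#' Restricts the volumetric mean to each positive region label (e.g. kidney
#' cortex = 1, medulla = 2). Background (label 0) is never included. Labels
#' with no valid voxel are absent from the result rather than reported as
#' zero; it is an error only if no requested label has any valid voxel.
#'
#' @param vol An `rr_volume`.
#' @param labels Integer array of region labels, same shape as the volume.
#' @param region_names Optional named translation of labels (e.g.
#'   `c("1" = "cortex", "2" = "medulla")`; the default).
#' @return Tibble with columns `label`, `region`, `mean_rr`, `n_valid`.
#' @export
regional_means <- function(vol, labels,
                           region_names = c("1" = "cortex", "2" = "medulla")) {
  stopifnot(inherits(vol, "rr_volume"))
  if (!identical(dim(labels), dim(vol$rr))) {
    rlang::abort("Label volume shape does not match the ratio volume.",
                 class = "cryoredox_dim_error")
  }
  present <- sort(unique(labels[labels > 0 & vol$valid]))
  if (length(present) == 0) {
    rlang::abort("No region label has any valid voxel.",
                 class = "cryoredox_empty_ratio")
  }
  rows <- lapply(present, function(l) {
    sel <- vol$valid & labels == l
    tibble::tibble(
      label = as.integer(l),
      region = if (as.character(l) %in% names(region_names))
        unname(region_names[as.character(l)]) else as.character(l),
      mean_rr = mean(vol$rr[sel]),
      n_valid = sum(sel))
  })
  dplyr::bind_rows(rows)
}

#' Percent decrease of a test group mean relative to a reference mean
#'
#' `100 * (reference - test) / reference`; negative values indicate an
#' increase. This is the effect size used to compare a mutant group's mean
#' redox ratio against its control.
#'
#' @param reference_mean Reference (e.g. control) mean; must be positive.
#' @param test_mean Test (e.g. mutant) mean.
#' @return Percent decrease (a single number, in percent).
#' @examples
#' percent_decrease(1.0, 0.681) # 31.9
#' @export
percent_decrease <- function(reference_mean, test_mean) {
  if (!is.finite(reference_mean) || reference_mean <= 0) {
    rlang::abort("`reference_mean` must be positive.",
                 class = "cryoredox_param_error")
  }
  100 * (reference_mean - test_mean) / reference_mean
}
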