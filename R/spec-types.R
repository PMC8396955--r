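#' Acquisition geometry and detector metadata for a cryo-imaging stack
#'
#' Describes how one sample was (or is to be) imaged: slice thickness and
#' count, in-plane frame size, detector bit depth and pixel pitch. These are
#' the parameters of a serial block-face cryo-imager that alternates microtome
#' cuts with surface fluorescence snapshots; defaults mirror a 25 um microtome
#' step, ~150 slices per organ and a 16-bit CCD.
#'
#' @param slice_thickness_um Microtome step between successive slices, in
#'   micrometres. Default 25.
#' @param n_slices Number of slices (z extent of the volume). Default 150.
#' @param slice_shape Integer vector `c(rows, cols)` of the in-plane frame
#'   size. Default `c(128, 128)`.
#' @param bit_depth Detector bit depth; 8 or 16. Default 16.
#' @param pixel_size_um In-plane pixel pitch in micrometres. Default 25.
#' @return An object of class `acquisition_spec`.
#' @examples
#' acquisition_spec(n_slices = 60)
#' @export
acquisition_spec <- function(slice_thickness_um = 25, n_slices = 150,
                             slice_shape = c(128L, 128L), bit_depth = 16L,
                             pixel_size_um = 25) {
  stopifnot(length(slice_shape) == 2)
  slice_shape <- as.integer(slice_shape)
  n_slices <- as.integer(n_slices)
  if (!bit_depth %in% c(8L, 16L)) {
    rlang::abort("`bit_depth` must be 8 or 16.", class = "cryoredox_param_error")
  }
  if (n_slices < 1L || any(slice_shape < 8L)) {
    rlang::abort("Need `n_slices` >= 1 and both slice dimensions >= 8.",
                 class = "cryoredox_param_error")
  }
  if (slice_thickness_um <= 0 || pixel_size_um <= 0) {
    rlang::abort("Physical voxel dimensions must be positive.",
                 class = "cryoredox_param_error")
  }
  structure(
    list(slice_thickness_um = slice_thickness_um, n_slices = n_slices,
         slice_shape = slice_shape, bit_depth = as.integer(bit_depth),
         pixel_size_um = pixel_size_um),
    class = "acquisition_spec"
  )
}

#' @export
print.acquisition_spec <- function(x, ...) {
  cat(sprintf("<acquisition_spec> %d x %d px, %d slices, %d-bit, %g um slice / %g um pixel\n",
              x$slice_shape[1], x$slice_shape[2], x$n_slices, x$bit_depth,
              x$slice_thickness_um, x$pixel_size_um))
  invisible(x)
}

#' Volume dimensions implied by an acquisition spec
#'
#' @param acq An [acquisition_spec()].
#' @return Integer vector `c(rows, cols, n_slices)`.
#' @export
acq_dims <- function(acq) {
  stopifnot(inherits(acq, "acquisition_spec"))
  c(acq$slice_shape, acq$n_slices)
}

#' Organ geometry for the synthetic phantom
#'
#' Organs are modelled as ellipsoids in voxel space: a single ellipsoid for the
#' heart, and nested ellipsoids for the kidney where the inner ellipsoid
#' (scaled by `medulla_fraction`) is the medulla and the shell is the cortex.
#' Nesting preserves the cortex/medulla topology that makes kidney redox maps
#' regionally heterogeneous while keeping the geometry fully parametric.
#'
#' @param kind `"heart"` or `"kidney"`.
#' @param semi_axes_vox Positive semi-axes (row, col, z) of the outer
#'   ellipsoid, in voxels.
#' @param center_vox Ellipsoid centre (row, col, z), in (1-based, possibly
#'   fractional) voxel coordinates.
#' @param medulla_fraction Scale of the inner (medulla) ellipsoid relative to
#'   the outer one; kidney only. Default 0.45.
#' @return An object of class `organ_geometry`.
#' @seealso [default_geometry()] for a geometry sized to an acquisition spec.
#' @export
organ_geometry <- function(kind = c("heart", "kidney"), semi_axes_vox,
                           center_vox, medulla_fraction = 0.45) {
  kind <- match.arg(kind)
  stopifnot(length(semi_axes_vox) == 3, length(center_vox) == 3)
  if (any(semi_axes_vox <= 0)) {
    rlang::abort("Semi-axes must be positive.", class = "cryoredox_param_error")
  }
  if (medulla_fraction < 0 || medulla_fraction >= 1) {
    rlang::abort("`medulla_fraction` must lie in [0, 1).",
                 class = "cryoredox_param_error")
  }
  structure(
    list(kind = kind, semi_axes_vox = as.numeric(semi_axes_vox),
         center_vox = as.numeric(center_vox),
         medulla_fraction = medulla_fraction),
    class = "organ_geometry"
  )
}

#' @export
print.organ_geometry <- function(x, ...) {
  cat(sprintf("<organ_geometry> %s, semi-axes (%s) vox, centre (%s)%s\n",
              x$kind, paste(signif(x$semi_axes_vox, 4), collapse = ", "),
              paste(signif(x$center_vox, 4), collapse = ", "),
              if (x$kind == "kidney")
                sprintf(", medulla fraction %.2f", x$medulla_fraction) else ""))
  invisible(x)
}

#' Default organ geometry for a given acquisition spec
#'
#' Centres the organ in the volume (at half-voxel offsets so slice
#' cross-sections never degenerate to a single plane) and sizes the semi-axes
#' to leave a comfortable margin of embedding medium on every side.
#'
#' The z semi-axis is snapped to an integer: with the centre at a half-voxel
#' offset, the outermost intersected slice then sits half a voxel inside the
#' pole, so its cross-section stays near `pi * a * b / c` voxels instead of
#' degenerating to a sliver that per-slice small-object cleanup would drop.
#'
#' @inheritParams organ_geometry
#' @param acq An [acquisition_spec()].
#' @param fill Fraction of each half-dimension used by the semi-axis.
#'   Default 0.72.
#' @return An `organ_geometry`.
#' @export
default_geometry <- function(acq, kind = c("heart", "kidney"), fill = 0.72,
                             medulla_fraction = 0.45) {
  kind <- match.arg(kind)
  dims <- acq_dims(acq)
  semi <- pmax(3, fill * dims / 2)
  semi[3] <- max(3, round(semi[3]))
  organ_geometry(kind = kind,
                 semi_axes_vox = semi,
                 center_vox = (dims + 1) / 2,
                 medulla_fraction = medulla_fraction)
}

#' Group-level ground-truth parameters for a synthetic cohort
#'
#' Each experimental group (e.g. wild-type control vs a severe mutant) is
#' described by the number of animals, the group-level mean redox ratio, the
#' between-animal SD of per-animal mean RR, the within-organ spatial SD of the
#' smooth RR field, and (kidneys) an additive medullary RR offset.
#'
#' @param name Group label.
#' @param n_samples Number of animals in the group.
#' @param rr_mean Group-level true mean redox ratio (NADH/FAD); must be
#'   positive.
#' @param rr_between_sd Between-animal SD of the per-animal mean RR.
#' @param rr_within_sd SD of the smooth spatial RR variation within an organ.
#'   Default 0.1.
#' @param medulla_rr_offset Additive RR offset applied inside the medulla
#'   (kidney geometries only). Default 0.
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(name, n_samples, rr_mean, rr_between_sd = 0,
                       rr_within_sd = 0.1, medulla_rr_offset = 0) {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L) {
    rlang::abort(sprintf("Group '%s' must have at least one sample.", name),
                 class = "cryoredox_config_error")
  }
  if (rr_mean <= 0 || rr_between_sd < 0 || rr_within_sd < 0) {
    rlang::abort("Need `rr_mean` > 0 and nonnegative SDs.",
                 class = "cryoredox_param_error")
  }
  if (rr_mean - 3 * rr_between_sd <= 0) {
    rlang::abort("`rr_mean` - 3 * `rr_between_sd` must stay positive.",
                 class = "cryoredox_param_error")
  }
  structure(
    list(name = as.character(name), n_samples = n_samples, rr_mean = rr_mean,
         rr_between_sd = rr_between_sd, rr_within_sd = rr_within_sd,
         medulla_rr_offset = medulla_rr_offset),
    class = "group_spec"
  )
}

#' @export
print.group_spec <- function(x, ...) {
  cat(sprintf("<group_spec> '%s': n = %d, RR %.3f (between-SD %.3f, within-SD %.3f%s)\n",
              x$name, x$n_samples, x$rr_mean, x$rr_between_sd, x$rr_within_sd,
              if (x$medulla_rr_offset != 0)
                sprintf(", medulla offset %+.2f", x$medulla_rr_offset) else ""))
  invisible(x)
}

#' CCD noise and intensity model for rendered phantom channels
#'
#' The forward model holds the FAD channel at a constant in-tissue base level
#' and derives NADH as RR x FAD, then applies the standard CCD noise chain:
#' optional Poisson shot noise on the fluorescence signal, a constant
#' background offset, additive Gaussian read noise, clipping to the detector
#' range and integer quantization.
#'
#' @param fad_base_intensity Mean in-tissue FAD signal, in detector counts.
#'   Default 1000.
#' @param background_offset Constant detector background added to both
#'   channels, in counts. Default 50.
#' @param read_noise_sd SD of the additive Gaussian read noise, in counts.
#'   Default 10.
#' @param shot_noise Apply Poisson shot noise to the fluorescence signal?
#'   Default `TRUE`.
#' @param seed Optional default seed used when a rendering call does not pass
#'   its own.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(fad_base_intensity = 1000, background_offset = 50,
                       read_noise_sd = 10, shot_noise = TRUE, seed = NULL) {
  if (fad_base_intensity <= 0 || background_offset < 0 || read_noise_sd < 0) {
    rlang::abort("Intensities must be positive and noise SDs nonnegative.",
                 class = "cryoredox_param_error")
  }
  structure(
    list(fad_base_intensity = fad_base_intensity,
         background_offset = background_offset,
         read_noise_sd = read_noise_sd,
         shot_noise = isTRUE(shot_noise),
         seed = seed),
    class = "noise_spec"
  )
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("<noise_spec> FAD base %g, background %g, read SD %g, shot noise %s\n",
              x$fad_base_intensity, x$background_offset, x$read_noise_sd,
              if (x$shot_noise) "on" else "off"))
  invisible(x)
}

#' A noise spec with all stochastic terms and offsets switched off
#'
#' Convenience for noiseless phantoms: no shot noise, no read noise, no
#' background. Under this spec the rendered channels reproduce the ground
#' truth up to integer quantization only.
#'
#' @inheritParams noise_spec
#' @return A `noise_spec`.
#' @export
noiseless_spec <- function(fad_base_intensity = 1000) {
  noise_spec(fad_base_intensity = fad_base_intensity, background_offset = 0,
             read_noise_sd = 0, shot_noise = FALSE)
}

# Check that the organ ellipsoid fits the volume with >= 2 voxels of margin.
validate_geometry_fits <- function(geometry, acq) {
  dims <- acq_dims(acq)
  lo <- geometry$center_vox - geometry$semi_axes_vox
  hi <- geometry$center_vox + geometry$semi_axes_vox
  # need two integer voxel planes of embedding medium outside each face
  if (any(lo <= 2) || any(hi >= dims - 1)) {
    rlang::abort(
      sprintf("Organ ellipsoid does not fit the %s volume with a 2-voxel margin.",
              paste(dims, collapse = "x")),
      class = "cryoredox_dim_error")
  }
  invisible(TRUE)
}
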