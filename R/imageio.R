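# Stack I/O. Canonical container: multi-page grayscale TIFF, one file per
# channel per sample; page index = z slice (page 1 = first cut face). Volumes
# are numeric arrays indexed [row, col, z], origin top-left, 1-based.
#
# Integer stacks (8/16-bit) go through the tiff package. Real-valued volumes
# (redox ratios) are stored as 32-bit IEEE float with NaN marking invalid
# voxels; they are written by a minimal uncompressed writer in this file
# (float samples outside [0, 1] and NaN must survive verbatim) and read back
# through tiff::readTIFF, i.e. libtiff, which keeps the format honest.

CHANNEL_FILTERS <- list(
  NADH = list(excitation_nm = 350, emission_nm = 460),
  FAD  = list(excitation_nm = 437, emission_nm = 537)
)

#' Construct a single-channel intensity stack
#'
#' @param voxels Numeric 3D array `[row, col, z]` of nonnegative intensities
#'   within the detector range.
#' @param channel `"NADH"` or `"FAD"`.
#' @param acq An [acquisition_spec()]; its dimensions must match `voxels`.
#' @param sample_id Sample identifier.
#' @return An object of class `channel_stack`. The excitation/emission filter
#'   centres for the channel are attached as metadata labels.
#' @export
channel_stack <- function(voxels, channel = c("NADH", "FAD"), acq,
                          sample_id = "sample") {
  channel <- match.arg(channel)
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  if (!identical(as.integer(dim(voxels)), as.integer(acq_dims(acq)))) {
    rlang::abort(sprintf(
      "Voxel array is %s but the acquisition spec says %s.",
      paste(dim(voxels), collapse = "x"),
      paste(acq_dims(acq), collapse = "x")), class = "cryoredox_dim_error")
  }
  maxval <- 2^acq$bit_depth - 1
  if (min(voxels) < 0 || max(voxels) > maxval) {
    rlang::abort(sprintf("Intensities must lie in [0, %d].", maxval),
                 class = "cryoredox_param_error")
  }
  structure(
    list(voxels = voxels, channel = channel, acq = acq,
         sample_id = as.character(sample_id),
         filters = CHANNEL_FILTERS[[channel]]),
    class = "channel_stack"
  )
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<channel_stack> %s '%s': %dx%d px, %d slices, %d-bit (ex %g / em %g nm)\n",
              x$channel, x$sample_id, d[1], d[2], d[3], x$acq$bit_depth,
              x$filters$excitation_nm, x$filters$emission_nm))
  invisible(x)
}

#' @export
dim.channel_stack <- function(x) dim(x$voxels)

#' Pair co-registered NADH and FAD stacks for one sample
#'
#' @param nadh,fad `channel_stack` objects for the two channels.
#' @return An object of class `volume_pair` with members `nadh` and `fad`.
#'   Fails if the shapes, sample ids or acquisition metadata disagree.
#' @export
pair_channels <- function(nadh, fad) {
  stopifnot(inherits(nadh, "channel_stack"), inherits(fad, "channel_stack"))
  if (nadh$channel != "NADH" || fad$channel != "FAD") {
    rlang::abort("Arguments must be the NADH and FAD stacks, in that order.",
                 class = "cryoredox_pairing_error")
  }
  if (!identical(dim(nadh$voxels), dim(fad$voxels))) {
    rlang::abort(sprintf("Channel shapes differ: NADH %s vs FAD %s.",
                         paste(dim(nadh$voxels), collapse = "x"),
                         paste(dim(fad$voxels), collapse = "x")),
                 class = "cryoredox_pairing_error")
  }
  if (!identical(nadh$sample_id, fad$sample_id)) {
    rlang::abort(sprintf("Sample ids differ: '%s' vs '%s'.",
                         nadh$sample_id, fad$sample_id),
                 class = "cryoredox_pairing_error")
  }
  if (!identical(unclass(nadh$acq), unclass(fad$acq))) {
    rlang::abort("Acquisition metadata differs between the channels.",
                 class = "cryoredox_pairing_error")
  }
  structure(list(nadh = nadh, fad = fad, sample_id = nadh$sample_id),
            class = "volume_pair")
}

#' @export
print.volume_pair <- function(x, ...) {
  d <- dim(x$nadh$voxels)
  cat(sprintf("<volume_pair> '%s': NADH + FAD, %dx%dx%d\n",
              x$sample_id, d[1], d[2], d[3]))
  invisible(x)
}

# ---- reading ---------------------------------------------------------------

read_pages <- function(path) {
  # as.is keeps native integer counts; unsupported for float samples, which
  # already come back verbatim
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) tiff::readTIFF(path, all = TRUE))
  if (!is.list(pages)) pages <- list(pages)
  pages
}

#' Read a slice stack from a multi-page TIFF or a directory of slice TIFFs
#'
#' Directories are read in lexicographic filename order (zero-padded numeric
#' suffixes recommended); multi-page files in page order. Either way, slice 1
#' is the first cut face. Integer TIFFs keep their native counts; 32-bit
#' float TIFFs keep their values (including NaN).
#'
#' @param path A TIFF file or a directory containing per-slice TIFFs.
#' @param channel `"NADH"` or `"FAD"`.
#' @param acq Optional [acquisition_spec()]; defaults to one inferred from
#'   the data (25 um slices/pixels, bit depth from the data range).
#' @param sample_id Sample identifier; defaults to the file/directory name
#'   stripped of a trailing `_NADH`/`_FAD` suffix.
#' @return A `channel_stack`.
#' @export
read_stack <- function(path, channel = c("NADH", "FAD"), acq = NULL,
                       sample_id = NULL) {
  channel <- match.arg(channel)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0) {
      rlang::abort(sprintf("No TIFF slices found in '%s'.", path),
                   class = "cryoredox_format_error")
    }
    pages <- lapply(files, function(f) {
      p <- read_pages(f)
      if (length(p) != 1) {
        rlang::abort(sprintf("Slice file '%s' has %d pages; expected 1.",
                             basename(f), length(p)),
                     class = "cryoredox_format_error")
      }
      p[[1]]
    })
    names(pages) <- basename(files)
  } else if (file.exists(path)) {
    pages <- read_pages(path)
  } else {
    rlang::abort(sprintf("'%s' does not exist.", path),
                 class = "cryoredox_format_error")
  }
  if (length(pages) == 0) {
    rlang::abort("Empty stack.", class = "cryoredox_format_error")
  }
  shp <- dim(pages[[1]])
  for (i in seq_along(pages)) {
    if (!identical(dim(pages[[i]]), shp)) {
      bad <- if (!is.null(names(pages))) names(pages)[i] else sprintf("page %d", i)
      rlang::abort(sprintf("Slice '%s' is %s, but the first slice is %s.",
                           bad, paste(dim(pages[[i]]), collapse = "x"),
                           paste(shp, collapse = "x")),
                   class = "cryoredox_format_error")
    }
  }
  vox <- array(0, dim = c(shp, length(pages)))
  for (i in seq_along(pages)) vox[, , i] <- pages[[i]]
  if (is.null(acq)) {
    bit_depth <- if (max(vox) > 255) 16L else if (max(vox) <= 1) 16L else 8L
    acq <- acquisition_spec(n_slices = length(pages), slice_shape = shp,
                            bit_depth = bit_depth)
  }
  if (is.null(sample_id)) {
    sample_id <- sub("_(NADH|FAD)$", "",
                     tools::file_path_sans_ext(basename(path)))
  }
  channel_stack(vox, channel, acq, sample_id)
}

# ---- writing ---------------------------------------------------------------

# Minimal uncompressed little-endian multi-page 32-bit float grayscale TIFF.
# One strip per page; SampleFormat = IEEE float so NaN and values outside
# [0, 1] are stored verbatim.
write_float_tiff <- function(vol, path) {
  dims <- dim(vol)
  nr <- dims[1]; nc <- dims[2]; nz <- dims[3]
  npix <- nr * nc
  n_entries <- 9L
  ifd_size <- 2L + n_entries * 12L + 4L
  data_size <- npix * 4L
  # layout: 8-byte header, then per page [pixel data][IFD]
  data_off <- 8L + (seq_len(nz) - 1L) * (data_size + ifd_size)
  ifd_off <- data_off + data_size
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  writeChar("II", con, nchars = 2, eos = NULL)
  wi(42L, 2); wi(ifd_off[1], 4)
  entry <- function(tag, type, count, value) {
    wi(tag, 2); wi(type, 2); wi(count, 4); wi(value, 4)
  }
  for (k in seq_len(nz)) {
    # TIFF is row-major within a strip
    writeBin(as.numeric(t(vol[, , k])), con, size = 4, endian = "little")
    wi(n_entries, 2)
    entry(256L, 3L, 1L, nc)            # ImageWidth
    entry(257L, 3L, 1L, nr)            # ImageLength
    entry(258L, 3L, 1L, 32L)           # BitsPerSample
    entry(259L, 3L, 1L, 1L)            # Compression: none
    entry(262L, 3L, 1L, 1L)            # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_off[k])   # StripOffsets
    entry(278L, 3L, 1L, nr)            # RowsPerStrip
    entry(279L, 4L, 1L, data_size)     # StripByteCounts
    entry(339L, 3L, 1L, 3L)            # SampleFormat: IEEE float
    wi(if (k < nz) ifd_off[k + 1] else 0L, 4)
  }
  invisible(path)
}

write_int_tiff <- function(vol, path, bit_depth) {
  maxval <- 2^bit_depth - 1
  pages <- lapply(seq_len(dim(vol)[3]), function(k) vol[, , k] / maxval)
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bit_depth),
                  compression = "none")
  invisible(path)
}

#' Write a stack or volume as a multi-page grayscale TIFF
#'
#' `channel_stack` objects and integer-valued arrays are written at their
#' native bit depth (8 or 16 bit). Real-valued volumes (e.g. redox-ratio
#' volumes) are written as 32-bit IEEE float, with NaN preserved for invalid
#' voxels. Page order is slice order.
#'
#' @param x A `channel_stack`, an `rr_volume`, or a numeric 3D array.
#' @param path Output file path; the parent directory must exist.
#' @param bit_depth Bit depth for bare integer arrays (default 16); ignored
#'   for `channel_stack` (taken from its metadata) and float volumes.
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path, bit_depth = 16L) {
  if (!dir.exists(dirname(path))) {
    rlang::abort(sprintf("Parent directory '%s' does not exist.", dirname(path)),
                 class = "cryoredox_io_error")
  }
  if (inherits(x, "channel_stack")) {
    return(invisible(write_int_tiff(x$voxels, path, x$acq$bit_depth)))
  }
  if (inherits(x, "rr_volume")) x <- x$rr
  stopifnot(is.array(x), length(dim(x)) == 3)
  if (any(is.infinite(x))) {
    rlang::abort("Volume contains non-finite values other than NaN.",
                 class = "cryoredox_value_error")
  }
  is_int <- !anyNA(x) && all(x == round(x)) && min(x) >= 0 &&
    max(x) <= 2^bit_depth - 1
  if (is_int) {
    invisible(write_int_tiff(x, path, bit_depth))
  } else {
    x[is.na(x)] <- NaN
    invisible(write_float_tiff(x, path))
  }
}

#' Read a real-valued (redox-ratio) volume from a float TIFF
#'
#' @param path Path to a 32-bit float multi-page TIFF.
#' @return A numeric 3D array with NaN at invalid voxels.
#' @export
read_volume <- function(path) {
  pages <- read_pages(path)
  vox <- array(NA_real_, dim = c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) vox[, , i] <- pages[[i]]
  vox
}

# Ground-truth / segmentation masks as 8-bit 0/255 TIFFs.
write_mask <- function(mask, path) {
  write_int_tiff(array(ifelse(mask, 255, 0), dim = dim(mask)), path, 8L)
}

read_mask <- function(path) {
  vol <- read_volume(path)
  vol > 127
}

# Region labels (small nonnegative integers) as 8-bit TIFF.
write_labels <- function(labels, path) {
  write_int_tiff(labels, path, 8L)
}

read_labels <- function(path) {
  vol <- read_volume(path)
  array(as.integer(round(vol)), dim = dim(vol))
}
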