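#' Write an image stack as a multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered z-major (all channels of plane 1, then plane 2, ...).
#' Pixel pitch, channel names and acquisition metadata go to
#' `<path>.json`. Requires the `tiff` package.
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required", call. = FALSE)
  d <- dim(stack$data)
  pages <- list()
  for (z in seq_len(d[4])) for (ci in seq_len(d[3]))
    pages[[length(pages) + 1L]] <- stack$data[, , ci, z]
  mx <- max(1, max(stack$data))
  tiff::writeTIFF(lapply(pages, function(p) p / mx), path,
                  bits.per.sample = 16L)
  jsonlite::write_json(list(channels = stack$channels,
                            pixel_pitch_um = stack$pixel_pitch_um,
                            intensity_scale = mx,
                            dim = d, meta = stack$meta[c("fov_um", "z_planes",
                                                         "z_step_um")]),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#' @param path TIFF path (the `<path>.json` sidecar must exist).
#' @return An `image_stack`.
#' @export
read_image_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required", call. = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- meta$dim
  data <- array(0L, dim = d)
  k <- 0L
  for (z in seq_len(d[4])) for (ci in seq_len(d[3])) {
    k <- k + 1L
    data[, , ci, z] <- round(pages[[k]] * meta$intensity_scale)
  }
  structure(list(data = data, channels = meta$channels,
                 pixel_pitch_um = meta$pixel_pitch_um,
                 meta = as.list(meta$meta)), class = "image_stack")
}

#' Write a decay image as a flat binary array with a JSON sidecar
#'
#' Counts are stored as little-endian 32-bit integers in (y, x, bin) order;
#' the sidecar records dimensions, bin width and the IRF curve.
#'
#' @param dimg A `decay_image`.
#' @param path Output path (binary); sidecar at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_decay_image <- function(dimg, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(dimg$counts), con, size = 4L, endian = "little")
  jsonlite::write_json(list(dim = dim(dimg$counts),
                            bin_width_ps = dimg$bin_width_ps,
                            irf = dimg$irf$curve,
                            irf_fwhm_ps = dimg$irf$fwhm_ps,
                            irf_center_ps = dimg$irf$center_ps),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a decay image written by [write_decay_image()]
#' @param path Binary path (with `<path>.json` sidecar).
#' @return A `decay_image`.
#' @export
read_decay_image <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(path, "rb")
  on.exit(close(con))
  counts <- array(readBin(con, "integer", n = n, size = 4L,
                          endian = "little"), dim = meta$dim)
  irf <- structure(list(curve = meta$irf, bin_width_ps = meta$bin_width_ps,
                        n_bins = length(meta$irf),
                        fwhm_ps = meta$irf_fwhm_ps,
                        center_ps = meta$irf_center_ps), class = "irf")
  structure(list(counts = counts, irf = irf,
                 bin_width_ps = meta$bin_width_ps, frame = meta$dim[1],
                 owner = NULL, acq = NULL), class = "decay_image")
}

#' Write segmentation labels as a 16-bit TIFF
#' @param labels Integer label matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_image <- function(labels, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required", call. = FALSE)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
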