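#' Write a sinogram container
#'
#' Plain-text directory container: `B.csv` (views x bins line integrals),
#' `angles.csv`, `channel_of_view.csv`, and `header.json` with the geometry
#' and acquisition metadata.
#'
#' @param sino a [simulate_kvp_switching_scan()] result.
#' @param dir output directory (created if needed).
#' @export
write_sinogram <- function(sino, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(sino$B, file.path(dir, "B.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(sino$geometry$view_angles, file.path(dir, "angles.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(sino$channel_of_view,
                     file.path(dir, "channel_of_view.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  g <- sino$geometry
  hdr <- list(kvps = sino$kvps,
              n_pixels = g$n_pixels, pixel_size_cm = g$pixel_size_cm,
              sad_cm = g$sad_cm, sdd_cm = g$sdd_cm,
              n_detector_bins = g$n_detector_bins,
              detector_bin_width_cm = g$detector_bin_width_cm,
              n_clamped = sino$n_clamped)
  jsonlite::write_json(hdr, file.path(dir, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a sinogram container written by [write_sinogram()]
#'
#' @param dir container directory.
#' @return A `multi_channel_sinogram` (without spectra / protocol, which are
#'   not needed for reconstruction).
#' @export
read_sinogram <- function(dir) {
  hdr <- jsonlite::read_json(file.path(dir, "header.json"),
                             simplifyVector = TRUE)
  B <- as.matrix(utils::read.table(file.path(dir, "B.csv"), sep = ","))
  dimnames(B) <- NULL
  angles <- as.numeric(utils::read.table(file.path(dir, "angles.csv"),
                                         sep = ",")[[1]])
  chan <- as.integer(utils::read.table(file.path(dir, "channel_of_view.csv"),
                                       sep = ",")[[1]])
  geometry <- scan_geometry(n_pixels = hdr$n_pixels,
                            pixel_size_cm = hdr$pixel_size_cm,
                            sad_cm = hdr$sad_cm, sdd_cm = hdr$sdd_cm,
                            n_detector_bins = hdr$n_detector_bins,
                            detector_bin_width_cm = hdr$detector_bin_width_cm,
                            view_angles = angles)
  structure(list(B = B, channel_of_view = chan, kvps = hdr$kvps,
                 geometry = geometry, n_clamped = hdr$n_clamped),
            class = "multi_channel_sinogram")
}

#' Write an image as 32-bit TIFF with a range sidecar
#'
#' TIFF stores values in `[0, 1]`, so the image is min-max scaled and the
#' affine range is recorded in a small JSON sidecar (`<path>.json`) for exact
#' restoration by [read_image_tiff()].
#'
#' @param image image matrix (any real values).
#' @param path output file path.
#' @export
write_image_tiff <- function(image, path) {
  lo <- min(image)
  hi <- max(image)
  scaled <- if (hi > lo) (image - lo) / (hi - lo) else image * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(min = lo, max = hi), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image written by [write_image_tiff()]
#' @param path TIFF file path.
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    rng <- jsonlite::read_json(side, simplifyVector = TRUE)
    img <- img * (rng$max - rng$min) + rng$min
  }
  img
}
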