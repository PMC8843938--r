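#' Fan-beam scan geometry
#'
#' Describes a circular fan-beam acquisition on the central slice: source and
#' detector distances, the view angles of a full rotation, and the equiangular
#' detector arc. The reconstruction grid is square with the isocenter at its
#' center.
#'
#' @param n_pixels image grid side length (pixels).
#' @param pixel_size_cm pixel size in cm.
#' @param n_views number of projection views, evenly spaced over `[0, 2*pi)`.
#' @param sad_cm source-to-isocenter distance (cm).
#' @param sdd_cm source-to-detector distance (cm).
#' @param n_detector_bins number of detector bins. The default spans twice the
#'   grid diagonal at the detector plane with a bin width matched to the pixel
#'   size at the isocenter.
#' @param detector_bin_width_cm detector bin width (cm, arc length at the
#'   detector).
#' @param view_angles optional explicit ascending view angles in radians;
#'   overrides `n_views`.
#'
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(n_pixels = 256, pixel_size_cm = 0.1,
                          n_views = 600, sad_cm = 100, sdd_cm = 150,
                          n_detector_bins = NULL,
                          detector_bin_width_cm = NULL,
                          view_angles = NULL) {
  if (pixel_size_cm <= 0) stop("pixel size must be positive")
  if (sad_cm <= 0 || sdd_cm <= sad_cm)
    stop("need source_to_detector > source_to_isocenter > 0")
  mag <- sdd_cm / sad_cm
  if (is.null(detector_bin_width_cm))
    detector_bin_width_cm <- pixel_size_cm * mag
  diag_cm <- sqrt(2) * n_pixels * pixel_size_cm
  if (is.null(n_detector_bins))
    n_detector_bins <- 2L * as.integer(ceiling(diag_cm * mag /
                                                 detector_bin_width_cm / 2)) * 2L
  if (is.null(view_angles)) {
    view_angles <- seq(0, 2 * pi, length.out = n_views + 1)[seq_len(n_views)]
  } else {
    n_views <- length(view_angles)
  }
  if (any(diff(view_angles) <= 0))
    stop("view angles must be strictly increasing")
  if (max(view_angles) - min(view_angles) < 2 * pi * (1 - 2 / n_views))
    warning("view angles do not cover a full rotation")
  g <- list(n_pixels = as.integer(n_pixels),
            pixel_size_cm = pixel_size_cm,
            n_views = as.integer(n_views),
            view_angles = view_angles,
            sad_cm = sad_cm, sdd_cm = sdd_cm,
            n_detector_bins = as.integer(n_detector_bins),
            detector_bin_width_cm = detector_bin_width_cm,
            dgamma = detector_bin_width_cm / sdd_cm)
  class(g) <- "scan_geometry"
  g
}

#' @exportS3Method base::print
print.scan_geometry <- function(x, ...) {
  cat("Fan-beam scan geometry\n")
  cat(sprintf("  grid: %d x %d pixels, %.3g cm\n",
              x$n_pixels, x$n_pixels, x$pixel_size_cm))
  cat(sprintf("  SAD %.4g cm, SDD %.4g cm\n", x$sad_cm, x$sdd_cm))
  cat(sprintf("  %d views, %d detector bins of %.3g cm (equiangular)\n",
              x$n_views, x$n_detector_bins, x$detector_bin_width_cm))
  invisible(x)
}

# number of image pixels
n_image_pixels <- function(geometry) geometry$n_pixels^2L
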