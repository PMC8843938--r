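#' Filtered back projection for equiangular fan-beam data
#'
#' Direct fan-beam FBP: cosine pre-weighting of the sinogram, ramp filtering
#' along the detector coordinate in the frequency domain (zero-padded to the
#' next power of two), and pixel-driven backprojection with inverse-square
#' distance weighting. No fan-to-parallel rebinning is performed.
#'
#' @param sino `n_views x n_bins` matrix of line integrals.
#' @param geometry a [scan_geometry()].
#' @param views indices of the views in `sino` (default all); must be evenly
#'   spread over the rotation.
#' @param filter_name `"ramp"` or `"hann"` (Hann-apodized ramp).
#' @return `n x n` image of attenuation per cm.
#' @export
fbp_reconstruct <- function(sino, geometry, views = seq_len(geometry$n_views),
                            filter_name = c("ramp", "hann")) {
  stopifnot(inherits(geometry, "scan_geometry"))
  filter_name <- match.arg(filter_name)
  angles <- geometry$view_angles[views]
  nv <- length(angles)
  nb <- geometry$n_detector_bins
  if (!is.matrix(sino) || nrow(sino) != nv || ncol(sino) != nb)
    stop("sinogram must be n_views x n_detector_bins for the requested views")
  span <- (max(angles) - min(angles)) * nv / max(nv - 1, 1)
  if (span < 2 * pi * 0.98)
    warning("angular coverage below a full rotation; FBP will be inaccurate")

  dg <- geometry$dgamma
  gamma <- (seq_len(nb) - 1 - (nb - 1) / 2) * dg

  # cosine pre-weighting (equiangular fan)
  g2 <- sweep(sino, 2, geometry$sad_cm * cos(gamma), "*")

  # fan-beam ramp kernel: h(0) = 1/(8 dg^2), h(n odd) = -1/(2 pi^2 sin^2(n dg))
  npad <- 2^ceiling(log2(2 * nb))
  h <- numeric(npad)
  h[1] <- 1 / (8 * dg^2)
  n_odd <- seq(1, nb - 1, by = 2)
  h[1 + n_odd] <- -1 / (2 * pi^2 * sin(n_odd * dg)^2)
  h[npad + 1 - n_odd] <- h[1 + n_odd]
  H <- fft(h)
  if (filter_name == "hann") {
    f <- pmin(seq_len(npad) - 1, npad - (seq_len(npad) - 1)) / (npad / 2)
    H <- H * (0.5 + 0.5 * cos(pi * f))
  }

  # filter each view (columns of the transposed block) by circular convolution
  gp <- rbind(t(g2), matrix(0, npad - nb, nv))
  q <- Re(mvfft(mvfft(gp) * H, inverse = TRUE)) / npad
  q <- t(q[seq_len(nb), , drop = FALSE]) * dg

  dbeta <- 2 * pi / nv
  cpp_fan_backproject(q, angles, geometry$n_pixels, geometry$n_pixels,
                      geometry$pixel_size_cm, geometry$sad_cm, dg, dbeta)
}
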