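# Shared small fixtures, built once per test run.

# small geometry: 64-pixel grid (4 mm pixels, 25.6 cm FOV), 240 views
small_geometry <- function(n_views = 240) {
  scan_geometry(n_pixels = 64, pixel_size_cm = 0.4, n_views = n_views)
}

# uniform disk image of attenuation `mu` (per cm) and radius `r` (cm)
disk_image <- function(geometry, mu = 0.2, r = 8, center = c(0, 0)) {
  n <- geometry$n_pixels
  dx <- geometry$pixel_size_cm
  xs <- (seq_len(n) - 0.5) * dx - n * dx / 2
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(xs, n, n)
  ifelse((X - center[1])^2 + (Y - center[2])^2 <= r^2, mu, 0)
}

# dense projection matrix built column by column through the public
# forward-projection path; independent of the sparse storage
dense_projector <- function(P) {
  M <- ncol(P$P)
  vapply(seq_len(M), function(j) {
    e <- numeric(M)
    e[j] <- 1
    as.numeric(t(forward_project(e, P)))
  }, numeric(nrow(P$P)))
}

# default spectra triple used throughout
test_spectra <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- lapply(c(80, 100, 120), generate_spectrum)
    val
  }
})

# single-line spectrum at a given energy (for monoenergetic oracles)
mono_spectrum <- function(energy_kev, kvp = energy_kev) {
  structure(list(kvp = kvp, energy_kev = energy_kev, fluence = 1,
                 filtration_mm_al = 0), class = "spectrum")
}

# synthetic calibration materials with well-separated design rows
synthetic_materials <- function() {
  list(list(red = 1.00, lambda = c(H = 0.1119, O = 0.8881, I = 0)),
       list(red = 0.95, lambda = c(H = 0.30, O = 0.70, I = 0)),
       list(red = 1.05, lambda = c(H = 0.10, O = 0.88, I = 0.02)),
       list(red = 1.20, lambda = c(H = 0.05, O = 0.75, I = 0.20)))
}

# noiseless data generated exactly from the reconstruction model:
# F_true = X_true A, B = P F_true
model_instance <- function(n = 32, n_views = 120) {
  g <- scan_geometry(n_pixels = n, pixel_size_cm = 25.6 / n,
                     n_views = n_views)
  dict <- build_dictionary()
  calib <- calibrate_scanner(test_spectra(), method = "effective")
  KM <- compute_K_matrices(dict, calib$params, n * n)
  dx <- g$pixel_size_cm
  xs <- (seq_len(n) - 0.5) * dx - n * dx / 2
  X <- matrix(xs, n, n, byrow = TRUE); Y <- matrix(xs, n, n)
  body <- X^2 + Y^2 <= 10^2
  ins <- (X - 5)^2 + (Y - 2)^2 <= 2.5^2     # 3.5 mg/ml iodine blob
  c_i <- 3.5 / 1000
  lam_i <- c_i / (1 + c_i)
  rho_i <- 1 + c_i * (53 / 126.904) / meercbct:::.water_z_over_a
  E <- nrow(dict$Lambda)
  Xmat <- matrix(0, n * n, E)
  w <- match("water", dict$names)
  Xmat[body, w] <- 1
  Xmat[ins, w] <- rho_i * (1 - lam_i)
  Xmat[ins, dict$iodine_row] <- rho_i * lam_i
  F_true <- Xmat %*% KM$A
  channel_of_view <- rep_len(1:3, n_views)
  B <- matrix(0, n_views, g$n_detector_bins)
  projs <- list()
  for (ch in 1:3) {
    v <- which(channel_of_view == ch)
    projs[[ch]] <- build_system_matrix(g, v)
    B[v, ] <- matrix(as.numeric(projs[[ch]]$P %*% F_true[, ch]),
                     length(v), g$n_detector_bins, byrow = TRUE)
  }
  sino <- structure(list(B = B, channel_of_view = channel_of_view,
                         kvps = c(80, 100, 120), geometry = g),
                    class = "multi_channel_sinogram")
  list(sino = sino, F_true = F_true, X_true = Xmat, dict = dict,
       calib = calib, ins = ins, projs = projs, g = g)
}

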