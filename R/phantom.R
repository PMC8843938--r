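#' Digital nine-insert iodine phantom
#'
#' Voxelizes the cylindrical water phantom on the reconstruction grid: a
#' 20 cm diameter water body with nine 3 cm inserts, one (pure water) at the
#' center and eight on a 7.5 cm radius circle containing iodine-stock
#' dilutions. Ground-truth relative electron density, elemental fractions and
#' iodine density maps are derived from the insert materials.
#'
#' @param geometry a [scan_geometry()] defining the grid.
#' @param concentrations dilution fractions of the eight peripheral inserts
#'   (default the study set 0.1\%..10\%).
#' @param stock_mg_per_ml iodine stock strength (default 175).
#' @param body_material `"water"` (default) or `"acrylic"` for an
#'   experiment-like body.
#' @param body_radius_cm,insert_radius_cm,ring_radius_cm phantom dimensions.
#' @return Object of class `digital_phantom` with the label map, per-label
#'   materials, `rho` (rED map), `lambda` (M x 3), `iodine_mg_ml` truth map,
#'   and per-element density maps for the scan simulator.
#' @export
build_insert_phantom <- function(geometry,
                                 concentrations = c(0.001, 0.005, 0.010,
                                                    0.015, 0.020, 0.030,
                                                    0.050, 0.100),
                                 stock_mg_per_ml = 175,
                                 body_material = c("water", "acrylic"),
                                 body_radius_cm = 10,
                                 insert_radius_cm = 1.5,
                                 ring_radius_cm = 7.5) {
  stopifnot(inherits(geometry, "scan_geometry"))
  body_material <- match.arg(body_material)
  if (length(concentrations) != 8)
    stop("eight peripheral insert concentrations required")
  if (any(concentrations < 0 | concentrations > 1))
    stop("concentrations are stock dilution fractions in [0, 1]")
  if (ring_radius_cm + insert_radius_cm > body_radius_cm)
    stop("inserts extend beyond the phantom body")
  ang <- seq(0, 2 * pi, length.out = 9)[1:8]
  centers <- rbind(c(0, 0), cbind(ring_radius_cm * cos(ang),
                                  ring_radius_cm * sin(ang)))
  d <- as.matrix(stats::dist(centers))
  diag(d) <- Inf
  if (min(d) < 2 * insert_radius_cm) stop("inserts overlap")

  n <- geometry$n_pixels
  dx <- geometry$pixel_size_cm
  xs <- (seq_len(n) - 0.5) * dx - n * dx / 2
  X <- matrix(xs, n, n, byrow = TRUE)   # column -> x
  Y <- matrix(xs, n, n)                 # row -> y (bottom up)

  label <- matrix(0L, n, n)
  body <- X^2 + Y^2 <= body_radius_cm^2
  label[body] <- 1L
  for (m in seq_len(9)) {
    inside <- (X - centers[m, 1])^2 + (Y - centers[m, 2])^2 <=
      insert_radius_cm^2
    label[inside] <- 1L + m      # 2 = center water insert, 3..10 peripheral
  }

  body_mat <- if (body_material == "water") water_material()
              else acrylic_material()
  materials <- c(list(NULL, body_mat, water_material()),
                 lapply(concentrations, iodine_solution,
                        stock_mg_per_ml = stock_mg_per_ml))

  M <- n * n
  rho <- numeric(M)
  lambda <- matrix(0, M, 3, dimnames = list(NULL, c("H", "O", "I")))
  iodine <- numeric(M)
  elem_names <- unique(unlist(lapply(materials[-1],
                                     function(m) names(m$composition))))
  dens <- matrix(0, M, length(elem_names), dimnames = list(NULL, elem_names))
  for (lab in 1:10) {
    idx <- which(label == lab)
    if (!length(idx)) next
    m <- materials[[lab + 1L]]
    rho[idx] <- m$red
    lambda[idx, ] <- matrix(m$lambda, length(idx), 3, byrow = TRUE)
    iodine[idx] <- if (!is.null(m$iodine_mg_ml)) m$iodine_mg_ml else 0
    for (e in names(m$composition))
      dens[idx, e] <- m$density * m$composition[[e]]
  }

  structure(list(geometry = geometry, label = label,
                 materials = materials,
                 concentrations = concentrations,
                 stock_mg_per_ml = stock_mg_per_ml,
                 insert_centers_cm = centers,
                 insert_radius_cm = insert_radius_cm,
                 rho = matrix(rho, n, n),
                 lambda = lambda,
                 iodine_mg_ml = matrix(iodine, n, n),
                 element_density = dens),
            class = "digital_phantom")
}

#' @exportS3Method base::print
print.digital_phantom <- function(x, ...) {
  cat(sprintf("digital phantom: %d x %d grid, 9 inserts, dilutions %s\n",
              nrow(x$label), ncol(x$label),
              paste(sprintf("%.1f%%", 100 * x$concentrations),
                    collapse = ", ")))
  invisible(x)
}

#' Ground-truth per-channel attenuation images
#'
#' Evaluates the fluence-averaged attenuation of each phantom material under
#' each spectrum and paints it onto the label map; the reference `F` used for
#' image-error evaluation.
#'
#' @param phantom a [build_insert_phantom()] result.
#' @param spectra list of [generate_spectrum()] objects.
#' @return `n x n x N` array of attenuation per cm.
#' @export
make_ground_truth_channel_images <- function(phantom, spectra) {
  n <- nrow(phantom$label)
  out <- array(0, c(n, n, length(spectra)))
  for (i in seq_along(spectra)) {
    mu <- c(0, vapply(phantom$materials[-1], effective_channel_attenuation,
                      numeric(1), spectrum = spectra[[i]]))
    out[, , i] <- matrix(mu[phantom$label + 1L], n, n)
  }
  out
}
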