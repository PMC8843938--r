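# Embedded mass-attenuation tables and x-ray spectrum model.

.attenuation_env <- new.env(parent = emptyenv())

# Load the packaged element mass-attenuation table once per session.
attenuation_table <- function() {
  if (is.null(.attenuation_env$tab)) {
    path <- system.file("extdata", "mass_attenuation.csv", package = "meercbct",
                        mustWork = TRUE)
    .attenuation_env$tab <- read.csv(path, stringsAsFactors = FALSE)
  }
  .attenuation_env$tab
}

#' Mass attenuation coefficient of an element
#'
#' Log-log interpolation of the packaged tables (cm^2/g). The iodine K-edge at
#' 33.17 keV is represented by a breakpoint pair, so interpolation never
#' crosses the edge.
#'
#' @param element element symbol (one of H, C, N, O, Al, Cl, I).
#' @param energy_kev numeric vector of photon energies in keV.
#' @export
mass_attenuation <- function(element, energy_kev) {
  tab <- attenuation_table()
  sub <- tab[tab$element == element, ]
  if (nrow(sub) == 0) stop("unknown element symbol: ", element)
  if (any(energy_kev < min(sub$energy_kev) | energy_kev > max(sub$energy_kev)))
    stop("energy outside tabulated range for ", element)
  exp(approx(log(sub$energy_kev), log(sub$mu_rho_cm2_g),
             xout = log(energy_kev), rule = 1)$y)
}

#' Generate a filtered bremsstrahlung spectrum
#'
#' Kramers-law bremsstrahlung weights (proportional to `kvp - E`, i.e. the
#' energy-fluence form, which also absorbs the energy weighting of an
#' energy-integrating detector) hardened by an aluminium filter, tabulated on
#' a 1 keV grid from 10 keV to the tube voltage, and normalized to unit total
#' weight. Characteristic lines are not modeled, giving a smooth spectrum
#' that shifts monotonically with kVp.
#'
#' @param kvp tube voltage in kV (supported range 40-150).
#' @param filtration_mm_al aluminium filtration thickness in mm (default 2.5).
#' @return An object of class `spectrum` with `energy_kev` and `fluence`
#'   (weights summing to 1).
#' @export
generate_spectrum <- function(kvp, filtration_mm_al = 2.5) {
  if (kvp < 40 || kvp > 150) stop("kvp outside supported range [40, 150]")
  energy <- seq(10, kvp, by = 1)
  w <- kvp - energy
  mu_al <- mass_attenuation("Al", energy) * 2.699    # /cm in solid Al
  w <- w * exp(-mu_al * filtration_mm_al / 10)
  w[energy >= kvp] <- 0
  w <- w / sum(w)
  structure(list(kvp = kvp, energy_kev = energy, fluence = w,
                 filtration_mm_al = filtration_mm_al),
            class = "spectrum")
}

#' @exportS3Method base::print
print.spectrum <- function(x, ...) {
  cat(sprintf("x-ray spectrum: %g kVp, %g mm Al, mean energy %.1f keV\n",
              x$kvp, x$filtration_mm_al, sum(x$energy_kev * x$fluence)))
  invisible(x)
}

#' Fluence-averaged linear attenuation of a material
#'
#' Mixture-rule linear attenuation, weighted by the spectrum's photon fluence:
#' `sum_E w(E) * density * sum_e c_e (mu/rho)_e(E)` in 1/cm. Used to generate
#' ground-truth channel images, calibration targets, and the per-channel water
#' reference for HU conversion.
#'
#' @param material a [material()] (full elemental composition and density).
#' @param spectrum a [generate_spectrum()] result.
#' @export
effective_channel_attenuation <- function(material, spectrum) {
  stopifnot(inherits(material, "ct_material"), inherits(spectrum, "spectrum"))
  mu_rho <- rep(0, length(spectrum$energy_kev))
  for (e in names(material$composition)) {
    mu_rho <- mu_rho +
      material$composition[[e]] * mass_attenuation(e, spectrum$energy_kev)
  }
  material$density * sum(spectrum$fluence * mu_rho)
}

#' Convert attenuation to Hounsfield units
#'
#' `HU = 1000 * (mu - mu_water) / mu_water` applied per channel.
#'
#' @param image attenuation image (per cm); matrix or array.
#' @param water_reference positive scalar water attenuation for the channel.
#' @export
mu_to_hu <- function(image, water_reference) {
  if (any(water_reference <= 0)) stop("water reference must be positive")
  1000 * (image - water_reference) / water_reference
}
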