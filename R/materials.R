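#' Define a material by elemental composition and density
#'
#' A material carries its full elemental mass fractions (which may include
#' elements beyond H/O/I, e.g. carbon in acrylic), its mass density, and its
#' relative electron density (water = 1) derived from the electron content of
#' the mixture.
#'
#' @param name material name.
#' @param composition named numeric vector of elemental mass fractions summing
#'   to 1 (names are element symbols known to [mass_attenuation()]).
#' @param density mass density in g/cm^3.
#' @return Object of class `ct_material` with fields `name`, `composition`,
#'   `density`, `red` (relative electron density) and `lambda` (mass fractions
#'   restricted and renormalized to the modeled elements H, O, I).
#' @export
material <- function(name, composition, density) {
  composition <- unlist(composition)
  if (abs(sum(composition) - 1) > 1e-6)
    stop("composition mass fractions must sum to 1")
  unknown <- setdiff(names(composition), .elements$symbol)
  if (length(unknown)) stop("unknown element symbol: ", unknown[1])
  za <- .elements$z_over_a[match(names(composition), .elements$symbol)]
  red <- density * sum(composition * za) / .water_z_over_a
  lam <- c(H = 0, O = 0, I = 0)
  for (e in intersect(names(composition), c("H", "O", "I")))
    lam[e] <- composition[[e]]
  if (sum(lam) <= 0) stop("material has no H/O/I content")
  lam <- lam / sum(lam)
  structure(list(name = name, composition = as.list(composition),
                 density = density, red = red, lambda = lam),
            class = "ct_material")
}

#' @exportS3Method base::print
print.ct_material <- function(x, ...) {
  cat(sprintf("material '%s': density %.4g g/cc, rED %.4f\n",
              x$name, x$density, x$red))
  invisible(x)
}

#' Water
#' @export
water_material <- function() {
  material("water", c(H = 0.1119, O = 0.8881), density = 1.0)
}

#' Iodine solution as a dilution of a stock
#'
#' A \%w/w iodine-solution concentration is interpreted as the dilution fraction
#' of the iodine stock: a `dilution` of 0.025 of a 175 mgI/ml stock carries
#' 4.375 mg of elemental iodine per ml. The solution is modeled as water plus
#' the added iodine mass, neglecting the volume change, so the density is
#' `1 + c_I` g/cm^3 with `c_I` the iodine density in g/cm^3.
#'
#' @param dilution fraction of stock in `[0, 1]`.
#' @param stock_mg_per_ml iodine content of the stock (default 175 mgI/ml).
#' @export
iodine_solution <- function(dilution, stock_mg_per_ml = 175) {
  if (dilution < 0 || dilution > 1) stop("dilution must be in [0, 1]")
  c_i <- dilution * stock_mg_per_ml / 1000   # g iodine per cm^3
  total <- 1 + c_i
  comp <- c(H = 0.1119 / total, O = 0.8881 / total, I = c_i / total)
  m <- material(sprintf("iodine_%.3g%%", 100 * dilution), comp,
                density = total)
  m$iodine_mg_ml <- dilution * stock_mg_per_ml
  m
}

#' Acrylic (PMMA)
#' @export
acrylic_material <- function() {
  # C5H8O2, density 1.18 g/cc
  material("acrylic", c(H = 0.0805, C = 0.5998, O = 0.3197), density = 1.18)
}
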