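#' Build the elemental-composition dictionary
#'
#' Assembles the dictionary matrix Lambda (materials x elements) over the
#' modeled elements (H, O, I) from a tissue table of hydrogen and oxygen mass
#' fractions. Because only H, O and I are modeled, each tissue's H/O fractions
#' are renormalized to sum to one over (H, O): the carbon/nitrogen/... mass of
#' real tissues is redistributed onto the H/O balance. A pure-iodine entry
#' `(0, 0, 1)` is appended when `include_iodine` is set, so any iodine
#' concentration is expressible as a mixture of tissue and the iodine entry.
#' Calcium-bearing materials are intentionally absent.
#'
#' @param tissue_table data frame with columns `name`, `h_fraction`,
#'   `o_fraction` (mass fractions of the whole tissue); default is the
#'   packaged table of representative soft tissues.
#' @param include_iodine append the 100\% iodine entry (default TRUE).
#' @return Object of class `material_dictionary` with `names`, `Lambda`
#'   (E x 3), `z = c(1, 8, 53)` and `iodine_row` (index or NA).
#' @export
build_dictionary <- function(tissue_table = NULL, include_iodine = TRUE) {
  if (is.null(tissue_table)) {
    path <- system.file("extdata", "tissues.csv", package = "meercbct",
                        mustWork = TRUE)
    tissue_table <- read.csv(path, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "h_fraction", "o_fraction") %in% names(tissue_table)))
  tot <- tissue_table$h_fraction + tissue_table$o_fraction
  if (any(tot <= 0)) stop("tissue with zero H+O mass fraction")
  Lambda <- cbind(H = tissue_table$h_fraction / tot,
                  O = tissue_table$o_fraction / tot,
                  I = 0)
  names_ <- tissue_table$name
  iodine_row <- NA_integer_
  if (include_iodine) {
    Lambda <- rbind(Lambda, c(0, 0, 1))
    names_ <- c(names_, "iodine")
    iodine_row <- nrow(Lambda)
  }
  rownames(Lambda) <- names_
  structure(list(names = names_, Lambda = Lambda, z = c(1, 8, 53),
                 iodine_row = iodine_row),
            class = "material_dictionary")
}

#' @exportS3Method base::print
print.material_dictionary <- function(x, ...) {
  cat(sprintf("material dictionary: %d entries over elements H, O, I%s\n",
              nrow(x$Lambda),
              if (!is.na(x$iodine_row)) " (includes pure iodine)" else ""))
  invisible(x)
}

#' Derived K matrices of the reconstruction model
#'
#' From the dictionary and calibrated model coefficients, computes
#' `K[d, i] = k_pe_i z_d^3.62 + k_r_i z_d^1.86` (elements x channels), the
#' rank-one Compton matrices `K_MC` (pixels x channels) and `K_EC`
#' (entries x channels), and the dictionary-to-attenuation operator
#' `A = Lambda K + K_EC` used by the X-subproblem.
#'
#' @param dict a [build_dictionary()] result.
#' @param params an [attenuation_model_params()].
#' @param M number of image pixels (for `K_MC`).
#' @export
compute_K_matrices <- function(dict, params, M) {
  z <- dict$z
  K <- outer(z^.pe_exponent, params$k_pe) +
    outer(z^.rayleigh_exponent, params$k_r)                  # D x N
  kc <- params$k_c
  E <- nrow(dict$Lambda)
  K_EC <- matrix(kc, E, length(kc), byrow = TRUE)
  K_MC <- matrix(kc, M, length(kc), byrow = TRUE)
  A <- dict$Lambda %*% K + K_EC                              # E x N
  list(K = K, K_MC = K_MC, K_EC = K_EC, A = A)
}
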