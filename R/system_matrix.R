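#' Build the sparse x-ray system matrix
#'
#' Computes the ray-tracing projection matrix for a subset of views by Siddon's
#' exact intersection-length algorithm. Rows are ordered view-major (all
#' detector bins of the first requested view, then the second, ...); columns
#' index image pixels in R's column-major order with rows counting y from the
#' bottom of the grid.
#'
#' @param geometry a [scan_geometry()].
#' @param views integer indices of views to include (default: all views).
#' @return A `system_matrix` object wrapping a `Matrix::dgCMatrix` of
#'   intersection lengths in cm, with the geometry and view subset attached.
#' @export
build_system_matrix <- function(geometry, views = seq_len(geometry$n_views)) {
  stopifnot(inherits(geometry, "scan_geometry"))
  views <- as.integer(views)
  if (length(views) == 0) stop("view set must be nonempty")
  if (any(views < 1L | views > geometry$n_views)) stop("view index out of range")
  trip <- cpp_siddon_triplets(geometry$n_pixels, geometry$n_pixels,
                              geometry$pixel_size_cm, geometry$sad_cm,
                              geometry$sdd_cm, geometry$n_detector_bins,
                              geometry$dgamma, geometry$view_angles[views])
  P <- Matrix::sparseMatrix(
    i = trip$i + 1L, j = trip$j + 1L, x = trip$x,
    dims = c(length(views) * geometry$n_detector_bins,
             n_image_pixels(geometry)))
  structure(list(P = P, geometry = geometry, views = views),
            class = "system_matrix")
}

#' @exportS3Method base::print
print.system_matrix <- function(x, ...) {
  cat(sprintf("System matrix: %d rays x %d pixels, %d nonzeros (%d views)\n",
              nrow(x$P), ncol(x$P), length(x$P@x), length(x$views)))
  invisible(x)
}

#' Forward project an image
#'
#' Applies the system matrix to a single-channel image, returning the sinogram
#' block (line integrals) for the matrix's views as a `n_views x n_bins`
#' matrix.
#'
#' @param image `n x n` image matrix (attenuation per cm), or a flattened
#'   vector of the same length.
#' @param P a [build_system_matrix()] result.
#' @export
forward_project <- function(image, P) {
  stopifnot(inherits(P, "system_matrix"))
  x <- as.numeric(image)
  if (length(x) != ncol(P$P)) stop("image does not match projector dimensions")
  y <- as.numeric(P$P %*% x)
  matrix(y, nrow = length(P$views), ncol = P$geometry$n_detector_bins,
         byrow = TRUE)
}

#' Back project (adjoint of forward projection)
#'
#' Applies the transpose of the system matrix to a sinogram block. This is the
#' unweighted adjoint used inside iterative solvers, not filtered back
#' projection.
#'
#' @param sino `n_views x n_bins` sinogram block (or flattened vector in
#'   view-major ray order).
#' @param P a [build_system_matrix()] result.
#' @return `n x n` image matrix.
#' @export
back_project <- function(sino, P) {
  stopifnot(inherits(P, "system_matrix"))
  if (is.matrix(sino)) sino <- as.numeric(t(sino))
  if (length(sino) != nrow(P$P)) stop("sinogram does not match projector")
  n <- P$geometry$n_pixels
  matrix(as.numeric(Matrix::crossprod(P$P, sino)), n, n)
}

# ray order helper: flatten a (views x bins) block into view-major ray order
flatten_sino <- function(sino) as.numeric(t(sino))
unflatten_sino <- function(x, n_views, n_bins) {
  matrix(x, nrow = n_views, ncol = n_bins, byrow = TRUE)
}
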