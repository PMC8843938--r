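# Single-level undecimated piecewise-linear B-spline framelet in 2-D.
# 1-D filter bank: h0 = (1,2,1)/4 (low pass), h1 = sqrt(2)/4 * (1,0,-1),
# h2 = (-1,2,-1)/4; these satisfy sum_i |H_i(w)|^2 = 1, so the undecimated
# 2-D transform (9 separable bands, periodic boundaries) is a Parseval tight
# frame: t(W) %*% W = I and ||Wx|| = ||x||.

.tf_filters <- list(c(1, 2, 1) / 4,
                    sqrt(2) / 4 * c(1, 0, -1),
                    c(-1, 2, -1) / 4)

# circular 3-tap filtering along rows (dim 1) of a matrix; adjoint reverses
# the shift direction (equivalently applies the time-reversed filter)
.tf_filter_dim1 <- function(x, h, adjoint = FALSE) {
  n <- nrow(x)
  up <- c(2:n, 1)       # index i+1 (periodic)
  dn <- c(n, 1:(n - 1)) # index i-1
  if (!adjoint) h[1] * x[up, , drop = FALSE] + h[2] * x +
    h[3] * x[dn, , drop = FALSE]
  else h[1] * x[dn, , drop = FALSE] + h[2] * x +
    h[3] * x[up, , drop = FALSE]
}

#' Tight-frame analysis transform
#'
#' Applies the undecimated framelet filter bank to an image, returning the
#' nine sub-bands as an `n x n x 9` array. Periodic boundary handling keeps
#' the transform an exact Parseval frame.
#'
#' @param x `n x n` image matrix.
#' @export
tf_analysis <- function(x) {
  stopifnot(is.matrix(x))
  out <- array(0, c(nrow(x), ncol(x), 9))
  b <- 0L
  for (i in 1:3) {
    xi <- .tf_filter_dim1(x, .tf_filters[[i]])
    for (j in 1:3) {
      b <- b + 1L
      out[, , b] <- t(.tf_filter_dim1(t(xi), .tf_filters[[j]]))
    }
  }
  out
}

#' Tight-frame synthesis transform (adjoint of [tf_analysis()])
#'
#' @param u `n x n x 9` coefficient array.
#' @return `n x n` image; `tf_synthesis(tf_analysis(x))` recovers `x` to
#'   machine precision.
#' @export
tf_synthesis <- function(u) {
  stopifnot(length(dim(u)) == 3, dim(u)[3] == 9)
  out <- matrix(0, dim(u)[1], dim(u)[2])
  b <- 0L
  for (i in 1:3) {
    acc <- matrix(0, dim(u)[1], dim(u)[2])
    for (j in 1:3) {
      b <- b + 1L
      acc <- acc + t(.tf_filter_dim1(t(u[, , b]), .tf_filters[[j]],
                                     adjoint = TRUE))
    }
    out <- out + .tf_filter_dim1(acc, .tf_filters[[i]], adjoint = TRUE)
  }
  out
}

# elementwise signed soft-thresholding
soft_threshold <- function(x, thresh) {
  sign(x) * pmax(abs(x) - thresh, 0)
}
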