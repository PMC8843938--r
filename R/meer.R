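#' Hyperparameters of the joint reconstruction model
#'
#' Defaults follow the study's operating point: `beta = 50` (model-coupling
#' weight), `alpha1 = 1` (tight-frame sparsity), `alpha2 = 0.001` (dictionary
#' sparsity). The augmented-Lagrangian penalties `mu1`, `mu2` affect only the
#' convergence rate of the convex solver; tolerances and iteration caps are
#' engineering choices.
#'
#' @param beta,alpha1,alpha2 model weights (positive).
#' @param mu1,mu2 ADMM penalty parameters (positive).
#' @param tol outer relative-change stopping tolerance on `F`.
#' @param tol_inner inner (X-subproblem) relative-change tolerance.
#' @param k_max,p_max outer / inner iteration caps.
#' @param cg_iters,cg_tol conjugate-gradient cap and relative-residual
#'   tolerance for the F-subproblem.
#' @export
meer_params <- function(beta = 50, alpha1 = 1.0, alpha2 = 0.001,
                        mu1 = 12, mu2 = 10,
                        tol = 1e-3, tol_inner = 1e-4,
                        k_max = 40, p_max = 100,
                        cg_iters = 50, cg_tol = 1e-8) {
  vals <- c(beta = beta, alpha1 = alpha1, alpha2 = alpha2, mu1 = mu1,
            mu2 = mu2, k_max = k_max, p_max = p_max, cg_iters = cg_iters,
            cg_tol = cg_tol)
  if (any(vals < 0) || mu1 <= 0 || mu2 <= 0 || k_max < 1 || p_max < 1)
    stop("hyperparameters must be positive")
  structure(list(beta = beta, alpha1 = alpha1, alpha2 = alpha2,
                 mu1 = mu1, mu2 = mu2, tol = tol, tol_inner = tol_inner,
                 k_max = as.integer(k_max), p_max = as.integer(p_max),
                 cg_iters = as.integer(cg_iters), cg_tol = cg_tol),
            class = "meer_params")
}

# conjugate gradient for SPD systems; returns solution and iteration count
cg_solve <- function(apply_op, b, x0, tol, maxit) {
  x <- x0
  r <- b - apply_op(x)
  p <- r
  rs <- sum(r * r)
  bn <- sqrt(sum(b * b))
  if (bn == 0) return(list(x = 0 * b, iters = 0L, relres = 0))
  it <- 0L
  while (sqrt(rs) / bn > tol && it < maxit) {
    Ap <- apply_op(p)
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
    it <- it + 1L
  }
  list(x = x, iters = it, relres = sqrt(rs) / bn)
}

#' Objective value of the convex joint model
#'
#' `0.5 * sum_i ||P_i f_i - b_i||^2 + beta/2 ||F - X A||_F^2 +
#' alpha1 * sum_i ||W f_i||_1 + alpha2 * sum_j ||x_j||_1`.
#'
#' @param F `M x N` channel-attenuation matrix.
#' @param X `M x E` nonnegative coefficient matrix.
#' @param b_list list of per-channel ray-data vectors.
#' @param P_list list of per-channel [build_system_matrix()] objects.
#' @param A `E x N` dictionary-to-attenuation operator.
#' @param params a [meer_params()].
#' @export
objective_value <- function(F, X, b_list, P_list, A, params) {
  n <- as.integer(sqrt(nrow(F)))
  fid <- 0
  for (i in seq_along(P_list)) {
    r <- as.numeric(P_list[[i]]$P %*% F[, i]) - b_list[[i]]
    fid <- fid + sum(r^2)
  }
  tf <- 0
  for (i in seq_len(ncol(F)))
    tf <- tf + sum(abs(tf_analysis(matrix(F[, i], n, n))))
  0.5 * fid + params$beta / 2 * sum((F - X %*% A)^2) +
    params$alpha1 * tf + params$alpha2 * sum(abs(X))
}

#' Solve the F-subproblem by conjugate gradient
#'
#' Solves, per channel, the normal equations
#' `(P' P + (beta + mu1) I) f = P' b + beta (X A)_i + mu1 W'(U_i - eta1_i)`
#' (the tight frame satisfies `W' W = I`). Warm-started from `F_init`.
#'
#' @param P_list per-channel projectors.
#' @param Ptb_list per-channel precomputed `P' b` vectors.
#' @param XA `M x N` current model prediction `X %*% A` (or NULL when
#'   `beta = 0`).
#' @param U,eta1 per-channel lists of `n x n x 9` frame-coefficient arrays.
#' @param params a [meer_params()]; set `beta = 0` for the single-energy
#'   variant.
#' @param F_init `M x N` warm start.
#' @return list with updated `F` and per-channel CG iteration counts.
#' @export
solve_F_subproblem <- function(P_list, Ptb_list, XA, U, eta1, params,
                               F_init) {
  n <- as.integer(sqrt(nrow(F_init)))
  shift <- params$beta + params$mu1
  F_new <- F_init
  iters <- integer(length(P_list))
  for (i in seq_along(P_list)) {
    P <- P_list[[i]]$P
    rhs <- Ptb_list[[i]] +
      params$mu1 * as.numeric(tf_synthesis(U[[i]] - eta1[[i]]))
    if (params$beta > 0) rhs <- rhs + params$beta * XA[, i]
    op <- function(x) as.numeric(Matrix::crossprod(P, P %*% x)) + shift * x
    sol <- cg_solve(op, rhs, F_init[, i], params$cg_tol, params$cg_iters)
    if (sol$relres > sqrt(params$cg_tol))
      warning(sprintf("CG did not reach tolerance (channel %d, relres %.2e)",
                      i, sol$relres))
    F_new[, i] <- sol$x
    iters[i] <- sol$iters
  }
  list(F = F_new, cg_iters = iters)
}

#' Frame-coefficient update (soft shrinkage)
#'
#' Signed soft-thresholding of `W f + eta1` at `alpha1 / mu1`, applied to
#' every frame coefficient independently.
#'
#' @param WF frame coefficients of the current image (`n x n x 9` array).
#' @param eta1 multiplier array of the same shape.
#' @param alpha1,mu1 sparsity weight and penalty parameter.
#' @export
update_U <- function(WF, eta1, alpha1, mu1) {
  soft_threshold(WF + eta1, alpha1 / mu1)
}

#' Solve the X-subproblem by inner ADMM
#'
#' Minimizes `beta/2 ||F - X A||_F^2 + alpha2 ||X||_1` subject to `X >= 0`
#' by splitting with an auxiliary `Y`: the X-update is the row-wise linear
#' solve `X = (beta F A' + mu2 (Y - eta2)) (beta A A' + mu2 I)^-1`, the
#' Y-update the one-sided shrinkage `max(X + eta2 - alpha2/mu2, 0)`, followed
#' by the multiplier step. Returns the nonnegative-feasible iterate (the
#' final `Y`).
#'
#' @param F `M x N` current channel images.
#' @param A `E x N` dictionary operator.
#' @param Y_init,eta2_init warm starts (`M x E`).
#' @param params a [meer_params()].
#' @return list with `X` (nonnegative), `Y`, `eta2`, `iters`.
#' @export
solve_X_subproblem <- function(F, A, Y_init, eta2_init, params) {
  G <- solve(params$beta * A %*% t(A) +
               params$mu2 * diag(nrow(A)))          # E x E
  bFA <- params$beta * F %*% t(A)                   # M x E
  Y <- Y_init
  eta2 <- eta2_init
  X <- Y_init
  for (p in seq_len(params$p_max)) {
    X_old <- X
    X <- (bFA + params$mu2 * (Y - eta2)) %*% G
    Y <- pmax(X + eta2 - params$alpha2 / params$mu2, 0)
    eta2 <- eta2 - (Y - X)
    rel <- norm(X - X_old, "F") / max(norm(X, "F"), 1e-30)
    if (rel < params$tol_inner) break
  }
  list(X = Y, Y = Y, eta2 = eta2, iters = p)
}

#' Joint multi-energy reconstruction and element decomposition
#'
#' Runs the nested ADMM on kVp-switching data: an outer loop alternating the
#' conjugate-gradient F-subproblem, the frame-coefficient shrinkage, the
#' inner-ADMM X-subproblem and the multiplier update, tracking the objective
#' and the relative successive changes of `F` and `X`. The model is convex,
#' so the solution does not depend on the initialization (which only affects
#' speed); the default start is a per-channel FBP from each channel's own
#' views and a pure-water coefficient map.
#'
#' @param sino a [simulate_kvp_switching_scan()] result (or compatible list).
#' @param dict a [build_dictionary()] result.
#' @param calib a [calibrate_scanner()] result.
#' @param params a [meer_params()].
#' @param init optional list with elements `F` (`M x N`) and/or `X`
#'   (`M x E`).
#' @param projectors optional precomputed list of per-channel
#'   [build_system_matrix()] objects (reused across reconstructions).
#' @param verbose print per-iteration progress.
#' @return Object of class `meer_recon`: `F` (`n x n x N` attenuation
#'   images, clipped to be nonnegative), `X`, convergence `trace`
#'   (data.frame: iteration, objective, rel_f, rel_x), and the inputs needed
#'   to interpret them.
#' @export
meer_reconstruct <- function(sino, dict, calib, params = meer_params(),
                             init = NULL, projectors = NULL,
                             verbose = FALSE) {
  geometry <- sino$geometry
  n <- geometry$n_pixels
  M <- n * n
  channels <- sort(unique(sino$channel_of_view))
  N <- length(channels)
  KM <- compute_K_matrices(dict, calib$params, M)
  A <- KM$A
  E <- nrow(A)

  views_list <- lapply(channels, function(ch) which(sino$channel_of_view == ch))
  if (is.null(projectors))
    projectors <- lapply(views_list, build_system_matrix, geometry = geometry)
  b_list <- lapply(views_list, function(v) flatten_sino(sino$B[v, , drop = FALSE]))
  Ptb <- lapply(seq_len(N), function(i)
    as.numeric(Matrix::crossprod(projectors[[i]]$P, b_list[[i]])))

  # initialization
  F <- matrix(0, M, N)
  if (!is.null(init$F)) F <- init$F
  else for (i in seq_len(N))
    F[, i] <- as.numeric(fbp_reconstruct(sino$B[views_list[[i]], , drop = FALSE],
                                         geometry, views_list[[i]]))
  X <- matrix(0, M, E)
  if (!is.null(init$X)) X <- init$X
  else {
    w_row <- if ("water" %in% dict$names) match("water", dict$names) else 1L
    X[, w_row] <- 1
  }
  U <- lapply(seq_len(N), function(i) tf_analysis(matrix(F[, i], n, n)))
  eta1 <- lapply(seq_len(N), function(i) array(0, c(n, n, 9)))
  Y <- X
  eta2 <- matrix(0, M, E)

  trace <- data.frame(iteration = integer(), objective = numeric(),
                      rel_f = numeric(), rel_x = numeric())
  n_increase <- 0L
  obj_prev <- Inf
  for (k in seq_len(params$k_max)) {
    F_old <- F
    X_old <- X
    upd <- solve_F_subproblem(projectors, Ptb, X %*% A, U, eta1, params, F)
    F <- upd$F
    for (i in seq_len(N)) {
      WFi <- tf_analysis(matrix(F[, i], n, n))
      U[[i]] <- update_U(WFi, eta1[[i]], params$alpha1, params$mu1)
      eta1[[i]] <- eta1[[i]] - (U[[i]] - WFi)
    }
    xs <- solve_X_subproblem(F, A, Y, eta2, params)
    X <- xs$X
    Y <- xs$Y
    eta2 <- xs$eta2

    obj <- objective_value(F, X, b_list, projectors, A, params)
    rel_f <- norm(F - F_old, "F") / max(norm(F, "F"), 1e-30)
    rel_x <- norm(X - X_old, "F") / max(norm(X, "F"), 1e-30)
    trace[k, ] <- list(k, obj, rel_f, rel_x)
    if (verbose)
      message(sprintf("iter %2d: obj %.6e relF %.2e relX %.2e (cg %s)",
                      k, obj, rel_f, rel_x,
                      paste(upd$cg_iters, collapse = "/")))
    # ADMM is not strictly objective-monotone; only sustained, material
    # growth above the best objective seen so far counts as divergence
    obj_best <- min(trace$objective)
    n_increase <- if (obj > obj_prev && obj > 1.02 * obj_best)
      n_increase + 1L else 0L
    if (n_increase >= 5L)
      stop("objective increased over 5 consecutive outer iterations; ",
           "the solver is diverging (check hyperparameters)")
    obj_prev <- obj
    if (rel_f < params$tol) break
  }

  structure(list(F = array(pmax(F, 0), c(n, n, N)), X = X,
                 trace = trace, iterations = nrow(trace),
                 params = params, dict = dict, calib = calib,
                 geometry = geometry, kvps = sino$kvps,
                 A = A),
            class = "meer_recon")
}

#' @exportS3Method base::print
print.meer_recon <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf(paste0("joint multi-energy reconstruction: %d iterations, ",
                     "objective %.4e, relF %.1e, relX %.1e\n"),
              x$iterations, last$objective, last$rel_f, last$rel_x))
  invisible(x)
}

#' Single-energy tight-frame iterative reconstruction
#'
#' The `beta = 0` variant: reconstructs one channel from its own views with
#' tight-frame sparsity regularization only (F-subproblem and shrinkage
#' loop), ignoring the inter-channel model.
#'
#' @param sino a [simulate_kvp_switching_scan()] result.
#' @param channel channel index to reconstruct.
#' @param params a [meer_params()] (its `beta` is ignored).
#' @param projector optional precomputed [build_system_matrix()] for the
#'   channel's views.
#' @param init optional `n x n` starting image.
#' @return list of class `se_recon`: `image` (`n x n`), `trace`.
#' @export
single_energy_reconstruct <- function(sino, channel, params = meer_params(),
                                      projector = NULL, init = NULL) {
  geometry <- sino$geometry
  n <- geometry$n_pixels
  views <- which(sino$channel_of_view == channel)
  if (!length(views)) stop("channel has no views")
  if (is.null(projector)) projector <- build_system_matrix(geometry, views)
  b <- flatten_sino(sino$B[views, , drop = FALSE])
  Ptb <- as.numeric(Matrix::crossprod(projector$P, b))
  p0 <- params
  p0$beta <- 0
  f <- if (is.null(init))
    as.numeric(fbp_reconstruct(sino$B[views, , drop = FALSE], geometry, views))
  else as.numeric(init)
  U <- list(tf_analysis(matrix(f, n, n)))
  eta1 <- list(array(0, c(n, n, 9)))
  trace <- data.frame(iteration = integer(), objective = numeric(),
                      rel_f = numeric())
  Fm <- matrix(f, ncol = 1)
  for (k in seq_len(params$k_max)) {
    F_old <- Fm
    upd <- solve_F_subproblem(list(projector), list(Ptb), NULL, U, eta1,
                              p0, Fm)
    Fm <- upd$F
    WFi <- tf_analysis(matrix(Fm[, 1], n, n))
    U[[1]] <- update_U(WFi, eta1[[1]], p0$alpha1, p0$mu1)
    eta1[[1]] <- eta1[[1]] - (U[[1]] - WFi)
    rel_f <- norm(Fm - F_old, "F") / max(norm(Fm, "F"), 1e-30)
    r <- as.numeric(projector$P %*% Fm[, 1]) - b
    obj <- 0.5 * sum(r^2) +
      p0$alpha1 * sum(abs(tf_analysis(matrix(Fm[, 1], n, n))))
    trace[k, ] <- list(k, obj, rel_f)
    if (rel_f < params$tol) break
  }
  structure(list(image = matrix(pmax(Fm[, 1], 0), n, n), trace = trace,
                 channel = channel, geometry = geometry),
            class = "se_recon")
}

#' Recover electron density, composition and iodine maps
#'
#' Implements the variable split in reverse: `rho = rowSums(X)`,
#' `V = X / rho` (rows with `rho` below `rho_threshold` are flagged
#' undefined), `lambda = V Lambda`, and the iodine concentration in mg/ml
#' from the iodine mass fraction and the voxel mass density implied by `rho`
#' and `lambda`.
#'
#' @param X `M x E` nonnegative coefficient matrix (or a `meer_recon`).
#' @param dict the [build_dictionary()] used in reconstruction.
#' @param stock_mg_per_ml iodine stock strength used to also express the map
#'   as a dilution fraction.
#' @param rho_threshold voxels with `rho` below this are reported as NA
#'   composition.
#' @return Object of class `decomposition_maps`: `rho` (rED vector), `V`,
#'   `lambda` (`M x 3`), `iodine_mg_ml`, `dilution_fraction`, `undefined`
#'   (logical).
#' @export
recover_decomposition <- function(X, dict, stock_mg_per_ml = 175,
                                  rho_threshold = 1e-6) {
  if (inherits(X, "meer_recon")) {
    dict <- X$dict
    X <- X$X
  }
  if (any(X < -1e-9)) stop("X must be nonnegative")
  rho <- rowSums(X)
  undefined <- rho <= rho_threshold
  V <- X / ifelse(undefined, 1, rho)
  V[undefined, ] <- NA_real_
  lambda <- V %*% dict$Lambda
  za <- .elements$z_over_a[match(colnames(dict$Lambda), .elements$symbol)]
  denom <- as.numeric(lambda %*% za)
  mass_density <- rho * .water_z_over_a / ifelse(denom > 0, denom, NA)
  iodine <- 1000 * lambda[, "I"] * mass_density
  iodine[undefined] <- 0
  structure(list(rho = rho, V = V, lambda = lambda,
                 iodine_mg_ml = iodine,
                 dilution_fraction = iodine / stock_mg_per_ml,
                 undefined = undefined),
            class = "decomposition_maps")
}
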