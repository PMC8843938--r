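# End-to-end solver properties on small instances.

test_that("noiseless model-generated data is recovered", {
  mi <- model_instance()
  params <- meer_params(alpha1 = 1e-3, alpha2 = 1e-6, k_max = 80,
                        tol = 1e-6)
  rec <- meer_reconstruct(mi$sino, mi$dict, mi$calib, params,
                          projectors = mi$projs)
  Fhat <- matrix(rec$F, ncol = 3)
  expect_lt(norm(Fhat - mi$F_true, "F") / norm(mi$F_true, "F"), 0.01)
  d <- recover_decomposition(rec)
  expect_equal(mean(d$iodine_mg_ml[mi$ins]), 3.5, tolerance = 0.05)
  # objective decays overall (per-step monotonicity is asserted for the
  # default hyperparameters in the acceptance suite)
  obj <- rec$trace$objective
  expect_lt(obj[length(obj)], obj[1])
})

test_that("the convex solution is initialization-independent", {
  mi <- model_instance(n = 24, n_views = 90)
  params <- meer_params(alpha1 = 0.01, alpha2 = 1e-5, k_max = 200,
                        tol = 1e-7)
  rec1 <- meer_reconstruct(mi$sino, mi$dict, mi$calib, params,
                           projectors = mi$projs)
  E <- nrow(mi$dict$Lambda)
  init2 <- list(F = matrix(0, 24 * 24, 3), X = matrix(1 / E, 24 * 24, E))
  rec2 <- meer_reconstruct(mi$sino, mi$dict, mi$calib, params,
                           init = init2, projectors = mi$projs)
  F1 <- matrix(rec1$F, ncol = 3); F2 <- matrix(rec2$F, ncol = 3)
  expect_lt(norm(F1 - F2, "F") / norm(F1, "F"), 1e-3)
})

test_that("reconstruction is deterministic for fixed inputs", {
  mi <- model_instance(n = 24, n_views = 90)
  params <- meer_params(k_max = 5, tol = 0)
  r1 <- meer_reconstruct(mi$sino, mi$dict, mi$calib, params,
                         projectors = mi$projs)
  r2 <- meer_reconstruct(mi$sino, mi$dict, mi$calib, params,
                         projectors = mi$projs)
  expect_identical(r1$F, r2$F)
  expect_identical(r1$trace, r2$trace)
})

test_that("single-energy reconstruction without sparsity solves least squares", {
  g <- small_geometry(n_views = 240)
  P <- build_system_matrix(g)
  img <- disk_image(g, 0.2, 8)
  B <- forward_project(img, P)
  sino <- structure(list(B = B, channel_of_view = rep(1L, 240),
                         kvps = 80, geometry = g),
                    class = "multi_channel_sinogram")
  params <- meer_params(alpha1 = 0, mu1 = 0.1, k_max = 60, tol = 1e-9,
                        cg_iters = 200, cg_tol = 1e-12)
  se <- single_energy_reconstruct(sino, 1, params, projector = P)
  b <- meercbct:::flatten_sino(B)
  Ptb <- as.numeric(Matrix::crossprod(P$P, b))
  ls <- meercbct:::cg_solve(function(x)
    as.numeric(Matrix::crossprod(P$P, P$P %*% x)), Ptb,
    numeric(ncol(P$P)), 1e-12, 2000)
  expect_lt(sqrt(mean((as.numeric(se$image) - ls$x)^2)) /
              sqrt(mean(ls$x^2)), 1e-4)
  # zero data give a zero image
  z <- single_energy_reconstruct(
    structure(list(B = 0 * B, channel_of_view = rep(1L, 240), kvps = 80,
                   geometry = g), class = "multi_channel_sinogram"),
    1, meer_params(k_max = 3), projector = P)
  expect_equal(z$image, matrix(0, 64, 64))
})

test_that("tight-frame regularization denoises relative to FBP", {
  g <- small_geometry(n_views = 240)
  ph <- build_insert_phantom(g)
  proto <- acquisition_protocol(n_views = 240, rng_seed = 3)
  s <- suppressWarnings(simulate_kvp_switching_scan(ph, proto, g,
                                                    test_spectra()))
  v <- channel_views(s, 1)
  fbp <- fbp_reconstruct(s$B[v, , drop = FALSE], g, v)
  se <- single_energy_reconstruct(s, 1, meer_params(k_max = 15))
  n <- g$n_pixels
  cen <- as.vector(outer((n / 2 - 3):(n / 2 + 3),
                         ((n / 2 - 3):(n / 2 + 3) - 1) * n, "+"))
  expect_lt(sd(se$image[cen]), sd(fbp[cen]))
})

test_that("decomposition recovery implements the variable split in reverse", {
  dict <- build_dictionary()
  E <- nrow(dict$Lambda)
  X <- matrix(0, 3, E)
  X[1, c(1, 2)] <- c(0.3, 0.7)      # generic tissue mix, rho = 1
  X[2, ] <- 0                        # empty voxel: undefined composition
  X[3, match("water", dict$names)] <- 1.05
  d <- recover_decomposition(X, dict)
  expect_equal(d$rho, c(1, 0, 1.05))
  expect_true(d$undefined[2])
  expect_equal(as.numeric(d$V[1, 1:2]), c(0.3, 0.7))
  expect_true(all(is.na(d$V[2, ])))
  expect_equal(d$iodine_mg_ml[2], 0)
  expect_error(recover_decomposition(-X, dict), "nonnegative")
})

test_that("ground-truth coefficients round-trip to phantom iodine densities", {
  g <- small_geometry(n_views = 12)
  ph <- build_insert_phantom(g)
  dict <- build_dictionary()
  lam_i <- ph$lambda[, "I"]
  Xmat <- matrix(0, length(lam_i), nrow(dict$Lambda))
  Xmat[, match("water", dict$names)] <- ph$rho * (1 - lam_i)
  Xmat[, dict$iodine_row] <- ph$rho * lam_i
  d <- recover_decomposition(Xmat, dict)
  expect_equal(matrix(d$iodine_mg_ml, g$n_pixels),
               ph$iodine_mg_ml, tolerance = 1e-8)
  expect_equal(d$rho[!d$undefined], as.numeric(ph$rho)[!d$undefined],
               tolerance = 1e-12)
})
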