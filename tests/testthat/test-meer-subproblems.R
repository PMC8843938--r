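# Small-instance oracles for every ADMM building block.

tiny_problem <- function(n = 4, n_views = 6) {
  g <- scan_geometry(n_pixels = n, pixel_size_cm = 25.6 / n,
                     n_views = n_views)
  P <- build_system_matrix(g)
  list(g = g, P = P, M = n * n)
}

test_that("objective value matches an independent term-wise evaluation", {
  tp <- tiny_problem()
  set.seed(1)
  N <- 2; E <- 3
  F <- matrix(runif(tp$M * N), tp$M)
  X <- matrix(runif(tp$M * E), tp$M)
  A <- matrix(runif(E * N), E)
  b <- lapply(1:N, function(i) rnorm(nrow(tp$P$P)))
  params <- meer_params(beta = 7, alpha1 = 0.3, alpha2 = 0.05)
  got <- objective_value(F, X, b, list(tp$P, tp$P), A, params)
  Pd <- as.matrix(tp$P$P)
  want <- 0
  for (i in 1:N) want <- want + 0.5 * sum((Pd %*% F[, i] - b[[i]])^2)
  want <- want + 7 / 2 * sum((F - X %*% A)^2)
  n <- tp$g$n_pixels
  for (i in 1:N) want <- want + 0.3 * sum(abs(tf_analysis(matrix(F[, i], n, n))))
  want <- want + 0.05 * sum(abs(X))
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(objective_value(0 * F, 0 * X, lapply(b, function(x) 0 * x),
                               list(tp$P, tp$P), A, params), 0)
})

test_that("the F-subproblem CG solve matches a dense direct solve", {
  tp <- tiny_problem()
  n <- tp$g$n_pixels
  set.seed(2)
  params <- meer_params(beta = 5, mu1 = 2, cg_iters = 400, cg_tol = 1e-12)
  XA <- matrix(runif(tp$M * 2), tp$M)
  U <- lapply(1:2, function(i) array(rnorm(n * n * 9), c(n, n, 9)))
  eta1 <- lapply(1:2, function(i) array(rnorm(n * n * 9), c(n, n, 9)))
  b <- lapply(1:2, function(i) rnorm(nrow(tp$P$P)))
  Ptb <- lapply(b, function(bb) as.numeric(Matrix::crossprod(tp$P$P, bb)))
  F0 <- matrix(0, tp$M, 2)
  got <- solve_F_subproblem(list(tp$P, tp$P), Ptb, XA, U, eta1, params, F0)
  Pd <- as.matrix(tp$P$P)
  Hmat <- crossprod(Pd) + (5 + 2) * diag(tp$M)
  for (i in 1:2) {
    rhs <- Ptb[[i]] + 5 * XA[, i] +
      2 * as.numeric(tf_synthesis(U[[i]] - eta1[[i]]))
    expect_equal(got$F[, i], as.numeric(solve(Hmat, rhs)), tolerance = 1e-8)
  }
})

test_that("the F-subproblem reduces to identity recovery and warm starts", {
  # P = I, beta = 0, mu1 -> 0: the normal equations give F = B
  M <- 16
  Pid <- structure(list(P = Matrix::Diagonal(M)), class = "system_matrix")
  params <- meer_params(beta = 0, mu1 = 1e-12, cg_iters = 200,
                        cg_tol = 1e-12)
  b <- rnorm(M)
  U <- list(array(0, c(4, 4, 9)))
  eta1 <- list(array(0, c(4, 4, 9)))
  got <- solve_F_subproblem(list(Pid), list(b), NULL, U, eta1, params,
                            matrix(0, M, 1))
  expect_equal(got$F[, 1], b, tolerance = 1e-9)
  # warm-started call with unchanged inputs converges immediately
  again <- solve_F_subproblem(list(Pid), list(b), NULL, U, eta1, params,
                              got$F)
  expect_lte(again$cg_iters[1], 2)
})

test_that("soft shrinkage is signed and threshold-0 is the identity", {
  expect_equal(update_U(array(5, c(1, 1, 9)), array(0, c(1, 1, 9)), 2, 1)[1],
               3)
  expect_equal(update_U(array(-5, c(1, 1, 9)), array(0, c(1, 1, 9)), 2, 1)[1],
               -3)
  x <- array(rnorm(9), c(1, 1, 9))
  expect_equal(update_U(x, 0 * x, 0, 1), x)
})

test_that("the X-subproblem matches a constrained convex oracle", {
  set.seed(4)
  M <- 4; E <- 2; N <- 2
  A <- matrix(c(0.3, 0.15, 2, 5), E, N, byrow = TRUE)
  F <- matrix(runif(M * N, 0, 0.4), M)
  params <- meer_params(beta = 50, alpha2 = 0.01, mu2 = 5, p_max = 3000,
                        tol_inner = 1e-12)
  got <- solve_X_subproblem(F, A, matrix(0, M, E), matrix(0, M, E), params)
  expect_true(all(got$X >= 0))
  # oracle: with X >= 0 the l1 term is linear, so L-BFGS-B solves it exactly
  obj <- function(x) {
    X <- matrix(x, M, E)
    50 / 2 * sum((F - X %*% A)^2) + 0.01 * sum(X)
  }
  gr <- function(x) {
    X <- matrix(x, M, E)
    as.numeric(50 * (X %*% A - F) %*% t(A) + 0.01)
  }
  o <- optim(rep(0.1, M * E), obj, gr, method = "L-BFGS-B", lower = 0,
             control = list(maxit = 10000, factr = 1))
  expect_equal(obj(as.numeric(got$X)), o$value, tolerance = 1e-6)
  expect_equal(as.numeric(got$X), o$par, tolerance = 1e-4)
})

test_that("without sparsity the X-subproblem is ridge-free least squares", {
  set.seed(5)
  M <- 6; E <- 2; N <- 3
  A <- matrix(runif(E * N, 0.1, 1), E)
  Xtrue <- matrix(runif(M * E, 0.2, 1), M)
  F <- Xtrue %*% A
  params <- meer_params(beta = 50, alpha2 = 0, mu2 = 1, p_max = 5000,
                        tol_inner = 1e-13)
  got <- solve_X_subproblem(F, A, matrix(0, M, E), matrix(0, M, E), params)
  X_ls <- 50 * F %*% t(A) %*% solve(50 * A %*% t(A))
  expect_equal(got$X, X_ls, tolerance = 1e-8)
  # F = 0 gives X = 0
  z <- solve_X_subproblem(0 * F, A, matrix(0, M, E), matrix(0, M, E), params)
  expect_equal(z$X, matrix(0, M, E))
})
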