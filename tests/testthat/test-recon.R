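# Reconstruction chain: operator adjointness, coil handling, FISTA against
# a long-run ISTA oracle, subspace extraction/synthesis identities, and the
# subspace-benefit and denoising properties of the two-stage scheme.

test_that("forward/adjoint pairs pass the dot-product test", {
  withr::local_seed(42)
  maps <- make_coil_maps(4L, c(32L, 32L), seed = 3L)
  mask <- array(stats::runif(32 * 32 * 8) < 0.3, c(32L, 32L, 8L))
  sv <- svd(matrix(stats::rnorm(64), 8L))
  basis <- subspace_basis(sv$u[, 1:3])
  for (b in list(NULL, basis)) {
    op <- encoding_operator(maps, mask, b)
    u <- array(complex(real = stats::rnorm(prod(op$img_dim)),
                       imaginary = stats::rnorm(prod(op$img_dim))),
               op$img_dim)
    v <- array(complex(real = stats::rnorm(32 * 32 * 8 * 4),
                       imaginary = stats::rnorm(32 * 32 * 8 * 4)),
               c(32L, 32L, 8L, 4L))
    lhs <- sum(op$forward(u) * Conj(v))
    rhs <- sum(u * Conj(op$adjoint(v)))
    expect_lt(Mod(lhs - rhs), 1e-10 * Mod(lhs))
  }
})

test_that("operator norm is at most 1 for unit-RSS maps and orthonormal basis", {
  maps <- make_coil_maps(4L, c(24L, 24L), seed = 2L)
  mask <- array(TRUE, c(24L, 24L, 6L))
  op <- encoding_operator(maps, mask)
  expect_lte(operator_norm_sq(op), 1 + 1e-9)
  # identity coil + full mask: forward is a plain unitary FFT per echo
  one <- make_coil_maps(1L, c(24L, 24L))
  op1 <- encoding_operator(one, mask)
  withr::local_seed(1)
  x <- array(complex(real = stats::rnorm(24 * 24 * 6),
                     imaginary = stats::rnorm(24 * 24 * 6)), c(24L, 24L, 6L))
  y <- op1$forward(x)
  for (e in 1:6) {
    expect_equal(y[, , e, 1L], calipr:::fft2c(x[, , e]), tolerance = 1e-12)
  }
})

test_that("coil maps estimated from the calibration region match the truth", {
  sc <- make_test_scene(grid = c(48L, 48L), n_echoes = 4L, n_coils = 4L)
  est <- estimate_coil_maps(sc$kspace, calib_shape = c(16L, 16L))
  rss <- sqrt(apply(Mod(est$maps)^2, c(1, 2), sum))
  expect_equal(max(abs(rss - 1)), 0, tolerance = 1e-10)
  # compare on the interior support, modulo a global phase per coil
  interior <- sc$truth$support
  interior[c(1:8, 41:48), ] <- FALSE
  interior[, c(1:8, 41:48)] <- FALSE
  for (c in 1:4) {
    e <- est$maps[, , c][interior]
    t <- sc$maps$maps[, , c][interior]
    ph <- sum(Conj(e) * t)
    ph <- ph / Mod(ph)
    expect_lt(stats::median(Mod(e * ph - t) / Mod(t)), 0.05)
  }
  # single uniform coil: map is 1 on the support
  sc1 <- make_test_scene(grid = c(32L, 32L), n_echoes = 2L, n_coils = 1L)
  est1 <- estimate_coil_maps(sc1$kspace, calib_shape = c(12L, 12L))
  expect_equal(max(Mod(est1$maps[, , 1L][est1$support] - 1)), 0,
               tolerance = 1e-8)
  expect_error(estimate_coil_maps(sc1$kspace, calib_shape = c(0L, 0L)),
               "empty")
})

test_that("coil compression conserves energy and matches the SVD tail", {
  sc <- make_test_scene(grid = c(32L, 32L), n_echoes = 3L, n_coils = 6L,
                        noise_sigma = 0.02)
  # n_virtual = n_coils: unitary, energy conserved
  full <- coil_compress(sc$kspace, 6L)
  expect_equal(sum(Mod(full$kspace$data)^2), sum(Mod(sc$kspace$data)^2),
               tolerance = 1e-10)
  expect_equal(full$energy_retained, 1, tolerance = 1e-12)
  # compression error on the calibration block equals the discarded
  # singular-value energy (direct SVD oracle)
  pr <- calipr:::calib_range(32L, 12L)
  sr <- calipr:::calib_range(32L, 12L)
  X <- t(matrix(sc$kspace$data[pr, sr, 1L, ], ncol = 6L))
  sv <- svd(X)
  cc <- coil_compress(sc$kspace, 3L)
  Xc <- t(matrix(cc$kspace$data[pr, sr, 1L, ], ncol = 3L))
  err <- sum(Mod(X)^2) - sum(Mod(Xc)^2)
  expect_equal(err, sum(sv$d[4:6]^2), tolerance = 1e-8)
  expect_error(coil_compress(sc$kspace, 0L), "positive")
  expect_error(coil_compress(sc$kspace, 7L), "exceeds")
})

test_that("FISTA solves the toy L1 problem like long-run ISTA and behaves at the limits", {
  # 1D toy problem embedded in the solver's own machinery is overkill;
  # check the core iteration against a brute-force ISTA oracle instead.
  withr::local_seed(5)
  A <- matrix(stats::rnorm(8 * 8), 8L)[sample(8L, 5L), , drop = FALSE]
  y <- as.numeric(A %*% c(2, 0, 0, -1, 0, 0, 0.5, 0))
  x_oracle <- ista_oracle(A, y, lambda = 0.05)
  # same problem through a hand-built operator interface (real case via
  # complex arrays with zero imaginary part, no wavelet: levels = 0)
  op <- list(
    forward = function(x) array(A %*% as.vector(Re(x)), c(5L, 1L, 1L, 1L)),
    adjoint = function(r) array(crossprod(A, as.vector(Re(r))), c(8L, 1L, 1L)),
    img_dim = c(8L, 1L, 1L)
  )
  fit <- fista_solve(op, array(y, c(5L, 1L, 1L, 1L)), lambda = 0.05,
                     max_iters = 5000L, rel_tol = 1e-12, wavelet_levels = 0L)
  expect_equal(as.vector(Re(fit$solution)), x_oracle, tolerance = 1e-6)
  expect_true(all(diff(fit$objective) <= 1e-9))

  # lambda = 0, fully sampled, identity coil: solution is the inverse FFT
  sc <- make_test_scene(grid = c(32L, 32L), n_echoes = 4L, n_coils = 1L)
  opf <- encoding_operator(sc$maps, array(TRUE, c(32L, 32L, 4L)))
  ls <- fista_solve(opf, sc$kspace$data, 0, max_iters = 50L)
  expect_lt(nrmse(ls$solution, sc$truth$echo_images), 1e-8)

  # very large lambda: everything is shrunk away
  big <- fista_solve(opf, sc$kspace$data, 1e6, max_iters = 10L)
  expect_lt(sum(Mod(big$solution)^2), 1e-12)
})

test_that("subspace extraction captures low-rank echo structure exactly", {
  # uniform flip field: each tissue class contributes exactly one decay
  # curve, so three classes span a rank-3 echo matrix
  spec <- default_phantom_spec(c(32L, 32L), n_coils = 1L)
  spec$flip_map[] <- 160
  truth <- make_phantom(spec, mese_sequence(12L, 6))
  x <- echo_series(truth$echo_images)
  b <- build_subspace(x, K = 12L)
  proj_resid <- function(K) {
    bK <- b$basis[, seq_len(K), drop = FALSE]
    d <- dim(x$images)
    m <- matrix(x$images, d[1L] * d[2L], d[3L])
    fit <- m %*% Conj(bK) %*% t(bK)
    sqrt(sum(Mod(m - fit)^2) / sum(Mod(m)^2))
  }
  resids <- vapply(1:12, proj_resid, numeric(1))
  expect_true(all(diff(resids) <= 1e-12))       # non-increasing in K
  expect_lt(resids[3L], 1e-8)                   # rank-3 data
  # rank-1 data: single shared decay curve
  seqp <- mese_sequence(12L, 6)
  curve <- epg_mese(80, seqp)
  r1 <- array(0 + 0i, c(8L, 8L, 12L))
  withr::local_seed(6)
  amp <- matrix(stats::runif(64, 0.5, 1), 8L)
  for (e in seq_len(12L)) r1[, , e] <- amp * curve[e]
  b1 <- build_subspace(echo_series(r1), K = 1L)
  m <- matrix(r1, 64L, 12L)
  fit1 <- m %*% Conj(b1$basis) %*% t(b1$basis)
  expect_lt(sqrt(sum(Mod(m - fit1)^2)), 1e-10)
  expect_error(build_subspace(echo_series(r1 * 0 + 0i), K = 1L,
                              intensity_threshold_fraction = 2),
               "threshold")
})

test_that("echo synthesis is the exact basis expansion and an isometry", {
  withr::local_seed(8)
  sv <- svd(matrix(stats::rnorm(100), 10L))
  basis <- subspace_basis(sv$u[, 1:4])
  alpha <- array(complex(real = stats::rnorm(6 * 6 * 4),
                         imaginary = stats::rnorm(6 * 6 * 4)), c(6L, 6L, 4L))
  x <- synthesize_echo_images(alpha, basis)
  # per-voxel norm preserved under the orthonormal extension
  na <- apply(Mod(alpha)^2, c(1, 2), sum)
  nx <- apply(Mod(x$images)^2, c(1, 2), sum)
  expect_equal(nx, na, tolerance = 1e-12)
  # identity basis returns the coefficients unchanged
  bi <- subspace_basis(diag(4L))
  expect_equal(synthesize_echo_images(alpha, bi)$images, alpha)
  # synthesize(project(x)) = x for in-span data
  proj <- array(matrix(x$images, 36L, 10L) %*% Conj(basis$basis),
                c(6L, 6L, 4L))
  expect_equal(synthesize_echo_images(proj, basis)$images, x$images,
               tolerance = 1e-12)
})

test_that("subspace-constrained solve is exact for in-span fully sampled data", {
  spec <- default_phantom_spec(c(32L, 32L), n_coils = 2L)
  spec$flip_map[] <- 160                      # rank-3 signal manifold
  seqp <- mese_sequence(12L, 6)
  truth <- make_phantom(spec, seqp)
  maps <- make_coil_maps(2L, c(32L, 32L), seed = 1L)
  ksp <- simulate_kspace(truth, maps, NULL, 0, 1L)
  basis <- build_subspace(echo_series(truth$echo_images), K = 4L)
  cfg <- recon_config(lambda = 0, K = 4L, n_virtual_coils = 2L,
                      max_iters = 80L, rel_tol = 1e-10)
  alpha <- subspace_reconstruct(ksp, maps, basis, cfg)
  x <- synthesize_echo_images(alpha, echo_times = ksp$echo_times)
  expect_lt(nrmse(x$images, truth$echo_images), 1e-6)
})

test_that("the full chain is deterministic and beats plain CS when undersampled", {
  v <- validation_experiment(grid_shape = c(64L, 64L), n_echoes = 32L,
                             n_coils = 4L, target_acceleration = 8,
                             noise_sigma = 0.01, seed = 1L,
                             config = recon_config(lambda = 0.004, K = 12L,
                                                   n_virtual_coils = 4L,
                                                   max_iters = 40L))
  expect_lt(v$nrmse["calipr"], v$nrmse["cs"])
  expect_lt(v$nrmse["reference"], v$nrmse["cs"])
  # bit-reproducibility of the deterministic chain
  under <- retrospective_undersample(
    simulate_kspace(v$truth, make_coil_maps(4L, c(64L, 64L), seed = 1L),
                    NULL, 0.01, seed = 8L), v$scheme)
  cfg <- recon_config(lambda = 0.004, K = 6L, n_virtual_coils = 4L,
                      max_iters = 10L)
  r1 <- run_calipr(under, cfg)
  r2 <- run_calipr(under, cfg)
  expect_identical(r1$echoes$images, r2$echoes$images)
})

test_that("subspace projection denoises fully sampled noisy data", {
  sc <- make_test_scene(grid = c(32L, 32L), n_echoes = 16L, n_coils = 2L,
                        noise_sigma = 0.03)
  cfg0 <- recon_config(lambda = 0, K = 16L, n_virtual_coils = 2L,
                       max_iters = 40L)
  cs <- cs_reconstruct(sc$kspace, sc$maps, cfg0)
  err_cs <- nrmse(cs$images, sc$truth$echo_images)
  for (K in c(6L, 9L, 12L)) {
    basis <- build_subspace(cs, K = K)
    d <- dim(cs$images)
    m <- matrix(cs$images, d[1L] * d[2L], d[3L])
    proj <- array(m %*% Conj(basis$basis) %*% t(basis$basis), d)
    expect_lt(nrmse(proj, sc$truth$echo_images), err_cs)
  }
})
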