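# Independent oracles used across the suite.  Each deliberately avoids the
# package's own code paths: the isochromat simulator uses dense 3x3 rotation
# matrices, the NNLS oracle is plain projected gradient, the ISTA oracle has
# no momentum, and the median/SVD oracles use direct definitions.

# Dense isochromat CPMG simulator: N spins with uniform discrete dephasing
# angles reproduce EPG echo amplitudes exactly when N > 4 * n_echoes.
iso_mese_oracle <- function(t2, n_echoes, delta_te, flip_deg, t1 = 1000) {
  N <- 4L * n_echoes + 1L
  th <- 2 * pi * (0:(N - 1L)) / N
  e2 <- exp(-delta_te / 2 / t2)
  e1 <- exp(-delta_te / 2 / t1)
  a <- flip_deg * pi / 180
  Rx <- matrix(c(1, 0, 0,
                 0, cos(a), sin(a),
                 0, -sin(a), cos(a)), 3L, 3L)
  M <- matrix(rep(c(1, 0, 0), N), 3L, N)    # after the 90-degree excitation
  half <- function(M) {
    M[1, ] <- M[1, ] * e2
    M[2, ] <- M[2, ] * e2
    M[3, ] <- M[3, ] * e1 + (1 - e1)
    x <- M[1, ] * cos(th) - M[2, ] * sin(th)
    y <- M[1, ] * sin(th) + M[2, ] * cos(th)
    M[1, ] <- x; M[2, ] <- y
    M
  }
  ech <- numeric(n_echoes)
  for (i in seq_len(n_echoes)) {
    M <- half(M)
    M <- Rx %*% M
    M <- half(M)
    ech[i] <- Mod(mean(complex(real = M[1, ], imaginary = M[2, ])))
  }
  ech
}

# Projected-gradient NNLS oracle: gradient descent on 0.5||Ax-b||^2 with
# projection onto the nonnegative orthant, run to tight tolerance.
pg_nnls_oracle <- function(A, b, max_iter = 200000L, tol = 1e-12) {
  L <- max(svd(A, nu = 0, nv = 0)$d)^2
  x <- numeric(ncol(A))
  for (i in seq_len(max_iter)) {
    g <- as.vector(crossprod(A, A %*% x - b))
    x_new <- pmax(x - g / L, 0)
    if (max(abs(x_new - x)) < tol) return(x_new)
    x <- x_new
  }
  x
}

# Long-run ISTA (no momentum) oracle for the L1 least-squares toy problem
# min 0.5||A x - y||^2 + lambda ||x||_1 over real vectors.
ista_oracle <- function(A, y, lambda, iters = 50000L) {
  L <- max(svd(A, nu = 0, nv = 0)$d)^2
  x <- numeric(ncol(A))
  st <- function(v, t) sign(v) * pmax(abs(v) - t, 0)
  for (i in seq_len(iters)) {
    x <- st(x - as.vector(crossprod(A, A %*% x - y)) / L, lambda / L)
  }
  x
}

# small fully deterministic phantom + k-space bundle shared by tests
make_test_scene <- function(grid = c(32L, 32L), n_echoes = 16L,
                            n_coils = 4L, noise_sigma = 0,
                            accel = NULL, seed = 1L) {
  spec <- default_phantom_spec(grid, noise_sigma = noise_sigma,
                               n_coils = n_coils, seed = seed)
  seqp <- mese_sequence(n_echoes = n_echoes, delta_te = 6)
  truth <- make_phantom(spec, seqp)
  maps <- make_coil_maps(n_coils, grid, seed = seed)
  scheme <- if (is.null(accel)) NULL else
    generate_sampling_scheme(grid, n_echoes, accel, seed = seed + 100L)
  ksp <- simulate_kspace(truth, maps, scheme, noise_sigma, seed = seed + 7L)
  list(spec = spec, seq = seqp, truth = truth, maps = maps,
       scheme = scheme, kspace = ksp)
}
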