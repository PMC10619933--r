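# Multicomponent T2 analysis: dictionary structure, NNLS against an
# independent projected-gradient oracle, automatic regularization, flip
# recovery, spectral summary metrics, and volume fitting.

test_that("decay dictionary columns are EPG curves with expected structure", {
  grid <- t2_grid()
  expect_equal(length(grid), 40L)
  expect_equal(range(grid), c(8, 2000))
  expect_true(all(diff(grid) > 0))
  seqp <- mese_sequence(16L, 6)
  B <- build_decay_basis(grid, seqp, 180)
  # at 180 degrees columns are pure exponentials
  expect_equal(B$A[, 10L], exp(-echo_times(seqp) / grid[10L]),
               tolerance = 1e-12)
  expect_true(all(B$A >= 0 & B$A <= 1 + 1e-12))
  # column norms strictly increase with T2 (slower decay -> more energy)
  expect_true(all(diff(sqrt(colSums(B$A^2))) > 0))
  # brain protocol: 56 echoes at 6 ms span TE 6-336 ms
  expect_equal(range(echo_times(mese_sequence(56L, 6))), c(6, 336))
})

test_that("rnnls matches the projected-gradient oracle and pracma", {
  seqp <- mese_sequence(24L, 8, 160)
  grid <- t2_grid(20L)
  B <- build_decay_basis(grid, seqp, 160)
  # exact basis column recovers the unit spike
  d <- B$A[, 7L]
  f <- rnnls(d, B, mu = 0)
  expect_lt(sum(abs(f$s - replace(numeric(20L), 7L, 1))), 1e-8)
  # solver versus the projected-gradient oracle on well-conditioned
  # systems, where the NNLS minimizer is unique and PG converges
  withr::local_seed(31)
  for (i in 1:5) {
    A <- matrix(stats::rnorm(30 * 10), 30L)
    b <- stats::rnorm(30L)
    mine <- rnnls(b, A, mu = 0)$s
    expect_lt(max(abs(mine - pg_nnls_oracle(A, b))), 1e-6)
  }
  # on the (near-singular) EPG dictionary itself, agree with the
  # independent active-set implementation
  for (i in 1:5) {
    s_true <- numeric(20L)
    s_true[sample(20L, 3L)] <- stats::runif(3L)
    d <- as.numeric(B$A %*% s_true) + stats::rnorm(24L, 0, 0.01)
    mine <- rnnls(d, B, mu = 0)$s
    expect_lt(max(abs(mine - pracma::lsqnonneg(B$A, d)$x)), 1e-8)
    # both reach the same misfit even if the ridge is flat
    expect_lt(abs(sum((B$A %*% mine - d)^2) -
                    pracma::lsqnonneg(B$A, d)$resid.norm), 1e-10)
  }
})

test_that("automatic regularization hits the chi-square target and is monotone", {
  seqp <- mese_sequence(32L, 6, 165)
  grid <- t2_grid()
  B <- build_decay_basis(grid, seqp, 165)
  sig0 <- 0.088 * epg_mese(20, seqp) + 0.912 * epg_mese(80, seqp)
  withr::local_seed(7)
  for (i in 1:5) {
    d <- Mod(complex(real = sig0 + stats::rnorm(32L, 0, 0.005),
                     imaginary = stats::rnorm(32L, 0, 0.005)))
    f <- rnnls(d, B, mu = "auto")
    expect_lt(abs(f$chi2 - 1.02 * f$chi2_min), 0.001 * 1.02 * f$chi2_min)
  }
  # ||s||^2 non-increasing in mu
  d <- Mod(complex(real = sig0 + stats::rnorm(32L, 0, 0.01),
                   imaginary = stats::rnorm(32L, 0, 0.01)))
  mus <- c(0, 1e-4, 1e-3, 1e-2, 0.1, 1)
  norms <- vapply(mus, function(m) sum(rnnls(d, B, mu = m)$s^2), numeric(1))
  expect_true(all(diff(norms) <= 1e-10))
  # MWF invariant to global scaling of the signal
  f1 <- rnnls(d, B, mu = "auto")
  f2 <- rnnls(37 * d, B, mu = "auto")
  expect_equal(compute_mwf(f1), compute_mwf(f2), tolerance = 1e-6)
})

test_that("flip-angle estimation recovers the simulated refocusing angle", {
  seqp <- mese_sequence(32L, 6)
  grid <- t2_grid()
  make_sig <- function(flip) {
    s <- seqp; s$refocus_flip <- flip
    0.088 * epg_mese(20, s) + 0.912 * epg_mese(80, s)
  }
  bank <- calipr:::.basis_bank(grid, seqp, seq.int(90L, 180L))
  # noiseless: within 1 degree
  for (true_flip in c(180, 160)) {
    est <- estimate_flip(make_sig(true_flip), grid, seqp,
                         flip_candidates = seq.int(90L, 180L),
                         basis_bank = bank)
    expect_lt(abs(est$flip - true_flip), 1 + 1e-9)
  }
  # all-zero signal flags undefined
  expect_true(is.na(estimate_flip(numeric(32L), grid, seqp)$flip))
  # Monte-Carlo at SNR 200: two-pool signal at 140 degrees within 3 degrees
  withr::local_seed(14)
  sig <- make_sig(140)
  est <- replicate(100, {
    d <- Mod(complex(real = sig + stats::rnorm(32L, 0, sig[1L] / 200 / sqrt(2)),
                     imaginary = stats::rnorm(32L, 0, sig[1L] / 200 / sqrt(2))))
    estimate_flip(d, grid, seqp, flip_candidates = seq.int(90L, 180L),
                  basis_bank = bank)$flip
  })
  expect_lt(abs(mean(est) - 140), 3)
})

test_that("MWF and IET2 follow their spectral definitions exactly", {
  grid <- c(20, 50, 80, 180, 200, 2000)
  expect_equal(compute_mwf(c(1, 0, 0, 0, 0, 0), grid), 1)
  expect_equal(compute_mwf(c(0.15, 0, 0.85, 0, 0, 0), grid), 0.15)
  # a grid point exactly at the 40 ms cutoff is excluded (strict <)
  g2 <- c(40, 80)
  expect_equal(compute_mwf(c(0.3, 0.7), g2), 0)
  expect_true(is.na(compute_mwf(c(0, 0), g2)))
  # IET2: single component, open-window boundary exclusion, geometric mean
  expect_equal(compute_iet2(c(0, 0, 1, 0, 0, 0), grid), 80)
  expect_equal(compute_iet2(c(0, 1, 0, 0, 1, 0), grid), 50)  # 200 excluded
  expect_equal(compute_iet2(c(0, 1, 0, 1, 0, 0), grid), sqrt(50 * 180))
  expect_true(is.na(compute_iet2(c(1, 0, 0, 0, 0, 1), grid)))
})

test_that("volume fitting recovers phantom MWF and flags empty voxels", {
  spec <- default_phantom_spec(c(24L, 24L), n_coils = 1L)
  seqp <- mese_sequence(32L, 6)
  truth <- make_phantom(spec, seqp)
  q <- fit_volume(truth$echo_images, seqp, support = truth$support)
  ok <- truth$support & q$defined
  expect_gt(sum(ok), 100L)
  expect_lt(mean(abs(q$mwf[ok] - truth$mwf_map[ok])), 0.01)
  wm <- truth$class_map == 1L & q$defined
  expect_lt(abs(mean(q$mwf[wm]) - 0.088), 0.01)
  expect_lt(stats::median(abs(q$flip[ok] - truth$flip_map[ok])), 1)
  # IET2 recovered where defined; CSF voxels (no 40-200 ms weight in truth)
  ie <- ok & !is.na(truth$iet2_map) & !is.na(q$iet2)
  expect_lt(stats::median(abs(q$iet2[ie] - truth$iet2_map[ie])), 5)
  # all-zero volume: everything undefined
  z <- fit_volume(array(0, c(4L, 4L, 32L)), seqp,
                  support = matrix(TRUE, 4L, 4L))
  expect_true(all(!z$defined))
})

test_that("spatial regularization reduces noise without erasing edges", {
  # piecewise-constant two-class phantom at SNR 50
  grid_shape <- c(20L, 20L)
  cm <- matrix(1L, 20L, 20L)
  cm[11:20, ] <- 2L
  spec <- phantom_spec(grid_shape, cm,
                       list(`1` = cbind(c(20, 80), c(0.15, 0.85)),
                            `2` = cbind(c(20, 80), c(0.05, 0.95))),
                       c(`1` = 1, `2` = 1), flip_map = 165, n_coils = 1L)
  seqp <- mese_sequence(32L, 6)
  truth <- make_phantom(spec, seqp)
  withr::local_seed(77)
  sigma <- max(Mod(truth$echo_images[, , 1L])) / 50 / sqrt(2)
  img <- Mod(truth$echo_images +
               array(complex(real = stats::rnorm(length(truth$echo_images), 0, sigma),
                             imaginary = stats::rnorm(length(truth$echo_images), 0, sigma)),
                     dim(truth$echo_images)))
  support <- matrix(TRUE, 20L, 20L)
  cfg0 <- fit_config(spatial_weight = 0)
  base <- spatial_regularized_fit(img, seqp, support, cfg0)
  plain <- fit_volume(img, seqp, support, cfg0)
  expect_equal(base$mwf, plain$mwf)            # zero weight: identical
  cfg <- fit_config(spatial_weight = 1, n_spatial_iters = 2L)
  sp <- spatial_regularized_fit(img, seqp, support, cfg)
  rmse <- function(q) sqrt(mean((q$mwf[q$defined] -
                                   truth$mwf_map[q$defined])^2))
  expect_lte(rmse(sp), rmse(plain))
  # the class step across the boundary survives within 20% of the truth
  prof_sp <- rowMeans(sp$mwf, na.rm = TRUE)
  step_sp <- mean(prof_sp[1:8]) - mean(prof_sp[13:20])
  expect_gt(step_sp, 0.8 * 0.10)
  expect_lt(step_sp, 1.2 * 0.10)
})
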