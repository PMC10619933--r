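# The two-stage subspace-constrained reconstruction chain.
#
# Step 1: conventional CS reconstruction of all echoes jointly,
#         min_x 0.5||y - MFSx||^2 + lambda ||T(x)||_1.
# Step 2: intensity-threshold the first-echo image, SVD the surviving
#         multi-echo signals, keep the first K right singular vectors.
# Step 3: re-reconstruct with the explicit subspace constraint,
#         min_a 0.5||y - MFS Phi_K a||^2 + lambda ||T(a)||_1.
# Step 4: synthesize echo images x = Phi_K a.
#
# lambda is scale-sensitive, so k-space is normalized before solving such
# that the zero-filled root-sum-of-squares first-echo image has unit
# 99th-percentile magnitude; the published defaults (0.004 brain / 0.001
# cord) are interpreted on that scale.

# zero-filled RSS image at one echo
.rss_zero_filled <- function(kspace, echo = 1L) {
  d <- dim(kspace$data)
  acc <- matrix(0, d[1L], d[2L])
  for (c in seq_len(d[4L])) {
    acc <- acc + Mod(ifft2c(kspace$data[, , echo, c]))^2
  }
  sqrt(acc)
}

#' Normalization factor for a k-space dataset
#'
#' 99th percentile of the zero-filled root-sum-of-squares first-echo image
#' magnitude; dividing the data by this factor puts the regularization
#' weights on a scanner-independent scale.
#'
#' @param kspace a [kspace_data()] object.
#' @return positive scalar.
#' @export
kspace_norm_factor <- function(kspace) {
  f <- stats::quantile(.rss_zero_filled(kspace, 1L), 0.99, names = FALSE)
  if (f <= 0) stop("first-echo image is identically zero")
  f
}

#' Estimate coil sensitivity maps from the echo-1 calibration region
#'
#' The fully sampled central calibration block at echo 1 is apodized with a
#' Hann window, zero-filled to the full grid and inverse-transformed per
#' coil; the smooth low-resolution coil images are normalized by their
#' root-sum-of-squares, which cancels the anatomy and leaves the relative
#' coil sensitivities. The support is the region where the RSS image
#' exceeds `support_threshold` times its maximum.
#'
#' @param kspace a [kspace_data()] object with a fully sampled central
#'   calibration region at echo 1.
#' @param calib_shape integer length-2 calibration extent.
#' @param support_threshold support cut as a fraction of the peak
#'   calibration RSS (default 0.05).
#' @return a [coil_maps()] object (RSS magnitude exactly 1 everywhere the
#'   calibration image is nonzero).
#' @export
estimate_coil_maps <- function(kspace, calib_shape = c(12L, 12L),
                               support_threshold = 0.05) {
  d <- dim(kspace$data)
  calib_shape <- as.integer(rep(calib_shape, length.out = 2L))
  if (any(calib_shape <= 0L)) stop("empty calibration region")
  pr <- calib_range(d[1L], calib_shape[1L])
  sr <- calib_range(d[2L], calib_shape[2L])
  if (!all(kspace$mask[pr, sr, 1L])) {
    stop("echo-1 calibration region is not fully sampled")
  }
  # symmetric window about the DC sample so that Hermitian (real-image)
  # calibration data yield a real low-resolution image: use the largest
  # DC-centred odd block inside the calibration region, Hann-apodized
  h1 <- (calib_shape[1L] - 1L) %/% 2L
  h2 <- (calib_shape[2L] - 1L) %/% 2L
  c1 <- d[1L] %/% 2L + 1L
  c2 <- d[2L] %/% 2L + 1L
  pr <- c1 + (-h1:h1)
  sr <- c2 + (-h2:h2)
  hann <- function(h) 0.5 * (1 + cos(pi * (-h:h) / (h + 1)))
  w <- outer(hann(h1), hann(h2))
  n_coil <- d[4L]
  low <- array(0 + 0i, c(d[1L], d[2L], n_coil))
  for (c in seq_len(n_coil)) {
    k <- matrix(0 + 0i, d[1L], d[2L])
    k[pr, sr] <- kspace$data[pr, sr, 1L, c] * w
    low[, , c] <- ifft2c(k)
  }
  rss <- sqrt(apply(Mod(low)^2, c(1, 2), sum))
  support <- rss > support_threshold * max(rss)
  denom <- pmax(rss, .Machine$double.eps)
  maps <- low
  for (c in seq_len(n_coil)) maps[, , c] <- low[, , c] / denom
  coil_maps(maps, support)
}

#' SVD coil compression to virtual channels
#'
#' A compression matrix is fitted by SVD of the echo-1 calibration-region
#' samples (coils x samples) and applied to the full dataset, retaining the
#' `n_virtual` dominant virtual channels.
#'
#' @param kspace a [kspace_data()] object.
#' @param n_virtual number of virtual channels (1..n_coils).
#' @param calib_shape calibration extent used to fit the compression.
#' @return list with `kspace` (compressed [kspace_data()]), `matrix`
#'   (n_virtual x n_coils), `energy_retained` (fraction of squared singular
#'   values kept), `singular_values`.
#' @export
coil_compress <- function(kspace, n_virtual, calib_shape = c(12L, 12L)) {
  d <- dim(kspace$data)
  n_coil <- d[4L]
  if (n_virtual <= 0L) stop("n_virtual must be positive")
  if (n_virtual > n_coil) stop("n_virtual exceeds the number of coils")
  pr <- calib_range(d[1L], calib_shape[1L])
  sr <- calib_range(d[2L], calib_shape[2L])
  X <- t(matrix(kspace$data[pr, sr, 1L, ], ncol = n_coil))  # coil x samples
  sv <- svd(X)
  Cmat <- Conj(t(sv$u[, seq_len(n_virtual), drop = FALSE]))  # nv x ncoil
  dm <- matrix(kspace$data, ncol = n_coil)
  out <- array(dm %*% t(Cmat), c(d[1:3], n_virtual))
  energy <- sum(sv$d[seq_len(n_virtual)]^2) / sum(sv$d^2)
  list(kspace = kspace_data(out, kspace$mask, kspace$echo_times),
       matrix = Cmat, energy_retained = energy, singular_values = sv$d)
}

#' Conventional CS reconstruction (reconstruction step 1)
#'
#' Solves the L1-wavelet-regularized SENSE problem jointly over all echoes,
#' with the proximal step applied to each echo image.  Initialization is the
#' zero-filled adjoint reconstruction.
#'
#' @param kspace a [kspace_data()] object (already coil-compressed if
#'   desired).
#' @param maps a [coil_maps()] object.
#' @param config a [recon_config()].
#' @return an [echo_series()] with attributes `objective` and `fista`.
#' @export
cs_reconstruct <- function(kspace, maps, config = recon_config()) {
  scale <- kspace_norm_factor(kspace)
  y <- kspace$data / scale
  op <- encoding_operator(maps, kspace$mask)
  fit <- fista_solve(op, y, config$lambda, max_iters = config$max_iters,
                     rel_tol = config$rel_tol,
                     wavelet_levels = config$wavelet_levels)
  out <- echo_series(fit$solution * scale, kspace$echo_times)
  attr(out, "objective") <- fit$objective
  attr(out, "fista") <- fit[c("iterations", "converged")]
  out
}

#' Data-driven temporal subspace extraction (reconstruction step 2)
#'
#' Voxels whose first-echo magnitude exceeds
#' `intensity_threshold_fraction` x (99th percentile of first-echo
#' magnitude) form a voxels x echoes calibration matrix whose right singular
#' vectors, ordered by singular value, give the temporal basis; the first K
#' columns are retained.
#'
#' @param x an [echo_series()] (step-1 reconstruction).
#' @param K subspace size (default 12).
#' @param intensity_threshold_fraction background threshold (default 0.1).
#' @return a [subspace_basis()] carrying the full singular-value spectrum.
#' @export
build_subspace <- function(x, K = 12L,
                           intensity_threshold_fraction = 0.1) {
  img <- x$images
  d <- dim(img)
  if (K > d[3L]) stop("K exceeds the number of echoes")
  mag1 <- Mod(img[, , 1L])
  thr <- intensity_threshold_fraction *
    stats::quantile(mag1, 0.99, names = FALSE)
  vox <- which(mag1 > thr)
  if (length(vox) == 0L) stop("no voxels above the intensity threshold")
  sig <- matrix(img, d[1L] * d[2L], d[3L])[vox, , drop = FALSE]
  sv <- svd(sig, nu = 0, nv = d[3L])
  basis <- sv$v[, seq_len(K), drop = FALSE]
  subspace_basis(basis, singular_values = sv$d)
}

#' Subspace-constrained reconstruction (reconstruction step 3)
#'
#' Identical to [cs_reconstruct()] but solving for K subspace coefficient
#' images under the explicit constraint x = Phi_K alpha; the wavelet penalty
#' acts on the coefficient images.  Initialization is the basis projection
#' of `x_init` (typically the step-1 echo images).
#'
#' @param kspace a [kspace_data()] object.
#' @param maps a [coil_maps()] object.
#' @param basis a [subspace_basis()].
#' @param config a [recon_config()].
#' @param x_init optional [echo_series()] used for initialization.
#' @return list of class `coefficient_images` with `coeffs` (phase x slice
#'   x K), `basis`, `objective`.
#' @export
subspace_reconstruct <- function(kspace, maps, basis,
                                 config = recon_config(), x_init = NULL) {
  scale <- kspace_norm_factor(kspace)
  y <- kspace$data / scale
  op <- encoding_operator(maps, kspace$mask, basis)
  x0 <- NULL
  if (!is.null(x_init)) {
    d <- dim(x_init$images)
    xm <- matrix(x_init$images / scale, d[1L] * d[2L], d[3L])
    x0 <- array(xm %*% Conj(basis$basis), c(d[1L], d[2L], basis$K))
  }
  fit <- fista_solve(op, y, config$lambda, x0 = x0,
                     max_iters = config$max_iters, rel_tol = config$rel_tol,
                     wavelet_levels = config$wavelet_levels)
  structure(list(coeffs = fit$solution * scale, basis = basis,
                 objective = fit$objective,
                 iterations = fit$iterations, converged = fit$converged),
            class = "coefficient_images")
}

#' Synthesize echo images from subspace coefficients (step 4)
#'
#' Computes `x_e = sum_k Phi[e, k] * alpha_k` voxelwise.
#'
#' @param alpha a `coefficient_images` object or a complex array (phase x
#'   slice x K).
#' @param basis a [subspace_basis()] (taken from `alpha` when omitted).
#' @param echo_times optional echo-time vector attached to the result.
#' @return an [echo_series()].
#' @export
synthesize_echo_images <- function(alpha, basis = NULL, echo_times = NULL) {
  if (inherits(alpha, "coefficient_images")) {
    if (is.null(basis)) basis <- alpha$basis
    alpha <- alpha$coeffs
  }
  d <- dim(alpha)
  stopifnot(d[3L] == basis$K)
  am <- matrix(alpha, d[1L] * d[2L], d[3L])
  x <- array(am %*% t(basis$basis), c(d[1L], d[2L], nrow(basis$basis)))
  echo_series(x, echo_times)
}

#' Run the full subspace-constrained reconstruction chain
#'
#' Orchestrates coil-map estimation from the echo-1 calibration region,
#' SVD coil compression, the conventional CS first pass, data-driven
#' subspace extraction, the subspace-constrained second pass, and echo-image
#' synthesis.  Fully deterministic for fixed inputs.
#'
#' @param kspace a [kspace_data()] object.
#' @param config a [recon_config()].
#' @param maps optional [coil_maps()] (estimated from the calibration
#'   region when `NULL`).
#' @param keep_intermediates keep the step-1 echo images in the result.
#' @return object of class `calipr_recon` with elements `echoes`
#'   (an [echo_series()]), `alpha`, `basis`, `maps`, `diagnostics` (objective
#'   traces, singular values, compression energy, sampled fraction), and
#'   optionally `cs_echoes`.
#' @export
run_calipr <- function(kspace, config = recon_config(), maps = NULL,
                       keep_intermediates = FALSE) {
  if (is.null(maps)) {
    maps <- estimate_coil_maps(kspace, config$calib_shape)
  }
  n_coil <- dim(kspace$data)[4L]
  comp_energy <- 1
  if (config$n_virtual_coils < n_coil) {
    cc <- coil_compress(kspace, config$n_virtual_coils, config$calib_shape)
    kspace <- cc$kspace
    comp_energy <- cc$energy_retained
    # compress the maps with the same matrix
    dm <- dim(maps$maps)
    mm <- matrix(maps$maps, ncol = dm[3L]) %*% t(cc$matrix)
    cmaps <- array(mm, c(dm[1:2], config$n_virtual_coils))
    rss <- sqrt(apply(Mod(cmaps)^2, c(1, 2), sum))
    for (c in seq_len(config$n_virtual_coils)) {
      cmaps[, , c] <- cmaps[, , c] / pmax(rss, .Machine$double.eps)
    }
    maps <- coil_maps(cmaps, maps$support)
  }
  cs <- cs_reconstruct(kspace, maps, config)
  basis <- build_subspace(cs, config$K, config$intensity_threshold_fraction)
  alpha <- subspace_reconstruct(kspace, maps, basis, config, x_init = cs)
  echoes <- synthesize_echo_images(alpha, basis, kspace$echo_times)
  out <- structure(list(
    echoes = echoes, alpha = alpha, basis = basis, maps = maps,
    diagnostics = list(
      cs_objective = attr(cs, "objective"),
      subspace_objective = alpha$objective,
      singular_values = basis$singular_values,
      compression_energy = comp_energy,
      sampled_fraction = mean(kspace$mask)
    )
  ), class = "calipr_recon")
  if (keep_intermediates) out$cs_echoes <- cs
  out
}

#' @export
print.calipr_recon <- function(x, ...) {
  d <- dim(x$echoes$images)
  cat(sprintf("subspace-constrained reconstruction: %d x %d grid, %d echoes, K = %d\n",
              d[1L], d[2L], d[3L], x$basis$K))
  cat(sprintf("  sampled fraction %.4f; CS pass %d iters, subspace pass %d iters\n",
              x$diagnostics$sampled_fraction,
              length(x$diagnostics$cs_objective),
              length(x$diagnostics$subspace_objective)))
  invisible(x)
}

#' Normalized root-mean-square error between image stacks
#'
#' `||x - ref||_2 / ||ref||_2` over all voxels and echoes, on complex or
#' magnitude data.
#'
#' @param x,ref arrays (or [echo_series()]) of identical shape.
#' @param magnitude compare magnitudes rather than complex values.
#' @return scalar NRMSE.
#' @export
nrmse <- function(x, ref, magnitude = FALSE) {
  if (inherits(x, "echo_series")) x <- x$images
  if (inherits(ref, "echo_series")) ref <- ref$images
  stopifnot(identical(dim(x), dim(ref)))
  if (magnitude) { x <- Mod(x); ref <- Mod(ref) }
  sqrt(sum(Mod(x - ref)^2) / sum(Mod(ref)^2))
}
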