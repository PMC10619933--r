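# Lightweight S3 containers for the reconstruction chain.
#
# Internal array layout is (phase, slice, echo[, coil]) so that the 2D
# phase-slice plane is contiguous for per-echo FFTs.

#' Multi-coil multi-echo Cartesian k-space container
#'
#' @param data complex array (phase x slice x echo x coil); entries outside
#'   `mask` must be zero.
#' @param mask logical array (phase x slice x echo).
#' @param echo_times strictly increasing numeric vector of echo times (ms).
#' @return object of class `kspace_data`.
#' @export
kspace_data <- function(data, mask, echo_times) {
  d <- dim(data)
  stopifnot(length(d) == 4L, identical(dim(mask), d[1:3]),
            length(echo_times) == d[3L])
  if (is.unsorted(echo_times, strictly = TRUE)) {
    stop("echo_times must be strictly increasing")
  }
  structure(list(data = data, mask = mask, echo_times = echo_times),
            class = "kspace_data")
}

#' @export
print.kspace_data <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("k-space data: %d x %d grid, %d echoes, %d coils\n",
              d[1L], d[2L], d[3L], d[4L]))
  cat(sprintf("  sampled fraction: %.4f; TE %.3g-%.3g ms\n",
              mean(x$mask), min(x$echo_times), max(x$echo_times)))
  invisible(x)
}

#' Coil sensitivity map container
#'
#' @param maps complex array (phase x slice x coil), root-sum-of-squares 1
#'   on the support.
#' @param support logical matrix marking voxels with usable sensitivity.
#' @return object of class `coil_maps`.
#' @export
coil_maps <- function(maps, support) {
  stopifnot(length(dim(maps)) == 3L,
            identical(dim(support), dim(maps)[1:2]))
  structure(list(maps = maps, support = support), class = "coil_maps")
}

#' Echo image series container
#'
#' @param images complex array (phase x slice x echo).
#' @param echo_times numeric vector of echo times (ms), optional.
#' @return object of class `echo_series`.
#' @export
echo_series <- function(images, echo_times = NULL) {
  stopifnot(length(dim(images)) == 3L, all(is.finite(Mod(images))))
  structure(list(images = images, echo_times = echo_times),
            class = "echo_series")
}

#' Temporal subspace basis container
#'
#' @param basis complex or numeric matrix (n_echoes x K) with orthonormal
#'   columns.
#' @param singular_values singular values of the calibration matrix
#'   (optional, full length).
#' @return object of class `subspace_basis`.
#' @export
subspace_basis <- function(basis, singular_values = NULL) {
  basis <- as.matrix(basis)
  K <- ncol(basis)
  stopifnot(K >= 1L, K <= nrow(basis))
  g <- Conj(t(basis)) %*% basis
  if (max(Mod(g - diag(K))) > 1e-10) {
    stop("basis columns are not orthonormal")
  }
  structure(list(basis = basis, K = K, singular_values = singular_values),
            class = "subspace_basis")
}

#' @export
print.subspace_basis <- function(x, ...) {
  cat(sprintf("temporal subspace basis: %d echoes -> K = %d components\n",
              nrow(x$basis), x$K))
  if (!is.null(x$singular_values)) {
    sv <- x$singular_values
    cat(sprintf("  retained energy: %.4f%%\n",
                100 * sum(sv[seq_len(x$K)]^2) / sum(sv^2)))
  }
  invisible(x)
}

#' Reconstruction configuration
#'
#' Defaults mirror the in vivo brain MWI protocol: subspace size `K = 12`,
#' L1 wavelet weight `lambda = 0.004` on normalized data (use 0.001 for the
#' spinal cord protocol), Daubechies-4 wavelets with 3 decomposition levels,
#' and 8 virtual coils.
#'
#' @param lambda L1 wavelet regularization weight (on the normalized scale
#'   where the zero-filled RSS first-echo image has unit 99th-percentile
#'   magnitude).
#' @param K subspace size.
#' @param wavelet_levels dyadic decomposition levels (capped per grid).
#' @param max_iters maximum FISTA iterations.
#' @param rel_tol relative-change stopping tolerance.
#' @param intensity_threshold_fraction background threshold for subspace
#'   calibration, as a fraction of the 99th-percentile first-echo magnitude.
#' @param n_virtual_coils virtual channels for coil compression.
#' @param calib_shape calibration-region extent used for coil-map
#'   estimation and coil compression.
#' @return object of class `recon_config`.
#' @export
recon_config <- function(lambda = 0.004, K = 12L, wavelet_levels = 3L,
                         max_iters = 100L, rel_tol = 1e-5,
                         intensity_threshold_fraction = 0.1,
                         n_virtual_coils = 8L,
                         calib_shape = c(12L, 12L)) {
  stopifnot(lambda >= 0, K >= 1L)
  structure(list(lambda = lambda, K = as.integer(K),
                 wavelet_levels = as.integer(wavelet_levels),
                 max_iters = as.integer(max_iters), rel_tol = rel_tol,
                 intensity_threshold_fraction = intensity_threshold_fraction,
                 n_virtual_coils = as.integer(n_virtual_coils),
                 calib_shape = as.integer(rep(calib_shape, length.out = 2L))),
            class = "recon_config")
}
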