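# Digital tissue phantoms with known multicomponent T2 ground truth.
#
# Phantoms live on the 2D phase x slice plane: in a Cartesian MESE
# acquisition the readout dimension is fully sampled and decouples by FFT,
# so the undersampling problem is natively two-dimensional.  Each tissue
# class carries a discrete T2 spectrum (t2 / weight pairs), a proton
# density, and the voxel sees a smoothly varying refocusing flip angle.
# Echo images are built from EPG decay curves, multiplied by synthetic
# smooth coil sensitivities, Fourier transformed, and degraded with complex
# Gaussian noise and the sampling scheme's masks.

#' Specify a digital phantom
#'
#' @param grid_shape integer length-2, (phase, slice).
#' @param class_map integer matrix of tissue labels (0 = background).
#' @param components named list; one entry per class label (as character),
#'   each a two-column matrix/data.frame of (t2_ms, weight) with weights
#'   summing to 1.
#' @param proton_density named numeric; one entry per class label.
#' @param flip_map numeric matrix of refocusing flip angles in degrees, or a
#'   single number for a uniform field.
#' @param noise_sigma complex noise SD relative to the peak coil-combined
#'   signal (see [simulate_kspace()]).
#' @param n_coils number of synthetic receive coils.
#' @param seed integer seed for coil maps and noise.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, class_map, components, proton_density,
                         flip_map = 165, noise_sigma = 0, n_coils = 4L,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(identical(dim(class_map), grid_shape))
  if (length(flip_map) == 1L) {
    flip_map <- matrix(flip_map, grid_shape[1L], grid_shape[2L])
  }
  stopifnot(all(flip_map > 0), all(flip_map <= 180))
  labels <- setdiff(sort(unique(as.vector(class_map))), 0L)
  for (lab in labels) {
    key <- as.character(lab)
    if (is.null(components[[key]])) {
      stop(sprintf("no components for class label %d", lab))
    }
    comp <- as.matrix(components[[key]])
    if (any(comp[, 2L] < 0) || abs(sum(comp[, 2L]) - 1) > 1e-8) {
      stop(sprintf("weights for class %d must be nonnegative and sum to 1", lab))
    }
    if (is.na(proton_density[key])) {
      stop(sprintf("no proton density for class label %d", lab))
    }
  }
  structure(list(grid_shape = grid_shape, class_map = class_map,
                 components = components, proton_density = proton_density,
                 flip_map = flip_map, noise_sigma = noise_sigma,
                 n_coils = as.integer(n_coils), seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default concentric-shape brain-like phantom specification
#'
#' Three concentric tissue classes on a disc: a white-matter-like annulus
#' (two-pool spectrum, MWF 0.088), a gray-matter-like ring (MWF 0.03), and a
#' CSF-like core (single long-T2 pool, MWF 0).  The refocusing flip field is
#' a smooth radial droop from `flip_center` at the centre to about
#' `flip_center - 12` degrees at the edge, emulating transmit-field
#' inhomogeneity.
#'
#' @param grid_shape integer length-2, default `c(64, 64)`.
#' @param noise_sigma,n_coils,seed passed through to [phantom_spec()].
#' @param flip_center flip angle at the FOV centre (degrees).
#' @return a [phantom_spec()] object.
#' @export
default_phantom_spec <- function(grid_shape = c(64L, 64L), noise_sigma = 0,
                                 n_coils = 4L, seed = 1L,
                                 flip_center = 165) {
  grid_shape <- as.integer(grid_shape)
  np <- grid_shape[1L]; ns <- grid_shape[2L]
  cx <- (np + 1) / 2; cy <- (ns + 1) / 2
  r <- sqrt(outer(((seq_len(np) - cx) / (np / 2))^2,
                  ((seq_len(ns) - cy) / (ns / 2))^2, `+`))
  class_map <- matrix(0L, np, ns)
  class_map[r <= 0.85] <- 1L   # WM-like annulus
  class_map[r <= 0.45] <- 2L   # GM-like ring
  class_map[r <= 0.20] <- 3L   # CSF-like core
  components <- list(
    `1` = cbind(t2 = c(20, 80),  weight = c(0.088, 0.912)),
    `2` = cbind(t2 = c(20, 80),  weight = c(0.030, 0.970)),
    `3` = cbind(t2 = 2000,       weight = 1)
  )
  proton_density <- c(`1` = 0.70, `2` = 0.85, `3` = 1.00)
  flip_map <- flip_center - 12 * r^2
  phantom_spec(grid_shape, class_map, components, proton_density, flip_map,
               noise_sigma, n_coils, seed)
}

#' Build noise-free echo images and quantitative ground truth
#'
#' Per voxel, the noise-free signal at echo i is
#' `pd * sum_j w_j * epg_mese(t2_j, seq)[i]`, with the EPG curve evaluated at
#' the voxel's refocusing flip angle (quantized to 0.5 degree for curve
#' caching).  Ground-truth MWF is the summed weight of components with
#' T2 < 40 ms; ground-truth IET2 is the amplitude-weighted geometric mean T2
#' over the open (40, 200) ms window, NA where that window holds no weight.
#'
#' @param spec a [phantom_spec()] object.
#' @param seq a [mese_sequence()] object (its `refocus_flip` is overridden
#'   voxelwise by the phantom flip map).
#' @return list of class `phantom_truth` with elements `echo_images`
#'   (complex phase x slice x echo), `mwf_map`, `iet2_map`, `flip_map`,
#'   `class_map`, `support` (logical foreground), and `seq`.
#' @export
make_phantom <- function(spec, seq = mese_sequence(n_echoes = 32L,
                                                   delta_te = 6)) {
  np <- spec$grid_shape[1L]; ns <- spec$grid_shape[2L]
  n_echo <- seq$n_echoes
  echo_images <- array(0 + 0i, c(np, ns, n_echo))
  mwf <- matrix(NA_real_, np, ns)
  iet2 <- matrix(NA_real_, np, ns)
  flip_q <- round(spec$flip_map * 2) / 2   # 0.5 degree quantization
  labels <- setdiff(sort(unique(as.vector(spec$class_map))), 0L)
  curve_cache <- new.env(parent = emptyenv())
  decay <- function(t2, flip) {
    key <- sprintf("%.6g_%.1f", t2, flip)
    if (is.null(curve_cache[[key]])) {
      s <- seq; s$refocus_flip <- flip
      curve_cache[[key]] <- epg_mese(t2, s)
    }
    curve_cache[[key]]
  }
  for (lab in labels) {
    comp <- as.matrix(spec$components[[as.character(lab)]])
    pd <- spec$proton_density[[as.character(lab)]]
    vox <- which(spec$class_map == lab)
    mwf[vox] <- sum(comp[comp[, 1L] < 40, 2L])
    w_ie <- comp[, 1L] > 40 & comp[, 1L] < 200
    iet2[vox] <- if (any(comp[w_ie, 2L] > 0)) {
      exp(sum(comp[w_ie, 2L] * log(comp[w_ie, 1L])) / sum(comp[w_ie, 2L]))
    } else NA_real_
    for (f in unique(flip_q[vox])) {
      vf <- vox[flip_q[vox] == f]
      sig <- numeric(n_echo)
      for (j in seq_len(nrow(comp))) {
        sig <- sig + comp[j, 2L] * decay(comp[j, 1L], f)
      }
      sig <- pd * sig
      for (e in seq_len(n_echo)) {
        plane <- echo_images[, , e]
        plane[vf] <- sig[e]
        echo_images[, , e] <- plane
      }
    }
  }
  structure(list(echo_images = echo_images, mwf_map = mwf, iet2_map = iet2,
                 flip_map = spec$flip_map, class_map = spec$class_map,
                 support = spec$class_map > 0L, seq = seq, spec = spec),
            class = "phantom_truth")
}

#' Synthetic smooth complex coil sensitivity maps
#'
#' Gaussian sensitivity lobes centred just outside the FOV at equal angular
#' spacing, each with a mild linear phase ramp, normalized so the
#' root-sum-of-squares magnitude is exactly 1 everywhere. With
#' `n_coils = 1` the map is identically 1.
#'
#' @param n_coils number of coils (>= 1).
#' @param grid_shape integer length-2, (phase, slice).
#' @param seed integer seed (jitters lobe positions and widths).
#' @return a [coil_maps()] object.
#' @export
make_coil_maps <- function(n_coils, grid_shape, seed = 1L) {
  stopifnot(n_coils >= 1L)
  grid_shape <- as.integer(grid_shape)
  np <- grid_shape[1L]; ns <- grid_shape[2L]
  if (n_coils == 1L) {
    maps <- array(1 + 0i, c(np, ns, 1L))
    return(coil_maps(maps, support = matrix(TRUE, np, ns)))
  }
  withr::local_preserve_seed()
  set.seed(seed)
  x <- (seq_len(np) - (np + 1) / 2) / (np / 2)
  y <- (seq_len(ns) - (ns + 1) / 2) / (ns / 2)
  maps <- array(0 + 0i, c(np, ns, n_coils))
  angles <- 2 * pi * (seq_len(n_coils) - 1) / n_coils +
    stats::runif(n_coils, -0.2, 0.2)
  widths <- stats::runif(n_coils, 0.9, 1.3)
  for (c in seq_len(n_coils)) {
    cx <- 1.4 * cos(angles[c]); cy <- 1.4 * sin(angles[c])
    mag <- exp(-(outer((x - cx)^2, (y - cy)^2, `+`)) / (2 * widths[c]^2))
    ph <- 0.5 * (outer(x, rep(1, ns)) * sin(angles[c]) -
                 outer(rep(1, np), y) * cos(angles[c]))
    maps[, , c] <- mag * exp(1i * ph)
  }
  rss <- sqrt(apply(Mod(maps)^2, c(1, 2), sum))
  for (c in seq_len(n_coils)) maps[, , c] <- maps[, , c] / rss
  coil_maps(maps, support = matrix(TRUE, np, ns))
}

#' Simulate multi-coil multi-echo k-space from a phantom
#'
#' For each coil c and echo e the simulated k-space is
#' `F(S_c * x_e) + n`, with `F` the centred orthonormal 2D FFT and `n`
#' complex Gaussian noise with `E|n|^2 = sigma_abs^2`, where `sigma_abs =
#' noise_sigma * max |x_1|` (the peak coil-combined first-echo magnitude).
#' Because the FFT is unitary, `noise_sigma` is also the relative noise
#' level in the image domain, i.e. SNR = 1/noise_sigma at the brightest
#' voxel. Samples outside the scheme's masks are zeroed.
#'
#' @param truth a `phantom_truth` from [make_phantom()].
#' @param maps a [coil_maps()] object.
#' @param scheme a [sampling_scheme()] object (or `NULL` for full sampling).
#' @param noise_sigma relative complex noise SD (default: from the phantom
#'   spec).
#' @param seed integer seed for the noise draw.
#' @return a [kspace_data()] object.
#' @export
simulate_kspace <- function(truth, maps, scheme = NULL,
                            noise_sigma = NULL, seed = 1L) {
  x <- truth$echo_images
  d <- dim(x)
  dm <- dim(maps$maps)
  if (!identical(d[1:2], dm[1:2])) stop("coil map / phantom shape mismatch")
  if (!is.null(scheme) &&
      (!identical(as.integer(d[1:2]), as.integer(scheme$grid_shape)) ||
       d[3L] != scheme$n_echoes)) {
    stop("sampling scheme shape mismatch")
  }
  if (is.null(noise_sigma)) {
    noise_sigma <- if (!is.null(truth$spec)) truth$spec$noise_sigma else 0
  }
  n_coil <- dm[3L]
  ksp <- array(0 + 0i, c(d[1:2], d[3L], n_coil))
  for (c in seq_len(n_coil)) {
    for (e in seq_len(d[3L])) {
      ksp[, , e, c] <- fft2c(maps$maps[, , c] * x[, , e])
    }
  }
  if (noise_sigma > 0) {
    withr::local_preserve_seed()
    set.seed(seed)
    peak <- max(Mod(x[, , 1L]))
    s <- noise_sigma * peak / sqrt(2)
    n <- length(ksp)
    ksp <- ksp + complex(real = stats::rnorm(n, 0, s),
                         imaginary = stats::rnorm(n, 0, s))
  }
  mask <- if (is.null(scheme)) {
    array(TRUE, d)
  } else scheme$masks
  m4 <- array(mask, dim(ksp))
  ksp[!m4] <- 0
  kspace_data(ksp, mask, echo_times(truth$seq))
}
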