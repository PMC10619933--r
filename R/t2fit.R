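# Multicomponent T2 analysis: EPG dictionary, flip-angle refinement,
# Tikhonov-regularized NNLS, optional neighborhood spatial regularization,
# and MWF / IET2 map computation.
#
# Each voxel's magnitude decay d (length n_echoes) is modelled as d = A s
# with A the EPG dictionary over a log-spaced T2 grid at the voxel's
# refocusing flip angle and s >= 0 the T2 spectrum.  The myelin water
# fraction is the spectral fraction with T2 < 40 ms; IET2 is the
# amplitude-weighted geometric mean T2 strictly inside (40, 200) ms.

#' Logarithmic T2 grid
#'
#' @param n number of grid points (default 40).
#' @param range T2 range in ms (default 8 to 2000).
#' @return strictly increasing numeric vector of T2 values in ms.
#' @export
t2_grid <- function(n = 40L, range = c(8, 2000)) {
  stopifnot(n >= 2L, range[1L] > 0, range[2L] > range[1L])
  exp(seq(log(range[1L]), log(range[2L]), length.out = n))
}

#' EPG decay dictionary over a T2 grid
#'
#' Column j holds the EPG echo amplitudes for `grid[j]` at the given
#' refocusing flip angle.
#'
#' @param grid T2 grid from [t2_grid()] (ms).
#' @param seq a [mese_sequence()] object.
#' @param flip refocusing flip angle in degrees (default: from `seq`).
#' @return object of class `decay_basis`: list with `A` (n_echoes x n_T2),
#'   `grid`, `flip`, `seq`.
#' @export
build_decay_basis <- function(grid, seq, flip = seq$refocus_flip) {
  s <- seq
  s$refocus_flip <- flip
  A <- vapply(grid, function(t2) epg_mese(t2, s), numeric(seq$n_echoes))
  structure(list(A = A, grid = grid, flip = flip, seq = seq),
            class = "decay_basis")
}

# dictionary cache across candidate flips (keyed by flip, shared seq/grid)
.basis_bank <- function(grid, seq, flips) {
  bank <- new.env(parent = emptyenv())
  get_basis <- function(flip) {
    key <- sprintf("%.4f", flip)
    if (is.null(bank[[key]])) {
      bank[[key]] <- build_decay_basis(grid, seq, flip)
    }
    bank[[key]]
  }
  for (f in flips) get_basis(f)
  get_basis
}

#' Estimate the refocusing flip angle of a decay curve
#'
#' Returns the candidate flip whose unregularized NNLS fit leaves the
#' smallest residual.  This exploits the stimulated-echo signature: decay
#' curves at different refocusing flips are not related by scaling, so the
#' flip is identifiable from a single voxel's curve.
#'
#' @param signal magnitude decay (length `seq$n_echoes`).
#' @param grid T2 grid.
#' @param seq a [mese_sequence()] object.
#' @param flip_candidates candidate flips in degrees (default 90:180).
#' @param basis_bank optional cache from repeated calls (internal use).
#' @return list with `flip` (degrees, `NA` for an all-zero signal) and
#'   `residual`.
#' @export
estimate_flip <- function(signal, grid, seq,
                          flip_candidates = seq.int(90L, 180L),
                          basis_bank = NULL) {
  if (all(signal == 0)) return(list(flip = NA_real_, residual = NA_real_))
  if (is.null(basis_bank)) basis_bank <- .basis_bank(grid, seq, flip_candidates)
  best <- c(flip = NA_real_, res = Inf)
  for (f in flip_candidates) {
    B <- basis_bank(f)
    fit <- nnls_lh(B$A, signal)
    if (fit$resnorm < best["res"]) best <- c(flip = f, res = fit$resnorm)
  }
  list(flip = unname(best["flip"]), residual = unname(best["res"]))
}

#' Regularized non-negative least squares T2 spectrum fit
#'
#' Solves `min ||A s - d||^2 + mu^2 ||s||^2, s >= 0` via the stacked system
#' `[A; mu I] s ~ [d; 0]`. With `mu = "auto"` the regularization weight is
#' chosen by bisection so that the misfit chi-square equals
#' `chi2_factor` times the unregularized minimum (1.02 by default, the
#' usual myelin-water-imaging criterion).
#'
#' @param signal magnitude decay vector.
#' @param basis a [build_decay_basis()] object (or plain dictionary matrix).
#' @param mu nonnegative scalar, or `"auto"`.
#' @param chi2_factor target misfit inflation for `mu = "auto"`.
#' @param mu_tol relative bisection tolerance on the chi-square target.
#' @return list of class `t2_distribution`: `s` (amplitudes on the grid),
#'   `mu`, `chi2`, `chi2_min`.
#' @export
rnnls <- function(signal, basis, mu = "auto", chi2_factor = 1.02,
                  mu_tol = 1e-4) {
  A <- if (inherits(basis, "decay_basis")) basis$A else basis
  n <- ncol(A)
  solve_mu <- function(mu) {
    if (mu == 0) {
      fit <- nnls_lh(A, signal)
      return(list(s = fit$x, chi2 = fit$resnorm))
    }
    As <- rbind(A, diag(mu, n))
    ds <- c(signal, numeric(n))
    fit <- nnls_lh(As, ds)
    r <- signal - A %*% fit$x
    list(s = fit$x, chi2 = sum(r^2))
  }
  base <- solve_mu(0)
  if (identical(mu, "auto")) {
    chi2_min <- base$chi2
    if (chi2_min <= .Machine$double.eps * sum(signal^2)) {
      # (near-)exact fit: no room for a 2% misfit inflation
      out <- base
      out$mu <- 0
    } else {
      target <- chi2_factor * chi2_min
      lo <- 0
      hi <- max(colSums(A^2))^0.5 * 1e-3
      f_hi <- solve_mu(hi)
      while (f_hi$chi2 < target) {
        hi <- hi * 2
        f_hi <- solve_mu(hi)
        if (hi > 1e8) break
      }
      for (i in 1:60) {
        mid <- (lo + hi) / 2
        f_mid <- solve_mu(mid)
        if (f_mid$chi2 < target) lo <- mid else hi <- mid
        if ((hi - lo) < 1e-12 ||
            abs(f_mid$chi2 - target) < mu_tol * target) break
      }
      out <- solve_mu((lo + hi) / 2)
      out$mu <- (lo + hi) / 2
    }
    out$chi2_min <- chi2_min
  } else {
    stopifnot(is.numeric(mu), mu >= 0)
    out <- solve_mu(mu)
    out$mu <- mu
    out$chi2_min <- base$chi2
  }
  structure(list(s = as.numeric(out$s), mu = out$mu, chi2 = out$chi2,
                 chi2_min = out$chi2_min,
                 grid = if (inherits(basis, "decay_basis")) basis$grid else NULL),
            class = "t2_distribution")
}

#' Myelin water fraction of a T2 distribution
#'
#' Spectral amplitude with T2 strictly below `cutoff`, divided by the total
#' amplitude; `NA` when the distribution is empty.
#'
#' @param dist a `t2_distribution` (or plain amplitude vector).
#' @param grid T2 grid (taken from `dist` when available).
#' @param cutoff myelin water cutoff in ms (default 40; strict `<`).
#' @return fraction in [0, 1], or `NA`.
#' @export
compute_mwf <- function(dist, grid = NULL, cutoff = 40) {
  s <- if (inherits(dist, "t2_distribution")) dist$s else dist
  if (is.null(grid) && inherits(dist, "t2_distribution")) grid <- dist$grid
  tot <- sum(s)
  if (tot <= 0) return(NA_real_)
  sum(s[grid < cutoff]) / tot
}

#' Geometric mean intra/extracellular T2 of a distribution
#'
#' Amplitude-weighted geometric mean of the T2 values strictly inside the
#' open window; `NA` when the window carries no amplitude.
#'
#' @param dist a `t2_distribution` (or plain amplitude vector).
#' @param grid T2 grid.
#' @param window open interval in ms, default `c(40, 200)`.
#' @return geometric mean T2 in ms, or `NA`.
#' @export
compute_iet2 <- function(dist, grid = NULL, window = c(40, 200)) {
  s <- if (inherits(dist, "t2_distribution")) dist$s else dist
  if (is.null(grid) && inherits(dist, "t2_distribution")) grid <- dist$grid
  inside <- grid > window[1L] & grid < window[2L]
  w <- s[inside]
  if (sum(w) <= 0) return(NA_real_)
  exp(sum(w * log(grid[inside])) / sum(w))
}

#' Fit configuration for multicomponent T2 analysis
#'
#' @param grid T2 grid (default 40 log-spaced points in 8-2000 ms).
#' @param chi2_factor misfit inflation target for automatic regularization.
#' @param flip_candidates candidate refocusing flips for the coarse search
#'   stage (degrees).
#' @param flip_refine_step fine search step around the coarse optimum
#'   (degrees; 0 disables refinement).
#' @param spatial_weight weight of the neighborhood-reference penalty in
#'   [spatial_regularized_fit()], relative to the temporal `mu`.
#' @param n_spatial_iters spatial refinement passes (default 2).
#' @param mwf_cutoff myelin water T2 cutoff (ms).
#' @param iet2_window intra/extracellular T2 window (ms).
#' @return object of class `fit_config`.
#' @export
fit_config <- function(grid = t2_grid(), chi2_factor = 1.02,
                       flip_candidates = seq(90, 180, by = 5),
                       flip_refine_step = 1,
                       spatial_weight = 1, n_spatial_iters = 2L,
                       mwf_cutoff = 40, iet2_window = c(40, 200)) {
  structure(list(grid = grid, chi2_factor = chi2_factor,
                 flip_candidates = flip_candidates,
                 flip_refine_step = flip_refine_step,
                 spatial_weight = spatial_weight,
                 n_spatial_iters = as.integer(n_spatial_iters),
                 mwf_cutoff = mwf_cutoff, iet2_window = iet2_window),
            class = "fit_config")
}

# two-stage flip search: coarse candidates then 1-degree refinement
.fit_one_voxel <- function(signal, seq, config, get_basis) {
  est <- estimate_flip(signal, config$grid, seq,
                       flip_candidates = config$flip_candidates,
                       basis_bank = get_basis)
  flip <- est$flip
  if (!is.na(flip) && config$flip_refine_step > 0) {
    lo <- max(min(config$flip_candidates), flip - 4)
    hi <- min(180, flip + 4)
    fine <- seq.int(lo, hi, by = config$flip_refine_step)
    est <- estimate_flip(signal, config$grid, seq, flip_candidates = fine,
                         basis_bank = get_basis)
    flip <- est$flip
  }
  if (is.na(flip)) {
    return(list(flip = NA_real_, dist = NULL, chi2 = NA_real_))
  }
  B <- get_basis(flip)
  dist <- rnnls(signal, B, mu = "auto", chi2_factor = config$chi2_factor)
  list(flip = flip, dist = dist, chi2 = dist$chi2)
}

#' Voxelwise multicomponent T2 fit of an echo-image volume
#'
#' Per voxel: two-stage refocusing-flip search (coarse grid then 1-degree
#' refinement), then automatically regularized NNLS at the estimated flip.
#' Voxels outside the support mask, or with all-zero signal, are flagged
#' undefined (`NA`) rather than zero-filled.
#'
#' @param echo_images magnitude array (phase x slice x echo), an
#'   [echo_series()], or complex images (magnitude is taken).
#' @param seq a [mese_sequence()] describing the echo train.
#' @param support logical matrix of voxels to fit (default: voxels whose
#'   first-echo magnitude exceeds 10% of the 99th percentile).
#' @param config a [fit_config()].
#' @param keep_distributions return the full spectra (nvox x nT2).
#' @return object of class `quant_maps` with matrices `mwf`, `iet2`, `flip`,
#'   `residual` (relative chi-square) and logical `defined`.
#' @export
fit_volume <- function(echo_images, seq, support = NULL,
                       config = fit_config(), keep_distributions = FALSE) {
  if (inherits(echo_images, "echo_series")) echo_images <- echo_images$images
  mag <- Mod(echo_images)
  d <- dim(mag)
  stopifnot(d[3L] == seq$n_echoes)
  if (is.null(support)) {
    thr <- 0.1 * stats::quantile(mag[, , 1L], 0.99, names = FALSE)
    support <- mag[, , 1L] > thr
  }
  get_basis <- .basis_bank(config$grid, seq, config$flip_candidates)
  mwf <- matrix(NA_real_, d[1L], d[2L])
  iet2 <- mwf; flip <- mwf; residual <- mwf; mu_map <- mwf
  dists <- if (keep_distributions) {
    matrix(NA_real_, d[1L] * d[2L], length(config$grid))
  } else NULL
  sig_mat <- matrix(mag, d[1L] * d[2L], d[3L])
  for (v in which(support)) {
    signal <- sig_mat[v, ]
    if (all(signal == 0)) next
    fit <- .fit_one_voxel(signal, seq, config, get_basis)
    if (is.null(fit$dist)) next
    flip[v] <- fit$flip
    mwf[v] <- compute_mwf(fit$dist, config$grid, config$mwf_cutoff)
    iet2[v] <- compute_iet2(fit$dist, config$grid, config$iet2_window)
    residual[v] <- fit$chi2 / max(sum(signal^2), .Machine$double.eps)
    mu_map[v] <- fit$dist$mu
    if (keep_distributions) dists[v, ] <- fit$dist$s
  }
  structure(list(mwf = mwf, iet2 = iet2, flip = flip, residual = residual,
                 mu_map = mu_map, defined = !is.na(flip), grid = config$grid,
                 distributions = dists, seq = seq, config = config),
            class = "quant_maps")
}

#' @export
print.quant_maps <- function(x, ...) {
  nd <- sum(x$defined)
  cat(sprintf("quantitative T2 maps: %d x %d grid, %d fitted voxels\n",
              nrow(x$mwf), ncol(x$mwf), nd))
  if (nd > 0) {
    cat(sprintf("  MWF  median %.4f (IQR %.4f-%.4f)\n",
                stats::median(x$mwf[x$defined], na.rm = TRUE),
                stats::quantile(x$mwf[x$defined], 0.25, na.rm = TRUE,
                                names = FALSE),
                stats::quantile(x$mwf[x$defined], 0.75, na.rm = TRUE,
                                names = FALSE)))
    if (any(!is.na(x$iet2))) {
      cat(sprintf("  IET2 median %.1f ms\n", stats::median(x$iet2, na.rm = TRUE)))
    }
    cat(sprintf("  flip median %.1f deg\n", stats::median(x$flip, na.rm = TRUE)))
  }
  invisible(x)
}

#' Summary of quantitative maps
#' @param object a `quant_maps` object.
#' @param ... unused.
#' @return data frame of per-metric summary statistics over defined voxels.
#' @export
summary.quant_maps <- function(object, ...) {
  take <- function(m) m[object$defined & !is.na(m)]
  rows <- lapply(list(mwf = take(object$mwf), iet2 = take(object$iet2),
                      flip = take(object$flip)),
                 function(v) {
                   if (length(v) == 0L) {
                     return(data.frame(n = 0L, median = NA_real_,
                                       mean = NA_real_, sd = NA_real_))
                   }
                   data.frame(n = length(v), median = stats::median(v),
                              mean = mean(v), sd = stats::sd(v))
                 })
  out <- do.call(rbind, rows)
  out$metric <- names(rows)
  out[, c("metric", "n", "median", "mean", "sd")]
}

# kernel-weighted neighborhood average of spectra (3x3, weights 1-2-1
# separable); only defined in-bounds neighbors contribute
.neighborhood_reference <- function(dists, d12, defined) {
  np <- d12[1L]; ns <- d12[2L]
  kern <- outer(c(1, 2, 1), c(1, 2, 1))
  ref <- matrix(0, nrow(dists), ncol(dists))
  wsum <- numeric(nrow(dists))
  for (di in -1:1) {
    for (dj in -1:1) {
      w <- kern[di + 2L, dj + 2L]
      ti <- seq_len(np); tj <- seq_len(ns)
      oki <- ti + di >= 1L & ti + di <= np
      okj <- tj + dj >= 1L & tj + dj <= ns
      tgt <- as.vector(outer(ti[oki], (tj[okj] - 1L) * np, `+`))
      src <- as.vector(outer(ti[oki] + di, (tj[okj] + dj - 1L) * np, `+`))
      ok <- defined[src]
      ref[tgt[ok], ] <- ref[tgt[ok], , drop = FALSE] +
        w * dists[src[ok], , drop = FALSE]
      wsum[tgt[ok]] <- wsum[tgt[ok]] + w
    }
  }
  pos <- wsum > 0
  ref[pos, ] <- ref[pos, , drop = FALSE] / wsum[pos]
  ref
}

#' Spatially regularized multicomponent T2 fit
#'
#' Iterates the voxelwise fit with an added quadratic penalty pulling each
#' voxel's spectrum toward a kernel-weighted average of its 3x3
#' neighborhood's spectra from the previous pass:
#' `min ||A s - d||^2 + mu^2 ||s||^2 + (w mu)^2 ||s - s_ref||^2, s >= 0`.
#' Two spatial passes are the default.  With `spatial_weight = 0` the result
#' equals [fit_volume()].
#'
#' @inheritParams fit_volume
#' @return a `quant_maps` object.
#' @export
spatial_regularized_fit <- function(echo_images, seq, support = NULL,
                                    config = fit_config()) {
  if (inherits(echo_images, "echo_series")) echo_images <- echo_images$images
  base <- fit_volume(echo_images, seq, support, config,
                     keep_distributions = TRUE)
  if (config$spatial_weight <= 0 || config$n_spatial_iters == 0L) {
    return(base)
  }
  mag <- Mod(echo_images)
  d <- dim(mag)
  sig_mat <- matrix(mag, d[1L] * d[2L], d[3L])
  support <- base$defined
  get_basis <- .basis_bank(config$grid, seq, unique(base$flip[support]))
  cur <- base
  nT2 <- length(config$grid)
  for (pass in seq_len(config$n_spatial_iters)) {
    ref <- .neighborhood_reference(cur$distributions, d[1:2], support)
    dists <- cur$distributions
    mwf <- cur$mwf; iet2 <- cur$iet2; residual <- cur$residual
    for (v in which(support)) {
      signal <- sig_mat[v, ]
      B <- get_basis(base$flip[v])
      mu <- base$mu_map[v]
      nu <- config$spatial_weight * max(mu, 1e-6)
      As <- rbind(B$A, diag(mu, nT2), diag(nu, nT2))
      ds <- c(signal, numeric(nT2), nu * ref[v, ])
      fit <- nnls_lh(As, ds)
      s <- fit$x
      dists[v, ] <- s
      mwf[v] <- compute_mwf(s, config$grid, config$mwf_cutoff)
      iet2[v] <- compute_iet2(s, config$grid, config$iet2_window)
      r <- signal - B$A %*% s
      residual[v] <- sum(r^2) / max(sum(signal^2), .Machine$double.eps)
    }
    cur$distributions <- dists
    cur$mwf <- mwf; cur$iet2 <- iet2; cur$residual <- residual
  }
  cur
}
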