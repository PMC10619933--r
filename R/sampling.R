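# Temporally incoherent variable-density Poisson sampling schemes for
# Cartesian multi-echo spin-echo acquisitions.
#
# A scheme lists, for each echo, which (phase, slice) encodes are acquired.
# The design elements are: a fully sampled central calibration region at the
# first two echoes, an elliptical k-space shutter, a uniform undersampling
# grid of factor 2 in the phase direction, and an independent random seed per
# echo so that aliasing is incoherent along the echo dimension.

#' Construct a sampling scheme object
#'
#' Low-level constructor; most users should call
#' [generate_sampling_scheme()].
#'
#' @param masks logical array (phase x slice x echo).
#' @param encode_order integer matrix with columns echo, phase, slice, in
#'   acquisition order.
#' @param calib_shape integer length-2: extent of the fully sampled central
#'   calibration region (phase, slice).
#' @param target_acceleration requested acceleration factor R.
#' @param seeds integer vector, one seed per echo.
#' @param shutter logical, elliptical shutter on/off.
#' @param phase_grid_factor uniform undersampling factor along phase.
#' @return object of class `sampling_scheme`.
#' @export
sampling_scheme <- function(masks, encode_order, calib_shape,
                            target_acceleration, seeds,
                            shutter = TRUE, phase_grid_factor = 2L) {
  d <- dim(masks)
  stopifnot(length(d) == 3L)
  s <- structure(list(
    grid_shape = d[1:2],
    n_echoes = d[3L],
    masks = masks,
    encode_order = encode_order,
    calib_shape = as.integer(calib_shape),
    target_acceleration = target_acceleration,
    achieved_fraction = sum(masks) / length(masks),
    seeds = as.integer(seeds),
    shutter = isTRUE(shutter),
    phase_grid_factor = as.integer(phase_grid_factor)
  ), class = "sampling_scheme")
  s
}

#' @export
print.sampling_scheme <- function(x, ...) {
  cat("Cartesian MESE sampling scheme\n")
  cat(sprintf("  grid            : %d x %d (phase x slice), %d echoes\n",
              x$grid_shape[1L], x$grid_shape[2L], x$n_echoes))
  cat(sprintf("  target R        : %.3g\n", x$target_acceleration))
  cat(sprintf("  sampled fraction: %.4f (%.1f%%)\n",
              x$achieved_fraction, 100 * x$achieved_fraction))
  cat(sprintf("  calibration     : %d x %d at echoes 1-2\n",
              x$calib_shape[1L], x$calib_shape[2L]))
  cat(sprintf("  shutter %s, phase grid factor %d\n",
              if (x$shutter) "on" else "off", x$phase_grid_factor))
  invisible(x)
}

# eligible (non-calibration) encodes at one echo, honoring shutter and
# phase grid; returns logical matrix
.eligible_mask <- function(grid_shape, calib_shape, shutter,
                           phase_grid_factor) {
  ok <- matrix(TRUE, grid_shape[1L], grid_shape[2L])
  if (shutter) {
    ok <- ok & (grid_radius(grid_shape) <= 1 + 1e-12)
  }
  if (phase_grid_factor > 1L) {
    cp <- grid_shape[1L] %/% 2L + 1L
    keep_phase <- ((seq_len(grid_shape[1L]) - cp) %% phase_grid_factor) == 0L
    ok <- ok & matrix(keep_phase, grid_shape[1L], grid_shape[2L])
  }
  ok
}

.calib_mask <- function(grid_shape, calib_shape) {
  m <- matrix(FALSE, grid_shape[1L], grid_shape[2L])
  if (all(calib_shape > 0L)) {
    m[calib_range(grid_shape[1L], calib_shape[1L]),
      calib_range(grid_shape[2L], calib_shape[2L])] <- TRUE
  }
  m
}

#' Generate a temporally incoherent variable-density sampling scheme
#'
#' Draws an independent variable-density Poisson pattern for every echo, with
#' radial density `p(r) = p0 * (1 - r)^density_power` on the
#' shutter-normalized radius. `p0` is calibrated by bisection so the expected
#' sample count matches the budget, and the realized pattern is then trimmed
#' or topped up at random so that the total sample count across echoes equals
#' `round(n_phase * n_slice * n_echoes / target_acceleration)` exactly.
#'
#' A fully sampled central calibration region is always included at echoes 1
#' and 2 (and counts toward the sampling budget). With `shutter = TRUE`
#' samples outside the inscribed ellipse of the grid are excluded; a uniform
#' undersampling grid of `phase_grid_factor` is applied along the phase
#' direction outside the calibration region.
#'
#' @param grid_shape integer length-2, (n_phase, n_slice).
#' @param n_echoes number of echoes.
#' @param target_acceleration acceleration factor R >= 1 on the full
#'   rectangular phase x slice x echo grid.
#' @param calib_shape calibration region extent, default `c(12, 12)`.
#' @param seeds one integer seed per echo (default `seed + 0:(n_echoes-1)`).
#' @param seed base seed used when `seeds` is not given.
#' @param shutter apply the elliptical shutter (default `TRUE`).
#' @param phase_grid_factor uniform phase-direction undersampling factor
#'   (default 2; use 1 to disable).
#' @param density_power exponent of the radial density law (default 3).
#' @param encode_ordering `"center_out"` (default) orders encodes by radius
#'   within each echo, ties broken by angle.
#' @return a [sampling_scheme()] object.
#' @export
generate_sampling_scheme <- function(grid_shape, n_echoes,
                                     target_acceleration,
                                     calib_shape = c(12L, 12L),
                                     seeds = NULL, seed = 1L,
                                     shutter = TRUE,
                                     phase_grid_factor = 2L,
                                     density_power = 3,
                                     encode_ordering = "center_out") {
  grid_shape <- as.integer(grid_shape)
  n_echoes <- as.integer(n_echoes)
  calib_shape <- as.integer(rep(calib_shape, length.out = 2L))
  if (target_acceleration < 1) {
    stop("target_acceleration must be >= 1")
  }
  if (any(calib_shape > grid_shape)) {
    stop("calibration region does not fit inside the grid")
  }
  if (is.null(seeds)) seeds <- as.integer(seed) + seq_len(n_echoes) - 1L
  if (length(seeds) != n_echoes) stop("need one seed per echo")

  n_total <- prod(grid_shape) * n_echoes
  m_total <- round(n_total / target_acceleration)

  calib <- .calib_mask(grid_shape, calib_shape)
  n_calib <- sum(calib)
  eligible <- .eligible_mask(grid_shape, calib_shape, shutter,
                             phase_grid_factor)
  # calibration points at echoes 1-2 are mandatory
  n_forced <- 2L * n_calib
  if (n_echoes == 1L) n_forced <- n_calib
  if (m_total < n_forced) {
    r_min <- n_total / n_forced
    stop(sprintf(paste0("infeasible acceleration: calibration points alone ",
                        "exceed the sampling budget (minimum achievable ",
                        "acceleration is %.2f)"), r_min))
  }

  # per-echo budgets: equal split of the remainder after forcing calibration
  budget <- rep(m_total %/% n_echoes, n_echoes)
  extra <- m_total - sum(budget)
  if (extra > 0L) budget[seq_len(extra)] <- budget[seq_len(extra)] + 1L
  calib_echoes <- seq_len(min(2L, n_echoes))
  short <- pmax(n_calib - budget[calib_echoes], 0L)
  if (any(short > 0L)) {
    budget[calib_echoes] <- pmax(budget[calib_echoes], n_calib)
    # take the excess from the other echoes, round-robin
    others <- setdiff(seq_len(n_echoes), calib_echoes)
    need <- sum(short)
    while (need > 0L && length(others) > 0L) {
      for (e in others) {
        if (need == 0L) break
        if (budget[e] > 0L) { budget[e] <- budget[e] - 1L; need <- need - 1L }
      }
      if (all(budget[others] == 0L)) break
    }
    if (need > 0L) stop("infeasible acceleration: cannot honor calibration")
  }

  withr::local_preserve_seed()
  r <- grid_radius(grid_shape)
  # density law on free points; the small floor keeps every eligible encode
  # reachable so the Bernoulli density can always be calibrated to budget
  w_free <- pmax((1 - pmin(r, 1))^density_power, 1e-6)

  masks <- array(FALSE, c(grid_shape, n_echoes))
  for (e in seq_len(n_echoes)) {
    forced <- if (e %in% calib_echoes) calib else
      matrix(FALSE, grid_shape[1L], grid_shape[2L])
    free <- eligible & !forced
    m_free <- budget[e] - sum(forced)
    idx_free <- which(free)
    if (m_free > length(idx_free)) {
      r_min <- n_total /
        (n_echoes * (sum(eligible | calib)) )
      stop(sprintf(paste0("infeasible acceleration %.3g for this grid: not ",
                          "enough eligible encodes (minimum achievable ",
                          "acceleration about %.2f)"),
                   target_acceleration, max(r_min, 1)))
    }
    me <- forced
    if (m_free > 0L) {
      w <- w_free[idx_free]
      set.seed(seeds[e])
      # calibrate the Bernoulli density by bisection on p0
      expected <- function(p0) sum(pmin(p0 * w, 1))
      lo <- 0; hi <- 1
      while (expected(hi) < m_free) hi <- hi * 2
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        if (expected(mid) < m_free) lo <- mid else hi <- mid
      }
      p <- pmin(hi * w, 1)
      drawn <- stats::runif(length(p)) < p
      # exact-count adjustment: random trim/add among free points
      excess <- sum(drawn) - m_free
      if (excess > 0L) {
        on <- which(drawn)
        drawn[sample(on, excess)] <- FALSE
      } else if (excess < 0L) {
        off <- which(!drawn)
        take <- sample(off, -excess, prob = pmax(w[off], 1e-12))
        drawn[take] <- TRUE
      }
      me[idx_free[drawn]] <- TRUE
    }
    masks[, , e] <- me
  }

  encode_order <- .build_encode_order(masks, encode_ordering)
  sampling_scheme(masks, encode_order, calib_shape, target_acceleration,
                  seeds, shutter, phase_grid_factor)
}

# center-out ordering within each echo: by radius, ties broken by angle
.build_encode_order <- function(masks, ordering = "center_out") {
  d <- dim(masks)
  cp <- d[1L] %/% 2L + 1L
  cs <- d[2L] %/% 2L + 1L
  out <- vector("list", d[3L])
  for (e in seq_len(d[3L])) {
    idx <- which(masks[, , e], arr.ind = TRUE)
    if (nrow(idx) == 0L) { out[[e]] <- cbind(echo = integer(0),
                                             phase = integer(0),
                                             slice = integer(0)); next }
    dp <- idx[, 1L] - cp
    ds <- idx[, 2L] - cs
    rad <- sqrt(dp^2 + ds^2)
    ang <- atan2(ds, dp)
    o <- order(rad, ang)
    out[[e]] <- cbind(echo = e, phase = idx[o, 1L], slice = idx[o, 2L])
  }
  do.call(rbind, out)
}

#' Validate the invariants of a sampling scheme
#'
#' Checks mask/encode-order consistency, calibration completeness at the
#' first two echoes, shutter and phase-grid compliance, and the achieved
#' sampling fraction against the target acceleration.
#'
#' @param scheme a [sampling_scheme()] object.
#' @param tol relative tolerance on `1/target_acceleration`.
#' @return invisibly `TRUE`; warnings for degenerate (empty) echoes.
#' @export
validate_sampling_scheme <- function(scheme, tol = 0.005) {
  d <- dim(scheme$masks)
  eo <- scheme$encode_order
  if (anyDuplicated(eo)) stop("duplicate encode triples")
  m2 <- array(FALSE, d)
  m2[cbind(eo[, "phase"], eo[, "slice"], eo[, "echo"])] <- TRUE
  if (!identical(m2, scheme$masks)) {
    stop("encode_order and masks describe different point sets")
  }
  if (all(scheme$calib_shape > 0L)) {
    pr <- calib_range(d[1L], scheme$calib_shape[1L])
    sr <- calib_range(d[2L], scheme$calib_shape[2L])
    for (e in seq_len(min(2L, d[3L]))) {
      if (!all(scheme$masks[pr, sr, e])) {
        stop(sprintf("calibration region incomplete at echo %d", e))
      }
    }
  }
  calib <- .calib_mask(d[1:2], scheme$calib_shape)
  if (scheme$shutter) {
    outside <- grid_radius(d[1:2]) > 1 + 1e-12
    for (e in seq_len(d[3L])) {
      bad <- scheme$masks[, , e] & outside & !calib
      if (any(bad)) stop("sample outside the elliptical shutter")
    }
  }
  if (scheme$phase_grid_factor > 1L) {
    cp <- d[1L] %/% 2L + 1L
    off_grid <- ((seq_len(d[1L]) - cp) %% scheme$phase_grid_factor) != 0L
    for (e in seq_len(d[3L])) {
      bad <- scheme$masks[off_grid, , e] & !calib[off_grid, , drop = FALSE]
      if (any(bad)) stop("sample off the uniform phase grid")
    }
  }
  f_tgt <- 1 / scheme$target_acceleration
  if (abs(scheme$achieved_fraction - f_tgt) / f_tgt > tol) {
    stop(sprintf("achieved fraction %.5f misses target %.5f",
                 scheme$achieved_fraction, f_tgt))
  }
  per_echo <- apply(scheme$masks, 3L, sum)
  if (any(per_echo == 0L)) {
    warning(sprintf("echo(es) with no samples: %s",
                    paste(which(per_echo == 0L), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Write a sampling scheme as a plain-text acquisition table
#'
#' One `echo phase slice` triple per line in acquisition order, preceded by
#' `#`-prefixed header lines carrying the grid shape, echo count,
#' calibration extent and generator metadata.
#'
#' @param scheme a [sampling_scheme()] object.
#' @param path output file path.
#' @return invisibly `path`.
#' @export
write_sampling_table <- function(scheme, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# grid_shape %d %d", scheme$grid_shape[1L], scheme$grid_shape[2L]),
    sprintf("# n_echoes %d", scheme$n_echoes),
    sprintf("# calib_shape %d %d", scheme$calib_shape[1L], scheme$calib_shape[2L]),
    sprintf("# target_acceleration %.10g", scheme$target_acceleration),
    sprintf("# shutter %d", as.integer(scheme$shutter)),
    sprintf("# phase_grid_factor %d", scheme$phase_grid_factor),
    sprintf("# seeds %s", paste(scheme$seeds, collapse = " "))
  ), con)
  eo <- scheme$encode_order
  writeLines(sprintf("%d %d %d", eo[, "echo"], eo[, "phase"], eo[, "slice"]),
             con)
  invisible(path)
}

#' Read a sampling scheme from a plain-text acquisition table
#'
#' @param path file written by [write_sampling_table()].
#' @return a [sampling_scheme()] object; a validation warning is emitted if
#'   some echo carries no samples.
#' @export
read_sampling_table <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  get_hdr <- function(key, required = TRUE) {
    m <- hdr[startsWith(hdr, paste0("# ", key, " "))]
    if (length(m) == 0L) {
      if (required) stop(sprintf("missing header '%s'", key))
      return(NULL)
    }
    strsplit(sub(paste0("# ", key, " "), "", m[1L]), " ")[[1L]]
  }
  grid_shape <- as.integer(get_hdr("grid_shape"))
  n_echoes <- as.integer(get_hdr("n_echoes"))
  calib_shape <- as.integer(get_hdr("calib_shape"))
  target_acceleration <- as.numeric(get_hdr("target_acceleration"))
  shutter <- as.integer(get_hdr("shutter")) == 1L
  pgf <- as.integer(get_hdr("phase_grid_factor"))
  seeds <- as.integer(get_hdr("seeds"))

  body_idx <- which(!is_hdr & nzchar(trimws(lines)))
  n <- length(body_idx)
  eo <- matrix(0L, n, 3L, dimnames = list(NULL, c("echo", "phase", "slice")))
  for (i in seq_len(n)) {
    ln <- body_idx[i]
    parts <- suppressWarnings(as.integer(strsplit(trimws(lines[ln]), "\\s+")[[1L]]))
    if (length(parts) != 3L || anyNA(parts)) {
      stop(sprintf("parse error at line %d: expected 'echo phase slice'", ln))
    }
    if (parts[1L] < 1L || parts[1L] > n_echoes ||
        parts[2L] < 1L || parts[2L] > grid_shape[1L] ||
        parts[3L] < 1L || parts[3L] > grid_shape[2L]) {
      stop(sprintf("index out of range at line %d", ln))
    }
    eo[i, ] <- parts
  }
  masks <- array(FALSE, c(grid_shape, n_echoes))
  masks[eo[, c("phase", "slice", "echo"), drop = FALSE]] <- TRUE
  s <- sampling_scheme(masks, eo, calib_shape, target_acceleration, seeds,
                       shutter, pgf)
  per_echo <- apply(masks, 3L, sum)
  if (any(per_echo == 0L)) {
    warning(sprintf("sampling table has empty echo(es): %s",
                    paste(which(per_echo == 0L), collapse = ", ")))
  }
  s
}

#' Retrospectively undersample fully sampled k-space
#'
#' Zeroes every k-space sample outside the scheme's masks; samples inside the
#' masks are passed through bit-identically.
#'
#' @param kspace a [kspace_data()] object.
#' @param scheme a [sampling_scheme()] object matching the k-space grid and
#'   echo count.
#' @return a [kspace_data()] object with the scheme's mask applied.
#' @export
retrospective_undersample <- function(kspace, scheme) {
  d <- dim(kspace$data)  # phase x slice x echo x coil
  if (!identical(d[1:2], as.integer(scheme$grid_shape)) ||
      d[3L] != scheme$n_echoes) {
    stop("k-space shape does not match the sampling scheme")
  }
  m4 <- array(scheme$masks, d)  # recycle over coil dimension
  data <- kspace$data
  data[!m4] <- 0
  kspace_data(data, scheme$masks, kspace$echo_times)
}

#' Point-spread function of a sampling mask
#'
#' Peak-normalized magnitude of the inverse Fourier transform of a single
#' echo mask; used to assess aliasing incoherence.
#'
#' @param mask logical matrix (phase x slice).
#' @return numeric matrix, maximum value 1 at the PSF peak.
#' @export
mask_psf <- function(mask) {
  p <- Mod(ifft2c(mask * 1))
  p / max(p)
}

#' Export sampling masks as a NIfTI volume
#'
#' Masks are written as a phase x slice x 1 x echo 4D volume of 0/1 values
#' for visual inspection.
#'
#' @param scheme a [sampling_scheme()] object.
#' @param path output `.nii`/`.nii.gz` path.
#' @return invisibly `path`.
#' @export
write_masks_nifti <- function(scheme, path) {
  d <- dim(scheme$masks)
  arr <- array(as.numeric(scheme$masks), c(d[1L], d[2L], 1L, d[3L]))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}
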