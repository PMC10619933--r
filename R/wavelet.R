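# Orthonormal Daubechies-4 wavelet transform with periodic boundaries.
#
# Used as the sparsifying transform T in the L1-regularized reconstructions.
# The transform is orthogonal, so its inverse is the adjoint and the proximal
# operator of lambda*||T(x)||_1 is T^-1 o soft-threshold o T.

.db4_lo <- local({
  s3 <- sqrt(3)
  c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
})
.db4_hi <- .db4_lo[4:1] * c(1, -1, 1, -1)

# one analysis level along columns of a matrix (length must be even)
.dwt_cols <- function(x, lo, hi) {
  n <- nrow(x)
  idx <- seq.int(1L, n, by = 2L)
  a <- matrix(0, n %/% 2L, ncol(x))
  d <- a
  for (t in 0:3) {
    rows <- (idx - 1L + t) %% n + 1L
    a <- a + lo[t + 1L] * x[rows, , drop = FALSE]
    d <- d + hi[t + 1L] * x[rows, , drop = FALSE]
  }
  list(a = a, d = d)
}

# one synthesis level along columns: adjoint of .dwt_cols
.idwt_cols <- function(a, d, lo, hi) {
  n <- 2L * nrow(a)
  x <- matrix(0, n, ncol(a))
  idx <- seq.int(1L, n, by = 2L)
  for (t in 0:3) {
    # rows are distinct within a tap (stride-2 with circular wrap), so plain
    # indexed accumulation is safe
    rows <- (idx - 1L + t) %% n + 1L
    x[rows, ] <- x[rows, ] + lo[t + 1L] * a + hi[t + 1L] * d
  }
  x
}

.dwt2_level <- function(x) {
  cc <- .dwt_cols(x, .db4_lo, .db4_hi)
  ra <- .dwt_cols(t(cc$a), .db4_lo, .db4_hi)
  rd <- .dwt_cols(t(cc$d), .db4_lo, .db4_hi)
  # pack [LL LH; HL HH]
  rbind(cbind(t(ra$a), t(ra$d)), cbind(t(rd$a), t(rd$d)))
}

.idwt2_level <- function(w) {
  n1 <- nrow(w) %/% 2L
  n2 <- ncol(w) %/% 2L
  ll <- w[seq_len(n1), seq_len(n2), drop = FALSE]
  lh <- w[seq_len(n1), n2 + seq_len(n2), drop = FALSE]
  hl <- w[n1 + seq_len(n1), seq_len(n2), drop = FALSE]
  hh <- w[n1 + seq_len(n1), n2 + seq_len(n2), drop = FALSE]
  ca <- t(.idwt_cols(t(ll), t(lh), .db4_lo, .db4_hi))
  cd <- t(.idwt_cols(t(hl), t(hh), .db4_lo, .db4_hi))
  .idwt_cols(ca, cd, .db4_lo, .db4_hi)
}

# Number of usable dyadic decomposition levels for a grid: the largest
# L <= max_levels such that both dimensions divide by 2^L (and stay >= 8).
wavelet_depth <- function(dims, max_levels = 3L) {
  lev <- 0L
  while (lev < max_levels && all(dims %% 2L == 0L) && all(dims >= 8L)) {
    dims <- dims %/% 2L
    lev <- lev + 1L
  }
  lev
}

#' Forward 2D Daubechies-4 wavelet transform (periodic, orthonormal)
#'
#' @param x real or complex matrix; each dimension must be divisible by
#'   `2^levels`.
#' @param levels number of decomposition levels.
#' @return matrix of wavelet coefficients in pyramid packing, same shape.
#' @export
dwt2 <- function(x, levels = 3L) {
  if (is.complex(x)) {
    return(dwt2(Re(x), levels) + 1i * dwt2(Im(x), levels))
  }
  w <- x
  n1 <- nrow(x); n2 <- ncol(x)
  for (l in seq_len(levels)) {
    stopifnot(n1 %% 2L == 0L, n2 %% 2L == 0L)
    w[seq_len(n1), seq_len(n2)] <- .dwt2_level(w[seq_len(n1), seq_len(n2), drop = FALSE])
    n1 <- n1 %/% 2L
    n2 <- n2 %/% 2L
  }
  w
}

#' Inverse 2D Daubechies-4 wavelet transform
#'
#' Exact inverse (and adjoint) of [dwt2()].
#'
#' @param w coefficient matrix from [dwt2()].
#' @param levels number of decomposition levels used in the forward pass.
#' @return reconstructed matrix.
#' @export
idwt2 <- function(w, levels = 3L) {
  if (is.complex(w)) {
    return(idwt2(Re(w), levels) + 1i * idwt2(Im(w), levels))
  }
  x <- w
  n1 <- nrow(w) %/% (2L^levels)
  n2 <- ncol(w) %/% (2L^levels)
  for (l in seq_len(levels)) {
    n1 <- n1 * 2L
    n2 <- n2 * 2L
    x[seq_len(n1), seq_len(n2)] <- .idwt2_level(x[seq_len(n1), seq_len(n2), drop = FALSE])
  }
  x
}

#' Complex soft-thresholding
#'
#' Proximal operator of `t * ||.||_1`; complex values are shrunk along their
#' phase direction.
#'
#' @param x numeric or complex array.
#' @param t threshold (>= 0).
#' @return array of the same shape.
#' @keywords internal
soft_threshold <- function(x, t) {
  m <- Mod(x)
  scale <- pmax(m - t, 0) / pmax(m, .Machine$double.eps)
  x * scale
}

# prox of lambda*||dwt2(.)||_1 with step size `t` for one image
wavelet_prox <- function(x, t, levels) {
  if (levels == 0L) return(soft_threshold(x, t))
  idwt2(soft_threshold(dwt2(x, levels), t), levels)
}
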