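#' @useDynLib calipr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft mvfft median quantile rnorm sd var pt aov
#' @importFrom utils read.table write.table head tail
NULL

# Centered, orthonormal 2D Fourier transforms.
#
# k-space is stored with DC at the matrix centre (floor(n/2)+1), the usual
# display convention for Cartesian MRI raw data.  The pair below is unitary
# (Parseval holds exactly), so operator norms and noise levels carry over
# unchanged between domains.

fftshift2 <- function(x) {
  d <- dim(x)
  i <- c(seq_len(d[1L] - d[1L] %/% 2L) + d[1L] %/% 2L, seq_len(d[1L] %/% 2L))
  j <- c(seq_len(d[2L] - d[2L] %/% 2L) + d[2L] %/% 2L, seq_len(d[2L] %/% 2L))
  x[i, j, drop = FALSE]
}

ifftshift2 <- function(x) {
  d <- dim(x)
  h1 <- d[1L] - d[1L] %/% 2L
  h2 <- d[2L] - d[2L] %/% 2L
  i <- c(seq_len(d[1L] %/% 2L) + h1, seq_len(h1))
  j <- c(seq_len(d[2L] %/% 2L) + h2, seq_len(h2))
  x[i, j, drop = FALSE]
}

#' Centered orthonormal 2D FFT
#'
#' Forward transform image -> k-space with DC at the centre and 1/sqrt(N)
#' scaling so that the transform is unitary.
#'
#' @param x complex (or numeric) matrix.
#' @return complex matrix of the same shape.
#' @keywords internal
fft2c <- function(x) {
  fftshift2(fft(ifftshift2(x))) / sqrt(length(x))
}

#' Centered orthonormal 2D inverse FFT
#' @param k complex matrix (k-space, DC centred).
#' @return complex matrix (image domain).
#' @keywords internal
ifft2c <- function(k) {
  fftshift2(fft(ifftshift2(k), inverse = TRUE)) / sqrt(length(k))
}

# radius of each grid point on the shutter-normalized [0,1] scale,
# measured from the DC sample at floor(n/2)+1
grid_radius <- function(grid_shape) {
  cp <- grid_shape[1L] %/% 2L + 1L
  cs <- grid_shape[2L] %/% 2L + 1L
  rp <- (seq_len(grid_shape[1L]) - cp) / max(grid_shape[1L] - cp, cp - 1L)
  rs <- (seq_len(grid_shape[2L]) - cs) / max(grid_shape[2L] - cs, cs - 1L)
  sqrt(outer(rp^2, rs^2, `+`))
}

# index range of a centred calibration block of extent m on an axis of size n
calib_range <- function(n, m) {
  if (m <= 0L) return(integer(0))
  c0 <- n %/% 2L + 1L
  lo <- c0 - (m %/% 2L)
  seq.int(lo, lo + m - 1L)
}
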