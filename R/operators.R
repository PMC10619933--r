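# Forward and adjoint encoding operators.
#
# The forward model is y = M F S Phi_K alpha (or y = M F S x without the
# subspace): expand the temporal basis along the echo dimension, multiply by
# coil sensitivities, Fourier transform each phase-slice plane, and sample
# with the per-echo masks.  The adjoint is the exact conjugate transpose,
# verified by dot-product tests.

#' Build the (subspace-)SENSE encoding operator
#'
#' Returns a pair of closures `forward(x)` and `adjoint(y)`.  Without a
#' basis, `x` is an echo image stack (phase x slice x echo) and `y` a
#' k-space array (phase x slice x echo x coil).  With a basis `Phi`
#' (n_echoes x K), `x` holds K coefficient images instead.
#'
#' @param maps a [coil_maps()] object.
#' @param mask logical array (phase x slice x echo).
#' @param basis optional [subspace_basis()] object.
#' @return list with elements `forward`, `adjoint`, `img_dim`.
#' @export
encoding_operator <- function(maps, mask, basis = NULL) {
  S <- maps$maps
  dm <- dim(S)
  n_coil <- dm[3L]
  dmask <- dim(mask)
  n_echo <- dmask[3L]
  stopifnot(identical(dm[1:2], dmask[1:2]))
  Phi <- if (is.null(basis)) NULL else basis$basis
  n_img <- if (is.null(Phi)) n_echo else ncol(Phi)
  np <- dm[1L]; ns <- dm[2L]

  expand <- function(x) {
    if (is.null(Phi)) return(x)
    # x: np x ns x K -> np x ns x n_echo
    xm <- matrix(x, np * ns, ncol(Phi))
    array(xm %*% t(Phi), c(np, ns, n_echo))
  }
  reduce <- function(x) {
    if (is.null(Phi)) return(x)
    xm <- matrix(x, np * ns, n_echo)
    array(xm %*% Conj(Phi), c(np, ns, ncol(Phi)))
  }

  forward <- function(x) {
    xe <- expand(x)
    y <- array(0 + 0i, c(np, ns, n_echo, n_coil))
    for (c in seq_len(n_coil)) {
      Sc <- S[, , c]
      for (e in seq_len(n_echo)) {
        y[, , e, c] <- fft2c(Sc * xe[, , e])
      }
    }
    m4 <- array(mask, dim(y))
    y[!m4] <- 0
    y
  }
  adjoint <- function(y) {
    m4 <- array(mask, dim(y))
    y[!m4] <- 0
    xe <- array(0 + 0i, c(np, ns, n_echo))
    for (e in seq_len(n_echo)) {
      acc <- matrix(0 + 0i, np, ns)
      for (c in seq_len(n_coil)) {
        acc <- acc + Conj(S[, , c]) * ifft2c(y[, , e, c])
      }
      xe[, , e] <- acc
    }
    reduce(xe)
  }
  list(forward = forward, adjoint = adjoint,
       img_dim = c(np, ns, n_img))
}

#' Estimate the squared operator norm of A^H A by power iteration
#'
#' @param op an [encoding_operator()].
#' @param n_iters power iterations (default 20).
#' @param seed seed for the random start vector.
#' @return estimate of `||A||^2`, the Lipschitz constant of the data
#'   gradient.
#' @export
operator_norm_sq <- function(op, n_iters = 20L, seed = 7L) {
  withr::local_preserve_seed()
  set.seed(seed)
  x <- array(complex(real = stats::rnorm(prod(op$img_dim)),
                     imaginary = stats::rnorm(prod(op$img_dim))),
             op$img_dim)
  x <- x / sqrt(sum(Mod(x)^2))
  lam <- 1
  for (i in seq_len(n_iters)) {
    x2 <- op$adjoint(op$forward(x))
    lam <- sqrt(sum(Mod(x2)^2))
    if (lam == 0) return(0)
    x <- x2 / lam
  }
  lam
}
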