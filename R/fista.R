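# FISTA for L1-wavelet-regularized SENSE reconstruction.
#
# Solves min_x 0.5*||A x - y||^2 + lambda * sum_i ||W x_i||_1 where the sum
# runs over the echo (or subspace-coefficient) images and W is the
# orthonormal periodic Daubechies-4 transform.  Step size 1/L with L from
# power iteration; a monotone restart keeps the objective trace
# non-increasing.

#' Solve an L1-wavelet-regularized least-squares problem with FISTA
#'
#' @param op an [encoding_operator()] providing `forward` and `adjoint`.
#' @param y observed k-space array.
#' @param lambda L1 weight (>= 0).
#' @param x0 initial image stack (default: `adjoint(y)`).
#' @param max_iters,rel_tol stopping controls.
#' @param wavelet_levels decomposition levels (capped to the grid's dyadic
#'   depth; 0 falls back to plain soft-thresholding).
#' @param monotone enable restart-on-increase (default `TRUE`).
#' @param L Lipschitz constant `||A||^2`; estimated by power iteration when
#'   `NULL`.
#' @return list with `solution`, `objective` (per-iteration trace),
#'   `iterations`, `converged`.
#' @export
fista_solve <- function(op, y, lambda, x0 = NULL, max_iters = 100L,
                        rel_tol = 1e-5, wavelet_levels = 3L,
                        monotone = TRUE, L = NULL) {
  stopifnot(lambda >= 0)
  if (is.null(L)) L <- operator_norm_sq(op)
  if (L <= 0) stop("degenerate operator (zero norm)")
  step <- 1 / L
  lev <- wavelet_depth(op$img_dim[1:2], wavelet_levels)
  n_img <- op$img_dim[3L]

  l1_of <- function(x) {
    s <- 0
    for (i in seq_len(n_img)) {
      s <- s + if (lev > 0L) sum(Mod(dwt2(x[, , i], lev))) else
        sum(Mod(x[, , i]))
    }
    s
  }
  objective <- function(x, r) 0.5 * sum(Mod(r)^2) + lambda * l1_of(x)
  prox <- function(x, t) {
    for (i in seq_len(n_img)) {
      x[, , i] <- wavelet_prox(x[, , i], t, lev)
    }
    x
  }

  x <- if (is.null(x0)) op$adjoint(y) else x0
  z <- x
  tk <- 1
  obj <- numeric(0)
  f_prev <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iters) {
    it <- it + 1L
    r_z <- op$forward(z) - y
    x_new <- prox(z - step * op$adjoint(r_z), step * lambda)
    f_new <- objective(x_new, op$forward(x_new) - y)
    if (is.na(f_new) || !is.finite(f_new)) {
      stop(sprintf("FISTA diverged at iteration %d (objective %g)", it, f_new))
    }
    if (monotone && f_new > f_prev) {
      # restart momentum from the best iterate
      z <- x
      tk <- 1
      r_z <- op$forward(z) - y
      x_new <- prox(z - step * op$adjoint(r_z), step * lambda)
      f_new <- objective(x_new, op$forward(x_new) - y)
      if (f_new > f_prev) {      # no further progress possible at this step
        obj <- c(obj, f_prev)
        converged <- TRUE
        break
      }
    }
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    dx <- sqrt(sum(Mod(x_new - x)^2))
    nx <- sqrt(sum(Mod(x)^2))
    z <- x_new + ((tk - 1) / t_new) * (x_new - x)
    x <- x_new
    tk <- t_new
    f_prev <- f_new
    obj <- c(obj, f_new)
    if (nx > 0 && dx / nx < rel_tol) {
      converged <- TRUE
      break
    }
  }
  list(solution = x, objective = obj, iterations = it, converged = converged)
}
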