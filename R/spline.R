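# Cubic smoothing spline in the csaps convention.
#
# Minimizes  p * sum_j (y_j - f(x_j))^2 + (1 - p) * int f''(t)^2 dt
# over natural cubic splines with knots at the data (unit weights, x in
# bp). Solved by the Reinsch algorithm: with Q the n x (n-2) second
# divided-difference matrix and R the (n-2) tridiagonal Gram matrix of
# natural-spline second derivatives, the minimizer satisfies
#   (R + c Q'Q) gamma = Q'y,   f = y - c Q gamma,   c = (1-p)/p.
# The system is pentadiagonal SPD and solved sparsely. The p -> 1 limit is
# interpolation; the p -> 0 limit is the least-squares line (Q annihilates
# linear trends).

#' Smooth one profile segment with a cubic smoothing spline
#'
#' @param x Strictly increasing positions (bp).
#' @param y Values at `x` (same length).
#' @param p Smoothing parameter in (0, 1), csaps convention with `x` in bp.
#'   The pipeline default is `1e-16`, which at typical bin spacings gives an
#'   effective bandwidth of roughly 100 kb.
#' @return Fitted values `f(x)`. Segments with fewer than 4 points are
#'   returned unchanged with a warning.
#' @export
smooth_segment <- function(x, y, p = 1e-16) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
    stop("p must lie in (0, 1)")
  if (n < 4L) {
    warning("segment has fewer than 4 points; returned unsmoothed")
    return(y)
  }
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  h <- diff(x)
  m <- n - 2L
  i <- seq_len(m)
  Q <- Matrix::sparseMatrix(
    i = c(i, i + 1L, i + 2L), j = rep(i, 3L),
    x = c(1 / h[i], -(1 / h[i] + 1 / h[i + 1L]), 1 / h[i + 1L]),
    dims = c(n, m)
  )
  diags <- list((h[i] + h[i + 1L]) / 3)
  if (m >= 2L) diags <- c(diags, list(h[seq(2L, m)] / 6))
  R <- Matrix::bandSparse(m, m, k = seq(0L, length(diags) - 1L),
                          diagonals = diags, symmetric = TRUE)
  cc <- (1 - p) / p
  M <- R + cc * Matrix::crossprod(Q)
  gam <- Matrix::solve(M, Matrix::crossprod(Q, y))
  f <- y - cc * as.vector(Q %*% gam)
  if (any(!is.finite(f))) stop("smoothing failed (non-finite result)")
  f
}
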