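#' Nonuniform second-difference operator
#'
#' Builds the sparse (T-2) x T operator whose row i estimates the second
#' derivative at interior sample x_i from the three samples at
#' (x_{i-1}, x_i, x_{i+1}), without assuming uniform spacing. The stencil is
#' the exact three-point divided-difference formula
#' \deqn{c_{i-1} = \frac{2}{(x_{i-1}-x_i)(x_{i-1}-x_{i+1})},\quad
#'       c_i = \frac{-2}{(x_{i-1}-x_i)(x_i-x_{i+1})},\quad
#'       c_{i+1} = \frac{2}{(x_{i+1}-x_{i-1})(x_{i+1}-x_i)},}
#' which annihilates affine samples exactly and returns exactly 2 for
#' samples of \eqn{x^2} on any grid. On a uniform grid of spacing h the
#' un-normalized rows are \eqn{[1,-2,1]/h^2}.
#'
#' All rows are rescaled by the first row's leading coefficient (recorded in
#' attribute `norm_constant`), which reduces the dynamic range of the normal
#' equations; on a uniform grid the normalized rows are exactly
#' \eqn{[1,-2,1]}. Note the normalization couples grid geometry to the
#' effective regularization weight: the bandwidth calibration of
#' [sigma2_from_cutoff()] is expressed for this normalized operator with
#' frequencies in units of the representative sampling rate.
#'
#' @param times Strictly increasing sample times (s), length T >= 3.
#' @param normalize Divide all rows by the first row's leading coefficient
#'   (default `TRUE`, the form used by the smoother).
#' @return A `dgCMatrix` of dimension (T-2) x T with attribute
#'   `norm_constant` (the leading coefficient of the first un-normalized
#'   row, units 1/s^2).
#' @examples
#' d2hat(c(0, 1, 2, 3))        # uniform: rows [1, -2, 1]
#' d2hat(c(0, 1, 3), normalize = FALSE)
#' @export
d2hat <- function(times, normalize = TRUE) {
  check_times(times, min_len = 3)
  x <- as.numeric(times)
  T <- length(x)
  xm <- x[1:(T - 2)]   # x_{i-1}
  x0 <- x[2:(T - 1)]   # x_i
  xp <- x[3:T]         # x_{i+1}

  cm <- 2 / ((xm - x0) * (xm - xp))
  c0 <- -2 / ((xm - x0) * (x0 - xp))
  cp <- 2 / ((xp - xm) * (xp - x0))

  norm_constant <- cm[1]
  if (normalize) {
    cm <- cm / norm_constant
    c0 <- c0 / norm_constant
    cp <- cp / norm_constant
  }

  i <- rep(seq_len(T - 2), 3L)
  j <- c(seq_len(T - 2), seq_len(T - 2) + 1L, seq_len(T - 2) + 2L)
  op <- Matrix::sparseMatrix(
    i = i, j = j, x = c(cm, c0, cp),
    dims = c(T - 2L, T)
  )
  attr(op, "norm_constant") <- norm_constant
  op
}
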