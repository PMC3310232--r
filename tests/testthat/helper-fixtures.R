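# Shared fixtures: random irregular grids and a dense brute-force smoother.

random_grid <- function(T, dt_min = 0.3, dt_max = 1.7) {
  cumsum(runif(T, dt_min, dt_max))
}

random_series <- function(T, ...) {
  tibble::tibble(time = random_grid(T, ...), value = rnorm(T))
}

# Dense brute-force solve of (I + sigma2 D'D) y = z, independent of the
# package's sparse-Cholesky path.
dense_smooth_oracle <- function(times, values, sigma2) {
  D <- as.matrix(d2hat(times))
  A <- diag(length(values)) + sigma2 * crossprod(D)
  as.numeric(solve(A, values))
}

rel_err <- function(x, ref) {
  max(abs(x - ref)) / max(abs(ref), .Machine$double.eps)
}
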