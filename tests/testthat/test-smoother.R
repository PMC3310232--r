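test_that("sparse-Cholesky solve matches the dense brute-force oracle", {
  withr::local_seed(21)
  for (rep in 1:20) {
    T <- sample(10:200, 1)
    s <- random_series(T)
    sigma2 <- 10^runif(1, -2, 6)
    fit <- sgp_smooth(s, sigma2)
    expect_lt(rel_err(fit$trend, dense_smooth_oracle(s$time, s$value, sigma2)),
              1e-8)
  }
})

test_that("trend and residual always sum to the input", {
  withr::local_seed(22)
  s <- random_series(80)
  for (sigma2 in 10^seq(-2, 8, by = 2)) {
    fit <- sgp_smooth(s, sigma2)
    expect_lt(rel_err(fit$trend + fit$residual, s$value), 1e-10)
  }
})

test_that("sigma2 = 0 is the identity and constants are fixed points", {
  withr::local_seed(23)
  s <- random_series(50)
  fit0 <- sgp_smooth(s, 0)
  expect_identical(fit0$trend, s$value)
  expect_identical(fit0$residual, rep(0, 50))

  const <- tibble::tibble(time = s$time, value = rep(0.85, 50))
  for (sigma2 in c(0, 1, 1e6)) {
    fit <- sgp_smooth(const, sigma2)
    expect_lt(max(abs(fit$trend - 0.85)), 1e-10)
    expect_lt(max(abs(fit$residual)), 1e-10)
  }
})

test_that("large sigma2 converges to the least-squares affine fit", {
  withr::local_seed(24)
  s <- random_series(120)
  fit <- sgp_smooth(s, 1e12)
  affine <- unname(stats::lm.fit(cbind(1, s$time), s$value)$fitted.values)
  # relative to the data scale (the affine fit itself can be near zero)
  scale <- max(abs(s$value))
  expect_lt(max(abs(fit$trend - affine)) / scale, 1e-4)
  expect_lt(max(abs(fit$residual - (s$value - affine))) / scale, 1e-4)
})

test_that("trend variance is non-increasing in sigma2", {
  withr::local_seed(25)
  s <- random_series(150)
  v <- vapply(10^seq(-2, 8), function(s2) var(sgp_smooth(s, s2)$trend),
              numeric(1))
  expect_true(all(diff(v) <= 1e-12))
})

test_that("the implied smoother matrix is symmetric on a uniform grid (zero phase)", {
  T <- 60
  sigma2 <- 5
  H <- vapply(seq_len(T), function(j) {
    e <- rep(0, T); e[j] <- 1
    spa_smooth(e, sigma2)$trend
  }, numeric(T))
  expect_lt(max(abs(H - t(H))), 1e-12)
})

test_that("spa_smooth agrees with sgp_smooth on uniform grids and with the dense oracle", {
  withr::local_seed(26)
  v <- rnorm(20)
  sp <- spa_smooth(v, 1)
  sg <- sgp_smooth(tibble::tibble(time = as.numeric(0:19), value = v), 1)
  expect_lt(max(abs(sp$trend - sg$trend)), 1e-10)
  expect_lt(rel_err(sp$trend, dense_smooth_oracle(0:19, v, 1)), 1e-8)
  expect_identical(spa_smooth(v, 0)$trend, v)
})

test_that("no dense system matrix is materialized: factor bandwidth stays bounded", {
  # pentadiagonal system => sparse factor with O(T) nonzeros; check the
  # stored operator and normal-equations matrix stay sparse as T grows
  for (T in c(500, 2000)) {
    D <- d2hat(seq_len(T) + runif(T, 0, 0.3))
    A <- Matrix::Diagonal(T) + 2 * Matrix::crossprod(D)
    expect_lt(length(A@x), 6 * T)   # at most 5 diagonals stored (symmetric)
    expect_s4_class(A, "sparseMatrix")
  }
})

test_that("tidy and glance return well-formed tibbles", {
  withr::local_seed(27)
  fit <- sgp_smooth(random_series(40), 10)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("time", "value", "trend", "residual"))
  g <- glance(fit)
  expect_equal(nrow(g), 1)
  expect_equal(g$n, 40)
  expect_equal(g$sigma2, 10)
  expect_equal(g$cutoff_normalized, cutoff_from_sigma2(10))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("invalid smoothing inputs are rejected", {
  s <- random_series(10)
  expect_error(sgp_smooth(s, -1), "sigma2")
  expect_error(sgp_smooth(data.frame(time = c(0, 0, 1), value = 1:3), 1),
               "strictly increasing")
  expect_error(sgp_smooth(data.frame(a = 1:3), 1), "columns")
  expect_error(spa_smooth(c(1, 2), 1), "length >= 3")
})
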