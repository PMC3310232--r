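test_that("closed-form calibration matches its worked value and is monotone", {
  expect_equal(sigma2_from_cutoff(0.5), (sqrt(2) - 1) / 16, tolerance = 1e-12)
  wc <- seq(0.02, 0.95, by = 0.01)
  s2 <- sigma2_from_cutoff(wc)
  expect_true(all(diff(s2) < 0))
  expect_true(all(diff(cutoff_from_sigma2(10^seq(-4, 8))) < 0))
  # wc -> 0 blows up, wc -> 1 vanishes
  expect_gt(sigma2_from_cutoff(1e-4), 1e10)
  expect_lt(sigma2_from_cutoff(0.999), 1e-10)
})

test_that("cutoff/sigma2 round-trip is the identity to 1e-12", {
  wc <- seq(0.01, 0.9, by = 0.001)
  expect_equal(cutoff_from_sigma2(sigma2_from_cutoff(wc)), wc,
               tolerance = 1e-12)
  expect_equal(cutoff_from_sigma2((sqrt(2) - 1) / 16), 0.5, tolerance = 1e-12)
})

test_that("kernel response has unit DC gain and half power gain at the cut-off", {
  for (s2 in c(0.01, 1, 100)) {
    expect_equal(kernel_response(0, s2), 1)
    expect_equal(kernel_response(0, s2, warped = FALSE), 1)
    wc <- cutoff_from_sigma2(s2)
    expect_equal(kernel_response(wc, s2)^2, 0.5, tolerance = 1e-12)
  }
  expect_equal(kernel_response(seq(0, 1, 0.1), 0), rep(1, 11))
  expect_error(kernel_response(1.5, 1), "normalized")
  expect_error(sigma2_from_cutoff(1.2), "inside")
  expect_error(cutoff_from_sigma2(-1), "> 0")
})

test_that("representative sampling frequency is the reciprocal median interval", {
  expect_equal(representative_fs(seq(0, 10, by = 0.25)), 4)
  expect_equal(representative_fs(c(0, 1, 2, 4)), 1)
  expect_error(representative_fs(5), "at least 2")
})

test_that("welch_psd recovers a sinusoid peak and white-noise level", {
  withr::local_seed(31)
  n <- 4096
  x <- sin(2 * pi * 0.25 * (1:n) / 2) # normalized frequency 0.25 at fs = 2
  pw <- welch_psd(x)
  expect_equal(pw$frequency[which.max(pw$power)], 0.25, tolerance = 0.01)
  # integrated white-noise PSD approximates the variance
  z <- rnorm(n)
  pz <- welch_psd(z)
  expect_equal(sum(pz$power) * diff(pz$frequency[1:2]), var(z),
               tolerance = 0.15)
  expect_true(all(pz$power >= 0))
})

test_that("Monte Carlo -3 dB estimate agrees with the calibration at reduced scale", {
  est <- monte_carlo_cutoff(0.1, n_samples = 5000, n_reps = 50, seed = 101)
  expect_equal(est, 0.102, tolerance = 0.01 / 0.102)
})

test_that("empirical transfer function of the finite smoother tracks the kernel response", {
  withr::local_seed(33)
  s2 <- sigma2_from_cutoff(0.1)
  z <- rnorm(5000)
  sm <- spa_smooth(z, s2)
  pin <- welch_psd(z)
  pout <- welch_psd(sm$trend)
  gain <- sqrt(pout$power / pin$power)
  h <- kernel_response(pmin(pin$frequency, 1), s2)
  sel <- pin$frequency > 0 & pin$frequency <= 0.8
  # loose absolute agreement across the axis, tight relative agreement in
  # the low-frequency range where the bilinear approximation is designed
  # to hold
  expect_lt(max(abs(gain[sel] - h[sel])), 0.1)
  low <- pin$frequency > 0 & pin$frequency <= 0.05
  expect_lt(max(abs(gain[low] / h[low] - 1)), 0.1)
})
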