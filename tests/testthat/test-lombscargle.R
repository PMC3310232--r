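test_that("a sinusoid on an irregular grid is recovered at its frequency", {
  tg <- synth_irregular_sinusoid(f0 = 0.2, duration = 60, mean_dt = 0.2,
                                 seed = 41)
  pg <- lsp(tg)
  f_peak <- pg$frequency[which.max(pg$power)]
  expect_lt(abs(f_peak - 0.2), diff(pg$frequency[1:2]) + 1e-12)
  expect_true(all(pg$power >= 0))

  # two summed sinusoids give two distinct peaks
  a <- synth_irregular_sinusoid(0.1, duration = 120, mean_dt = 0.4, seed = 42)
  b <- tibble::tibble(time = a$time, value = a$value +
                        sin(2 * pi * 0.3 * a$time))
  pg2 <- lsp(b)
  ord <- order(pg2$power, decreasing = TRUE)
  peaks <- sort(pg2$frequency[ord[1:2]])
  # the top two local maxima should bracket 0.1 and 0.3 Hz; allow a few bins
  expect_lt(abs(peaks[1] - 0.1), 0.02)
  expect_lt(abs(peaks[2] - 0.3), 0.02)
})

test_that("the periodogram is invariant to time-origin translation", {
  withr::local_seed(43)
  s <- random_series(100)
  fr <- default_freq_grid(s)
  p1 <- lsp(s, freqs = fr)
  shifted <- tibble::tibble(time = s$time + 1234.5, value = s$value)
  p2 <- lsp(shifted, freqs = fr)
  expect_equal(p2$power, p1$power, tolerance = 1e-10)
})

test_that("on a uniform grid the LSP is proportional to the classical periodogram", {
  withr::local_seed(44)
  n <- 64
  y <- rnorm(n)
  fr <- (1:(n / 2 - 1)) / n # Fourier frequencies for fs = 1, no DC/Nyquist
  pg <- lsp(tibble::tibble(time = as.numeric(0:(n - 1)), value = y),
            freqs = fr)
  classical <- (Mod(stats::fft(y - mean(y)))^2 / n)[2:(n / 2)]
  ratio <- pg$power / classical
  expect_lt(max(ratio) / min(ratio) - 1, 1e-8)
})

test_that("constant series yields zero power, not an error", {
  s <- tibble::tibble(time = cumsum(runif(20, 0.5, 1)), value = rep(3, 20))
  pg <- lsp(s, freqs = c(0.1, 0.2, 0.3))
  expect_identical(pg$power, rep(0, 3))
  expect_error(lsp(s, freqs = numeric(0)), "non-empty")
  expect_error(lsp(s, freqs = c(0.3, 0.2)), "strictly increasing")
})

test_that("default frequency grid follows the stated construction", {
  s <- tibble::tibble(time = seq(0, 30, by = 0.5), value = 0)
  fr <- default_freq_grid(s, oversample = 4)
  expect_equal(fr[1], 1 / 30)
  expect_equal(diff(fr[1:2]), 1 / 120)
  expect_lte(max(fr), 1) # Nyquist = fs/2 = 1 Hz
  fr1 <- default_freq_grid(s, oversample = 1)
  expect_equal(diff(fr1[1:2]), 1 / 30)
  # longer record -> finer grid
  s2 <- tibble::tibble(time = seq(0, 60, by = 0.5), value = 0)
  expect_lt(diff(default_freq_grid(s2)[1:2]), diff(fr[1:2]))
})

test_that("band power integrates correctly and errors on disjoint bands", {
  fr <- seq(0.04, 0.15, by = 0.001)
  pg <- tibble::tibble(frequency = fr, power = rep(1, length(fr)))
  expect_equal(band_power(pg, 0.04, 0.15), 0.11, tolerance = 1e-12)
  expect_error(band_power(pg, 0.5, 0.6), "does not overlap")
  expect_error(band_power(pg, 0.2, 0.1), "lo < hi")

  # disjoint bands add up to the total over their union
  fr2 <- seq(0.01, 0.4, by = 0.0005)
  withr::local_seed(45)
  pg2 <- tibble::tibble(frequency = fr2, power = rexp(length(fr2)))
  parts <- hrv_band_powers(pg2)
  expect_equal(sum(parts$power), band_power(pg2, 0.01, 0.4), tolerance = 1e-10)
})

test_that("total integrated power is stable across irregular grids of equal density", {
  tot <- vapply(1:5, function(sd) {
    withr::local_seed(400 + sd)
    s <- random_series(2000, dt_min = 0.5, dt_max = 1.5)
    pg <- lsp(s)
    band_power(pg, min(pg$frequency), max(pg$frequency))
  }, numeric(1))
  expect_lt(max(tot) / min(tot) - 1, 0.10)
})

test_that("detrending removes very-low-frequency power from the tachogram", {
  # averaged over records: power of the detrended series below 0.01 Hz is
  # >= 10 dB down on the raw series
  fgrid <- seq(0.002, 0.05, by = 0.002)
  p0 <- p2 <- 0
  for (sd in 1:20) {
    tg <- synth_hrv(seed = sd)
    bp <- sgp_bandpass(tg, f_lo = 0.025, f_hi = 0.5)
    p0 <- p0 + lsp(tibble::tibble(time = bp$time, value = bp$vt0),
                   freqs = fgrid)$power * var(bp$vt0)
    p2 <- p2 + lsp(tibble::tibble(time = bp$time, value = bp$vt2),
                   freqs = fgrid)$power * var(bp$vt2)
  }
  low <- fgrid <= 0.01
  expect_gt(10 * log10(mean(p0[low]) / mean(p2[low])), 10)
})

test_that("periodogram CSV export round-trips", {
  withr::local_seed(46)
  pg <- lsp(random_series(50))
  path <- withr::local_tempfile(fileext = ".csv")
  write_periodogram_csv(pg, path)
  back <- utils::read.csv(path)
  expect_named(back, c("frequency_hz", "power"))
  expect_equal(back$power, pg$power, tolerance = 1e-12)
})
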