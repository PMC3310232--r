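#' Regularization weight for a desired -3 dB cut-off frequency
#'
#' The smoothing-priors filter's equivalent-kernel amplitude response on the
#' normalized digital frequency axis (Nyquist = 1) is
#' \deqn{h(\omega) = \frac{1}{\sigma^2 (2\tan(\omega\pi/2))^4 + 1},}
#' obtained from the continuous-frequency response by the bilinear
#' transform. Requiring the power gain \eqn{h^2} to be 1/2 at
#' \eqn{\omega_c} gives the closed-form calibration
#' \deqn{\sigma^2 = (\sqrt2 - 1)\,(2 \tan(\omega_c \pi / 2))^{-4}.}
#' The calibration refers to the normalized operator of [d2hat()] with
#' frequencies in units of the representative sampling rate; convert a
#' physical cut-off f (Hz) with `wc = 2 * f / representative_fs(times)`.
#'
#' @param wc Normalized cut-off frequency in (0, 1), Nyquist = 1.
#' @return The regularization weight `sigma2` (dimensionless).
#' @examples
#' sigma2_from_cutoff(0.5) # (sqrt(2) - 1) / 16
#' @seealso [cutoff_from_sigma2()] for the inverse, [kernel_response()].
#' @export
sigma2_from_cutoff <- function(wc) {
  if (!is.numeric(wc) || any(!is.finite(wc)) || any(wc <= 0) || any(wc >= 1)) {
    rlang::abort("`wc` must lie strictly inside (0, 1) (normalized, Nyquist = 1).")
  }
  (sqrt(2) - 1) * (2 * tan(wc * pi / 2))^(-4)
}

#' Cut-off frequency implied by a regularization weight
#'
#' Analytic inverse of [sigma2_from_cutoff()]:
#' \deqn{\omega_c = \frac{2}{\pi}\arctan\!\Big(\tfrac12\big((\sqrt2-1)/\sigma^2\big)^{1/4}\Big).}
#'
#' @param sigma2 Regularization weight, > 0.
#' @return Normalized -3 dB cut-off frequency in (0, 1).
#' @export
cutoff_from_sigma2 <- function(sigma2) {
  if (!is.numeric(sigma2) || any(!is.finite(sigma2)) || any(sigma2 <= 0)) {
    rlang::abort("`sigma2` must be > 0 and finite.")
  }
  (2 / pi) * atan(0.5 * ((sqrt(2) - 1) / sigma2)^(1 / 4))
}

#' Equivalent-kernel amplitude response of the smoother
#'
#' In the large-T limit the smoother acts as a linear zero-phase filter.
#' Its amplitude response is evaluated either on the bilinear-warped
#' normalized axis (the form the cut-off calibration inverts),
#' \eqn{h(\omega) = 1/(\sigma^2(2\tan(\omega\pi/2))^4 + 1)}, or in the
#' continuous-frequency form \eqn{h(f) = 1/(\sigma^2 4\pi^2 f^4 + 1)}.
#' The phase is identically zero; DC gain is 1 for every `sigma2`.
#'
#' @param freqs Frequencies: normalized in \[0, 1\] for `warped = TRUE`,
#'   arbitrary non-negative continuous frequencies otherwise.
#' @param sigma2 Regularization weight, >= 0.
#' @param warped Use the bilinear-warped digital-axis form (default) or the
#'   continuous-frequency form.
#' @return Amplitude response h at each frequency (power gain is h^2).
#' @export
kernel_response <- function(freqs, sigma2, warped = TRUE) {
  check_sigma2(sigma2)
  if (!is.numeric(freqs) || any(!is.finite(freqs)) || any(freqs < 0)) {
    rlang::abort("`freqs` must be finite and non-negative.")
  }
  if (warped) {
    if (any(freqs > 1)) {
      rlang::abort("Warped-axis frequencies are normalized: need 0 <= freqs <= 1.")
    }
    1 / (sigma2 * (2 * tan(freqs * pi / 2))^4 + 1)
  } else {
    1 / (sigma2 * 4 * pi^2 * freqs^4 + 1)
  }
}

#' Welch power spectral density (averaged modified periodogram)
#'
#' Averaged-periodogram spectral estimate: the record is split into
#' overlapping segments, each is mean-removed, windowed and transformed,
#' and the squared magnitudes are averaged. Used by the bandwidth Monte
#' Carlo and the generator spectral checks.
#'
#' @param x Numeric vector.
#' @param fs Sampling frequency (default 2, so frequencies are normalized
#'   with Nyquist = 1).
#' @param n_segments Number of segments (default 8).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return A tibble with columns `frequency` and `power` (one-sided, DC to
#'   Nyquist).
#' @export
welch_psd <- function(x, fs = 2, n_segments = 8, overlap = 0.5) {
  x <- as.numeric(x)
  n <- length(x)
  # segment length L such that n_segments segments at the given overlap
  # tile the record: n = L + (n_segments - 1) * L * (1 - overlap)
  L <- floor(n / (1 + (n_segments - 1) * (1 - overlap)))
  if (L < 8) rlang::abort("Record too short for the requested segmentation.")
  step <- max(1L, floor(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- hann_window(L)
  segs <- vapply(starts, function(s) {
    seg <- x[s:(s + L - 1L)]
    (seg - mean(seg)) * w
  }, numeric(L))
  spec <- Mod(stats::mvfft(segs))^2
  pxx <- rowMeans(spec) / (fs * sum(w^2))
  nf <- floor(L / 2) + 1L
  pxx <- pxx[seq_len(nf)]
  # one-sided: double everything except DC (and Nyquist when L is even)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (L %% 2 == 0) dbl[nf] <- 1
  tibble::tibble(
    frequency = (seq_len(nf) - 1) * fs / L,
    power = pxx * dbl
  )
}

hann_window <- function(L) {
  0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))
}

# Locate the -3 dB (half-power) point of a spectrum: the plateau is the
# mean power over the lowest `plateau_frac` of the frequency axis (DC bin
# excluded) and the crossing is found by log-linear interpolation.
half_power_frequency <- function(frequency, power, plateau_frac = 0.02) {
  keep <- frequency > 0
  f <- frequency[keep]; p <- power[keep]
  plateau_band <- f <= plateau_frac * max(frequency)
  if (!any(plateau_band)) plateau_band[1] <- TRUE
  plateau <- mean(p[plateau_band])
  target <- plateau / 2
  below <- which(p < target)
  if (length(below) == 0) {
    rlang::abort("Power never falls to half the low-frequency plateau; cannot locate a -3 dB point.")
  }
  k <- below[1]
  if (k == 1) return(f[1])
  # interpolate log-power between the bracketing grid frequencies
  lp1 <- log(p[k - 1]); lp2 <- log(p[k]); lt <- log(target)
  f[k - 1] + (f[k] - f[k - 1]) * (lp1 - lt) / (lp1 - lp2)
}

#' Monte Carlo estimate of the smoother's -3 dB cut-off
#'
#' Validates the closed-form bandwidth calibration empirically: white
#' Gaussian noise sequences on a uniform grid are low-pass filtered through
#' the smoother with `sigma2 = sigma2_from_cutoff(wc_true)`, their Welch
#' periodograms are averaged across replications, and the frequency at
#' which the averaged power first falls to half its low-frequency plateau
#' is located by log-linear interpolation.
#'
#' @param wc_true Nominal normalized cut-off in (0, 1).
#' @param n_samples Samples per noise sequence (default 5000).
#' @param n_reps Number of replications (default 1000).
#' @param seed Integer seed for the noise generator.
#' @param n_segments,overlap Welch segmentation (see [welch_psd()]).
#' @return Estimated -3 dB frequency (normalized, Nyquist = 1).
#' @examples
#' \donttest{
#' monte_carlo_cutoff(0.1, n_samples = 2000, n_reps = 50, seed = 1)
#' }
#' @export
monte_carlo_cutoff <- function(wc_true, n_samples = 5000, n_reps = 1000,
                               seed = 1, n_segments = 8, overlap = 0.5) {
  if (!is.numeric(wc_true) || length(wc_true) != 1 || wc_true <= 0 ||
      wc_true >= 1) {
    rlang::abort("`wc_true` must lie strictly inside (0, 1).")
  }
  if (n_samples < 100) rlang::abort("Need n_samples >= 100.")
  if (n_reps < 1) rlang::abort("Need n_reps >= 1.")
  sigma2 <- sigma2_from_cutoff(wc_true)
  # the grid (and hence the factorization) is identical for every
  # replication: factor once, reuse for all solves
  f <- smoother_factor(d2_uniform(n_samples), sigma2)
  withr::local_seed(seed)
  acc <- NULL
  block <- 100L
  done <- 0L
  while (done < n_reps) {
    nb <- min(block, n_reps - done)
    Z <- matrix(stats::rnorm(n_samples * nb), nrow = n_samples)
    Y <- smoother_apply(f, Z)
    for (j in seq_len(nb)) {
      pw <- welch_psd(Y[, j], fs = 2, n_segments = n_segments,
                      overlap = overlap)
      if (is.null(acc)) {
        acc <- pw
        acc$power <- acc$power / n_reps
      } else {
        acc$power <- acc$power + pw$power / n_reps
      }
    }
    done <- done + nb
  }
  half_power_frequency(acc$frequency, acc$power)
}
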