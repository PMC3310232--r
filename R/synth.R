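#' Synthetic HRV tachogram: band-limited Gaussian RR noise on an irregular axis
#'
#' Emulates a short resting tachogram as band-limited Gaussian noise:
#'
#' 1. Gaussian RR values (mean `mean_rr`, sd `std_rr`) are drawn on a fine
#'    uniform grid of rate `fs_fine` spanning `duration`;
#' 2. low-pass filtered at `lp_cutoff` with a 3rd-order Butterworth applied
#'    forward and backward (zero-phase by construction), so the series has
#'    no significant power above the cut-off;
#' 3. irregular sample times are drawn with near-Gaussian increments of
#'    mean `irregular_mean_dt` and variance `irregular_var_dt`, truncated
#'    below at 0.1 s (an RR interval shorter than that is not physiological);
#' 4. the filtered signal is interpolated onto those times.
#'
#' The defaults generate a 30 s record with RR mean 0.85 s (about 75 bpm),
#' RR sd 0.025 s, a 1 Hz band limit, and a representative sampling
#' frequency near 1.16 Hz. This is a spectral test fixture, not a
#' physiological simulation: it has no respiratory sinus arrhythmia or
#' sympathovagal structure, only a flat band-limited spectrum.
#'
#' @param duration Record length (s), > 0.
#' @param mean_rr,std_rr Mean and standard deviation of the RR values (s).
#' @param lp_cutoff Low-pass band limit (Hz).
#' @param irregular_mean_dt Mean inter-sample interval of the irregular
#'   axis (s).
#' @param irregular_var_dt Variance of the inter-sample intervals (s^2).
#' @param seed Integer seed; identical arguments and seed give bit-identical
#'   output. `NULL` uses the current RNG state.
#' @param fs_fine Rate of the intermediate uniform grid (Hz); must exceed
#'   `2 * lp_cutoff`.
#' @param interpolation `"cubic"` (default) or `"linear"` projection onto
#'   the irregular axis.
#' @return A tibble with columns `time` (s, strictly increasing) and
#'   `value` (RR, s). The pre-projection uniform signal is attached as
#'   attribute `uniform` (tibble `time`, `value`) for spectral checks.
#' @examples
#' tg <- synth_hrv(seed = 7)
#' representative_fs(tg$time)
#' @export
synth_hrv <- function(duration = 30,
                      mean_rr = 0.85,
                      std_rr = 0.025,
                      lp_cutoff = 1,
                      irregular_mean_dt = 0.86,
                      irregular_var_dt = 0.01,
                      seed = NULL,
                      fs_fine = 4,
                      interpolation = c("cubic", "linear")) {
  interpolation <- match.arg(interpolation)
  stopifnot(duration > 0, mean_rr > 0, std_rr >= 0, lp_cutoff > 0,
            irregular_mean_dt > 0, irregular_var_dt >= 0)
  if (fs_fine <= 2 * lp_cutoff) {
    rlang::abort("`fs_fine` must exceed twice `lp_cutoff`.")
  }
  if (!is.null(seed)) withr::local_seed(seed)

  t_fine <- seq(0, duration, by = 1 / fs_fine)
  raw <- stats::rnorm(length(t_fine), mean = mean_rr, sd = std_rr)
  filtered <- if (std_rr > 0) {
    zero_phase_lowpass(raw, fs = fs_fine, cutoff = lp_cutoff)
  } else {
    raw
  }

  t_irr <- draw_irregular_times(duration, irregular_mean_dt, irregular_var_dt)
  v_irr <- if (interpolation == "cubic") {
    stats::spline(t_fine, filtered, xout = t_irr)$y
  } else {
    stats::approx(t_fine, filtered, xout = t_irr)$y
  }

  out <- tibble::tibble(time = t_irr, value = v_irr)
  attr(out, "uniform") <- tibble::tibble(time = t_fine, value = filtered)
  out
}

# Forward-backward 3rd-order Butterworth low-pass (zero phase). The input
# is mean-removed and reflection-padded before filtering to suppress edge
# transients, then restored.
zero_phase_lowpass <- function(x, fs, cutoff, order = 3) {
  bf <- signal::butter(order, W = cutoff / (fs / 2), type = "low")
  m <- mean(x)
  xc <- x - m
  np <- min(length(x) - 1, 3 * ceiling(fs / cutoff))
  pad_head <- xc[(np + 1):2]
  pad_tail <- xc[(length(xc) - 1):(length(xc) - np)]
  padded <- c(pad_head, xc, pad_tail)
  y <- signal::filtfilt(bf, padded)
  y[(np + 1):(np + length(x))] + m
}

# Increments ~ Normal(mean_dt, sqrt(var_dt)) truncated below at 0.1 s;
# truncation triggers a redraw (warning if any redraw was needed).
draw_irregular_times <- function(duration, mean_dt, var_dt, floor_dt = 0.1) {
  n <- ceiling(duration / mean_dt) + 10
  dt <- stats::rnorm(n, mean = mean_dt, sd = sqrt(var_dt))
  bad <- dt < floor_dt
  tries <- 0
  while (any(bad) && tries < 100) {
    dt[bad] <- stats::rnorm(sum(bad), mean = mean_dt, sd = sqrt(var_dt))
    bad <- dt < floor_dt
    tries <- tries + 1
  }
  if (any(bad)) {
    rlang::warn("Some increments truncated at the 0.1 s floor after redraws.")
    dt[bad] <- floor_dt
  }
  t <- cumsum(dt)
  t <- t[t <= duration]
  if (length(t) < 3) {
    rlang::abort("Record too short: fewer than 3 irregular samples fit in `duration`.")
  }
  t
}

#' Irregularly sampled sinusoid test signal
#'
#' A unit-amplitude sinusoid sampled at random irregular times with
#' truncated-normal increments (mean `mean_dt`, sd `mean_dt / 5`, floor
#' `mean_dt / 10`). Used as a fixture for periodogram peak-recovery and
#' band-pass checks.
#'
#' @param f0 Sinusoid frequency (Hz); must be below the representative
#'   Nyquist `1 / (2 * mean_dt)`.
#' @param duration Record length (s).
#' @param mean_dt Mean inter-sample interval (s).
#' @param seed Integer seed (`NULL` = current RNG state).
#' @param amplitude Sinusoid amplitude (default 1).
#' @param phase Phase offset (radians).
#' @return A tibble with `time` and `value` columns.
#' @export
synth_irregular_sinusoid <- function(f0, duration = 60, mean_dt = 0.5,
                                     seed = NULL, amplitude = 1, phase = 0) {
  stopifnot(duration > 0, mean_dt > 0)
  if (f0 >= 1 / (2 * mean_dt)) {
    rlang::abort(sprintf(
      "f0 = %g Hz is at or above the representative Nyquist %g Hz for mean_dt = %g s.",
      f0, 1 / (2 * mean_dt), mean_dt
    ))
  }
  if (!is.null(seed)) withr::local_seed(seed)
  n <- ceiling(duration / mean_dt) + 10
  dt <- pmax(stats::rnorm(n, mean_dt, mean_dt / 5), mean_dt / 10)
  t <- cumsum(dt)
  t <- t[t <= duration]
  if (length(t) < 3) rlang::abort("Too few samples fit in `duration`.")
  tibble::tibble(time = t, value = amplitude * sin(2 * pi * f0 * t + phase))
}
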