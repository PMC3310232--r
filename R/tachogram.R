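#' Build a tachogram from a sequence of RR intervals
#'
#' A tachogram places each RR interval at the time of the beat that closes
#' it, so the time axis is the cumulative sum of the intervals and the value
#' at each time is the interval itself. The result is an irregularly sampled
#' series: the sampling times are dictated by the heart, not by a clock.
#'
#' @param rr Numeric vector of RR intervals in seconds; all must be positive
#'   and finite.
#' @return A tibble with columns `time` (s, strictly increasing) and `value`
#'   (the RR interval in s at that beat).
#' @examples
#' tachogram_from_rr(c(0.8, 0.9, 0.85))
#' @export
tachogram_from_rr <- function(rr) {
  if (!is.numeric(rr) || length(rr) == 0) {
    rlang::abort("`rr` must be a non-empty numeric vector of RR intervals (s).")
  }
  bad <- which(!is.finite(rr) | rr <= 0)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "All RR intervals must be positive and finite; first offending index: %d (value %g).",
      bad[1], rr[bad[1]]
    ))
  }
  tibble::tibble(time = cumsum(as.numeric(rr)), value = as.numeric(rr))
}

#' Representative sampling frequency of an irregular time axis
#'
#' For an irregularly sampled record there is no single sampling frequency;
#' a representative one is taken as the reciprocal of the median inter-sample
#' interval. It is used to relate physical frequencies (Hz) to the normalized
#' frequency axis of the smoother (Nyquist = 1).
#'
#' @param times Numeric vector of strictly increasing sample times (s),
#'   length at least 2.
#' @return Representative sampling frequency in Hz.
#' @examples
#' representative_fs(c(0, 1, 2, 4)) # median interval 1 s -> 1 Hz
#' @export
representative_fs <- function(times) {
  check_times(times, min_len = 2)
  1 / stats::median(diff(times))
}

# Validate a time axis: finite, strictly increasing, minimum length.
check_times <- function(times, min_len = 3) {
  if (!is.numeric(times) || length(times) < min_len) {
    rlang::abort(sprintf("Need at least %d sample times.", min_len))
  }
  if (any(!is.finite(times))) {
    rlang::abort("Sample times must all be finite.")
  }
  if (any(diff(times) <= 0)) {
    i <- which(diff(times) <= 0)[1]
    rlang::abort(sprintf(
      "Sample times must be strictly increasing; violation between indices %d and %d (%g >= %g). Times are never silently sorted: reordering an RR record would corrupt it.",
      i, i + 1, times[i], times[i + 1]
    ))
  }
  invisible(times)
}

# Validate a (time, value) data frame and return it as a plain list of
# numeric vectors. `data` must have the two named columns.
check_series <- function(data, min_len = 3, time = "time", value = "value") {
  if (!is.data.frame(data)) {
    rlang::abort("`data` must be a data frame with `time` and `value` columns.")
  }
  if (!all(c(time, value) %in% names(data))) {
    rlang::abort(sprintf("`data` must contain columns `%s` and `%s`.", time, value))
  }
  t <- as.numeric(data[[time]])
  v <- as.numeric(data[[value]])
  check_times(t, min_len = min_len)
  if (any(!is.finite(v))) {
    rlang::abort("Series values must all be finite.")
  }
  list(time = t, value = v)
}
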