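#' Read an RR-interval record from a plain-text file
#'
#' One interval per line; blank lines and lines starting with `#` are
#' ignored. Intervals may be in milliseconds or seconds; `unit = "auto"`
#' infers ms when the median value exceeds 10 (no plausible RR interval is
#' 10 s, and none is below 10 ms).
#'
#' @param path Path to the file.
#' @param unit `"auto"` (default), `"ms"`, or `"s"`.
#' @return A tibble of class `rr_record` with column `interval` (s) and
#'   attributes `unit_in` (unit found in the file) and `source` (the path).
#' @export
read_rr <- function(path, unit = c("auto", "ms", "s")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) rlang::abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  vals <- suppressWarnings(as.numeric(trimws(lines[keep])))
  if (any(is.na(vals))) {
    bad <- idx[which(is.na(vals))[1]]
    rlang::abort(sprintf("Non-numeric RR interval on line %d of %s: '%s'",
                         bad, path, trimws(lines[bad])))
  }
  if (length(vals) == 0) rlang::abort(sprintf("No intervals found in %s", path))
  if (unit == "auto") {
    unit <- if (stats::median(vals) > 10) "ms" else "s"
  }
  sec <- if (unit == "ms") vals / 1000 else vals
  nonpos <- which(sec <= 0)
  if (length(nonpos) > 0) {
    rlang::abort(sprintf(
      "Non-positive RR interval on line %d of %s", idx[nonpos[1]], path
    ))
  }
  out <- tibble::tibble(interval = sec)
  class(out) <- c("rr_record", class(out))
  attr(out, "unit_in") <- unit
  attr(out, "source") <- path
  out
}

#' Write RR intervals to a plain-text file
#'
#' @param rr Numeric vector of RR intervals in seconds, or an `rr_record`.
#' @param path Output file path.
#' @param unit Output unit, `"s"` (default) or `"ms"`.
#' @param digits Significant digits written (default 12, round-trip safe).
#' @return `path`, invisibly.
#' @export
write_rr <- function(rr, path, unit = c("s", "ms"), digits = 12) {
  unit <- match.arg(unit)
  if (is.data.frame(rr)) rr <- rr$interval
  vals <- if (unit == "ms") rr * 1000 else rr
  writeLines(formatC(vals, format = "g", digits = digits), path)
  invisible(path)
}

#' Run the command-line pipeline
#'
#' Backend of the `sgp-hrv` command-line tool (see `inst/cli/sgp-hrv`).
#' Subcommands:
#' \describe{
#'   \item{filter}{`--in <rr.txt> --lo <Hz> --hi <Hz> --out <dir>`
#'     (optional `--unit ms|s|auto`, `--oversample`): band-pass the record
#'     and write `filtered.csv` (time_s, vt0, vt1, vt2, vt3),
#'     `periodogram.csv` (frequency_hz, power of vt3) and `summary.txt`
#'     (key=value lines with band powers, sigma2 values, cut-offs and the
#'     representative sampling frequency).}
#'   \item{synth}{`--out <file> [--seed <int>] [--duration <s>]`: generate
#'     a synthetic tachogram and write its RR intervals as text.}
#'   \item{calibrate}{`--cutoff <wc>` or `--cutoff-hz <Hz> --fs <Hz>`:
#'     print the regularization weight for a cut-off.}
#'   \item{validate-table1}{`[--reps <int>] [--samples <int>]
#'     [--seed <int>]`: run the bandwidth Monte Carlo at normalized
#'     cut-offs 0.05, 0.1, 0.2, 0.3 and print the estimated -3 dB points.}
#' }
#'
#' @param args Character vector of command-line arguments (subcommand
#'   first), e.g. `c("filter", "--in", "rr.txt", ...)`.
#' @return Integer exit code (0 on success), invisibly. Errors print a
#'   message and return a nonzero code rather than aborting.
#' @export
run_pipeline_cli <- function(args) {
  code <- tryCatch({
    if (length(args) == 0) {
      stop("Usage: sgp-hrv <filter|synth|calibrate|validate-table1> [options]",
           call. = FALSE)
    }
    cmd <- args[1]
    opts <- parse_cli_flags(args[-1])
    switch(cmd,
      "filter" = cli_filter(opts),
      "synth" = cli_synth(opts),
      "calibrate" = cli_calibrate(opts),
      "validate-table1" = cli_validate_table1(opts),
      stop(sprintf("Unknown subcommand '%s'", cmd), call. = FALSE)
    )
    0L
  }, error = function(e) {
    message("sgp-hrv error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}

# --flag value pairs -> named list (flags without values become TRUE)
parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop(sprintf("Unexpected argument '%s'", a), call. = FALSE)
    key <- substring(a, 3)
    if (i < length(args) && !startsWith(args[i + 1], "--")) {
      opts[[key]] <- args[i + 1]
      i <- i + 2
    } else {
      opts[[key]] <- TRUE
      i <- i + 1
    }
  }
  opts
}

need_opt <- function(opts, key) {
  if (is.null(opts[[key]])) stop(sprintf("Missing required flag --%s", key), call. = FALSE)
  opts[[key]]
}

cli_filter <- function(opts) {
  path <- need_opt(opts, "in")
  lo <- as.numeric(need_opt(opts, "lo"))
  hi <- as.numeric(need_opt(opts, "hi"))
  out_dir <- need_opt(opts, "out")
  unit <- if (is.null(opts$unit)) "auto" else opts$unit
  oversample <- if (is.null(opts$oversample)) 4 else as.numeric(opts$oversample)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  rr <- read_rr(path, unit = unit)
  tg <- tachogram_from_rr(rr$interval)
  bp <- sgp_bandpass(tg, f_lo = lo, f_hi = hi)
  pg <- lsp(tibble::tibble(time = bp$time, value = bp$vt3),
            oversample = oversample)
  bands <- hrv_band_powers(pg)

  utils::write.csv(
    data.frame(time_s = bp$time, vt0 = bp$vt0, vt1 = bp$vt1,
               vt2 = bp$vt2, vt3 = bp$vt3),
    file.path(out_dir, "filtered.csv"), row.names = FALSE, quote = FALSE
  )
  write_periodogram_csv(pg, file.path(out_dir, "periodogram.csv"))

  g <- glance(bp)
  kv <- c(
    sprintf("input=%s", path),
    sprintf("n_beats=%d", g$n),
    sprintf("f_lo_hz=%.10g", g$f_lo),
    sprintf("f_hi_hz=%.10g", g$f_hi),
    sprintf("sigma2_lo=%.10g", g$sigma2_lo),
    sprintf("sigma2_hi=%.10g", g$sigma2_hi),
    sprintf("representative_fs_hz=%.10g", g$fs_rep),
    sprintf("var_vt2=%.10g", g$var_vt2),
    sprintf("var_vt3=%.10g", g$var_vt3),
    sprintf("power_%s=%.10g", tolower(bands$band), bands$power)
  )
  writeLines(kv, file.path(out_dir, "summary.txt"))
  message(sprintf("Wrote filtered.csv, periodogram.csv, summary.txt to %s", out_dir))
}

cli_synth <- function(opts) {
  out <- need_opt(opts, "out")
  seed <- if (is.null(opts$seed)) NULL else as.integer(opts$seed)
  duration <- if (is.null(opts$duration)) 30 else as.numeric(opts$duration)
  tg <- synth_hrv(duration = duration, seed = seed)
  write_rr(tg$value, out)
  message(sprintf("Wrote %d synthetic RR intervals to %s", nrow(tg), out))
}

cli_calibrate <- function(opts) {
  if (!is.null(opts$cutoff)) {
    wc <- as.numeric(opts$cutoff)
  } else {
    f <- as.numeric(need_opt(opts, "cutoff-hz"))
    fs <- as.numeric(need_opt(opts, "fs"))
    wc <- 2 * f / fs
  }
  cat(sprintf("wc=%.10g\nsigma2=%.10g\n", wc, sigma2_from_cutoff(wc)))
}

cli_validate_table1 <- function(opts) {
  reps <- if (is.null(opts$reps)) 200 else as.integer(opts$reps)
  samples <- if (is.null(opts$samples)) 5000 else as.integer(opts$samples)
  seed <- if (is.null(opts$seed)) 1L else as.integer(opts$seed)
  wcs <- c(0.05, 0.1, 0.2, 0.3)
  cat("nominal_cutoff\testimated_cutoff\n")
  for (w in wcs) {
    est <- monte_carlo_cutoff(w, n_samples = samples, n_reps = reps,
                              seed = seed)
    cat(sprintf("%.2f\t%.4f\n", w, est))
  }
}
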