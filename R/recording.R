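#' Construct a photometric time-contrast recording
#'
#' A `tc_recording` holds one photometric time series (raw sensor intensity
#' vs time) together with its acquisition metadata: which injector and
#' injection protocol produced it, the measurement day, and the contrast
#' medium used. Time is stored explicitly per sample rather than
#' reconstructed from the nominal sampling rate, because real loggers
#' jitter; the constructor flags recordings whose median sampling interval
#' departs from the nominal rate by more than 10%.
#'
#' @param recording_id Opaque identifier string.
#' @param time_s Numeric vector of sample times in seconds, starting at 0,
#'   strictly increasing.
#' @param signal Numeric vector of sensor intensities (arbitrary units),
#'   same length as `time_s`.
#' @param sampling_hz Nominal sampling rate in Hz (default 12.2).
#' @param injector_id,protocol_id Identifier strings linking the recording
#'   to a [study_design()].
#' @param day Integer replicate index (measurement day).
#' @param cm_type Contrast medium, `"Gadoterate"` or `"Gadoteridol"`.
#' @return An object of class `tc_recording`: a list with the fields above
#'   plus `rate_ok` (logical; `FALSE` when the observed sampling interval is
#'   inconsistent with `sampling_hz`).
#' @seealso [read_recording()], [write_recording()]
#' @export
tc_recording <- function(recording_id, time_s, signal, sampling_hz = 12.2,
                         injector_id = NA_character_, protocol_id = NA_character_,
                         day = 1L, cm_type = c("Gadoterate", "Gadoteridol")) {
  cm_type <- match.arg(cm_type)
  time_s <- as.numeric(time_s)
  signal <- as.numeric(signal)
  if (length(time_s) != length(signal)) {
    stop("time_s and signal must have the same length (", length(time_s),
         " vs ", length(signal), ")")
  }
  if (length(time_s) < 2L) {
    stop("a recording needs at least 2 samples, got ", length(time_s))
  }
  if (anyNA(time_s) || anyNA(signal)) stop("time_s and signal must be free of NA")
  if (any(diff(time_s) <= 0)) stop("time_s must be strictly increasing")
  if (!is.numeric(sampling_hz) || sampling_hz <= 0) stop("sampling_hz must be > 0")
  dt_med <- median(diff(time_s))
  rate_ok <- abs(dt_med - 1 / sampling_hz) <= 0.1 / sampling_hz
  structure(
    list(recording_id = as.character(recording_id),
         time_s = time_s, signal = signal,
         sampling_hz = sampling_hz,
         injector_id = as.character(injector_id),
         protocol_id = as.character(protocol_id),
         day = as.integer(day), cm_type = cm_type,
         rate_ok = rate_ok),
    class = "tc_recording")
}

#' @export
print.tc_recording <- function(x, ...) {
  cat("<tc_recording> ", x$recording_id, "\n", sep = "")
  cat("  ", length(x$time_s), " samples over ",
      format(round(max(x$time_s), 2)), " s @ ", x$sampling_hz, " Hz",
      if (!x$rate_ok) "  [sampling-rate mismatch]", "\n", sep = "")
  cat("  injector ", x$injector_id, ", protocol ", x$protocol_id,
      ", day ", x$day, ", ", x$cm_type, "\n", sep = "")
  invisible(x)
}

#' Read a photometric recording from CSV
#'
#' Recordings are two-column delimited text files (`time_s`, `signal`),
#' comma-separated with `.` decimal marks; a single header line is
#' auto-detected and skipped. Acquisition metadata (injector, protocol, day,
#' contrast medium) is not stored in the CSV and must be supplied via
#' `metadata`.
#'
#' @param path Path to a CSV file.
#' @param metadata Named list with any of `recording_id`, `injector_id`,
#'   `protocol_id`, `day`, `cm_type`, `sampling_hz`.
#' @return A [tc_recording()].
#' @export
read_recording <- function(path, metadata = list()) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty recording file: ", path)
  first_fields <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  has_header <- anyNA(suppressWarnings(as.numeric(first_fields)))
  data_lines <- if (has_header) lines[-1L] else lines
  line_no <- seq_along(lines)[if (has_header) -1L else TRUE]
  parts <- strsplit(data_lines, ",", fixed = TRUE)
  bad_cols <- which(lengths(parts) < 2L)
  if (length(bad_cols)) {
    stop("line ", line_no[bad_cols[1L]], " of ", path,
         " does not have 2 comma-separated columns")
  }
  tvals <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  svals <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(is.na(tvals) | is.na(svals))
  if (length(bad)) {
    stop("non-numeric value on line ", line_no[bad[1L]], " of ", path)
  }
  md <- function(key, default) if (!is.null(metadata[[key]])) metadata[[key]] else default
  tc_recording(
    recording_id = md("recording_id", sub("\\.[^.]*$", "", basename(path))),
    time_s = tvals, signal = svals,
    sampling_hz = md("sampling_hz", 12.2),
    injector_id = md("injector_id", NA_character_),
    protocol_id = md("protocol_id", NA_character_),
    day = md("day", 1L),
    cm_type = md("cm_type", "Gadoterate"))
}

#' Write a recording to CSV
#'
#' Inverse of [read_recording()]: writes a `time_s,signal` CSV with header.
#' Values are written with full double precision (17 significant digits) so
#' a read/write round trip reproduces the samples exactly.
#'
#' @param rec A [tc_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "tc_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_s,signal", con)
  writeLines(paste(sprintf("%.17g", rec$time_s),
                   sprintf("%.17g", rec$signal), sep = ","), con)
  invisible(path)
}
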