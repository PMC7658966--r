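#' Estimate the pre-injection baseline
#'
#' The 10 s injection delay at the start of every recording provides a
#' window of dye-free samples. The baseline is their mean and standard
#' deviation; downstream validity rules ("return to within two baseline
#' standard deviations") are expressed relative to it.
#'
#' @param rec A [tc_recording()].
#' @param window_s Length of the baseline window in seconds, counted from
#'   t = 0 (default 10, the injection delay).
#' @return An object of class `baseline_estimate` with fields `mean`, `sd`,
#'   `window` (c(t_start, t_end)) and `n`.
#' @export
estimate_baseline <- function(rec, window_s = 10) {
  stopifnot(inherits(rec, "tc_recording"))
  if (window_s < 1) stop("baseline window must be at least 1 s")
  if (max(rec$time_s) <= window_s) {
    stop("recording (", round(max(rec$time_s), 2),
         " s) does not extend beyond the baseline window (", window_s, " s)")
  }
  idx <- rec$time_s < window_s
  if (sum(idx) < 10L) {
    stop("fewer than 10 samples in the baseline window (got ", sum(idx), ")")
  }
  x <- rec$signal[idx]
  structure(
    list(mean = mean(x), sd = sd(x),
         window = c(0, window_s), n = sum(idx)),
    class = "baseline_estimate")
}

#' Convert raw sensor intensity to a concentration-proportional deflection
#'
#' The photometric sensor measures transmitted light; dye in the contrast
#' bolus attenuates it, so raw intensity dips during the bolus. The
#' deflection is defined positive-up so the TC-curve has the boxcar
#' orientation of an ideal bolus:
#'
#' * `beer_lambert` (default): `-log(signal / baseline_mean)` — the
#'   absorbance, exactly proportional to dye concentration for a photometric
#'   cell;
#' * `linear`: `(baseline_mean - signal) / baseline_mean` — the fractional
#'   intensity dip, a small-absorbance approximation.
#'
#' No clipping is applied: baseline-window deflections keep their symmetric
#' noise around zero (clipping at zero would bias the baseline positive and
#' break the return-to-baseline rule).
#'
#' @param rec A [tc_recording()].
#' @param baseline A `baseline_estimate` from [estimate_baseline()].
#' @param mode `"beer_lambert"` or `"linear"`.
#' @return An object of class `clean_curve`: fields `recording_id`,
#'   `time_s`, `deflection`, `baseline`, `mode`, `noise_sd` (baseline noise
#'   propagated to deflection units), `valid` (`NA` until
#'   [check_validity()] runs) and `validity_notes`.
#' @export
to_deflection <- function(rec, baseline = estimate_baseline(rec),
                          mode = c("beer_lambert", "linear")) {
  stopifnot(inherits(rec, "tc_recording"), inherits(baseline, "baseline_estimate"))
  mode <- match.arg(mode)
  if (mode == "beer_lambert") {
    if (baseline$mean <= 0) stop("beer_lambert mode requires a positive baseline mean")
    bad <- which(rec$signal <= 0)
    if (length(bad)) {
      stop("nonpositive signal at sample ", bad[1L],
           " cannot be log-transformed (beer_lambert mode)")
    }
    defl <- -log(rec$signal / baseline$mean)
  } else {
    defl <- (baseline$mean - rec$signal) / baseline$mean
  }
  # delta method: sd of -log(I/I0) and of (I0-I)/I0 are both sd(I)/I0 near baseline
  structure(
    list(recording_id = rec$recording_id,
         time_s = rec$time_s, deflection = defl,
         baseline = baseline, mode = mode,
         noise_sd = baseline$sd / baseline$mean,
         valid = NA, validity_notes = character(0)),
    class = "clean_curve")
}

#' Check recording validity
#'
#' Applies the bench acceptance rules to a deflection curve:
#'
#' * return to baseline: the mean deflection over the final `tail_s`
#'   seconds must lie within `k_sd` baseline standard deviations (in
#'   deflection units) of zero, otherwise the curve is invalid with note
#'   `"no_return_to_baseline"`;
#' * baseline stability: if the deflection sd inside the baseline window
#'   exceeds `stable_frac` of the peak deflection, the note
#'   `"unstable_baseline"` is added (informational; the curve stays valid).
#'
#' The function always returns an annotated curve and is idempotent.
#'
#' @param curve A `clean_curve` from [to_deflection()].
#' @param k_sd Allowed tail deviation in baseline standard deviations
#'   (default 2).
#' @param tail_s Length of the terminal window tested in seconds (default 2).
#' @param stable_frac Baseline-noise fraction of peak deflection above which
#'   the baseline is flagged unstable (default 0.05).
#' @return The curve with `valid` and `validity_notes` filled in.
#' @export
check_validity <- function(curve, k_sd = 2, tail_s = 2, stable_frac = 0.05) {
  stopifnot(inherits(curve, "clean_curve"))
  notes <- character(0)
  t_end <- max(curve$time_s)
  tail_idx <- curve$time_s >= t_end - tail_s
  tail_mean <- mean(curve$deflection[tail_idx])
  valid <- abs(tail_mean) <= k_sd * curve$noise_sd
  if (!valid) notes <- c(notes, "no_return_to_baseline")
  base_idx <- curve$time_s >= curve$baseline$window[1L] &
    curve$time_s < curve$baseline$window[2L]
  base_sd <- sd(curve$deflection[base_idx])
  peak <- max(curve$deflection)
  if (peak > 0 && base_sd > stable_frac * peak) {
    notes <- c(notes, "unstable_baseline")
  }
  curve$valid <- valid
  curve$validity_notes <- notes
  curve
}

#' @export
print.clean_curve <- function(x, ...) {
  cat("<clean_curve> ", x$recording_id, " (", x$mode, ")\n", sep = "")
  cat("  ", length(x$time_s), " samples, peak deflection ",
      format(round(max(x$deflection), 4)), "\n", sep = "")
  if (!is.na(x$valid)) {
    cat("  valid: ", x$valid,
        if (length(x$validity_notes)) paste0("  [", paste(x$validity_notes, collapse = ", "), "]"),
        "\n", sep = "")
  }
  invisible(x)
}
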