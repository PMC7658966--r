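#' Fit a boxcar function to a TC-curve by exhaustive least squares
#'
#' The ideal contrast bolus is a boxcar: a constant plateau between two
#' vertical flanks, at baseline level elsewhere. The fit places the two
#' discontinuities on the sample grid and finds the pair of changepoint
#' indices `i_on < i_off` (plateau covers samples `i_on .. i_off - 1`) that
#' globally minimizes the residual sum of squares, with the plateau and
#' baseline levels given in closed form as the conditional means inside and
#' outside the plateau. Only fits with `plateau_level >= baseline_level` are
#' admissible (a bolus is a positive deflection). Ties are broken by smaller
#' SSE, then shorter plateau duration, then earlier onset.
#'
#' The search is an exhaustive scan over all O(n^2) index pairs with O(1)
#' evaluation per pair via prefix sums; recordings sampled at 12.2 Hz are
#' short enough that no heuristic is needed, and the global optimum is
#' trivially checkable against a brute-force scan.
#'
#' A constant curve has no information about changepoints: it yields a
#' degenerate fit (one-sample plateau at the first sample, equal levels)
#' flagged with `degenerate = TRUE` rather than an error.
#'
#' @param curve A `clean_curve` from [to_deflection()], or any object with
#'   numeric fields `time_s` and `deflection`.
#' @return An object of class `boxcar_fit`: `t_on`, `t_off` (seconds, on
#'   sample boundaries), `i_on`, `i_off` (1-based indices), `baseline_level`,
#'   `plateau_level`, `sse`, `duration` (`t_off - t_on`), `degenerate`, `n`.
#' @export
fit_boxcar <- function(curve) {
  x <- curve$deflection
  t <- curve$time_s
  n <- length(x)
  if (n < 4L) stop("boxcar fitting needs at least 4 samples, got ", n)
  if (length(t) != n) stop("time and deflection length mismatch")

  if (max(x) == min(x)) {
    # constant curve: no changepoint information
    return(structure(
      list(t_on = t[1L], t_off = t[2L], i_on = 1L, i_off = 2L,
           baseline_level = x[1L], plateau_level = x[1L],
           sse = 0, duration = t[2L] - t[1L], degenerate = TRUE, n = n),
      class = "boxcar_fit"))
  }

  S <- c(0, cumsum(x))            # S[i+1] = sum of x[1..i]
  tot <- S[n + 1L]
  tot2 <- sum(x^2)

  best <- NULL
  # admissible pairs: 1 <= a < b <= n, plateau = a..(b-1), outside nonempty
  # chunked over onset index to bound memory on long recordings
  a_all <- seq_len(n - 1L)
  chunk <- max(1L, floor(2e6 / n))
  for (a0 in seq(1L, n - 1L, by = chunk)) {
    a_idx <- a_all[a_all >= a0 & a_all < a0 + chunk]
    reps <- n - a_idx                       # number of b values per a
    a <- rep.int(a_idx, reps)
    b <- sequence(reps, from = a_idx + 1L)  # b runs a+1 .. n
    m <- b - a
    sum_in <- S[b] - S[a]
    mean_in <- sum_in / m
    m_out <- n - m
    sum_out <- tot - sum_in
    mean_out <- sum_out / m_out
    ok <- mean_in >= mean_out
    if (!any(ok)) next
    sse <- tot2 - sum_in[ok]^2 / m[ok] - sum_out[ok]^2 / m_out[ok]
    a <- a[ok]; b <- b[ok]; m <- m[ok]
    mean_in <- mean_in[ok]; mean_out <- mean_out[ok]
    # numerical floor: SSE is >= 0 up to rounding
    sse[sse < 0] <- 0
    dur <- t[b] - t[a]
    cand <- order(sse, dur, a)[1L]
    rec <- list(a = a[cand], b = b[cand], sse = sse[cand], dur = dur[cand],
                mean_in = mean_in[cand], mean_out = mean_out[cand])
    if (is.null(best) ||
        rec$sse < best$sse - 1e-12 * max(1, best$sse) ||
        (abs(rec$sse - best$sse) <= 1e-12 * max(1, best$sse) &&
         (rec$dur < best$dur || (rec$dur == best$dur && rec$a < best$a)))) {
      best <- rec
    }
  }
  if (is.null(best)) stop("no admissible boxcar fit found")  # unreachable for nonconstant x

  structure(
    list(t_on = t[best$a], t_off = t[best$b],
         i_on = best$a, i_off = best$b,
         baseline_level = best$mean_out, plateau_level = best$mean_in,
         sse = best$sse, duration = t[best$b] - t[best$a],
         degenerate = best$mean_in == best$mean_out, n = n),
    class = "boxcar_fit")
}

#' @export
print.boxcar_fit <- function(x, ...) {
  cat("<boxcar_fit> plateau [", format(round(x$t_on, 3)), ", ",
      format(round(x$t_off, 3)), ") s (", format(round(x$duration, 3)),
      " s), levels ", format(round(x$baseline_level, 4)), " / ",
      format(round(x$plateau_level, 4)), ", sse ",
      format(signif(x$sse, 4)),
      if (x$degenerate) "  [degenerate]", "\n", sep = "")
  invisible(x)
}

#' Evaluate a fitted boxcar on the curve's sample grid
#'
#' @param fit A [fit_boxcar()] result.
#' @return Numeric vector: `plateau_level` for samples `i_on .. i_off - 1`,
#'   `baseline_level` elsewhere.
#' @export
boxcar_series <- function(fit) {
  stopifnot(inherits(fit, "boxcar_fit"))
  y <- rep.int(fit$baseline_level, fit$n)
  y[fit$i_on:(fit$i_off - 1L)] <- fit$plateau_level
  y
}

#' Correlation with the fitted boxcar function (cBCF)
#'
#' The first quality criterion: the Pearson correlation coefficient between
#' the measured deflection and the fitted boxcar evaluated on the same
#' sample grid. A perfect boxcar-shaped bolus gives cBCF = 1; dispersion,
#' flow ripple and noise pull it down. Undefined (NA) when either series has
#' zero variance, e.g. for a degenerate fit.
#'
#' @param curve The `clean_curve` the fit was computed on.
#' @param fit The corresponding [fit_boxcar()] result.
#' @return Pearson correlation in `[-1, 1]`, or `NA` if degenerate.
#' @export
compute_cbcf <- function(curve, fit) {
  stopifnot(inherits(fit, "boxcar_fit"))
  x <- curve$deflection
  if (length(x) != fit$n) stop("fit does not correspond to this curve (length mismatch)")
  y <- boxcar_series(fit)
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Deviation from the expected bolus injection time (dBIT)
#'
#' The second quality criterion: the effective injection time is the length
#' of the fitted plateau phase; dBIT is its difference to the expected
#' (programmed) time `volume / flow`, in seconds. The signed value keeps the
#' direction (positive = bolus longer than programmed); the absolute value
#' is used for ranking and testing, smaller being better.
#'
#' @param fit A non-degenerate [fit_boxcar()] result.
#' @param protocol The [injection_protocol()] of the recording.
#' @return List with `dbit_signed` and `dbit_abs` (seconds).
#' @export
compute_dbit <- function(fit, protocol) {
  stopifnot(inherits(fit, "boxcar_fit"))
  if (fit$degenerate) stop("dBIT is undefined for a degenerate boxcar fit")
  d <- fit$duration - expected_injection_time(protocol)
  list(dbit_signed = d, dbit_abs = abs(d))
}

#' Score one recording: boxcar fit, cBCF and dBIT
#'
#' Composes the full per-recording analysis: baseline estimation,
#' deflection conversion, validity check, boxcar fit, cBCF and dBIT.
#' Invalid or degenerate recordings yield `valid = FALSE` and are excluded
#' from group statistics downstream.
#'
#' @param rec A [tc_recording()].
#' @param protocol The matching [injection_protocol()].
#' @param mode Deflection mode passed to [to_deflection()].
#' @param window_s Baseline window passed to [estimate_baseline()];
#'   defaults to the protocol's injection delay.
#' @param ... Further arguments passed to [check_validity()].
#' @return An object of class `quality_result`: `recording_id`, `cbcf`,
#'   `dbit_signed`, `dbit_abs`, `fit`, `curve`, `expected_time_s`, `valid`,
#'   `notes`.
#' @export
score_recording <- function(rec, protocol, mode = "beer_lambert",
                            window_s = protocol$injection_delay_s, ...) {
  stopifnot(inherits(rec, "tc_recording"), inherits(protocol, "injection_protocol"))
  baseline <- estimate_baseline(rec, window_s = window_s)
  curve <- check_validity(to_deflection(rec, baseline, mode = mode), ...)
  fit <- fit_boxcar(curve)
  cbcf <- compute_cbcf(curve, fit)
  if (fit$degenerate || is.na(cbcf)) {
    dbit <- list(dbit_signed = NA_real_, dbit_abs = NA_real_)
    valid <- FALSE
    notes <- c(curve$validity_notes, "degenerate_fit")
  } else {
    dbit <- compute_dbit(fit, protocol)
    valid <- isTRUE(curve$valid)
    notes <- curve$validity_notes
  }
  structure(
    list(recording_id = rec$recording_id,
         cbcf = cbcf,
         dbit_signed = dbit$dbit_signed, dbit_abs = dbit$dbit_abs,
         fit = fit, curve = curve,
         expected_time_s = expected_injection_time(protocol),
         valid = valid, notes = notes),
    class = "quality_result")
}

#' @export
print.quality_result <- function(x, ...) {
  cat("<quality_result> ", x$recording_id, ": cBCF ",
      format(round(x$cbcf, 4)), ", dBIT ",
      format(round(x$dbit_signed, 3)), " s (expected ",
      format(round(x$expected_time_s, 2)), " s), valid ", x$valid, "\n", sep = "")
  invisible(x)
}

#' Score a batch of recordings against a study design
#'
#' Applies [score_recording()] to each recording, looking up its protocol
#' and injector in the design, and returns the flat quality table that the
#' statistics functions consume.
#'
#' @param recordings List of [tc_recording()] objects whose `protocol_id`
#'   and `injector_id` appear in `design`.
#' @param design The [study_design()].
#' @param ... Passed to [score_recording()].
#' @return A data.frame with one row per recording: `recording_id`,
#'   `injector_id`, `pump_type`, `line_volume_ml`, `max_pressure`,
#'   `line_config`, `protocol_id`, `group`, `cm_type`, `cm_volume_ml`,
#'   `flow_rate_ml_s`, `day`, `cbcf`, `dbit_signed`, `dbit_abs`, `valid`,
#'   `notes`. The list of full `quality_result` objects is attached as
#'   attribute `"results"`.
#' @export
score_study <- function(recordings, design, ...) {
  stopifnot(inherits(design, "study_design"))
  results <- lapply(recordings, function(rec) {
    protocol <- design$protocols[[rec$protocol_id]]
    if (is.null(protocol)) {
      stop("recording ", rec$recording_id, " references unknown protocol ",
           rec$protocol_id)
    }
    score_recording(rec, protocol, ...)
  })
  rows <- lapply(seq_along(recordings), function(i) {
    rec <- recordings[[i]]; res <- results[[i]]
    inj <- design$injectors[[rec$injector_id]]
    if (is.null(inj)) {
      stop("recording ", rec$recording_id, " references unknown injector ",
           rec$injector_id)
    }
    prot <- design$protocols[[rec$protocol_id]]
    data.frame(recording_id = rec$recording_id,
               injector_id = inj$injector_id, pump_type = inj$pump_type,
               line_volume_ml = inj$line_volume_ml,
               max_pressure = inj$max_pressure, line_config = inj$line_config,
               protocol_id = prot$protocol_id, group = prot$group,
               cm_type = prot$cm_type, cm_volume_ml = prot$cm_volume_ml,
               flow_rate_ml_s = prot$flow_rate_ml_s,
               day = rec$day,
               cbcf = res$cbcf, dbit_signed = res$dbit_signed,
               dbit_abs = res$dbit_abs, valid = res$valid,
               notes = paste(res$notes, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}
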