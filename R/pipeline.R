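#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> preprocess -> boxcar fit -> score ->
#' statistics -> report. Writes into `out_dir`:
#'
#' * `quality_results.csv` — one row per recording (the [score_study()]
#'   table);
#' * `rank_cbcf_<group>.csv`, `rank_dbit_<group>.csv` — rank-ordered
#'   median-and-range summaries per protocol group;
#' * `kw_tests.csv` — Kruskal-Wallis tests across injectors per metric and
#'   group;
#' * `dtk_<metric>_<group>.csv` — pairwise Dunnett-modified Tukey-Kramer
#'   comparisons;
#' * `ancova_<metric>.csv` — Type II ANCOVA tables on the constant-flow
#'   subset (flow 5 ml/s, volume 2-15 ml), aliased interactions dropped;
#' * `odds_ratio.json` — the contrast-medium compliance odds-ratio test;
#' * `manifest.json` — seed, configuration, package version, file list.
#'
#' @param design A [study_design()] or path to a YAML design file.
#' @param out_dir Output directory (created if needed).
#' @param sim_config A [simulation_config()], or `NULL` to analyze real
#'   recordings from `recordings_dir` instead of simulating.
#' @param recordings_dir Directory of recording CSVs named
#'   `<injector>_<protocol>_d<day>.csv` (used when `sim_config` is `NULL`).
#' @param seed Master seed; overrides `sim_config$seed` when simulating.
#' @param alpha Familywise level for the DTK intervals (default 0.05).
#' @param cbcf_min,dbit_abs_max Compliance thresholds for the odds-ratio
#'   test (`NULL` = study medians).
#' @param groups Protocol groups to summarise (default all four).
#' @param figures If `TRUE`, render a per-recording curve report via
#'   [render_curve_report()] into `out_dir/figures/`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the quality table and every statistics
#'   object, plus `out_dir`.
#' @export
run_pipeline <- function(design, out_dir, sim_config = simulation_config(),
                         recordings_dir = NULL, seed = NULL, alpha = 0.05,
                         cbcf_min = NULL, dbit_abs_max = NULL,
                         groups = c("all", "vVol", "cVol", "mVol"),
                         figures = FALSE, quiet = FALSE) {
  if (is.character(design)) design <- read_study_design(design)
  stopifnot(inherits(design, "study_design"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  groups <- match.arg(groups, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  if (!is.null(sim_config)) {
    if (!is.null(seed)) sim_config$seed <- as.integer(seed)
    say("simulating ", length(design$injectors) * length(design$protocols) *
          design$days, " recordings (seed ", sim_config$seed, ") ...")
    recordings <- generate_study(design, sim_config)
  } else {
    if (is.null(recordings_dir)) {
      stop("either sim_config or recordings_dir must be given")
    }
    files <- list.files(recordings_dir, pattern = "\\.csv$", full.names = TRUE)
    if (!length(files)) stop("no recording CSVs found in ", recordings_dir)
    say("reading ", length(files), " recordings from ", recordings_dir, " ...")
    recordings <- lapply(files, function(f) {
      id <- sub("\\.csv$", "", basename(f))
      day <- sub("^.*_d(\\d+)$", "\\1", id)
      stem <- sub("_d\\d+$", "", id)
      if (day == id) {
        stop("cannot parse recording file name '", basename(f),
             "' (expected <injector>_<protocol>_d<day>.csv)")
      }
      prot_id <- NULL
      for (p in names(design$protocols)) {
        if (endsWith(stem, paste0("_", p))) { prot_id <- p; break }
      }
      if (is.null(prot_id)) {
        stop("file ", basename(f), ": no protocol in the design matches its name")
      }
      inj_id <- substr(stem, 1L, nchar(stem) - nchar(prot_id) - 1L)
      if (is.null(design$injectors[[inj_id]])) {
        stop("file ", basename(f), ": unknown injector ", inj_id)
      }
      prot <- design$protocols[[prot_id]]
      read_recording(f, metadata = list(
        recording_id = id, injector_id = inj_id, protocol_id = prot_id,
        day = as.integer(day), cm_type = prot$cm_type))
    })
  }

  say("scoring ", length(recordings), " recordings ...")
  quality <- tryCatch(score_study(recordings, design),
                      error = function(e) stop("scoring stage failed: ",
                                               conditionMessage(e)))
  write.csv(quality, file.path(out_dir, "quality_results.csv"), row.names = FALSE)

  valid <- quality[quality$valid, ]
  stats_out <- list()
  kw_rows <- list()
  group_filter <- function(d, g) {
    if (g == "all") return(d)
    keep <- switch(g,
                   vVol = d$flow_rate_ml_s == 5 & d$cm_volume_ml >= 5,
                   cVol = d$cm_volume_ml == 10,
                   mVol = d$cm_volume_ml == 2)
    d[keep, ]
  }
  for (metric in c("cbcf", "dbit_abs")) {
    for (g in groups) {
      sub <- group_filter(valid, g)
      if (nrow(sub) == 0L) {
        say("group ", g, " has no valid recordings; skipped")
        next
      }
      rs <- rank_summary(quality, metric = metric, group = g)
      write.csv(rs, file.path(out_dir, sprintf(
        "rank_%s_%s.csv", sub("_abs", "", metric), g)), row.names = FALSE)
      stats_out[[paste0("rank_", metric, "_", g)]] <- rs
      by_inj <- split(sub[[metric]], sub$injector_id)
      by_inj <- by_inj[lengths(by_inj) >= 2L]
      if (length(by_inj) >= 2L) {
        kw <- kruskal_wallis(by_inj)
        kw_rows[[paste(metric, g)]] <- data.frame(
          metric = metric, group = g, H = kw$H, df = kw$df, p = kw$p)
        dtk <- dtk_pairwise(by_inj, alpha = alpha)
        write.csv(dtk, file.path(out_dir, sprintf(
          "dtk_%s_%s.csv", sub("_abs", "", metric), g)), row.names = FALSE)
        stats_out[[paste0("kw_", metric, "_", g)]] <- kw
        stats_out[[paste0("dtk_", metric, "_", g)]] <- dtk
      }
    }
    # covariate analysis on the constant-flow subset, as in the bench study
    anc_sub <- valid[valid$flow_rate_ml_s == 5 &
                       valid$cm_volume_ml >= 2 & valid$cm_volume_ml <= 15, ]
    anc <- tryCatch(ancova(anc_sub, response = metric, drop_aliased = TRUE),
                    error = function(e) {
                      say("ancova (", metric, ") skipped: ", conditionMessage(e))
                      NULL
                    })
    if (!is.null(anc)) {
      write.csv(as.data.frame(anc), file.path(out_dir, sprintf(
        "ancova_%s.csv", sub("_abs", "", metric))), row.names = FALSE)
      stats_out[[paste0("ancova_", metric)]] <- anc
    }
  }
  if (length(kw_rows)) {
    write.csv(do.call(rbind, kw_rows), file.path(out_dir, "kw_tests.csv"),
              row.names = FALSE)
  }

  orr <- tryCatch(compliance_odds_ratio(quality, cbcf_min = cbcf_min,
                                        dbit_abs_max = dbit_abs_max),
                  error = function(e) {
                    say("odds-ratio test skipped: ", conditionMessage(e))
                    NULL
                  })
  if (!is.null(orr)) {
    jsonlite::write_json(
      list(odds_ratio = orr$odds_ratio, p = orr$p,
           corrected = orr$corrected, cbcf_min = orr$cbcf_min,
           dbit_abs_max = orr$dbit_abs_max,
           table = as.data.frame.matrix(orr$table)),
      file.path(out_dir, "odds_ratio.json"), auto_unbox = TRUE, digits = NA)
    stats_out$odds_ratio <- orr
  }

  if (figures) {
    fig_dir <- file.path(out_dir, "figures")
    dir.create(fig_dir, showWarnings = FALSE)
    results <- attr(quality, "results")
    for (i in seq_along(recordings)) {
      rec <- recordings[[i]]
      render_curve_report(results[[i]], design$protocols[[rec$protocol_id]],
                          file.path(fig_dir, paste0(rec$recording_id, ".svg")))
    }
  }

  manifest <- list(
    package = "bolusqc",
    version = as.character(utils::packageVersion("bolusqc")),
    seed = if (!is.null(sim_config)) sim_config$seed else NA,
    simulated = !is.null(sim_config),
    config = if (!is.null(sim_config)) unclass(sim_config) else NULL,
    n_recordings = length(recordings),
    n_valid = sum(quality$valid),
    alpha = alpha,
    files = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say("done: ", out_dir)
  invisible(c(list(quality = quality, out_dir = out_dir, manifest = manifest),
              stats_out))
}

#' Render a per-recording curve report
#'
#' Plots the deflection TC-curve with the fitted boxcar (red) and the
#' protocol-nominal boxcar (green: width equal to the expected injection
#' time, at the fitted plateau level, aligned at the fitted onset). For a
#' degenerate fit the overlays are omitted with a warning.
#'
#' @param result A [score_recording()] result.
#' @param protocol The recording's [injection_protocol()].
#' @param path Output file; the extension selects the device (`.svg`,
#'   `.png` or `.pdf`).
#' @return `path`, invisibly.
#' @export
render_curve_report <- function(result, protocol, path) {
  stopifnot(inherits(result, "quality_result"),
            inherits(protocol, "injection_protocol"))
  curve <- result$curve
  fit <- result$fit
  df <- data.frame(t = curve$time_s, d = curve$deflection)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = t, y = d)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "time [s]", y = "deflection [a.u.]",
      title = result$recording_id,
      subtitle = if (fit$degenerate) "degenerate fit" else
        sprintf("cBCF = %.3f, dBIT = %+.2f s (expected %.1f s)",
                result$cbcf, result$dbit_signed, result$expected_time_s)) +
    ggplot2::theme_minimal()
  if (!fit$degenerate) {
    fitted <- data.frame(t = curve$time_s, y = boxcar_series(fit))
    t_exp <- expected_injection_time(protocol)
    nominal <- data.frame(
      t = c(min(curve$time_s), fit$t_on, fit$t_on, fit$t_on + t_exp,
            fit$t_on + t_exp, max(curve$time_s)),
      y = c(fit$baseline_level, fit$baseline_level, fit$plateau_level,
            fit$plateau_level, fit$baseline_level, fit$baseline_level))
    p <- p +
      ggplot2::geom_step(data = fitted, ggplot2::aes(x = t, y = y),
                         colour = "red", linewidth = 0.4) +
      ggplot2::geom_path(data = nominal, ggplot2::aes(x = t, y = y),
                         colour = "darkgreen", linewidth = 0.4)
  } else {
    warning("degenerate fit for ", result$recording_id,
            ": rendering without overlays")
  }
  ext <- tolower(sub(".*\\.", "", path))
  dev <- switch(ext, svg = grDevices::svg, pdf = grDevices::pdf,
                png = grDevices::png, stop("unsupported figure format: ", ext))
  if (ext == "png") dev(path, width = 800, height = 500) else dev(path, width = 8, height = 5)
  print(p)
  grDevices::dev.off()
  invisible(path)
}
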