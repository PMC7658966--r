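#' Kruskal-Wallis test on named groups
#'
#' Nonparametric k-sample comparison of a quality metric across injectors
#' (or protocol groups). Thin wrapper over [stats::kruskal.test()]: the H
#' statistic is computed on mid-ranks with tie correction and the p-value
#' from the chi-squared approximation with k - 1 degrees of freedom.
#'
#' @param groups Named list of numeric vectors, one per group, each with at
#'   least 2 values.
#' @return List with `H`, `df` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stop("kruskal_wallis needs at least 2 groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  small <- which(lengths(groups) < 2L)
  if (length(small)) {
    stop("group '", names(groups)[small[1L]], "' has fewer than 2 values")
  }
  kt <- stats::kruskal.test(unlist(groups, use.names = FALSE),
                            factor(rep(names(groups), lengths(groups)),
                                   levels = names(groups)))
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Dunnett-modified Tukey-Kramer pairwise comparisons
#'
#' Pairwise mean comparisons for groups with unequal sizes and unequal
#' variances (the Dunnett T3 / "modified Tukey-Kramer" family): for each
#' pair the interval is
#' \deqn{(\bar x_i - \bar x_j) \pm \frac{q_{1-\alpha'}(k, \nu_{ij})}{\sqrt 2}
#'       \sqrt{s_i^2/n_i + s_j^2/n_j}}
#' with unpooled variances, Welch-Satterthwaite per-pair degrees of freedom
#' \eqn{\nu_{ij}}, and the studentized-range quantile taken at the
#' Bonferroni-adjusted level \eqn{\alpha' = \alpha / m} across the
#' \eqn{m = k(k-1)/2} pairs (a conservative correction). A pair is
#' significant when its interval excludes 0; flags are also reported at the
#' 0.05 / 0.01 / 0.001 levels (each Bonferroni-adjusted the same way).
#'
#' Pairs in which both groups have zero within-group variance are
#' degenerate: they are flagged and never significant.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param alpha Familywise significance level for the reported interval
#'   (default 0.05).
#' @return A data.frame with one row per pair: `group_a`, `group_b`,
#'   `estimate` (mean_a - mean_b), `lo`, `hi`, `df`, `significant`,
#'   `sig_0.05`, `sig_0.01`, `sig_0.001`, `degenerate`.
#' @export
dtk_pairwise <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("dtk_pairwise needs at least 2 groups")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  small <- which(lengths(groups) < 2L)
  if (length(small)) {
    stop("group '", names(groups)[small[1L]], "' has fewer than 2 values")
  }
  k <- length(groups)
  m <- k * (k - 1L) / 2L
  means <- vapply(groups, mean, 0)
  vars <- vapply(groups, var, 0)
  ns <- lengths(groups)
  pairs <- utils::combn(k, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    vi <- vars[i] / ns[i]; vj <- vars[j] / ns[j]
    est <- means[i] - means[j]
    se <- sqrt(vi + vj)
    degenerate <- se == 0
    if (degenerate) {
      return(data.frame(group_a = names(groups)[i], group_b = names(groups)[j],
                        estimate = est, lo = est, hi = est, df = NA_real_,
                        significant = FALSE, sig_0.05 = FALSE,
                        sig_0.01 = FALSE, sig_0.001 = FALSE,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    df <- (vi + vj)^2 / (vi^2 / (ns[i] - 1L) + vj^2 / (ns[j] - 1L))
    half <- function(a) {
      q <- suppressWarnings(qtukey(1 - a / m, nmeans = k, df = df))
      # qtukey is numerically fragile at very small df; fall back to the
      # Bonferroni t quantile (exact for k = 2, conservative otherwise)
      if (!is.finite(q)) q <- sqrt(2) * stats::qt(1 - a / (2 * m), df = df)
      q / sqrt(2) * se
    }
    h <- half(alpha)
    sig_at <- function(a) abs(est) > half(a)
    data.frame(group_a = names(groups)[i], group_b = names(groups)[j],
               estimate = est, lo = est - h, hi = est + h, df = df,
               significant = abs(est) > h,
               sig_0.05 = sig_at(0.05), sig_0.01 = sig_at(0.01),
               sig_0.001 = sig_at(0.001),
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Analysis of covariance for quality-metric confounders
#'
#' Fits a linear model of a quality metric (cBCF or |dBIT|) on the
#' technical injector covariates — pump type and contrast-medium type as
#' factors, tube-line filling volume and maximum injection power as numeric
#' covariates — with all pairwise interactions, and reports per-term F tests
#' with Type II sums of squares (via [car::Anova()]).
#'
#' With few distinct injector models the injector-level interaction columns
#' (`line_volume:max_pressure`, and possibly others) can be exactly
#' collinear with the main effects: the design is rank deficient. By
#' default this is an error naming the aliased terms; with
#' `drop_aliased = TRUE` the aliased interaction terms are removed from the
#' model (recorded in the result) and the remaining terms are tested.
#'
#' @param data A data.frame containing the response column and the columns
#'   `pump_type`, `line_volume_ml`, `max_pressure`, `cm_type` (e.g. a
#'   [score_study()] table, typically pre-filtered to valid rows and to the
#'   protocol subset of interest).
#' @param response Name of the response column, `"cbcf"` or `"dbit_abs"`.
#' @param drop_aliased Drop rank-deficient interaction terms instead of
#'   erroring (default `FALSE`).
#' @return An object of class `ancova_result`: a data.frame of terms with
#'   `sum_sq`, `df`, `F`, `p`, plus attributes `dropped` (character vector
#'   of removed terms) and `model` (the fitted `lm`).
#' @export
ancova <- function(data, response = c("cbcf", "dbit_abs"), drop_aliased = FALSE) {
  response <- match.arg(response)
  needed <- c(response, "pump_type", "line_volume_ml", "max_pressure", "cm_type")
  miss <- setdiff(needed, names(data))
  if (length(miss)) stop("data is missing columns: ", paste(miss, collapse = ", "))
  df <- data.frame(y = data[[response]],
                   pump_type = factor(data$pump_type),
                   line_volume_ml = as.numeric(data$line_volume_ml),
                   max_pressure = as.numeric(data$max_pressure),
                   cm_type = factor(data$cm_type))
  df <- df[complete.cases(df), , drop = FALSE]
  if (nrow(df) < 10L) stop("too few complete rows for ANCOVA (", nrow(df), ")")

  if (var(df$y) == 0) {
    # constant response carries no information: all F = 0 by convention
    terms <- attr(stats::terms(
      y ~ (pump_type + line_volume_ml + max_pressure + cm_type)^2), "term.labels")
    out <- data.frame(term = terms, sum_sq = 0, df = 1L, F = 0, p = 1,
                      stringsAsFactors = FALSE)
    attr(out, "dropped") <- character(0)
    class(out) <- c("ancova_result", "data.frame")
    return(out)
  }

  full <- y ~ (pump_type + line_volume_ml + max_pressure + cm_type)^2
  fit <- lm(full, data = df)
  dropped <- character(0)
  while (anyNA(coef(fit))) {
    na_coefs <- names(coef(fit))[is.na(coef(fit))]
    assign_map <- attr(stats::model.matrix(fit), "assign")
    term_labels <- attr(stats::terms(fit), "term.labels")
    aliased_terms <- unique(term_labels[
      assign_map[match(na_coefs, colnames(stats::model.matrix(fit)))]])
    if (!drop_aliased) {
      stop("rank-deficient ANCOVA design; aliased terms: ",
           paste(aliased_terms, collapse = ", "),
           " (set drop_aliased = TRUE to remove them)")
    }
    # drop highest-order aliased terms first
    ord <- vapply(strsplit(aliased_terms, ":", fixed = TRUE), length, 1L)
    drop_now <- aliased_terms[ord == max(ord)]
    dropped <- c(dropped, drop_now)
    fit <- stats::update(fit, stats::as.formula(
      paste(". ~ . -", paste(drop_now, collapse = " - "))))
  }
  an <- car::Anova(fit, type = 2)
  keep <- rownames(an) != "Residuals"
  out <- data.frame(term = rownames(an)[keep],
                    sum_sq = an[keep, "Sum Sq"],
                    df = an[keep, "Df"],
                    F = an[keep, "F value"],
                    p = an[keep, "Pr(>F)"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  attr(out, "model") <- fit
  class(out) <- c("ancova_result", "data.frame")
  out
}

#' @export
print.ancova_result <- function(x, ...) {
  cat("ANCOVA (Type II sums of squares)\n")
  tab <- as.data.frame(x)
  tab$p <- format.pval(tab$p, digits = 4, eps = 1e-4)
  print(tab, row.names = FALSE)
  dropped <- attr(x, "dropped")
  if (length(dropped)) {
    cat("dropped aliased terms:", paste(dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compliance odds ratio between contrast media
#'
#' Tests whether one contrast medium achieves better compliance with the
#' quality criteria than the other. A recording is compliant when
#' `cbcf >= cbcf_min` and `dbit_abs <= dbit_abs_max`; by default both
#' thresholds are the study-wide medians (so "compliant" means
#' better-than-typical on both criteria — the thresholds are reported with
#' the result and should always be quoted alongside it). The odds ratio is
#' the cross-product ratio of the 2x2 table (compliant vs not, Gadoterate
#' vs Gadoteridol), with the Haldane-Anscombe +0.5 correction when a cell
#' is empty; the p-value comes from Fisher's exact test on the uncorrected
#' counts.
#'
#' @param results A [score_study()] table (only `valid` rows are used).
#' @param cbcf_min Compliance threshold on cBCF (default: median over valid
#'   rows).
#' @param dbit_abs_max Compliance threshold on |dBIT| (default: median).
#' @return List with `odds_ratio`, `p`, `table` (2x2 counts), `corrected`
#'   (logical), `cbcf_min`, `dbit_abs_max`.
#' @export
compliance_odds_ratio <- function(results, cbcf_min = NULL, dbit_abs_max = NULL) {
  ok <- results[results$valid & !is.na(results$cbcf) & !is.na(results$dbit_abs), ]
  if (!all(c("Gadoterate", "Gadoteridol") %in% ok$cm_type)) {
    stop("both contrast-medium types must be present among valid recordings")
  }
  if (is.null(cbcf_min)) cbcf_min <- median(ok$cbcf)
  if (is.null(dbit_abs_max)) dbit_abs_max <- median(ok$dbit_abs)
  compliant <- ok$cbcf >= cbcf_min & ok$dbit_abs <= dbit_abs_max
  cm <- factor(ok$cm_type, levels = c("Gadoterate", "Gadoteridol"))
  tab <- table(compliant = factor(compliant, levels = c(TRUE, FALSE)), cm = cm)
  corrected <- any(tab == 0)
  t2 <- tab + if (corrected) 0.5 else 0
  or <- (t2[1L, 1L] * t2[2L, 2L]) / (t2[1L, 2L] * t2[2L, 1L])
  p <- fisher.test(tab)$p.value
  list(odds_ratio = unname(or), p = p, table = tab, corrected = corrected,
       cbcf_min = cbcf_min, dbit_abs_max = dbit_abs_max)
}

#' Rank-ordered per-injector summary
#'
#' Summarises a quality metric per injector as median and range, ordered
#' best-first: descending median for cBCF, ascending for |dBIT|.
#'
#' @param results A [score_study()] table (only `valid` rows are used).
#' @param metric `"cbcf"` or `"dbit_abs"`.
#' @param group Protocol group to restrict to (`"all"`, `"vVol"`, `"cVol"`,
#'   `"mVol"`); membership follows [in_protocol_group()] rules on volume and
#'   flow, so shared protocols count in every grid they belong to.
#' @return A data.frame ordered best-first: `rank`, `injector_id`,
#'   `pump_type`, `n`, `median`, `min`, `max`.
#' @export
rank_summary <- function(results, metric = c("cbcf", "dbit_abs"),
                         group = c("all", "vVol", "cVol", "mVol")) {
  metric <- match.arg(metric)
  group <- match.arg(group)
  ok <- results[results$valid & !is.na(results[[metric]]), ]
  if (group != "all") {
    keep <- switch(group,
                   vVol = ok$flow_rate_ml_s == 5 & ok$cm_volume_ml >= 5,
                   cVol = ok$cm_volume_ml == 10,
                   mVol = ok$cm_volume_ml == 2)
    ok <- ok[keep, ]
  }
  if (nrow(ok) == 0L) stop("no valid recordings in group '", group, "'")
  sp <- split(ok, ok$injector_id)
  rows <- lapply(sp, function(d) {
    data.frame(injector_id = d$injector_id[1L], pump_type = d$pump_type[1L],
               n = nrow(d), median = median(d[[metric]]),
               min = min(d[[metric]]), max = max(d[[metric]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(out$median, decreasing = (metric == "cbcf"))
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("rank", "injector_id", "pump_type", "n", "median", "min", "max")]
}
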