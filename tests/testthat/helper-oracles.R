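# Independent oracles used to cross-check the implementation.
# These deliberately use the slowest, most transparent formulation.

# Exhaustive brute-force boxcar scan: for every pair (a, b), a < b <= n,
# plateau = samples a..(b-1), levels = plain segment means, SSE by direct
# summation. Only pairs with mean_in >= mean_out are admissible.
brute_boxcar <- function(x) {
  n <- length(x)
  best_sse <- Inf
  best <- NULL
  for (a in seq_len(n - 1L)) {
    for (b in seq.int(a + 1L, n)) {
      inside <- x[a:(b - 1L)]
      outside <- x[-(a:(b - 1L))]
      m_in <- mean(inside)
      m_out <- mean(outside)
      if (m_in < m_out) next
      sse <- sum((inside - m_in)^2) + sum((outside - m_out)^2)
      if (sse < best_sse - 1e-12) {
        best_sse <- sse
        best <- list(a = a, b = b, sse = sse, mean_in = m_in, mean_out = m_out)
      }
    }
  }
  best
}

# Exact Kruskal-Wallis permutation p-value for small balanced designs:
# enumerate every way of assigning the pooled values to the groups and
# count how often H is at least the observed value.
kw_permutation_p <- function(groups) {
  pooled <- unlist(groups, use.names = FALSE)
  ns <- lengths(groups)
  stopifnot(length(ns) == 3L)  # enumeration written for three groups
  H_of <- function(assign1, assign2) {
    g <- integer(length(pooled))
    g[assign1] <- 1L
    g[assign2] <- 2L
    g[g == 0L] <- 3L
    unname(stats::kruskal.test(pooled, factor(g))$statistic)
  }
  obs <- unname(stats::kruskal.test(
    pooled, factor(rep(seq_along(groups), ns)))$statistic)
  idx <- seq_along(pooled)
  first <- utils::combn(idx, ns[1L], simplify = FALSE)
  count <- 0L
  total <- 0L
  for (f in first) {
    rest <- setdiff(idx, f)
    second <- utils::combn(rest, ns[2L], simplify = FALSE)
    for (s in second) {
      total <- total + 1L
      if (H_of(f, s) >= obs - 1e-9) count <- count + 1L
    }
  }
  count / total
}

# A dispersed bolus-like random curve on a uniform grid: baseline noise plus
# a smoothed plateau of random position/width/height. Used for the
# fit-vs-oracle property tests.
random_bolus_curve <- function(n, fs = 12.2) {
  t <- (seq_len(n) - 1) / fs
  x <- rnorm(n, sd = runif(1, 0.002, 0.05))
  a <- sample.int(n - 3L, 1L)
  b <- a + sample.int(n - a, 1L)
  height <- runif(1, 0.1, 2)
  prof <- numeric(n)
  prof[a:min(b, n)] <- height
  k <- sample(0:3, 1L)
  if (k > 0L) for (i in seq_len(k)) prof <- stats::filter(prof, rep(1/3, 3), sides = 2)
  prof[is.na(prof)] <- 0
  list(time_s = t, deflection = x + as.numeric(prof))
}

# Minimal clean_curve wrapper for synthetic deflection series
as_curve <- function(time_s, deflection, noise_sd = 0) {
  structure(
    list(recording_id = "synthetic", time_s = time_s, deflection = deflection,
         baseline = structure(list(mean = 1, sd = noise_sd,
                                   window = c(0, 1), n = 10),
                              class = "baseline_estimate"),
         mode = "linear", noise_sd = noise_sd,
         valid = TRUE, validity_notes = character(0)),
    class = "clean_curve")
}

# Small two-injector, two-protocol design used across tests
tiny_design <- function(days = 1L) {
  study_design(
    injectors = list(
      injector_config("psA", "PS", line_volume_ml = 6, max_pressure = 10),
      injector_config("rpB", "RP", line_volume_ml = 80, max_pressure = 4)),
    protocols = list(
      injection_protocol("p15", "Gadoterate", 15, 5, "vVol"),
      injection_protocol("m2", "Gadoteridol", 2, 5, "mVol")),
    days = days)
}

# Fast simulator settings for tests that only need the generative structure
fast_config <- function(...) {
  simulation_config(n_tanks_base = 300L, seed = 7L, ...)
}
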