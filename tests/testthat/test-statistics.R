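test_that("Kruskal-Wallis matches hand-computed and permutation values", {
  # identical groups: H = 0, p = 1
  kw <- kruskal_wallis(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(kw$H, 0)
  expect_equal(kw$p, 1)

  # untied two-group case: H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2
  # ranks 1-4 vs 5-8 give H = 32/6
  kw2 <- kruskal_wallis(list(a = 1:4, b = 10:13))
  expect_equal(kw2$H, 32 / 6, tolerance = 1e-12)
  expect_equal(kw2$p, pchisq(32 / 6, df = 1, lower.tail = FALSE))

  expect_error(kruskal_wallis(list(a = 1:3)), "at least 2 groups")
  expect_error(kruskal_wallis(list(a = 1:3, b = 2)), "'b' has fewer than 2")

  # chi-squared approximation vs exact permutation enumeration, n = 4 x 3,
  # on a rank-separated fixture: exact p = 3!/C(12;4,4,4) = 6/34650
  groups <- list(a = c(0.8, 1.2, 1.9, 2.4),
                 b = c(4.1, 4.7, 5.3, 5.9),
                 c = c(8.2, 8.9, 9.6, 10.3))
  p_perm <- kw_permutation_p(groups)
  expect_equal(p_perm, 6 / 34650)
  p_chisq <- kruskal_wallis(groups)$p
  expect_lt(abs(p_perm - p_chisq), 0.02)
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  set.seed(11)
  groups <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, -1))
  base <- kruskal_wallis(groups)
  for (f in list(function(x) exp(x), function(x) x^3, function(x) atan(x))) {
    tr <- kruskal_wallis(lapply(groups, f))
    expect_equal(tr$H, base$H, tolerance = 1e-12)
    expect_equal(tr$p, base$p, tolerance = 1e-12)
  }
})

test_that("DTK pairwise comparisons behave at the extremes", {
  set.seed(5)
  far <- list(a = rnorm(10, 0, 1), b = rnorm(10, 100, 1))
  res <- dtk_pairwise(far, alpha = 0.05)
  expect_equal(nrow(res), 1L)
  expect_true(res$significant)
  expect_true(res$sig_0.001)
  expect_true(res$lo > 0 || res$hi < 0)

  # constant equal groups: degenerate, flagged, no rejections
  const <- list(a = rep(1, 5), b = rep(1, 5), c = rep(1, 5))
  resc <- dtk_pairwise(const)
  expect_true(all(resc$degenerate))
  expect_false(any(resc$significant))

  expect_error(dtk_pairwise(list(a = 1:5), 0.05), "at least 2 groups")
  expect_error(dtk_pairwise(list(a = 1:5, b = 1:5), alpha = 1.2), "alpha")
})

test_that("DTK intervals widen monotonically as alpha decreases", {
  set.seed(23)
  groups <- list(a = rnorm(12), b = rnorm(9, 0.5, 2), c = rnorm(15, -0.3, 0.5))
  widths <- sapply(c(0.2, 0.1, 0.05, 0.01, 0.001), function(a) {
    r <- dtk_pairwise(groups, alpha = a)
    r$hi - r$lo
  })
  for (row in seq_len(nrow(widths))) {
    expect_true(all(diff(widths[row, ]) > 0))
  }
})

test_that("DTK empirical type-I error stays near nominal under the null", {
  set.seed(999)
  reps <- 1500L
  rejections <- 0L
  for (i in seq_len(reps)) {
    g <- list(a = rnorm(20), b = rnorm(20))
    if (dtk_pairwise(g, alpha = 0.05)$significant) rejections <- rejections + 1L
  }
  expect_lte(rejections / reps, 0.065)
})

test_that("ANCOVA recovers a pure pump-type effect and rejects constants", {
  set.seed(77)
  # injector-level covariates varied enough that nothing is aliased
  base <- expand.grid(pump_type = c("PS", "RP"),
                      line_volume_ml = c(5, 20, 60),
                      max_pressure = c(3, 6, 10),
                      cm_type = c("Gadoterate", "Gadoteridol"),
                      rep = 1:2, stringsAsFactors = FALSE)
  hits_main <- 0L; clean_inter <- 0L; reps <- 40L
  for (i in seq_len(reps)) {
    base$cbcf <- 0.9 - 0.05 * (base$pump_type == "RP") + rnorm(nrow(base), 0, 0.01)
    a <- ancova(base, "cbcf")
    inter <- grepl(":", a$term)
    if (a$p[a$term == "pump_type"] < 0.001) hits_main <- hits_main + 1L
    if (all(a$p[inter] > 0.05)) clean_inter <- clean_inter + 1L
  }
  expect_equal(hits_main, reps)
  expect_gte(clean_inter / reps, 0.6)

  # constant response: all F = 0 by convention
  base$cbcf <- 0.9
  a0 <- ancova(base, "cbcf")
  expect_true(all(a0$F == 0))

  # affine rescaling of the response leaves F untouched
  set.seed(78)
  base$cbcf <- 0.9 - 0.05 * (base$pump_type == "RP") + rnorm(nrow(base), 0, 0.01)
  a1 <- ancova(base, "cbcf")
  base2 <- base; base2$cbcf <- 100 * base$cbcf - 17
  a2 <- ancova(base2, "cbcf")
  expect_equal(a1$F, a2$F, tolerance = 1e-8)
})

test_that("ANCOVA errors on aliased designs unless asked to drop terms", {
  set.seed(42)
  # two injector profiles only: interactions collinear with main effects
  d <- data.frame(pump_type = rep(c("PS", "RP"), each = 20),
                  line_volume_ml = rep(c(6, 90), each = 20),
                  max_pressure = rep(c(10, 4), each = 20),
                  cm_type = rep(c("Gadoterate", "Gadoteridol"), 20),
                  cbcf = rnorm(40, 0.9, 0.02))
  expect_error(ancova(d, "cbcf"), "aliased")
  a <- ancova(d, "cbcf", drop_aliased = TRUE)
  expect_gt(length(attr(a, "dropped")), 0L)
  expect_true("pump_type" %in% a$term)
})

test_that("compliance odds ratio matches the closed form", {
  mk <- function(counts) {
    # counts: [[compliant G, compliant Gd], [noncompliant G, noncompliant Gd]]
    cm <- c(rep("Gadoterate", counts[1, 1]), rep("Gadoteridol", counts[1, 2]),
            rep("Gadoterate", counts[2, 1]), rep("Gadoteridol", counts[2, 2]))
    comp <- rep(c(TRUE, FALSE), c(sum(counts[1, ]), sum(counts[2, ])))
    data.frame(cm_type = cm,
               cbcf = ifelse(comp, 0.99, 0.5),
               dbit_abs = ifelse(comp, 0.01, 5),
               valid = TRUE)
  }
  res <- compliance_odds_ratio(mk(rbind(c(10, 2), c(3, 9))),
                               cbcf_min = 0.9, dbit_abs_max = 1)
  expect_equal(res$odds_ratio, 15)
  expect_equal(res$p,
               fisher.test(rbind(c(10, 2), c(3, 9)))$p.value)
  expect_false(res$corrected)

  balanced <- compliance_odds_ratio(mk(rbind(c(5, 5), c(5, 5))),
                                    cbcf_min = 0.9, dbit_abs_max = 1)
  expect_equal(balanced$odds_ratio, 1)

  zero <- compliance_odds_ratio(mk(rbind(c(10, 0), c(3, 9))),
                                cbcf_min = 0.9, dbit_abs_max = 1)
  expect_true(zero$corrected)
  expect_true(is.finite(zero$odds_ratio))

  # invariant: swapping both row and column labels leaves the OR unchanged
  flipped <- compliance_odds_ratio(mk(rbind(c(3, 9), c(10, 2))[, 2:1]),
                                   cbcf_min = 0.9, dbit_abs_max = 1)
  expect_equal(flipped$odds_ratio, 15)

  one_cm <- mk(rbind(c(4, 0), c(4, 0)))
  one_cm <- one_cm[one_cm$cm_type == "Gadoterate", ]
  expect_error(compliance_odds_ratio(one_cm), "both contrast-medium types")
})

test_that("rank summaries order injectors best-first", {
  tab <- data.frame(
    injector_id = c("a", "a", "b", "b"), pump_type = c("PS", "PS", "RP", "RP"),
    cbcf = c(0.9, 0.8, 0.7, 0.72), dbit_abs = c(0.1, 0.2, 1, 1.5),
    flow_rate_ml_s = 5, cm_volume_ml = 10, valid = TRUE)
  rs <- rank_summary(tab, "cbcf", "all")
  expect_equal(rs$injector_id, c("a", "b"))
  expect_equal(rs$median[1], 0.85)
  expect_equal(rs$min[1], 0.8)
  expect_equal(rs$max[1], 0.9)
  rs2 <- rank_summary(tab, "dbit_abs", "all")
  expect_equal(rs2$injector_id, c("a", "b"))
  expect_equal(rs2$median, c(0.15, 1.25))
})
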