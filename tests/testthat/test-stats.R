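# Statistical procedures on per-frame datapoints.

# Independent closed-form oracles, coded directly from the textbook formulas.
oracle_prop_z <- function(x1, n1, x2, n2) {
  p <- (x1 + x2) / (n1 + n2)
  (x1 / n1 - x2 / n2) / sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
}
oracle_mean_z <- function(a, b) {
  (mean(a) - mean(b)) /
    sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
}
oracle_paired_t <- function(a, b) {
  d <- a - b
  mean(d) / (stats::sd(d) / sqrt(length(d)))
}

test_that("z and t statistics reproduce hand-computed reference values", {
  z <- two_proportion_ztest(50, 100, 90, 100)
  expect_equal(z$statistic, -6.172134, tolerance = 1e-6)
  expect_lt(z$p_raw, 1e-9)

  zm <- two_mean_ztest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(zm$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(zm$p_raw, 2.3856345403e-4, tolerance = 1e-8)

  tt <- paired_ttest(c(1, 2, 3, 4), c(2, 3, 5, 7))
  expect_equal(tt$statistic, -3.655631, tolerance = 1e-6)
  expect_equal(tt$df, 3)
})

test_that("statistics agree with independent oracles to 1e-10 on random inputs", {
  set.seed(99)
  for (i in 1:30) {
    n1 <- sample(30:200, 1)
    n2 <- sample(30:200, 1)
    x1 <- rbinom(1, n1, runif(1, 0.1, 0.9))
    x2 <- rbinom(1, n2, runif(1, 0.1, 0.9))
    z <- two_proportion_ztest(x1, n1, x2, n2)
    if (!z$degenerate) {
      expect_equal(z$statistic, oracle_prop_z(x1, n1, x2, n2),
                   tolerance = 1e-10)
    }
    a <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    expect_equal(two_mean_ztest(a, b)$statistic, oracle_mean_z(a, b),
                 tolerance = 1e-10)
    n <- sample(3:20, 1)
    v1 <- rnorm(n)
    v2 <- rnorm(n)
    tt <- paired_ttest(v1, v2)
    expect_equal(tt$statistic, oracle_paired_t(v1, v2), tolerance = 1e-10)
    # cross-check against the base-R implementations
    bt <- stats::t.test(v1, v2, paired = TRUE)
    expect_equal(tt$statistic, unname(bt$statistic), tolerance = 1e-10)
    expect_equal(tt$p_raw, bt$p.value, tolerance = 1e-10)
    pz <- stats::prop.test(c(x1, x2), c(n1, n2), correct = FALSE)
    if (!z$degenerate) {
      expect_equal(z$statistic^2, unname(pz$statistic), tolerance = 1e-8)
    }
  }
})

test_that("z-tests are symmetric, scale-invariant and null-stable", {
  z1 <- two_proportion_ztest(30, 90, 60, 120)
  z2 <- two_proportion_ztest(60, 120, 30, 90)
  expect_equal(z1$statistic, -z2$statistic)
  expect_equal(z1$p_raw, z2$p_raw)

  z0 <- two_proportion_ztest(20, 40, 30, 60) # equal proportions
  expect_equal(z0$statistic, 0)
  expect_equal(z0$p_raw, 1)

  a <- c(1.2, 3.4, 2.2, 5.5)
  b <- c(2.0, 2.5, 4.0, 1.0)
  expect_equal(two_mean_ztest(3 * a, 3 * b)$statistic,
               two_mean_ztest(a, b)$statistic, tolerance = 1e-12)
  expect_equal(two_mean_ztest(a, a)$statistic, 0)
  expect_equal(two_mean_ztest(a, a)$p_raw, 1)
})

test_that("degenerate inputs are flagged instead of silently mis-tested", {
  expect_true(two_proportion_ztest(0, 50, 0, 60)$degenerate)
  expect_true(two_proportion_ztest(50, 50, 60, 60)$degenerate)
  expect_error(two_proportion_ztest(5, 0, 1, 10), "positive")
  expect_error(two_proportion_ztest(11, 10, 1, 10), "exceed")

  expect_true(two_mean_ztest(c(1, 1, 1), c(2, 2, 2))$degenerate)
  z <- two_mean_ztest(c(1, 1), c(1, 1))
  expect_equal(c(z$statistic, z$p_raw), c(0, 1))

  t0 <- paired_ttest(c(3, 4, 5), c(3, 4, 5))
  expect_equal(c(t0$statistic, t0$p_raw), c(0, 1))
  expect_true(paired_ttest(c(2, 3, 4, 5), c(1, 2, 3, 4))$degenerate)
  expect_error(paired_ttest(1, 1), "at least two")
  expect_error(paired_ttest(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("Bonferroni correction is order-preserving, monotone and capped", {
  expect_equal(bonferroni(0.01, 4), 0.04)
  expect_equal(bonferroni(0.5, 4), 1.0)
  expect_equal(bonferroni(c(0.2, 0.01, 0.6), 1), c(0.2, 0.01, 0.6))
  p <- c(0.001, 0.04, 0.2, 0.9)
  pc <- bonferroni(p, 3)
  expect_true(all(pc >= p))
  expect_identical(order(pc), order(p))
  expect_equal(pc, pmin(1, 3 * p))
  expect_equal(bonferroni(p, length(p)), stats::p.adjust(p, "bonferroni"))
  expect_error(bonferroni(1.2, 2), "\\[0, 1\\]")
})

test_that("empirical type-I error is 5% +/- 1% under the null", {
  set.seed(2024)
  n_sim <- 10000L
  rej_mean <- 0L
  for (i in seq_len(n_sim)) {
    if (two_mean_ztest(rnorm(100), rnorm(100))$p_raw < 0.05) {
      rej_mean <- rej_mean + 1L
    }
  }
  expect_gte(rej_mean / n_sim, 0.04)
  expect_lte(rej_mean / n_sim, 0.06)

  rej_prop <- 0L
  for (i in seq_len(n_sim)) {
    x1 <- rbinom(1, 500, 0.3)
    x2 <- rbinom(1, 500, 0.3)
    p <- two_proportion_ztest(x1, 500, x2, 500)$p_raw
    if (!is.na(p) && p < 0.05) rej_prop <- rej_prop + 1L
  }
  expect_gte(rej_prop / n_sim, 0.04)
  expect_lte(rej_prop / n_sim, 0.06)
})

test_that("respirometry derivations follow the stated arithmetic", {
  ox <- derive_oxygraph(100, 20, 150, 10)
  expect_equal(ox$mito_respiration, 90)
  expect_equal(ox$atp_linked, 80)
  expect_equal(derive_oxygraph(50, 20, 80, 50)$mito_respiration, 0)
  expect_equal(derive_oxygraph(50, 50, 80, 5)$atp_linked, 0)
  expect_warning(derive_oxygraph(40, 10, 80, 55), "ROX")
  expect_error(derive_oxygraph(c(1, 2), 1, 1, 1), "equal length")
})

test_that("flux assessment detects a true inhibitor effect and rejects identity", {
  base <- simulate_frame_metrics(20, 100, 0.5, 2, seed = 8)
  inh <- simulate_frame_metrics(20, 100, 0.7, 4, seed = 9)
  fa <- assess_flux(base$dots_per_total_cells, inh$dots_per_total_cells,
                    n_comparisons = 2)
  expect_true(fa$flux_intact)
  expect_gt(fa$inhibited_mean, fa$baseline_mean)

  same <- assess_flux(base$dots_per_total_cells, base$dots_per_total_cells)
  expect_false(same$flux_intact)

  td <- tidy(fa)
  expect_true(td$flux_intact)
  expect_equal(td$p_bonferroni, fa$comparison$p_bonferroni)
})

test_that("flux stays undeclared under the null in >= 95% of replicates", {
  false_pos <- 0L
  for (r in 1:100) {
    base <- simulate_frame_metrics(20, 100, 0.5, 2, seed = 1000 + r)
    alt <- simulate_frame_metrics(20, 100, 0.5, 2, seed = 2000 + r)
    if (assess_flux(base$dots_per_total_cells,
                    alt$dots_per_total_cells)$flux_intact) {
      false_pos <- false_pos + 1L
    }
  }
  expect_lte(false_pos, 5L)
})

test_that("reports round-trip all numeric fields", {
  frames <- simulate_frame_metrics(5, 50, 0.5, 2, seed = 4)
  cmp <- two_mean_ztest(c(1, 2, 3), c(4, 5, 6), labels = c("glc", "gal"),
                        n_comparisons = 2)
  dir <- withr::local_tempdir()
  write_report(frames, cmp, dir)
  fr <- readr::read_csv(file.path(dir, "frames.csv"), show_col_types = FALSE)
  cm <- readr::read_csv(file.path(dir, "comparisons.csv"),
                        show_col_types = FALSE)
  expect_equal(fr$dots_per_total_cells, frames$dots_per_total_cells)
  expect_equal(cm$statistic, cmp$statistic)
  expect_equal(cm$p_bonferroni, cmp$p_bonferroni)
  expect_equal(nrow(cm), 1L)
  expect_true(file.exists(file.path(dir, "summary.txt")))

  write_report(frames[0, ], list(), dir)
  fr0 <- readr::read_csv(file.path(dir, "frames.csv"),
                         show_col_types = FALSE)
  expect_equal(nrow(fr0), 0L)
})

test_that("tidiers return one well-formed row per comparison", {
  z <- two_proportion_ztest(40, 80, 70, 90, labels = c("a", "b"),
                            n_comparisons = 3)
  td <- tidy(z)
  expect_equal(nrow(td), 1L)
  expect_equal(td$label1, "a")
  expect_equal(td$n_comparisons, 3L)
  expect_equal(td$p_bonferroni, min(1, 3 * td$p_raw))
  expect_identical(glance(z), td)
})
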