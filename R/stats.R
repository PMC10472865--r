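# Statistical procedures over per-frame datapoints: two-tailed Z-tests on
# proportions (pooled variance) and on per-frame means, paired t-tests for
# respirometry, Bonferroni correction, and the mitophagic-flux decision rule.

new_condition_comparison <- function(labels, kind, statistic, p_raw,
                                     n_comparisons, estimate1, estimate2,
                                     n1, n2, df = NA_real_,
                                     degenerate = FALSE) {
  structure(
    list(
      labels = labels, kind = kind, statistic = statistic, df = df,
      estimate1 = estimate1, estimate2 = estimate2, n1 = n1, n2 = n2,
      p_raw = p_raw, n_comparisons = as.integer(n_comparisons),
      p_bonferroni = if (is.na(p_raw)) NA_real_ else {
        bonferroni(p_raw, n_comparisons)
      },
      degenerate = degenerate
    ),
    class = "condition_comparison"
  )
}

#' Two-proportion Z-test (two-tailed, pooled variance)
#'
#' Normal-approximation test for a difference between two proportions, e.g.
#' the percentage of cells containing red-only dots in two conditions. Uses
#' the pooled-proportion standard error and a two-tailed p-value from the
#' standard normal.
#'
#' @param x1,n1 Successes and trials in the first sample.
#' @param x2,n2 Successes and trials in the second sample.
#' @param labels Length-2 condition labels.
#' @param n_comparisons Bonferroni family size applied to `p_bonferroni`.
#' @return A `condition_comparison`; a pooled proportion of exactly 0 or 1
#'   leaves the p-value undefined and sets `degenerate = TRUE`.
#' @export
two_proportion_ztest <- function(x1, n1, x2, n2,
                                 labels = c("group1", "group2"),
                                 n_comparisons = 1L) {
  for (v in list(x1, n1, x2, n2)) {
    stopifnot_scalar_num(v, "x1/n1/x2/n2", 0)
  }
  if (n1 <= 0 || n2 <= 0) {
    abort("`n1` and `n2` must be positive")
  }
  if (x1 > n1 || x2 > n2) {
    abort("successes cannot exceed trials")
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  if (pool <= 0 || pool >= 1) {
    return(new_condition_comparison(labels, "z_proportion", NA_real_,
                                    NA_real_, n_comparisons, p1, p2, n1, n2,
                                    degenerate = TRUE))
  }
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  new_condition_comparison(labels, "z_proportion", z, 2 * pnorm(-abs(z)),
                           n_comparisons, p1, p2, n1, n2)
}

#' Two-sample Z-test on per-frame means (two-tailed)
#'
#' Large-sample normal test for a difference between two groups of per-frame
#' averages: `z = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)`.
#'
#' @param values1,values2 Numeric vectors of per-frame values (>= 2 each).
#' @param labels Length-2 condition labels.
#' @param n_comparisons Bonferroni family size.
#' @return A `condition_comparison`. Zero variance in both groups yields
#'   `z = 0, p = 1` for equal means and a degenerate flag otherwise.
#' @export
two_mean_ztest <- function(values1, values2, labels = c("group1", "group2"),
                           n_comparisons = 1L) {
  if (length(values1) < 2L || length(values2) < 2L) {
    abort("each group needs at least two per-frame values")
  }
  if (any(!is.finite(values1)) || any(!is.finite(values2))) {
    abort("values must be finite")
  }
  n1 <- length(values1)
  n2 <- length(values2)
  m1 <- mean(values1)
  m2 <- mean(values2)
  v1 <- stats::var(values1)
  v2 <- stats::var(values2)
  if (v1 + v2 <= 0) {
    if (m1 == m2) {
      return(new_condition_comparison(labels, "z_mean", 0, 1, n_comparisons,
                                      m1, m2, n1, n2))
    }
    return(new_condition_comparison(labels, "z_mean", NA_real_, NA_real_,
                                    n_comparisons, m1, m2, n1, n2,
                                    degenerate = TRUE))
  }
  z <- (m1 - m2) / sqrt(v1 / n1 + v2 / n2)
  new_condition_comparison(labels, "z_mean", z, 2 * pnorm(-abs(z)),
                           n_comparisons, m1, m2, n1, n2)
}

#' Paired t-test (two-tailed)
#'
#' Standard paired t on the differences, `df = n - 1`; used for matched
#' respirometry measurements.
#'
#' @param values1,values2 Numeric vectors of equal length `n >= 2`.
#' @inheritParams two_mean_ztest
#' @return A `condition_comparison` with `kind = "t_paired"`. All-zero
#'   differences give `t = 0, p = 1`; zero-variance differences with a
#'   nonzero mean are flagged degenerate.
#' @export
paired_ttest <- function(values1, values2, labels = c("group1", "group2"),
                         n_comparisons = 1L) {
  if (length(values1) != length(values2)) {
    abort("paired samples must have equal length")
  }
  n <- length(values1)
  if (n < 2L) {
    abort("need at least two pairs")
  }
  d <- values1 - values2
  m1 <- mean(values1)
  m2 <- mean(values2)
  if (all(d == 0)) {
    return(new_condition_comparison(labels, "t_paired", 0, 1, n_comparisons,
                                    m1, m2, n, n, df = n - 1))
  }
  if (sd(d) == 0) {
    return(new_condition_comparison(labels, "t_paired", NA_real_, NA_real_,
                                    n_comparisons, m1, m2, n, n, df = n - 1,
                                    degenerate = TRUE))
  }
  t <- mean(d) / (sd(d) / sqrt(n))
  new_condition_comparison(labels, "t_paired", t,
                           2 * pt(-abs(t), df = n - 1), n_comparisons, m1,
                           m2, n, n, df = n - 1)
}

#' Bonferroni correction
#'
#' `p -> min(1, n_comparisons * p)`; order-preserving, never decreases a
#' p-value, caps at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param n_comparisons Family size (>= 1).
#' @return Corrected p-values.
#' @export
bonferroni <- function(p_values, n_comparisons) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  stopifnot_scalar_num(n_comparisons, "n_comparisons", 1)
  pmin(1, n_comparisons * p_values)
}

#' Derived respirometry quantities
#'
#' Computes the derived oxygen-flux quantities from high-resolution
#' respirometry states: mitochondrial respiration is basal respiration minus
#' residual (non-mitochondrial) oxygen consumption (ROX, after antimycin A),
#' and ATP-linked respiration is basal minus leak respiration (after
#' oligomycin). All fluxes in pmol O2 / s per million cells.
#'
#' @param basal,leak,ets,rox Numeric vectors of equal length: basal state,
#'   proton-leak state, maximal electron-transfer capacity, residual oxygen
#'   consumption.
#' @return Tibble with the inputs plus `mito_respiration` and `atp_linked`.
#'   `rox > basal` is allowed but triggers a warning.
#' @export
derive_oxygraph <- function(basal, leak, ets, rox) {
  lens <- lengths(list(basal, leak, ets, rox))
  if (length(unique(lens)) != 1L) {
    abort("all states must have equal length")
  }
  if (any(!is.finite(c(basal, leak, ets, rox)))) {
    abort("all states must be finite")
  }
  if (any(rox > basal)) {
    warn("ROX exceeds basal respiration; negative mitochondrial respiration")
  }
  tibble(
    basal = basal, leak = leak, ets = ets, rox = rox,
    mito_respiration = basal - rox, atp_linked = basal - leak
  )
}

#' Assess mitophagic flux from an inhibitor experiment
#'
#' Operationalizes the lysosomal-inhibitor flux readout: blocking lysosomal
#' proteolysis (e.g. pepstatin A + E64d) should accumulate red-only dots, so
#' flux is intact when the inhibited condition shows a significant increase
#' in per-frame red-only dots per cell over baseline. Uses
#' [two_mean_ztest()] with Bonferroni correction; `flux_intact` is `TRUE`
#' iff the inhibited mean exceeds baseline and the corrected p-value is
#' below `alpha`.
#'
#' @param baseline,inhibited Numeric vectors of per-frame dots-per-cell
#'   values.
#' @param alpha Significance level (default 0.05).
#' @param n_comparisons Bonferroni family size.
#' @param labels Length-2 condition labels.
#' @return An object of class `flux_assessment`.
#' @export
assess_flux <- function(baseline, inhibited, alpha = 0.05,
                        n_comparisons = 1L,
                        labels = c("baseline", "inhibited")) {
  cmp <- two_mean_ztest(baseline, inhibited, labels = labels,
                        n_comparisons = n_comparisons)
  intact <- !cmp$degenerate && !is.na(cmp$p_bonferroni) &&
    cmp$estimate2 > cmp$estimate1 && cmp$p_bonferroni < alpha
  structure(
    list(
      baseline_mean = cmp$estimate1, inhibited_mean = cmp$estimate2,
      delta = cmp$estimate2 - cmp$estimate1, comparison = cmp,
      alpha = alpha, flux_intact = intact
    ),
    class = "flux_assessment"
  )
}

#' Simulate per-frame red-only metrics without imaging
#'
#' Draws the frame-level quantification statistics directly from the
#' generative model used by the scene generator (per cell: Bernoulli
#' positivity, 1 + Poisson dots when positive), bypassing rendering and
#' detection. Used for statistical calibration at scale (null simulations,
#' power checks) where the quantity of interest is the behaviour of the
#' per-frame statistics, not the imaging chain.
#'
#' @param n_frames Number of frames.
#' @param n_cells_per_frame Cells per frame.
#' @param prob_positive Probability a cell contains any red-only dots.
#' @param mean_dots_per_positive Mean dots in a positive cell (>= 1).
#' @param seed Optional integer seed.
#' @return Tibble with one row per frame: `frame_id`, `n_cells`,
#'   `n_positive`, `pct_cells_with_red_only`, `dots_per_positive_cell`,
#'   `dots_per_total_cells`.
#' @export
simulate_frame_metrics <- function(n_frames, n_cells_per_frame,
                                   prob_positive, mean_dots_per_positive,
                                   seed = NULL) {
  with_seed(seed, {
    rows <- lapply(seq_len(n_frames), function(f) {
      pos <- rbinom(n_cells_per_frame, 1L, prob_positive)
      n_pos <- sum(pos)
      dots <- if (n_pos > 0L) {
        1L + rpois(n_pos, max(0, mean_dots_per_positive - 1))
      } else {
        integer()
      }
      tibble(
        frame_id = f, n_cells = n_cells_per_frame, n_positive = n_pos,
        pct_cells_with_red_only = 100 * n_pos / n_cells_per_frame,
        dots_per_positive_cell = if (n_pos > 0L) mean(dots) else NA_real_,
        dots_per_total_cells = sum(dots) / n_cells_per_frame
      )
    })
    bind_rows(rows)
  })
}

significance_stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 1e-4) return("****")
  if (p < 1e-3) return("***")
  if (p < 1e-2) return("**")
  if (p < 0.05) return("*")
  "ns"
}

#' Write per-frame quantification and comparison reports
#'
#' Writes tidy CSVs (one row per frame; one row per comparison) plus a
#' plain-text summary. Round-trip readable with `readr::read_csv()`.
#'
#' @param frame_quants Tibble of per-frame quantification rows.
#' @param comparisons A `condition_comparison`, `flux_assessment`, or list
#'   of them.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(frame_quants, comparisons, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create directory '%s'", dir))
  }
  if (inherits(comparisons, c("condition_comparison", "flux_assessment"))) {
    comparisons <- list(comparisons)
  }
  comp_tbl <- bind_rows(lapply(comparisons, tidy))
  readr::write_csv(frame_quants, file.path(dir, "frames.csv"))
  readr::write_csv(comp_tbl, file.path(dir, "comparisons.csv"))
  lines <- c(
    sprintf("frames: %d", nrow(frame_quants)),
    sprintf("comparisons: %d", nrow(comp_tbl))
  )
  if (nrow(comp_tbl) > 0L) {
    lines <- c(lines, vapply(seq_len(nrow(comp_tbl)), function(i) {
      r <- comp_tbl[i, ]
      sprintf("%s vs %s [%s]: statistic=%.4g p=%.3g p_bonf=%.3g %s",
              r$label1, r$label2, r$kind, r$statistic, r$p_raw,
              r$p_bonferroni, significance_stars(r$p_bonferroni))
    }, ""))
  }
  writeLines(lines, file.path(dir, "summary.txt"))
  invisible(dir)
}
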