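# broom-style tidiers and print methods for test-result objects.

#' Tidy a condition comparison
#'
#' @param x A `condition_comparison`.
#' @param ... Unused.
#' @return One-row tibble: labels, statistic kind and value, estimates,
#'   sample sizes, raw and Bonferroni-corrected p-values.
#' @export
tidy.condition_comparison <- function(x, ...) {
  tibble(
    label1 = x$labels[1L], label2 = x$labels[2L], kind = x$kind,
    statistic = x$statistic, df = x$df, estimate1 = x$estimate1,
    estimate2 = x$estimate2, n1 = x$n1, n2 = x$n2, p_raw = x$p_raw,
    n_comparisons = x$n_comparisons, p_bonferroni = x$p_bonferroni,
    degenerate = x$degenerate
  )
}

#' @rdname tidy.condition_comparison
#' @export
glance.condition_comparison <- function(x, ...) {
  tidy.condition_comparison(x, ...)
}

#' Tidy a flux assessment
#'
#' @param x A `flux_assessment`.
#' @param ... Unused.
#' @return One-row tibble with the group means, the test result and the
#'   `flux_intact` decision.
#' @export
tidy.flux_assessment <- function(x, ...) {
  cmp <- tidy(x$comparison)
  tibble(
    label1 = cmp$label1, label2 = cmp$label2,
    baseline_mean = x$baseline_mean, inhibited_mean = x$inhibited_mean,
    delta = x$delta, statistic = cmp$statistic, p_raw = cmp$p_raw,
    p_bonferroni = cmp$p_bonferroni, alpha = x$alpha,
    flux_intact = x$flux_intact
  )
}

#' @rdname tidy.flux_assessment
#' @export
glance.flux_assessment <- function(x, ...) {
  tidy.flux_assessment(x, ...)
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf(
    "<condition_comparison> %s vs %s (%s)\n", x$labels[1L], x$labels[2L],
    x$kind
  ))
  if (x$degenerate) {
    cat("  degenerate input: statistic undefined\n")
  } else {
    df_txt <- if (is.na(x$df)) "" else sprintf(", df = %g", x$df)
    cat(sprintf(
      "  statistic = %.4g%s, p = %.4g, p_bonferroni = %.4g (n = %d) %s\n",
      x$statistic, df_txt, x$p_raw, x$p_bonferroni, x$n_comparisons,
      significance_stars(x$p_bonferroni)
    ))
  }
  cat(sprintf("  estimates: %.4g (n=%g) vs %.4g (n=%g)\n", x$estimate1,
              x$n1, x$estimate2, x$n2))
  invisible(x)
}

#' @export
print.flux_assessment <- function(x, ...) {
  cat(sprintf(
    "<flux_assessment> baseline %.3g -> inhibited %.3g (delta %.3g)\n",
    x$baseline_mean, x$inhibited_mean, x$delta
  ))
  cat(sprintf(
    "  p_bonferroni = %.4g at alpha = %g: flux %s\n",
    x$comparison$p_bonferroni, x$alpha,
    if (x$flux_intact) "INTACT" else "not demonstrated"
  ))
  invisible(x)
}
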