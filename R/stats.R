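# Group comparisons (Welch's unequal-variance t-test, computed from raw
# samples or printed summary statistics) and significance marks.

welch_core <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                       var_equal = FALSE,
                       labels = c("a", "b")) {
  abort_if(n_a < 2 || n_b < 2, "each sample needs n >= 2")
  abort_if(sd_a < 0 || sd_b < 0, "SDs must be >= 0")
  va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
  if (va + vb == 0) {
    # zero variance in both samples: identical data are not evidence of
    # a difference; distinct constant samples are infinitely strong
    t <- if (mean_a == mean_b) 0 else sign(mean_a - mean_b) * Inf
    df <- n_a + n_b - 2
  } else if (var_equal) {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    t <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  } else {
    t <- (mean_a - mean_b) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  p <- max(p, .Machine$double.xmin)  # keep p in (0, 1]
  structure(list(labels = labels,
                 means = c(mean_a, mean_b), sds = c(sd_a, sd_b),
                 ns = c(n_a, n_b), t = t, df = df, p = p,
                 var_equal = var_equal,
                 mark = significance_mark(p)),
            class = "group_comparison")
}

#' Welch's two-sample t-test
#'
#' Two-sided unequal-variance location test with Welch-Satterthwaite
#' degrees of freedom:
#' `t = (m_a - m_b) / sqrt(s_a^2/n_a + s_b^2/n_b)`. Set
#' `var_equal = TRUE` for the pooled Student's variant (a sensitivity
#' option).
#'
#' @param sample_a,sample_b Numeric vectors, each of length >= 2.
#' @param var_equal Pool the variances (Student's t) instead of Welch.
#' @param labels Length-2 character labels for the report.
#' @return Object of class `group_comparison`: group means/SDs/Ns, `t`,
#'   `df`, two-sided `p`, and the significance `mark` (`"*"` for
#'   p < 0.005, `"**"` for p < 0.001).
#' @export
welch_t_test <- function(sample_a, sample_b, var_equal = FALSE,
                         labels = c("a", "b")) {
  welch_core(mean(sample_a), stats::sd(sample_a), length(sample_a),
             mean(sample_b), stats::sd(sample_b), length(sample_b),
             var_equal = var_equal, labels = labels)
}

#' Welch's t-test from summary statistics
#'
#' The same formulas as [welch_t_test()] applied to printed
#' mean/SD/N summaries, so published tables can be tested without raw
#' data.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries.
#' @inheritParams welch_t_test
#' @return A `group_comparison`.
#' @examples
#' # group moduli 260 +/- 100 vs 680 +/- 150 Pa, n = 6 each
#' welch_from_summary(260, 100, 6, 680, 150, 6)
#' @export
welch_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                               var_equal = FALSE, labels = c("a", "b")) {
  welch_core(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
             var_equal = var_equal, labels = labels)
}

#' Significance mark for a p-value
#'
#' `"**"` for p < 0.001, `"*"` for p < 0.005, otherwise `""`.
#' @param p A p-value.
#' @return A character mark.
#' @export
significance_mark <- function(p) {
  if (p < 0.001) "**" else if (p < 0.005) "*" else ""
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: %.3g+/-%.3g (n=%d) vs %.3g+/-%.3g (n=%d)\n",
              x$labels[1], x$labels[2], x$means[1], x$sds[1], x$ns[1],
              x$means[2], x$sds[2], x$ns[2]))
  cat(sprintf("  %s t = %.3f, df = %.2f, two-sided p = %.3g %s\n",
              if (x$var_equal) "Student's" else "Welch's", x$t, x$df,
              x$p, x$mark))
  invisible(x)
}
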