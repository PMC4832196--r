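# Nonparametric group statistics on per-animal summary values.

#' Mean, SEM and n of a sample
#'
#' @param values Numeric vector (n >= 1).
#' @return List with `mean`, `sem` (sample sd / sqrt(n); NA for n = 1), `n`.
#' @export
mean_sem <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1L) stop_vsdi("input error: empty sample")
  list(mean = mean(values),
       sem = if (n > 1L) stats::sd(values) / sqrt(n) else NA_real_,
       n = n)
}

new_group_comparison <- function(metric, test, statistic, p_value, method,
                                 a, b, labels, alpha, extra = list()) {
  structure(c(list(metric = metric, test = test, statistic = statistic,
                   p_value = p_value, method = method,
                   group_a = c(list(label = labels[1], values = a), mean_sem(a)),
                   group_b = c(list(label = labels[2], values = b), mean_sem(b)),
                   alpha = alpha, significant = p_value < alpha),
              extra),
            class = "group_comparison")
}

significance_stars <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' @export
print.group_comparison <- function(x, ...) {
  fmt <- function(g) sprintf("%s: %.4g +/- %.3g (n = %d)", g$label, g$mean,
                             g$sem, g$n)
  cat(sprintf("<group_comparison> %s (%s, %s)\n", x$metric %||% "metric",
              x$test, x$method))
  cat(" ", fmt(x$group_a), " vs ", fmt(x$group_b), "\n", sep = "")
  cat(sprintf("  statistic = %g, two-sided p = %.4g %s\n", x$statistic,
              x$p_value, significance_stars(x$p_value)))
  invisible(x)
}

#' Wilcoxon rank-sum (Mann-Whitney) comparison of two groups
#'
#' Two-sided test on per-animal values. The exact distribution is used for
#' combined n <= 20 without ties; otherwise the normal approximation with tie
#' correction (and continuity correction) is used. The choice is recorded in
#' the output.
#'
#' @param a,b Numeric vectors of per-animal values (each n >= 2).
#' @param metric Optional metric name carried into the result.
#' @param labels Group labels.
#' @param alpha Significance level (default 0.05).
#' @return A `group_comparison`.
#' @export
rank_sum_test <- function(a, b, metric = NULL, labels = c("A", "B"),
                          alpha = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop_vsdi("input error: each group needs >= 2 values")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b) <= 20L) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  new_group_comparison(metric, "Wilcoxon rank-sum", unname(ht$statistic),
                       ht$p.value,
                       if (exact) "exact" else "normal approximation",
                       a, b, labels, alpha)
}

#' Wilcoxon signed-rank test of paired values
#'
#' Two-sided test of paired differences (e.g. per-animal observed synchrony
#' against its spatial-shuffle null mean). Zero differences are dropped per
#' the standard convention and their count reported; the exact distribution
#' is used for n <= 25 nonzero differences without ties in their absolute
#' values.
#'
#' @param observed,null_reference Equal-length paired numeric vectors.
#' @param metric Optional metric name.
#' @param labels Labels for the two sides of the pairing.
#' @param alpha Significance level.
#' @return A `group_comparison` with `n_zero_differences` recorded.
#' @export
signed_rank_test <- function(observed, null_reference, metric = NULL,
                             labels = c("observed", "null"), alpha = 0.05) {
  stopifnot(length(observed) == length(null_reference))
  ok <- !is.na(observed) & !is.na(null_reference)
  observed <- observed[ok]; null_reference <- null_reference[ok]
  if (length(observed) < 2L)
    stop_vsdi("input error: need >= 2 complete pairs")
  d <- observed - null_reference
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  if (length(d) == 0L)
    stop_vsdi("degenerate pairing: all differences are zero")
  if (length(d) < 2L)
    stop_vsdi("input error: need >= 2 nonzero differences")
  exact <- length(d) <= 25L && anyDuplicated(abs(d)) == 0L
  ht <- suppressWarnings(
    stats::wilcox.test(d, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  new_group_comparison(metric, "Wilcoxon signed-rank", unname(ht$statistic),
                       ht$p.value,
                       if (exact) "exact" else "normal approximation",
                       observed, null_reference, labels, alpha,
                       extra = list(n_zero_differences = n_zero))
}
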