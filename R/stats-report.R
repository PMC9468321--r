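# Group-comparison protocol: per metric and depth condition, pool per-stitch
# values across subjects within each experience group (each stitch is one
# trial), screen normality with a Lilliefors test (reported, not gating), and
# compare groups with a two-sided Wilcoxon rank-sum test. Surface and depth
# conditions are analyzed separately. Raw p-values by default; optional
# Benjamini-Hochberg adjustment.

#' Lilliefors normality test
#'
#' Kolmogorov-Smirnov statistic against a normal distribution with mean and
#' standard deviation estimated from the sample, with the Dallal-Wilkinson
#' p-value approximation.
#'
#' @param x Numeric sample, n >= 5, finite, non-constant.
#' @return List with `statistic`, `p_value`, `method`.
#' @export
lilliefors_test <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 5L || any(!is.finite(x)))
    abort_validation("lilliefors_test needs >= 5 finite values")
  if (stats::sd(x) == 0)
    abort_validation("lilliefors_test: sample has zero variance")
  ht <- nortest::lillie.test(x)
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       method = "lilliefors-dallal-wilkinson")
}

#' Wilcoxon rank-sum test
#'
#' Two-group rank-sum test with the method switch made explicit: the exact
#' null distribution when the smaller group has at most 10 observations and
#' the pooled sample is tie-free, otherwise the normal approximation with
#' mid-ranks, tie-corrected variance and continuity correction. The method
#' actually used is recorded in the result.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List with `statistic` (rank-sum W of `x`), `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = "two.sided") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y))
    abort_validation("wilcoxon_rank_sum: both groups must be non-empty")
  if (any(!is.finite(c(x, y))))
    abort_validation("wilcoxon_rank_sum: values must be finite")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && min(length(x), length(y)) <= 10L
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       method = if (exact) "exact-enumeration" else "normal-approximation")
}

quartiles <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE,
                                         type = 7)

#' Attending-vs-resident comparison across all metrics
#'
#' For every metric in the vocabulary and every depth condition present,
#' pools per-stitch values across subjects within group and tests attending
#' vs resident with [wilcoxon_rank_sum()]. Per-group Lilliefors p-values are
#' reported but never gate the rank test. A cell missing one group is flagged
#' `testable = FALSE` rather than dropped.
#'
#' @param records Long-format metric table from [session_metrics()] /
#'   [cohort_metrics()].
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default, matching a raw-p-value protocol) or
#'   `"BH"` for Benjamini-Hochberg across all testable rows; when `"BH"`, the
#'   significance flag uses the adjusted p-values.
#' @return Tibble with one row per metric x depth: group sizes, medians and
#'   quartiles, normality p-values, test method, p-value and significance.
#' @export
compare_groups <- function(records, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  req <- c("group", "depth", "metric", "value")
  if (!all(req %in% names(records)))
    abort_validation("records must contain columns %s", paste(req, collapse = ", "))
  metrics <- intersect(metric_vocabulary(), unique(records$metric))
  extra <- setdiff(unique(records$metric), metric_vocabulary())
  if (length(extra))
    abort_validation("unknown metric name(s): %s", paste(extra, collapse = ", "))
  depths <- intersect(c("surface", "depth"), unique(records$depth))
  rows <- list()
  for (d in depths) for (m in metrics) {
    cell <- records[records$metric == m & records$depth == d, ]
    x <- cell$value[cell$group == "attending"]
    y <- cell$value[cell$group == "resident"]
    lp <- function(v) tryCatch(lilliefors_test(v)$p_value,
                               error = function(e) NA_real_)
    testable <- length(x) > 0L && length(y) > 0L
    w <- if (testable) wilcoxon_rank_sum(x, y)
         else list(p_value = NA_real_, method = NA_character_)
    qa <- if (length(x)) quartiles(x) else rep(NA_real_, 3)
    qr <- if (length(y)) quartiles(y) else rep(NA_real_, 3)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      metric = m, depth = d,
      n_attending = length(x), n_resident = length(y),
      q1_attending = qa[1], median_attending = qa[2], q3_attending = qa[3],
      q1_resident = qr[1], median_resident = qr[2], q3_resident = qr[3],
      lilliefors_p_attending = if (length(x)) lp(x) else NA_real_,
      lilliefors_p_resident = if (length(y)) lp(y) else NA_real_,
      test = "wilcoxon-rank-sum", method = w$method,
      p_value = w$p_value, testable = testable)
  }
  out <- dplyr::bind_rows(rows)
  if (adjust == "BH") {
    out$p_adjusted <- NA_real_
    out$p_adjusted[out$testable] <- stats::p.adjust(out$p_value[out$testable],
                                                    method = "BH")
    out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  } else {
    out$significant <- !is.na(out$p_value) & out$p_value < alpha
  }
  out
}

#' Box-plot summary statistics
#'
#' Per metric, depth and group: median, first and third quartiles
#' (linear-interpolation convention) and whisker extremes taken at the most
#' extreme data points (minimum and maximum, outliers included).
#'
#' @param records Long-format metric table.
#' @return Tibble with one row per metric x depth x group.
#' @export
summarize_boxplot <- function(records) {
  records |>
    dplyr::group_by(.data$metric, .data$depth, .data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      whisker_low = min(.data$value),
      q1 = stats::quantile(.data$value, 0.25, names = FALSE, type = 7),
      median = stats::median(.data$value),
      q3 = stats::quantile(.data$value, 0.75, names = FALSE, type = 7),
      whisker_high = max(.data$value),
      .groups = "drop")
}
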