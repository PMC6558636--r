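#' @title Cross-condition statistics and reporting
#' @description Compares co-localization coefficients across marker pairs
#'   (one-way ANOVA with Tukey's honestly-significant-difference post-hoc
#'   test) and association distances across regimes (pairwise Student
#'   t-tests), and renders the standard summary figures and tables.
#' @name stats_report
NULL

check_groups <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(tab < 2L)) stop("every group needs n >= 2", call. = FALSE)
  groups
}

#' Tukey HSD pairwise comparisons after one-way ANOVA
#'
#' @param values Numeric observations (per-frame coefficients, pooled
#'   distances, ...).
#' @param groups Group labels, one per observation (>= 2 groups, each
#'   n >= 2).
#' @param alpha Family-wise significance level for the `significant` flag.
#' @return Data frame with one row per group pair: `group1`, `group2`,
#'   `diff` (mean of `group1` minus mean of `group2`), `lwr`, `upr`
#'   (family-wise confidence bounds), `p_adj`, `significant`.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  groups <- check_groups(values, groups)
  df <- data.frame(value = values, group = factor(groups))
  fit <- stats::aov(value ~ group, data = df)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  labs <- strsplit(rownames(tk), "-", fixed = TRUE)
  out <- data.frame(
    group1 = vapply(labs, `[`, "", 1L),
    group2 = vapply(labs, `[`, "", 2L),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"])
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Pairwise Student t-tests (pooled variance) for every group pair
#'
#' Student's two-sample t-test with pooled variance for every pair of
#' groups; unadjusted p-values are the headline figures (matching the
#' conventional presentation of pairwise distance comparisons), with a
#' Bonferroni-adjusted column alongside. Welch's unequal-variance test is
#' available via `var_equal = FALSE`. Two groups with zero pooled variance
#' and equal means give p = 1 by convention (and p = 0 if the means
#' differ).
#'
#' @param values Numeric observations.
#' @param groups Group labels (>= 2 groups, each n >= 2).
#' @param var_equal Use the pooled-variance Student test (default) or
#'   Welch's test.
#' @return Data frame: `group1`, `group2`, `mean1`, `mean2`, `diff`,
#'   `t`, `df`, `p`, `p_bonferroni`.
#' @export
pairwise_t_tests <- function(values, groups, var_equal = TRUE) {
  groups <- check_groups(values, groups)
  labs <- unique(groups)
  combos <- utils::combn(labs, 2L)
  rows <- lapply(seq_len(ncol(combos)), function(k) {
    g1 <- combos[1L, k]; g2 <- combos[2L, k]
    x <- values[groups == g1]; y <- values[groups == g2]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      p <- if (mean(x) == mean(y)) 1 else 0
      return(data.frame(group1 = g1, group2 = g2,
                        mean1 = mean(x), mean2 = mean(y),
                        diff = mean(x) - mean(y),
                        t = if (p == 1) 0 else Inf,
                        df = length(x) + length(y) - 2L, p = p))
    }
    tt <- stats::t.test(x, y, var.equal = var_equal)
    data.frame(group1 = g1, group2 = g2, mean1 = mean(x), mean2 = mean(y),
               diff = mean(x) - mean(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out
}

#' Bar chart of co-localization coefficients by condition
#'
#' One bar per condition (mean per-frame coefficient, basis-mean) with
#' standard-deviation error bars, the standard presentation for
#' object-based co-localization across marker pairs.
#'
#' @param summaries Data frame with columns `condition`,
#'   `mean_coefficient_pct`, `sd_coefficient_pct` (one row per condition;
#'   e.g. [summarize_coloc()] rows with a `condition` column added).
#' @return A ggplot object.
#' @export
coloc_barplot <- function(summaries) {
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = condition, y = mean_coefficient_pct)) +
    ggplot2::geom_col(fill = "grey35", width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, mean_coefficient_pct - sd_coefficient_pct),
                   ymax = mean_coefficient_pct + sd_coefficient_pct),
      width = 0.2) +
    ggplot2::labs(x = NULL, y = "co-localization coefficient (%)") +
    ggplot2::ylim(0, 105) +
    ggplot2::theme_classic()
}

#' Distance-over-time and distance-distribution panels for paired tracks
#'
#' @param stats A [distance_stats()] result.
#' @param frame_interval_s Frame interval for the time axis.
#' @return A list of two ggplot objects: `time_series` (per-pair distance
#'   over time) and `histogram` (pooled distance distribution).
#' @export
distance_figure <- function(stats, frame_interval_s = 1) {
  d <- stats$distances
  d$time_s <- d$frame * frame_interval_s
  d$pair <- factor(d$pair_id)
  ts <- ggplot2::ggplot(d, ggplot2::aes(x = time_s, y = distance_um,
                                        color = pair)) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::labs(x = "time (s)", y = "distance (µm)") +
    ggplot2::theme_classic()
  h <- stats$histogram
  h$mid <- (h$bin_lo_um + h$bin_hi_um) / 2
  hist <- ggplot2::ggplot(h, ggplot2::aes(x = mid, y = count)) +
    ggplot2::geom_col(width = h$bin_hi_um[1] - h$bin_lo_um[1],
                      fill = "grey35") +
    ggplot2::labs(x = "distance (µm)", y = "frequency") +
    ggplot2::theme_classic()
  list(time_series = ts, histogram = hist)
}
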