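# Group-difference statistics: Anderson-Darling normality screening,
# Mann-Whitney U comparison, Glass's delta effect size, and summary-level
# t-test / one-way ANOVA for demographic tables reported as mean +- SD.

#' Anderson-Darling test of normality
#'
#' A-squared with mean and variance estimated from the sample, the
#' small-sample correction `A*2 = A2 (1 + 0.75/n + 2.25/n^2)`, and rejection
#' at the 5% level when `A*2 > 0.752`.
#'
#' @param x numeric sample, n >= 8, non-degenerate.
#' @return list with `a2` (uncorrected statistic), `a2_corrected`,
#'   `reject_5pct` (logical) and `p_value`.
#' @export
anderson_darling_normal <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 8L) {
    pm_stop("Anderson-Darling needs n >= 8", "phonemark_invalid_argument")
  }
  if (sd(x) == 0) {
    pm_stop("zero-variance sample", "phonemark_degenerate_sample")
  }
  res <- nortest::ad.test(x)
  n <- length(x)
  a2 <- unname(res$statistic)
  a2c <- a2 * (1 + 0.75 / n + 2.25 / n^2)
  list(a2 = a2, a2_corrected = a2c, reject_5pct = a2c > 0.752,
       p_value = unname(res$p.value))
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact p-value by complete enumeration of rank assignments when
#' `n_x + n_y <= 12` and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections. `u` is the number of
#' (x, y) pairs with `x > y` (plus half the tied pairs).
#'
#' @param x,y numeric samples, each non-empty.
#' @return list with `u` and `p_value`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    pm_stop("both samples must be non-empty", "phonemark_invalid_argument")
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= 12 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE, conf.int = FALSE))
  list(u = unname(wt$statistic), p_value = unname(wt$p.value))
}

#' Glass's delta from printed summaries
#'
#' Standardized control-vs-patient mean difference using the control group's
#' SD as the scale: `(mean_c - mean_pd) / sd_c`. Positive when the control
#' mean exceeds the patient mean.
#'
#' @param mean_c,sd_c control-group mean and SD (`sd_c > 0`).
#' @param mean_pd patient-group mean.
#' @return Glass's delta (dimensionless).
#' @export
glass_delta_from_summary <- function(mean_c, sd_c, mean_pd) {
  if (!is.finite(sd_c) || sd_c <= 0) {
    pm_stop("`sd_c` must be positive", "phonemark_invalid_argument")
  }
  (mean_c - mean_pd) / sd_c
}

#' Glass's delta from raw samples
#'
#' @param x_control,x_pd raw samples for the two groups.
#' @return Glass's delta, control SD as denominator.
#' @export
glass_delta <- function(x_control, x_pd) {
  glass_delta_from_summary(mean(x_control), sd(x_control), mean(x_pd))
}

#' Pooled two-sample t-test from summary statistics
#'
#' Classic unpaired t-test reconstructed from (mean, SD, n) per group:
#' pooled variance, `df = n1 + n2 - 2`, two-sided p.
#'
#' @param m1,s1,n1 mean, SD, size of group 1.
#' @param m2,s2,n2 mean, SD, size of group 2.
#' @return list with `t`, `df`, `p_value`.
#' @export
ttest_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2 || s1 < 0 || s2 < 0 || (s1 == 0 && s2 == 0)) {
    pm_stop("need n >= 2 per group and a positive pooled SD",
            "phonemark_invalid_argument")
  }
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p_value = 2 * pt(-abs(t), df))
}

#' One-way ANOVA from summary statistics
#'
#' Between/within sums of squares reconstructed from per-group
#' (mean, SD, n); with two groups, `F = t^2` of [ttest_from_summary()] and
#' the p-values coincide.
#'
#' @param groups list of numeric triples `c(mean, sd, n)`.
#' @return list with `f`, `df1`, `df2`, `p_value`.
#' @export
anova_from_summary <- function(groups) {
  if (length(groups) < 2L) {
    pm_stop("need at least 2 groups", "phonemark_invalid_argument")
  }
  m <- vapply(groups, `[`, numeric(1), 1L)
  s <- vapply(groups, `[`, numeric(1), 2L)
  n <- vapply(groups, `[`, numeric(1), 3L)
  if (any(n < 2) || any(s < 0)) {
    pm_stop("each group needs n >= 2 and SD >= 0",
            "phonemark_invalid_argument")
  }
  grand <- sum(n * m) / sum(n)
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((n - 1) * s^2)
  df1 <- length(groups) - 1
  df2 <- sum(n) - length(groups)
  if (ssw == 0) {
    pm_stop("zero within-group variance", "phonemark_invalid_argument")
  }
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, df1 = df1, df2 = df2, p_value = pf(f, df1, df2,
                                                 lower.tail = FALSE))
}

#' Per-feature group comparison table
#'
#' For every feature column of a feature table, computes group means and
#' SDs, Anderson-Darling normality per group, the Mann-Whitney two-sided
#' p-value, and Glass's delta (control SD as scale), per phoneme. No
#' multiple-testing correction is applied by default; pass
#' `p_adjust = "holm"` (or any [stats::p.adjust()] method) to add an
#' adjusted column.
#'
#' @param table a feature table (see [extract_features()]): data.frame with
#'   columns `subject_id`, `group` (values `"CO"`/`"PD"`), `phoneme`,
#'   `repetition` and one column per feature.
#' @param p_adjust `"none"` (default) or a [stats::p.adjust()] method.
#' @return data.frame, one row per (phoneme, feature).
#' @export
group_stats_table <- function(table, p_adjust = "none") {
  feats <- setdiff(names(table),
                   c("subject_id", "group", "phoneme", "repetition"))
  rows <- list()
  for (ph in unique(table$phoneme)) {
    sub <- table[table$phoneme == ph, , drop = FALSE]
    co <- sub[sub$group == "CO", , drop = FALSE]
    pd <- sub[sub$group == "PD", , drop = FALSE]
    for (f in feats) {
      xc <- co[[f]]; xp <- pd[[f]]
      mw <- mann_whitney_u(xc, xp)
      norm_c <- if (length(xc) >= 8 && sd(xc) > 0) {
        !anderson_darling_normal(xc)$reject_5pct
      } else NA
      norm_p <- if (length(xp) >= 8 && sd(xp) > 0) {
        !anderson_darling_normal(xp)$reject_5pct
      } else NA
      rows[[length(rows) + 1L]] <- data.frame(
        phoneme = ph, feature = f,
        mean_co = mean(xc), sd_co = sd(xc),
        mean_pd = mean(xp), sd_pd = sd(xp),
        normal_co = norm_c, normal_pd = norm_p,
        n_co = length(xc), n_pd = length(xp),
        p_value = mw$p_value,
        effect_size = glass_delta(xc, xp),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!identical(p_adjust, "none")) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  }
  out
}
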