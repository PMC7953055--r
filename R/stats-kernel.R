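#' Fisher z transformation of correlations
#'
#' Variance-stabilising transform `z = atanh(r)` applied to Pearson
#' correlations before any averaging or testing. Strictly increasing and odd.
#'
#' @param r Numeric vector of correlations, all strictly inside (-1, 1).
#'   Names, if present, are used to identify offending entries in errors.
#' @return Numeric vector of z values (names preserved).
#' @export
#' @examples
#' fisher_z(c(0, 0.5, 0.9))
fisher_z <- function(r) {
  bad <- which(!is.finite(r) | abs(r) >= 1)
  if (length(bad) > 0) {
    lab <- if (!is.null(names(r))) names(r)[bad] else as.character(bad)
    abort(paste0("fisher_z(): |r| >= 1 (or non-finite) for edge(s): ",
                 paste(lab, collapse = ", ")))
  }
  atanh(r)
}

#' Inverse Fisher z transformation
#' @param z Numeric vector of z values.
#' @return Correlations `tanh(z)`.
#' @export
inv_fisher_z <- function(z) tanh(z)

new_test_result <- function(method, statistic, df1, df2 = NA_real_,
                            p_value, tail, ...) {
  tibble::tibble(method = method, statistic = statistic,
                 df1 = df1, df2 = df2, p_value = p_value, tail = tail, ...)
}

#' Independent two-sample t test
#'
#' Student pooled-variance two-sample t with `df = n_a + n_b - 2` by default;
#' Welch's unequal-variance form is available via `var_equal = FALSE`.
#' The one-tailed direction `tail = "less"` tests for a reduction in `a`
#' relative to `b` (e.g. patient edge values below healthy-control values).
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param tail `"two.sided"` (default), `"less"` (a < b) or `"greater"`.
#' @param var_equal Pool variances (default TRUE).
#' @return One-row tibble: `method`, `statistic`, `df1`, `df2`, `p_value`,
#'   `tail`, `estimate` (mean difference a - b).
#' @export
#' @examples
#' two_sample_t(rnorm(10), rnorm(10) + 1, tail = "less")
two_sample_t <- function(a, b, tail = c("two.sided", "less", "greater"),
                         var_equal = TRUE) {
  tail <- match.arg(tail)
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) abort("two_sample_t(): each sample needs n >= 2")
  diff <- mean(a) - mean(b)
  if (var_equal) {
    df <- na + nb - 2
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / df
    if (sp2 == 0) {
      if (diff != 0)
        abort("two_sample_t(): zero pooled variance with unequal means")
      tstat <- 0
    } else {
      tstat <- diff / sqrt(sp2 * (1 / na + 1 / nb))
    }
  } else {
    va <- var(a) / na; vb <- var(b) / nb
    if (va + vb == 0) {
      if (diff != 0)
        abort("two_sample_t(): zero variance with unequal means")
      tstat <- 0; df <- na + nb - 2
    } else {
      tstat <- diff / sqrt(va + vb)
      df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
    }
  }
  p <- switch(tail,
    two.sided = 2 * pt(abs(tstat), df, lower.tail = FALSE),
    less = pt(tstat, df),
    greater = pt(tstat, df, lower.tail = FALSE))
  new_test_result(if (var_equal) "two-sample t (pooled)" else "Welch t",
                  tstat, df, NA_real_, p, tail, estimate = diff)
}

#' Paired t test
#'
#' One-sample t on the paired differences `a - b`, `df = n - 1`.
#'
#' @param a,b Numeric samples of equal length >= 2.
#' @param tail As in [two_sample_t()].
#' @return One-row tibble as in [two_sample_t()]; `estimate` is the mean
#'   difference.
#' @export
paired_t <- function(a, b, tail = c("two.sided", "less", "greater")) {
  tail <- match.arg(tail)
  if (length(a) != length(b)) abort("paired_t(): samples must have equal length")
  if (length(a) < 2) abort("paired_t(): need n >= 2 pairs")
  d <- as.numeric(a) - as.numeric(b)
  n <- length(d)
  sdd <- sd(d)
  if (sdd == 0) {
    if (mean(d) != 0)
      abort("paired_t(): zero variance of differences with nonzero mean")
    tstat <- 0
  } else {
    tstat <- mean(d) / (sdd / sqrt(n))
  }
  p <- switch(tail,
    two.sided = 2 * pt(abs(tstat), n - 1, lower.tail = FALSE),
    less = pt(tstat, n - 1),
    greater = pt(tstat, n - 1, lower.tail = FALSE))
  new_test_result("paired t", tstat, n - 1, NA_real_, p, tail,
                  estimate = mean(d))
}

anova_from_ss <- function(ssb, ssw, k, n_total, method) {
  df1 <- k - 1; df2 <- n_total - k
  if (ssw <= 0) abort("one-way ANOVA: zero within-group variance everywhere")
  fstat <- (ssb / df1) / (ssw / df2)
  new_test_result(method, fstat, df1, df2,
                  pf(fstat, df1, df2, lower.tail = FALSE), "two.sided")
}

#' One-way ANOVA on raw observations
#'
#' `F = MS_between / MS_within` with `df = (k - 1, N - k)`.
#'
#' @param data Data frame with one row per observation.
#' @param value,group Column names (tidy-eval) holding the response and the
#'   grouping factor.
#' @return One-row tibble: `method`, `statistic` (F), `df1`, `df2`,
#'   `p_value`, `tail`.
#' @export
#' @examples
#' df <- data.frame(y = rnorm(30), g = rep(letters[1:3], 10))
#' anova_oneway(df, y, g)
anova_oneway <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  ns <- table(g)
  if (length(ns) < 2) abort("anova_oneway(): need >= 2 groups")
  if (any(ns < 2)) abort("anova_oneway(): every group needs n >= 2")
  gm <- mean(v)
  means <- tapply(v, g, mean)
  ssb <- sum(as.numeric(ns) * (means - gm)^2)
  ssw <- sum(tapply(v, g, function(x) sum((x - mean(x))^2)))
  anova_from_ss(ssb, ssw, length(ns), length(v), "one-way ANOVA")
}

#' One-way ANOVA from printed group summaries
#'
#' Recovers the ANOVA table from per-group means, standard deviations and
#' sizes (as printed in a demographics table):
#' `SS_between = sum n_i (m_i - m)^2`, `SS_within = sum (n_i - 1) s_i^2`.
#'
#' @param summary Data frame with columns `mean`, `sd`, `n` (one row per
#'   group); extra columns are ignored.
#' @return One-row tibble as in [anova_oneway()].
#' @export
#' @examples
#' anova_oneway_summary(data.frame(mean = c(1, 2), sd = c(1, 1), n = c(10, 10)))
anova_oneway_summary <- function(summary) {
  need <- c("mean", "sd", "n")
  miss <- setdiff(need, names(summary))
  if (length(miss) > 0)
    abort(paste0("anova_oneway_summary(): missing column(s): ",
                 paste(miss, collapse = ", ")))
  m <- summary$mean; s <- summary$sd; n <- summary$n
  if (length(n) < 2) abort("anova_oneway_summary(): need >= 2 groups")
  if (any(n < 2)) abort("anova_oneway_summary(): every group needs n >= 2")
  if (any(s < 0)) abort("anova_oneway_summary(): negative sd")
  gm <- sum(n * m) / sum(n)
  anova_from_ss(sum(n * (m - gm)^2), sum((n - 1) * s^2),
                length(n), sum(n), "one-way ANOVA (summary)")
}

#' Tukey honestly-significant-difference pairwise comparisons
#'
#' All pairwise group comparisons after a one-way ANOVA, with p values from
#' the studentized-range distribution. Unbalanced designs use the
#' Tukey-Kramer standard error `sqrt(MSE / 2 * (1/n_i + 1/n_j))`.
#'
#' @inheritParams anova_oneway
#' @param conf_level Confidence level for the HSD intervals (default 0.95).
#' @return Tibble with one row per group pair: `group1`, `group2`, `diff`
#'   (mean of group1 minus mean of group2), `se`, `q` (studentized-range
#'   statistic), `p_adj`, `conf_low`, `conf_high`, `df`.
#' @export
tukey_hsd <- function(data, value, group, conf_level = 0.95) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  ns <- table(g)
  k <- length(ns)
  if (k < 2) abort("tukey_hsd(): need >= 2 groups")
  if (any(ns < 2)) abort("tukey_hsd(): every group needs n >= 2")
  df2 <- length(v) - k
  mse <- sum(tapply(v, g, function(x) sum((x - mean(x))^2))) / df2
  if (mse <= 0) abort("tukey_hsd(): zero within-group variance everywhere")
  means <- tapply(v, g, mean)
  labs <- names(ns)
  pairs <- utils::combn(labs, 2)
  qcrit <- stats::qtukey(conf_level, k, df2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    se <- sqrt(mse / 2 * (1 / ns[[g1]] + 1 / ns[[g2]]))
    d <- means[[g1]] - means[[g2]]
    q <- abs(d) / se
    tibble::tibble(
      group1 = g1, group2 = g2, diff = d, se = se, q = q,
      p_adj = ptukey(q, k, df2, lower.tail = FALSE),
      conf_low = d - qcrit * se, conf_high = d + qcrit * se, df = df2)
  })
}

#' Two-level repeated-measures (mixed) ANOVA, main within-subject effect
#'
#' Main effect of a two-level within-subject factor with a between-subject
#' grouping factor, computed exactly through difference scores: with
#' `d_i = y_i1 - y_i2`, the within-factor main effect is
#' `F(1, N - k) = N * dbar^2 / (SSE_d / (N - k))` where `SSE_d` pools the
#' within-group sums of squares of the differences. For a single group this
#' reduces to the square of the paired t statistic. Exact for two levels, so
#' no sphericity machinery is needed.
#'
#' @param data Long data frame, two rows per subject.
#' @param subject,value,within,group Columns (tidy-eval): subject id,
#'   response, the two-level within-subject factor, and the between-subject
#'   group.
#' @return One-row tibble: F statistic with `df1 = 1`, `df2 = N - k`.
#' @export
mixed_anova_within <- function(data, subject, value, within, group) {
  df <- dplyr::tibble(
    subject = as.character(dplyr::pull(data, {{ subject }})),
    value = dplyr::pull(data, {{ value }}),
    within = as.character(dplyr::pull(data, {{ within }})),
    group = as.character(dplyr::pull(data, {{ group }})))
  lv <- sort(unique(df$within))
  if (length(lv) != 2)
    abort("mixed_anova_within(): the within factor must have exactly 2 levels")
  wide <- tidyr::pivot_wider(df, names_from = "within", values_from = "value")
  bad <- wide$subject[!complete.cases(wide[, lv])]
  if (length(bad) > 0)
    abort(paste0("mixed_anova_within(): missing within-factor level for ",
                 "subject(s): ", paste(bad, collapse = ", ")))
  d <- wide[[lv[1]]] - wide[[lv[2]]]
  g <- wide$group
  n_total <- length(d)
  k <- length(unique(g))
  if (k < 1 || n_total <= k)
    abort("mixed_anova_within(): not enough subjects for the error df")
  sse <- sum(tapply(d, g, function(x) sum((x - mean(x))^2)))
  df2 <- n_total - k
  ss_effect <- n_total * mean(d)^2 / 2
  mse <- (sse / 2) / df2
  fstat <- if (mse == 0 && ss_effect == 0) 0 else ss_effect / mse
  new_test_result("repeated-measures ANOVA (within main effect)", fstat,
                  1, df2, pf(fstat, 1, df2, lower.tail = FALSE), "two.sided")
}

#' Pearson chi-square test of independence
#'
#' `chi2 = sum (O - E)^2 / E` with expected counts from the row/column
#' margins and `df = (R - 1)(C - 1)`. No continuity correction is applied.
#'
#' @param counts Matrix or data frame of non-negative integer counts,
#'   at least 2 x 2.
#' @return One-row tibble: `method`, `statistic`, `df1`, `p_value`, `tail`.
#' @export
#' @examples
#' chisq_independence(rbind(c(10, 0), c(0, 10)))
chisq_independence <- function(counts) {
  m <- as.matrix(counts)
  if (!is.numeric(m) || any(m < 0) || any(m != round(m)))
    abort("chisq_independence(): counts must be non-negative integers")
  if (nrow(m) < 2 || ncol(m) < 2)
    abort("chisq_independence(): need at least a 2 x 2 table")
  if (sum(m) <= 0) abort("chisq_independence(): empty table")
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0) || any(cs == 0))
    abort("chisq_independence(): zero row or column margin")
  e <- outer(rs, cs) / sum(m)
  stat <- sum((m - e)^2 / e)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  new_test_result("Pearson chi-square", stat, df, NA_real_,
                  pchisq(stat, df, lower.tail = FALSE), "two.sided")
}

#' Pearson correlation with t-based p value
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @param tail As in [two_sample_t()]; default two-sided, from
#'   `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df.
#' @return One-row tibble: `estimate` (r), `statistic` (t), `df1`, `p_value`,
#'   `n`, `tail`.
#' @export
pearson_cor <- function(x, y, tail = c("two.sided", "less", "greater")) {
  tail <- match.arg(tail)
  if (length(x) != length(y)) abort("pearson_cor(): unequal lengths")
  n <- length(x)
  if (n < 3) abort("pearson_cor(): need n >= 3")
  if (sd(x) == 0 || sd(y) == 0) abort("pearson_cor(): zero variance input")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  tstat <- if (abs(r) == 1) sign(r) * Inf else r * sqrt((n - 2) / (1 - r^2))
  p <- switch(tail,
    two.sided = 2 * pt(abs(tstat), n - 2, lower.tail = FALSE),
    less = pt(tstat, n - 2),
    greater = pt(tstat, n - 2, lower.tail = FALSE))
  new_test_result("Pearson correlation", tstat, n - 2, NA_real_, p, tail,
                  estimate = r, n = n)
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up FDR adjustment: sorted p values are compared to `i * alpha / m`;
#' adjusted p values are the monotone envelope `min_k>=i (m / k) p_(k)`.
#' The Benjamini-Yekutieli variant (valid under arbitrary dependence)
#' multiplies by the harmonic sum and is available via `method = "BY"`.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @param method `"BH"` (default) or `"BY"`.
#' @return Tibble in input order: `p`, `p_adj`, `significant`.
#' @export
#' @examples
#' bh_fdr(c(0.001, 0.02, 0.2, 0.9))
bh_fdr <- function(p, alpha = 0.05, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(!is.finite(p) | p < 0 | p > 1))
    abort("bh_fdr(): p values must lie in [0, 1]")
  m <- length(p)
  cm <- if (method == "BY") sum(1 / seq_len(m)) else 1
  o <- order(p)
  ps <- p[o]
  adj <- rev(cummin(rev(pmin(1, cm * m / seq_len(m) * ps))))
  p_adj <- numeric(m)
  p_adj[o] <- adj
  tibble::tibble(p = p, p_adj = p_adj, significant = p_adj <= alpha)
}
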