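test_that("fisher_z matches the closed form and is odd", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.54931, tolerance = 1e-5)
  expect_equal(fisher_z(0.9), 1.47222, tolerance = 1e-5)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_equal(inv_fisher_z(fisher_z(r)), r)
})

test_that("fisher_z names the offending edge on domain errors", {
  expect_error(fisher_z(c(`lIFG-lMFG` = 0.5, `lIFG-lSTG` = 1)), "lIFG-lSTG")
  expect_error(fisher_z(1.2), "1")
})

test_that("two_sample_t agrees with the base-R oracle across random cases", {
  set.seed(42)
  for (i in 1:20) {
    a <- rnorm(sample(3:30, 1)); b <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    tail <- sample(c("two.sided", "less", "greater"), 1)
    mine <- two_sample_t(a, b, tail = tail)
    ref <- t.test(a, b, var.equal = TRUE, alternative = tail)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$df1, unname(ref$parameter))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    welch <- two_sample_t(a, b, tail = tail, var_equal = FALSE)
    refw <- t.test(a, b, alternative = tail)
    expect_equal(welch$statistic, unname(refw$statistic), tolerance = 1e-12)
    expect_equal(welch$df1, unname(refw$parameter), tolerance = 1e-9)
  }
})

test_that("two_sample_t handles shifted and degenerate samples", {
  a <- c(1, 2, 3)
  # hand pooled-t formula on 3+3 values shifted by +1
  mine <- two_sample_t(a, a + 1)
  sp2 <- (2 * var(a) + 2 * var(a)) / 4
  expect_equal(mine$statistic, -1 / sqrt(sp2 * (2 / 3)))
  expect_equal(two_sample_t(a, a)$statistic, 0)
  ct <- two_sample_t(c(1, 1, 1), c(1, 1), tail = "less")
  expect_equal(ct$statistic, 0)
  expect_equal(ct$p_value, 0.5)
  expect_error(two_sample_t(c(1, 1), c(2, 2)), "zero pooled variance")
  expect_error(two_sample_t(1, c(1, 2)), "n >= 2")
})

test_that("two-sided two-sample p values are calibrated under the null", {
  set.seed(7)
  rej <- mean(replicate(2000, {
    two_sample_t(rnorm(15), rnorm(15))$p_value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 2000) + 1e-9)
})

test_that("paired_t equals a one-sample t on the differences", {
  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(12); b <- rnorm(12, 0.3)
    mine <- paired_t(a, b)
    ref <- t.test(a - b)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$df1, 11)
  }
  expect_equal(paired_t(1:5, 1:5)$statistic, 0)
  expect_error(paired_t(c(2, 3, 4, 5), c(1, 2, 3, 4)), "zero variance")
  expect_error(paired_t(1:3, 1:4), "equal length")
})

test_that("one-way ANOVA matches aov and the F = t^2 identity", {
  set.seed(11)
  df <- data.frame(y = rnorm(45), g = rep(c("a", "b", "c"), each = 15))
  mine <- anova_oneway(df, y, g)
  ref <- anova(aov(y ~ g, df))
  expect_equal(mine$statistic, ref[1, "F value"], tolerance = 1e-12)
  expect_equal(mine$p_value, ref[1, "Pr(>F)"], tolerance = 1e-12)
  expect_equal(c(mine$df1, mine$df2), c(2, 42))
  # two groups: F equals the squared pooled t
  df2 <- df[df$g != "c", ]
  tt <- two_sample_t(df2$y[df2$g == "a"], df2$y[df2$g == "b"])
  expect_equal(anova_oneway(df2, y, g)$statistic, tt$statistic^2,
               tolerance = 1e-10)
  # equal constants shifted equally -> degenerate within variance
  dfc <- data.frame(y = rep(c(1, 2), each = 3), g = rep(c("a", "b"), each = 3))
  expect_error(anova_oneway(dfc, y, g), "zero within-group variance")
})

test_that("summary ANOVA equals raw ANOVA on exactly-summarised data", {
  summ <- data.frame(mean = c(10, 12, 11.5), sd = c(2, 2.5, 1.8),
                     n = c(8, 12, 10))
  raw <- do.call(rbind, lapply(1:3, function(i)
    data.frame(y = exact_sample(summ$mean[i], summ$sd[i], summ$n[i]),
               g = letters[i])))
  expect_equal(anova_oneway_summary(summ)$statistic,
               anova_oneway(raw, y, g)$statistic, tolerance = 1e-10)
  expect_equal(anova_oneway_summary(
    data.frame(mean = c(5, 5), sd = c(1, 3), n = c(6, 9)))$statistic, 0)
  expect_error(anova_oneway_summary(data.frame(mean = 1:2, sd = c(1, 1),
                                               n = c(1, 5))), "n >= 2")
  expect_error(anova_oneway_summary(data.frame(mean = 1:2, sd = c(1, 1))),
               "missing column")
})

test_that("tukey_hsd reproduces TukeyHSD for unbalanced designs", {
  set.seed(5)
  df <- data.frame(y = rnorm(40) + rep(c(0, 0.5, 1, 0), c(8, 12, 10, 10)),
                   g = rep(letters[1:4], c(8, 12, 10, 10)))
  mine <- tukey_hsd(df, y, g)
  ref <- TukeyHSD(aov(y ~ g, df))$g
  key <- paste0(mine$group2, "-", mine$group1)
  expect_equal(mine$p_adj, unname(ref[key, "p adj"]), tolerance = 1e-6)
  expect_equal(-mine$diff, unname(ref[key, "diff"]), tolerance = 1e-12)
})

test_that("tukey_hsd flags only the separated group and respects the 2-group limit", {
  set.seed(9)
  base <- rnorm(12)
  df <- data.frame(y = c(base, base + 0.1 * rnorm(12), base + 8),
                   g = rep(c("a", "b", "c"), each = 12))
  th <- tukey_hsd(df, y, g)
  involving_c <- th$group1 == "c" | th$group2 == "c"
  expect_true(all(th$p_adj[involving_c] < 0.001))
  expect_true(all(th$p_adj[!involving_c] > 0.05))
  # two identical groups: p near 1
  dfi <- data.frame(y = c(base, base), g = rep(c("a", "b"), each = 12))
  expect_gt(tukey_hsd(dfi, y, g)$p_adj, 0.999)
  # balanced 2-group case agrees with the pooled t decision
  df2 <- data.frame(y = rnorm(24, rep(c(0, 0.9), each = 12)),
                    g = rep(c("a", "b"), each = 12))
  th2 <- tukey_hsd(df2, y, g)
  tt <- two_sample_t(df2$y[df2$g == "a"], df2$y[df2$g == "b"])
  expect_equal(th2$p_adj, tt$p_value, tolerance = 1e-6)
})

test_that("mixed_anova_within matches aov's within-subject stratum", {
  set.seed(21)
  d <- data.frame(subject = rep(sprintf("s%02d", 1:30), each = 2),
                  side = rep(c("A", "B"), 30),
                  group = rep(rep(c("g1", "g2", "g3"), each = 2), 10))
  d$value <- rnorm(60) + ifelse(d$side == "A", 0.4, 0)
  mine <- mixed_anova_within(d, subject, value, side, group)
  ref <- summary(aov(value ~ group * side + Error(subject / side),
                     data = d))[["Error: subject:side"]][[1]]
  expect_equal(mine$statistic, ref["side", "F value"], tolerance = 1e-10)
  expect_equal(mine$df2, ref["Residuals", "Df"])
  expect_equal(mine$df1, 1)
})

test_that("mixed_anova_within degenerate and single-group behaviour", {
  d <- data.frame(subject = rep(1:8, each = 2), side = rep(c("A", "B"), 8),
                  group = rep(c("g1", "g2"), each = 8))
  d$value <- rep(rnorm(8), each = 2)  # identical within levels
  expect_equal(mixed_anova_within(d, subject, value, side, group)$statistic, 0)
  # single group: F equals the squared paired t
  set.seed(2)
  d1 <- data.frame(subject = rep(1:10, each = 2), side = rep(c("A", "B"), 10),
                   group = "g1", value = rnorm(20))
  wide_a <- d1$value[d1$side == "A"]; wide_b <- d1$value[d1$side == "B"]
  f <- mixed_anova_within(d1, subject, value, side, group)
  expect_equal(f$statistic, paired_t(wide_a, wide_b)$statistic^2,
               tolerance = 1e-10)
  # missing level names the subject
  d2 <- d1[-2, ]
  expect_error(mixed_anova_within(d2, subject, value, side, group), "1")
})

test_that("mixed_anova_within detects a known within-effect with high power", {
  set.seed(31)
  hits <- replicate(500, {
    n_per <- 10; k <- 4
    d <- data.frame(subject = rep(seq_len(n_per * k), each = 2),
                    side = rep(c("A", "B"), n_per * k),
                    group = rep(paste0("g", 1:k), each = 2 * n_per))
    d$value <- rnorm(nrow(d)) + ifelse(d$side == "A", 0.8, 0)
    mixed_anova_within(d, subject, value, side, group)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("chi-square matches hand computation and the base-R oracle", {
  r <- chisq_independence(rbind(c(10, 0), c(0, 10)))
  expect_equal(r$statistic, 20)
  expect_equal(r$df1, 1)
  # perfectly proportional table
  expect_equal(chisq_independence(rbind(c(10, 20), c(5, 10)))$statistic, 0)
  set.seed(13)
  for (i in 1:10) {
    tab <- matrix(rpois(12, 10) + 1, 3, 4)
    mine <- chisq_independence(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
  expect_error(chisq_independence(rbind(c(0, 0), c(1, 2))), "margin")
  expect_error(chisq_independence(rbind(c(1.5, 2), c(1, 2))), "integer")
})

test_that("pearson_cor matches cor.test and the hand examples", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_cor(x, x)$estimate, 1)
  expect_equal(pearson_cor(x, -2 * x + 3)$estimate, -1)
  expect_equal(pearson_cor(x, c(1, 3, 2, 4))$estimate, 0.8)
  set.seed(17)
  a <- rnorm(25); b <- a * 0.4 + rnorm(25)
  mine <- pearson_cor(a, b)
  ref <- cor.test(a, b)
  expect_equal(mine$estimate, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(pearson_cor(a, rep(1, 25)), "zero variance")
  expect_error(pearson_cor(1:2, 1:2), "n >= 3")
})

test_that("bh_fdr equals p.adjust and the brute-force step-up scan", {
  brute_bh <- function(p, alpha) {
    m <- length(p); o <- order(p)
    ok <- which(p[o] <= seq_len(m) * alpha / m)
    rej <- logical(m)
    if (length(ok) > 0) rej[o[seq_len(max(ok))]] <- TRUE
    rej
  }
  set.seed(19)
  for (i in 1:20) {
    p <- runif(sample(3:60, 1))^sample(1:3, 1)
    res <- bh_fdr(p, alpha = 0.05)
    expect_equal(res$p_adj, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_identical(res$significant, brute_bh(p, 0.05))
    # never more rejections than uncorrected testing
    expect_lte(sum(res$significant), sum(p < 0.05))
    # adding a p = 1 hypothesis never increases the rejection count
    expect_lte(sum(bh_fdr(c(p, 1))$significant), sum(res$significant) + 0)
    expect_equal(bh_fdr(p, method = "BY")$p_adj, p.adjust(p, "BY"),
                 tolerance = 1e-12)
  }
  expect_equal(sum(bh_fdr(rep(1, 10))$significant), 0)
  expect_true(all(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05))$significant))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})
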