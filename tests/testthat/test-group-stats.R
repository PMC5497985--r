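test_that("2-SD exclusion follows the single-pass rule", {
  expect_true(all(exclude_outliers(rep(5, 10))))          # sd = 0
  expect_true(all(exclude_outliers(3)))                   # n = 1
  expect_true(all(exclude_outliers(c(1, 2))))             # n < 3
  x <- c(rep(0, 9), 50)
  mask <- exclude_outliers(x)
  expect_equal(mask, abs(x - mean(x)) <= 2 * sd(x))       # arithmetic oracle
  expect_false(mask[10])
  # single pass: values that would only become outliers after re-exclusion stay
  y <- c(0, 0, 0, 0, 0, 0, 10, 100)
  kept <- exclude_outliers(y)
  expect_true(kept[7])
})

test_that("pooled t, df and Cohen's d match the textbook formulas", {
  a <- c(3.1, 2.8, 4.0, 3.3, 2.9)
  b <- c(2.2, 2.6, 1.9, 2.8, 2.4)
  res <- two_sample_t(a, b)
  sp2 <- ((5 - 1) * var(a) + (5 - 1) * var(b)) / 8
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  expect_equal(res$statistic, t_hand, tolerance = 1e-10)
  expect_equal(res$df, 8)
  expect_equal(res$p_raw, 2 * pt(-abs(t_hand), 8), tolerance = 1e-10)
  expect_equal(res$effect_size, (mean(a) - mean(b)) / sqrt(sp2),
               tolerance = 1e-10)

  same <- two_sample_t(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$effect_size, 0)
  expect_error(two_sample_t(c(1, 1), c(2, 2)), "infinite")
})

test_that("d = 0.8 arises from a 0.8 pooled-sd mean difference", {
  a <- c(1.8 - 1, 1.8 + 1, 1.8 - 1, 1.8 + 1, 1.8)
  b <- c(1.0 - 1, 1.0 + 1, 1.0 - 1, 1.0 + 1, 1.0)
  res <- two_sample_t(a, b)
  expect_equal(res$effect_size, 0.8 / sd(a), tolerance = 1e-10)
  a2 <- a / sd(a); b2 <- b / sd(b)            # rescale to pooled sd 1
  expect_equal(two_sample_t(a2, b2)$effect_size, 0.8, tolerance = 1e-10)
})

test_that("Pearson r matches the covariance formula with df = n - 2", {
  x <- c(1.2, 2.4, 3.1, 4.8, 5.0, 6.1)
  y <- c(2.0, 2.2, 3.9, 4.1, 5.5, 5.9)
  res <- pearson_r(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$statistic, r_hand, tolerance = 1e-12)
  expect_equal(res$df, 4)
  t_hand <- r_hand * sqrt(4 / (1 - r_hand^2))
  expect_equal(res$p_raw, 2 * pt(-abs(t_hand), 4), tolerance = 1e-10)

  expect_equal(pearson_r(x, 2 * x + 1)$statistic, 1, tolerance = 1e-12)
  y_orth <- residuals(lm(y ~ x))
  expect_lt(abs(pearson_r(x, y_orth)$statistic), 1e-12)
  expect_error(pearson_r(x, rep(1, 6)), "constant")
})

test_that("Bonferroni correction multiplies, caps at 1, and is monotone", {
  expect_equal(bonferroni(0.03, 7), 0.21)
  expect_equal(bonferroni(0.2, 1), 0.2)
  expect_equal(bonferroni(0.5, 3), 1.0)
  ps <- seq(0, 0.4, by = 0.05)
  expect_true(all(diff(bonferroni(ps, 5)) >= 0))
  expect_true(all(bonferroni(ps, 50) <= 1))
})

test_that("mixed ANOVA SS terms match the brute-force decomposition", {
  set.seed(21)
  tab <- make_mixed_table(replicate(8, rnorm(2, mean = c(10, 12)),
                                    simplify = FALSE),
                          rep(c("A", "B"), each = 4))
  res <- mixed_anova_2x2(tab)
  ss <- attr(res, "ss")
  oracle <- ss_oracle(tab)
  expect_equal(ss$ss[ss$term == "group"], oracle["group"],
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(ss$ss[ss$term == "subject_within_group"], oracle["subj"],
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(ss$ss[ss$term == "time"], oracle["time"],
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(ss$ss[ss$term == "group:time"], oracle["int"],
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(ss$ss[ss$term == "time:subject_within_group"], oracle["err"],
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(sum(ss$ss), oracle["total"], ignore_attr = TRUE,
               tolerance = 1e-10)
  # partial eta squared from its own error stratum
  expect_equal(res$effect_size[res$name == "group"],
               oracle[["group"]] / (oracle[["group"]] + oracle[["subj"]]),
               tolerance = 1e-10)
  expect_equal(res$effect_size[res$name == "group:time"],
               oracle[["int"]] / (oracle[["int"]] + oracle[["err"]]),
               tolerance = 1e-10)
})

test_that("degenerate mixed designs behave as defined", {
  const <- make_mixed_table(replicate(8, c(3, 3), simplify = FALSE),
                            rep(c("A", "B"), each = 4))
  res <- mixed_anova_2x2(const)
  expect_true(all(res$statistic == 0))
  expect_true(all(res$effect_size == 0))

  # parallel change in both groups: zero interaction SS
  set.seed(5)
  base <- rnorm(8)
  par_tab <- make_mixed_table(lapply(base, function(b) c(b, b + 2)),
                              rep(c("A", "B"), each = 4))
  ss <- attr(mixed_anova_2x2(par_tab), "ss")
  expect_lt(ss$ss[ss$term == "group:time"], 1e-20)

  missing_level <- const[-2, ]
  expect_error(mixed_anova_2x2(missing_level), "exactly one value")
})

test_that("t squared equals the one-way between-groups F", {
  set.seed(31)
  a <- rnorm(9, 1); b <- rnorm(12, 0)
  t_val <- two_sample_t(a, b)$statistic
  # brute-force one-way decomposition
  all_v <- c(a, b); gm <- mean(all_v)
  ss_b <- 9 * (mean(a) - gm)^2 + 12 * (mean(b) - gm)^2
  ss_w <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  f_val <- (ss_b / 1) / (ss_w / 19)
  expect_equal(t_val^2, f_val, tolerance = 1e-10)
})

test_that("compare_groups applies exclusion, correction, and validates names", {
  set.seed(41)
  mt <- data.frame(subject_id = sprintf("s%02d", 1:20),
                   group = rep(c("SU", "NU"), each = 10),
                   m1 = rnorm(20), m2 = rnorm(20))
  res <- compare_groups(mt, measures = c("m1", "m2"))
  expect_equal(nrow(res), 2)
  expect_equal(res$p_corrected, bonferroni(res$p_raw, 2))
  single <- compare_groups(mt, measures = "m1")
  expect_true(is.na(single$p_corrected))
  expect_error(compare_groups(mt, measures = "nope"), "known measures")
  # outlier exclusion reflected in reported group sizes
  mt$m1[1] <- 1000
  res2 <- compare_groups(mt, measures = "m1")
  expect_gte(res2$n_excluded, 1)                  # the planted outlier goes
  expect_equal(res2$n_a + res2$n_b, 20 - res2$n_excluded)
  expect_equal(compare_groups(mt, measures = "m1",
                              threshold_sd = Inf)$n_excluded, 0)
})

test_that("empirical power at d = 0.8, n = 16 vs 35 matches the analytic value", {
  n1 <- 16; n2 <- 35; d <- 0.8
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  crit <- qt(0.975, df)
  analytic <- 1 - pt(crit, df, ncp) + pt(-crit, df, ncp)
  set.seed(51)
  rej <- mean(replicate(500, {
    two_sample_t(rnorm(n1, d), rnorm(n2, 0))$p_raw < 0.05
  }))
  expect_lt(abs(rej - analytic), 0.05)
})
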