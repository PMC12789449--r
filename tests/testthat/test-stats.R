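test_that("group_summary computes n-1 statistics", {
  g <- group_summary(c(1, 2, 3), method = 1)
  expect_equal(g$mean, 2)
  expect_equal(g$sd, 1)
  expect_equal(g$sem, 1 / sqrt(3))
  const <- group_summary(rep(0.5, 10))
  expect_equal(const$sd, 0)
  expect_equal(const$sem, 0)
  expect_error(group_summary(1), "insufficient")
})

test_that("levene_test matches a direct evaluation and car::leveneTest", {
  g1 <- c(1.2, 0.8, 1.5, 0.9, 2.1)
  g2 <- c(0.2, 0.25, 0.3, 0.15)
  lev <- levene_test(g1, g2)
  # direct formula: one-way ANOVA F on |x - group mean|
  z <- c(abs(g1 - mean(g1)), abs(g2 - mean(g2)))
  grp <- factor(rep(1:2, c(5, 4)))
  ref <- anova(lm(z ~ grp))
  expect_equal(lev$F, ref$`F value`[1], tolerance = 1e-12)
  expect_equal(lev$p, ref$`Pr(>F)`[1], tolerance = 1e-12)
  # independent implementation
  cc <- car::leveneTest(c(g1, g2), grp, center = mean)
  expect_equal(lev$F, cc$`F value`[1], tolerance = 1e-10)
  # identical groups: no between-group spread at all
  expect_equal(levene_test(g1, g1)$F, 0)
  expect_error(levene_test(1, g2), "insufficient")
})

test_that("t_test_independent reports both variance assumptions correctly", {
  g1 <- c(1, 2, 3)
  g2 <- c(1, 2, 3, 4, 5, 6)
  rep_ <- t_test_independent(g1, g2)
  expect_equal(rep_$mean_difference, mean(g1) - mean(g2))
  expect_equal(rep_$equal$df, length(g1) + length(g2) - 2)
  # Welch-Satterthwaite df by hand
  a <- var(g1) / 3
  b <- var(g2) / 6
  df_w <- (a + b)^2 / (a^2 / 2 + b^2 / 5)
  expect_equal(rep_$welch$df, df_w, tolerance = 1e-12)
  # Student t by hand (pooled variance)
  sp2 <- (2 * var(g1) + 5 * var(g2)) / 7
  t_hand <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / 3 + 1 / 6))
  expect_equal(rep_$equal$t, t_hand, tolerance = 1e-12)
  # CI brackets the mean difference
  expect_lte(rep_$equal$ci_low, rep_$mean_difference)
  expect_gte(rep_$equal$ci_high, rep_$mean_difference)
  # identical groups
  same <- t_test_independent(g2, g2)
  expect_equal(same$equal$t, 0)
  expect_equal(same$equal$p, 1)
  # undefined when both groups are constant and equal
  expect_error(t_test_independent(rep(0, 5), rep(0, 5)),
               class = "implacc_undefined_t")
})

test_that("Welch df never exceeds Student df and converges when balanced", {
  set.seed(83)
  for (i in 1:25) {
    g1 <- rnorm(sample(3:20, 1), sd = runif(1, 0.5, 3))
    g2 <- rnorm(sample(3:20, 1), sd = runif(1, 0.5, 3))
    r <- t_test_independent(g1, g2)
    expect_lte(r$welch$df, r$equal$df + 1e-12)
  }
  # balanced equal-variance limit: Welch df -> Student df
  n <- 1e4
  big <- t_test_independent(rnorm(n), rnorm(n))
  expect_lt(abs(big$welch$df - big$equal$df) / big$equal$df, 0.01)
})

test_that("build_reports reproduces the packaged study (full precision)", {
  # regression values computed from the packaged 2-dp table itself
  rep_ <- build_reports(example_deviation_table())
  a <- rep_$deviation_a
  expect_equal(a$summaries[[1]]$mean, 0.4515, tolerance = 1e-10)
  expect_equal(a$summaries[[2]]$mean, 1.2230, tolerance = 1e-10)
  expect_equal(a$summaries[[1]]$sd, 0.1599103, tolerance = 1e-6)
  expect_equal(a$levene$F, 8.1914325, tolerance = 1e-6)
  expect_equal(a$ttest$equal$t, -5.4706563, tolerance = 1e-6)
  expect_equal(a$ttest$welch$df, 21.5985213, tolerance = 1e-6)
  b <- rep_$deviation_b
  expect_equal(b$ttest$equal$t, -6.5424453, tolerance = 1e-6)
  expect_equal(b$levene$F, 16.1526165, tolerance = 1e-6)
  ang <- rep_$angle_error
  expect_equal(ang$ttest$equal$t, -1.7936550, tolerance = 1e-6)
  expect_equal(ang$ttest$equal$p, 0.080830, tolerance = 1e-4)
})

test_that("build_reports surfaces undefined tests and grouping errors", {
  zero <- data.frame(block = rep(1:10, each = 4),
                     deviation_a = 0, deviation_b = 0, angle_error = 0)
  rep_ <- build_reports(zero)
  for (m in names(rep_)) {
    expect_null(rep_[[m]]$ttest)
    expect_match(rep_[[m]]$error, "undefined")
  }
  d <- example_deviation_table()
  expect_error(build_reports(d, grouping = c(`1` = 1)), "missing blocks")
  expect_error(build_reports(d, grouping = setNames(rep(1, 10), 1:10)),
               "exactly two methods")
})
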