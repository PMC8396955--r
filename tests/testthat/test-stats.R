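# Cohort statistics: KS normality screen, two-sample t, ANOVA + Tukey HSD.
# Closed-form implementations are checked against the stock R machinery
# (ks.test, t.test, aov/TukeyHSD) as independent oracles.

test_that("KS normality screen matches ks.test and classifies clear cases", {
  x_norm <- withr::with_seed(1, stats::rnorm(1000))
  r <- ks_normality(x_norm)
  ref <- stats::ks.test(x_norm, "pnorm", mean(x_norm), stats::sd(x_norm),
                        exact = FALSE)
  expect_lt(abs(r$statistic - unname(ref$statistic)), 1e-6)
  expect_lt(abs(r$p_value - ref$p.value), 1e-6)
  expect_gt(r$p_value, 0.05)

  x_exp <- withr::with_seed(2, stats::rexp(1000))
  r2 <- ks_normality(x_exp)
  ref2 <- stats::ks.test(x_exp, "pnorm", mean(x_exp), stats::sd(x_exp),
                         exact = FALSE)
  expect_lt(abs(r2$statistic - unname(ref2$statistic)), 1e-6)
  expect_lt(r2$p_value, 0.05)

  expect_error(ks_normality(c(1, 1, 1)), class = "cryoredox_degenerate_error")
  expect_error(ks_normality(c(1, 2)), class = "cryoredox_param_error")
})

test_that("the pooled t test reproduces the closed form and t.test", {
  a <- group_summary(c(1, 2, 3), "a")
  b <- group_summary(c(4, 5, 6), "b")
  cmp <- two_group_test(a, b)
  expect_equal(abs(cmp$statistic), 3.674, tolerance = 5e-4)
  expect_equal(cmp$dof, 4)
  expect_equal(cmp$p_value, 0.0213, tolerance = 5e-3)

  ref <- stats::t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_lt(abs(cmp$statistic - unname(ref$statistic)), 1e-6)
  expect_lt(abs(cmp$p_value - ref$p.value), 1e-6)
  expect_lt(max(abs(c(cmp$ci95_low, cmp$ci95_high) - ref$conf.int)), 1e-6)

  # CI endpoints are mean_diff +/- t_{0.975, dof} * SE
  se <- sqrt(((3 - 1) * 1 + (3 - 1) * 1) / 4 * (1 / 3 + 1 / 3))
  expect_equal(cmp$ci95_low, -3 - stats::qt(0.975, 4) * se, tolerance = 1e-12)
  expect_equal(cmp$ci95_high, -3 + stats::qt(0.975, 4) * se, tolerance = 1e-12)
  expect_equal(cmp$percent_decrease,
               percent_decrease(a$group_mean, b$group_mean))
})

test_that("the Welch variant matches t.test with unequal variances", {
  x <- withr::with_seed(11, stats::rnorm(8, 1, 0.2))
  y <- withr::with_seed(12, stats::rnorm(13, 0.8, 0.6))
  cmp <- two_group_test(group_summary(x, "x"), group_summary(y, "y"), "welch")
  ref <- stats::t.test(x, y)
  expect_lt(abs(cmp$statistic - unname(ref$statistic)), 1e-6)
  expect_lt(abs(cmp$dof - unname(ref$parameter)), 1e-6)
  expect_lt(abs(cmp$p_value - ref$p.value), 1e-6)
})

test_that("degenerate two-group inputs behave as specified", {
  same <- group_summary(c(2, 2, 2), "a")
  cmp <- two_group_test(same, group_summary(c(2, 2, 2), "b"))
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)
  expect_equal(c(cmp$ci95_low, cmp$ci95_high), c(0, 0))
  expect_error(two_group_test(same, group_summary(c(3, 3, 3), "b")),
               class = "cryoredox_degenerate_error")
  expect_error(two_group_test(group_summary(1, "a"), same),
               class = "cryoredox_param_error")
  cmp_id <- two_group_test(group_summary(c(1, 2, 3), "a"),
                           group_summary(c(1, 2, 3), "b"))
  expect_equal(cmp_id$statistic, 0)
  expect_equal(cmp_id$p_value, 1)
})

test_that("p < alpha iff the 95% CI excludes zero (pooled t)", {
  withr::with_seed(42, {
    for (rep in 1:25) {
      a <- group_summary(stats::rnorm(sample(3:9, 1), 1, 0.3), "a")
      b <- group_summary(stats::rnorm(sample(3:12, 1), 1 + stats::runif(1, -0.6, 0.6), 0.3), "b")
      cmp <- two_group_test(a, b)
      excludes <- cmp$ci95_low > 0 || cmp$ci95_high < 0
      expect_identical(cmp$p_value < 0.05, excludes)
    }
  })
})

test_that("ANOVA + Tukey HSD matches aov/TukeyHSD and handles ties", {
  g1 <- group_summary(c(1, 2, 3), "g1")
  g2 <- group_summary(c(1, 2, 3), "g2")
  g3 <- group_summary(c(10, 11, 12), "g3")
  res <- anova_posthoc(list(g1, g2, g3))
  cmp <- res$comparisons
  sig <- cmp$p_value < 0.05
  expect_identical(sig, c(FALSE, TRUE, TRUE))

  df <- data.frame(y = c(1, 2, 3, 1, 2, 3, 10, 11, 12),
                   g = rep(c("g1", "g2", "g3"), each = 3))
  fit <- stats::aov(y ~ g, data = df)
  expect_lt(abs(res$anova$f_statistic - summary(fit)[[1]]$`F value`[1]), 1e-6)
  expect_lt(abs(res$anova$p_value - summary(fit)[[1]]$`Pr(>F)`[1]), 1e-6)
  tk <- stats::TukeyHSD(fit)$g
  # our rows are (g1,g2), (g1,g3), (g2,g3); TukeyHSD's are g2-g1, g3-g1, g3-g2
  expect_lt(max(abs(cmp$p_value - unname(tk[, "p adj"]))), 1e-6)
  expect_lt(max(abs(cmp$mean_diff - (-unname(tk[, "diff"])))), 1e-9)
  expect_lt(max(abs(cmp$ci95_low - (-unname(tk[, "upr"])))), 1e-6)
  expect_lt(max(abs(cmp$ci95_high - (-unname(tk[, "lwr"])))), 1e-6)

  # three identical groups: omnibus and pairwise all null
  res0 <- anova_posthoc(list(g1, g2, group_summary(c(1, 2, 3), "g4")))
  expect_equal(res0$anova$f_statistic, 0)
  expect_equal(res0$anova$p_value, 1)
  expect_true(all(res0$comparisons$p_value == 1))
})

test_that("ANOVA with unequal n matches the Tukey-Kramer reference", {
  withr::with_seed(77, {
    y <- c(stats::rnorm(5, 1, 0.3), stats::rnorm(9, 1.2, 0.3),
           stats::rnorm(7, 0.8, 0.3))
    g <- rep(c("a", "b", "c"), c(5, 9, 7))
  })
  res <- anova_posthoc(list(group_summary(y[g == "a"], "a"),
                            group_summary(y[g == "b"], "b"),
                            group_summary(y[g == "c"], "c")))
  tk <- stats::TukeyHSD(stats::aov(y ~ g))$g
  expect_lt(max(abs(res$comparisons$p_value - unname(tk[, "p adj"]))), 1e-6)
  expect_true(all(res$comparisons$p_value >=
                    res$comparisons$p_unadjusted - 1e-12))
})

test_that("balanced two-group ANOVA F equals the squared pooled t", {
  withr::with_seed(8, {
    x <- stats::rnorm(6, 1, 0.2)
    y <- stats::rnorm(6, 1.1, 0.2)
  })
  a <- group_summary(x, "a"); b <- group_summary(y, "b")
  res <- anova_posthoc(list(a, b))
  cmp <- two_group_test(a, b)
  expect_equal(res$anova$f_statistic, cmp$statistic^2, tolerance = 1e-12)
})

test_that("compare_cohort wires groups, normality and the designed test", {
  tab <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:9),
    group = rep(c("control", "severe", "mild"), each = 3),
    mean_rr = c(1.1, 1.2, 1.3, 0.8, 0.85, 0.9, 1.0, 1.05, 1.1))
  res <- compare_cohort(tab, "three_group", ref_group = "control")
  expect_equal(res$group_table$group[1], "control")
  expect_equal(nrow(res$comparisons), 3)
  expect_equal(nrow(res$normality), 3)
  expect_true(all(c("p_value", "percent_decrease") %in% names(tidy(res))))
  expect_equal(nrow(glance(res)), 1)

  two <- compare_cohort(dplyr::filter(tab, group != "mild"), "two_group",
                        ref_group = "control")
  expect_equal(nrow(two$comparisons), 1)
  expect_equal(two$comparisons$percent_decrease,
               percent_decrease(mean(c(1.1, 1.2, 1.3)), mean(c(0.8, 0.85, 0.9))))

  bad <- tibble::tibble(group = c("a", "a", "b"), mean_rr = c(1, 2, 3))
  expect_error(compare_cohort(bad, "two_group"), "fewer than two",
               class = "cryoredox_param_error")
  expect_error(compare_cohort(tab, "two_group"),
               class = "cryoredox_param_error")
})

test_that("group summaries obey their defining identities", {
  gs <- group_summary(c(1.1, 0.9, 1.3), "g")
  expect_equal(gs$group_mean, mean(c(1.1, 0.9, 1.3)))
  expect_equal(gs$n, 3)
  expect_error(group_summary(numeric(0)), class = "cryoredox_param_error")
})
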