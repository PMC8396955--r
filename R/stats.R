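# Cohort statistics over per-sample mean redox ratios: normality screening,
# two-group t tests with confidence intervals and percent difference, and
# one-way ANOVA with Tukey HSD post hoc for three-genotype designs. The test
# statistics are computed in closed form on base-R distribution functions so
# the degenerate cases a redox cohort can produce (zero variance) have
# defined behaviour; stock implementations serve as cross-check oracles in
# the test suite.

#' Summarise one group's per-sample means
#'
#' @param sample_means Numeric vector of per-sample mean redox ratios.
#' @param group Group label.
#' @return An object of class `group_summary`: list with `group`,
#'   `sample_means`, `group_mean`, `group_sd`, `n`.
#' @export
group_summary <- function(sample_means, group = "group") {
  sample_means <- as.numeric(sample_means)
  if (length(sample_means) < 1 || anyNA(sample_means)) {
    rlang::abort(sprintf("Group '%s' needs at least one non-missing mean.", group),
                 class = "cryoredox_param_error")
  }
  structure(
    list(group = as.character(group), sample_means = sample_means,
         group_mean = mean(sample_means),
         group_sd = if (length(sample_means) > 1) stats::sd(sample_means) else NA_real_,
         n = length(sample_means)),
    class = "group_summary"
  )
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> '%s': n = %d, mean %.4f, SD %s\n", x$group,
              x$n, x$group_mean,
              if (is.na(x$group_sd)) "NA" else sprintf("%.4f", x$group_sd)))
  invisible(x)
}

# Asymptotic Kolmogorov distribution tail: P(sqrt(n) D > t).
kolmogorov_tail <- function(t) {
  if (t < 1e-8) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(max(p, 0), 1)
}

#' One-sample Kolmogorov-Smirnov check against a fitted normal
#'
#' Tests the per-sample means against a normal distribution whose mean and SD
#' are estimated from the same data, with the p-value from the asymptotic
#' Kolmogorov distribution. Because the parameters are estimated, the p-value
#' is conservative (the Lilliefors effect): true rejection rates run below
#' nominal, so non-rejection here is a weak sanity screen, not a proof of
#' normality.
#'
#' @param sample_means Numeric vector, length >= 3, non-constant.
#' @return List with `statistic` (the KS D) and `p_value`.
#' @export
ks_normality <- function(sample_means) {
  x <- as.numeric(sample_means)
  n <- length(x)
  if (n < 3) {
    rlang::abort("Need at least 3 values for the normality check.",
                 class = "cryoredox_param_error")
  }
  s <- stats::sd(x)
  if (s == 0) {
    rlang::abort("Constant sample: normality check is degenerate.",
                 class = "cryoredox_degenerate_error")
  }
  z <- sort((x - mean(x)) / s)
  fitted <- stats::pnorm(z)
  d_plus <- max(seq_len(n) / n - fitted)
  d_minus <- max(fitted - (seq_len(n) - 1) / n)
  d <- max(d_plus, d_minus)
  list(statistic = d, p_value = kolmogorov_tail(sqrt(n) * d))
}

comparison_row <- function(group_a, group_b, mean_diff, se, dof, statistic,
                           p_value, ci, percent_dec, method) {
  tibble::tibble(
    group_a = group_a, group_b = group_b, mean_diff = mean_diff,
    ci95_low = ci[1], ci95_high = ci[2], statistic = statistic,
    dof = dof, p_value = p_value, percent_decrease = percent_dec,
    method = method)
}

#' Two-sample t test between two group summaries
#'
#' Two-sided test of equal means with a 95% confidence interval for the
#' difference (reference minus test) and the percent decrease of the test
#' group relative to the reference. The default pools the two variances;
#' `variant = "welch"` uses the Welch-Satterthwaite approximation. With zero
#' variance in both groups the test is defined as p = 1 and CI = [0, 0] when
#' the means agree, and as a degeneracy error when they differ.
#'
#' @param a Reference [group_summary()] (e.g. control).
#' @param b Test [group_summary()] (e.g. mutant).
#' @param variant `"pooled"` (default) or `"welch"`.
#' @param conf_level Confidence level for the interval. Default 0.95.
#' @return One comparison row (tibble): groups, mean difference, CI bounds,
#'   t statistic, degrees of freedom, p-value, percent decrease, method.
#' @export
two_group_test <- function(a, b, variant = c("pooled", "welch"),
                           conf_level = 0.95) {
  variant <- match.arg(variant)
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  if (a$n < 2 || b$n < 2) {
    rlang::abort("Both groups need at least two samples.",
                 class = "cryoredox_param_error")
  }
  diff <- a$group_mean - b$group_mean
  va <- a$group_sd^2
  vb <- b$group_sd^2
  pdec <- percent_decrease(a$group_mean, b$group_mean)
  if (variant == "pooled") {
    dof <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * va + (b$n - 1) * vb) / dof
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    method <- "ttest_pooled"
  } else {
    se <- sqrt(va / a$n + vb / b$n)
    dof <- (va / a$n + vb / b$n)^2 /
      ((va / a$n)^2 / (a$n - 1) + (vb / b$n)^2 / (b$n - 1))
    method <- "ttest_welch"
  }
  if (!is.finite(se) || se == 0) {
    if (diff == 0) {
      return(comparison_row(a$group, b$group, 0, 0, dof, 0, 1, c(0, 0),
                            pdec, method))
    }
    rlang::abort("Zero variance with unequal means: t test is degenerate.",
                 class = "cryoredox_degenerate_error")
  }
  tstat <- diff / se
  p <- 2 * stats::pt(-abs(tstat), dof)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, dof)
  comparison_row(a$group, b$group, diff, se, dof, tstat, p,
                 diff + c(-1, 1) * tcrit * se, pdec, method)
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Computes the omnibus one-way ANOVA F test across all groups, then all
#' pairwise comparisons with Tukey's honestly-significant-difference
#' adjustment (studentized range; Tukey-Kramer standard errors for unequal
#' group sizes). Each pair also carries its unadjusted pooled-t p-value and a
#' family-wise 95% confidence interval.
#'
#' @param groups List of [group_summary()] objects (>= 2; >= 3 for a
#'   three-genotype design), each with n >= 2.
#' @param conf_level Family-wise confidence level. Default 0.95.
#' @return A `cohort_result` (see [compare_cohort()]) with `anova` (F, dofs,
#'   p) and one comparison row per pair, where `p_value` is the
#'   Tukey-adjusted p and `p_unadjusted` the pairwise pooled-t p.
#' @export
anova_posthoc <- function(groups, conf_level = 0.95) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(!vapply(groups, inherits, logical(1), "group_summary"))) {
    rlang::abort("`groups` must be a list of group_summary objects.",
                 class = "cryoredox_param_error")
  }
  ns <- vapply(groups, `[[`, numeric(1), "n")
  if (any(ns < 2)) {
    rlang::abort(sprintf("Every group needs n >= 2 (offender: '%s').",
                         groups[[which(ns < 2)[1]]]$group),
                 class = "cryoredox_param_error")
  }
  k <- length(groups)
  ntot <- sum(ns)
  means <- vapply(groups, `[[`, numeric(1), "group_mean")
  grand <- sum(ns * means) / ntot
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g$sample_means - g$group_mean)^2),
                          numeric(1)))
  df_between <- k - 1
  df_within <- ntot - k
  mse <- ss_within / df_within
  if (mse == 0 && ss_between == 0) {
    fstat <- 0; p_f <- 1
  } else if (mse == 0) {
    rlang::abort("Zero within-group variance with unequal means: ANOVA is degenerate.",
                 class = "cryoredox_degenerate_error")
  } else {
    fstat <- (ss_between / df_between) / mse
    p_f <- stats::pf(fstat, df_between, df_within, lower.tail = FALSE)
  }
  pairs <- utils::combn(k, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    diff <- means[i1] - means[i2]
    se_q <- sqrt(mse / 2 * (1 / ns[i1] + 1 / ns[i2]))
    se_t <- sqrt(mse * (1 / ns[i1] + 1 / ns[i2]))
    if (mse == 0) {
      q <- 0; p_adj <- 1; p_un <- 1; ci <- c(0, 0)
    } else {
      q <- abs(diff) / se_q
      p_adj <- stats::ptukey(q, k, df_within, lower.tail = FALSE)
      p_un <- 2 * stats::pt(-abs(diff / se_t), df_within)
      qcrit <- stats::qtukey(conf_level, k, df_within)
      ci <- diff + c(-1, 1) * qcrit * se_q
    }
    row <- comparison_row(groups[[i1]]$group, groups[[i2]]$group, diff, se_q,
                          df_within, q, p_adj,
                          ci, percent_decrease(means[i1], means[i2]),
                          "anova_tukey")
    row$p_unadjusted <- p_un
    row
  })
  new_cohort_result(
    groups = groups,
    comparisons = dplyr::bind_rows(rows),
    anova = list(f_statistic = fstat, df_between = df_between,
                 df_within = df_within, p_value = p_f),
    method = "anova_tukey")
}

groups_tibble <- function(groups) {
  dplyr::bind_rows(lapply(groups, function(g) tibble::tibble(
    group = g$group, n = g$n, group_mean = g$group_mean, group_sd = g$group_sd)))
}

new_cohort_result <- function(groups, comparisons, anova = NULL,
                              normality = NULL, method, alpha = 0.05) {
  structure(
    list(groups = groups, group_table = groups_tibble(groups),
         comparisons = comparisons, anova = anova, normality = normality,
         method = method, alpha = alpha),
    class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %s, alpha = %g\n", x$method, x$alpha))
  print(x$group_table)
  if (!is.null(x$anova)) {
    cat(sprintf("ANOVA: F(%d, %d) = %.4g, p = %.4g\n", x$anova$df_between,
                x$anova$df_within, x$anova$f_statistic, x$anova$p_value))
  }
  print(x$comparisons)
  invisible(x)
}

#' Compare a cohort of per-sample mean redox ratios across groups
#'
#' Builds a [group_summary()] per group, screens each group of size >= 3
#' with the Kolmogorov-Smirnov normality check, then runs the
#' design-appropriate test: a two-sample t test for `design = "two_group"`
#' (reference group first) or one-way ANOVA with Tukey HSD for
#' `design = "three_group"`. Percent decreases are reported relative to the
#' first (reference) group in two-group designs and pairwise otherwise.
#'
#' @param samples Data frame with one row per sample: a `group` column and a
#'   mean-RR column (`mean_rr`, or set `value_col`). A pipeline summary table
#'   or a cohort manifest joined to summaries both qualify.
#' @param design `"two_group"` or `"three_group"`.
#' @param ref_group Reference (control) group label; defaults to the first
#'   group in order of appearance.
#' @param variant t-test variant for two-group designs, `"pooled"` or
#'   `"welch"`.
#' @param alpha Significance level recorded with the result. Default 0.05.
#' @param value_col Name of the per-sample mean column. Default `"mean_rr"`.
#' @return A `cohort_result`: group table, comparison rows (with CI bounds,
#'   test statistics, p-values, percent decreases), per-group normality
#'   screens, the method run, and `alpha`. Use [generics::tidy()] /
#'   [generics::glance()] to extract tibbles.
#' @export
compare_cohort <- function(samples, design = c("two_group", "three_group"),
                           ref_group = NULL, variant = c("pooled", "welch"),
                           alpha = 0.05, value_col = "mean_rr") {
  design <- match.arg(design)
  variant <- match.arg(variant)
  samples <- tibble::as_tibble(samples)
  if (!all(c("group", value_col) %in% names(samples))) {
    rlang::abort(sprintf("`samples` needs columns 'group' and '%s'.", value_col),
                 class = "cryoredox_param_error")
  }
  lev <- unique(as.character(samples$group))
  if (!is.null(ref_group)) {
    if (!ref_group %in% lev) {
      rlang::abort(sprintf("Reference group '%s' not present.", ref_group),
                   class = "cryoredox_param_error")
    }
    lev <- c(ref_group, setdiff(lev, ref_group))
  }
  groups <- lapply(lev, function(g)
    group_summary(samples[[value_col]][samples$group == g], g))
  ns <- vapply(groups, `[[`, numeric(1), "n")
  if (any(ns < 2)) {
    rlang::abort(sprintf("Group '%s' has fewer than two samples.",
                         lev[which(ns < 2)[1]]),
                 class = "cryoredox_param_error")
  }
  n_expected <- switch(design, two_group = 2L, three_group = 3L)
  if (length(lev) != n_expected) {
    rlang::abort(sprintf("Design '%s' expects %d groups, found %d.",
                         design, n_expected, length(lev)),
                 class = "cryoredox_param_error")
  }
  normality <- dplyr::bind_rows(lapply(groups, function(g) {
    if (g$n >= 3 && !isTRUE(g$group_sd == 0)) {
      ks <- ks_normality(g$sample_means)
      tibble::tibble(group = g$group, ks_statistic = ks$statistic,
                     ks_p = ks$p_value)
    } else {
      tibble::tibble(group = g$group, ks_statistic = NA_real_, ks_p = NA_real_)
    }
  }))
  res <- if (design == "two_group") {
    new_cohort_result(groups,
                      two_group_test(groups[[1]], groups[[2]], variant),
                      method = paste0("ttest_", variant), alpha = alpha)
  } else {
    anova_posthoc(groups)
  }
  res$normality <- normality
  res$alpha <- alpha
  res
}

#' Tidy the pairwise comparisons of a cohort result
#'
#' @param x A `cohort_result`.
#' @param ... Unused.
#' @return Tibble of comparison rows with a logical `significant` column at
#'   the result's alpha.
#' @export
tidy.cohort_result <- function(x, ...) {
  dplyr::mutate(x$comparisons, significant = .data$p_value < x$alpha)
}

#' One-row summary of a cohort result
#'
#' @param x A `cohort_result`.
#' @param ... Unused.
#' @return One-row tibble: method, number of groups, total n, the headline
#'   statistic and p-value (omnibus F for ANOVA designs, t otherwise), and
#'   alpha.
#' @export
glance.cohort_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_groups = nrow(x$group_table),
    n_total = sum(x$group_table$n),
    statistic = if (!is.null(x$anova)) x$anova$f_statistic else x$comparisons$statistic[1],
    p_value = if (!is.null(x$anova)) x$anova$p_value else x$comparisons$p_value[1],
    alpha = x$alpha)
}
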