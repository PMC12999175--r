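#' Construct a statistics result record
#'
#' Common container for group-level tests: statistic, degrees of
#' freedom, two-sided p, effect size, and correction metadata.
#'
#' @keywords internal
stat_result <- function(name, statistic, dof, p, effect_size = NA_real_,
                        effect_name = NA_character_, correction = "none",
                        m_comparisons = 1L, p_adjusted = NULL) {
  structure(
    list(name = name, statistic = statistic, dof = dof, p = p,
         effect_size = effect_size, effect_name = effect_name,
         correction = correction, m_comparisons = m_comparisons,
         p_adjusted = p_adjusted %||% p),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: stat = %.4f, dof = (%s), p = %.4g",
              x$name, x$statistic, paste(x$dof, collapse = ", "), x$p))
  if (!is.na(x$effect_size)) {
    cat(sprintf(", %s = %.4f", x$effect_name, x$effect_size))
  }
  if (x$correction != "none") {
    cat(sprintf(" [%s, m = %d, p_adj = %.4g]", x$correction,
                x$m_comparisons, x$p_adjusted))
  }
  cat("\n")
  invisible(x)
}

#' Mixed-design ANOVA interaction (2 x 2)
#'
#' Interaction F for a design with one two-level between-subject factor
#' (group) and one two-level within-subject factor, computed via
#' difference scores: for each subject the within-factor difference
#' a - b is formed and the pooled two-sample t between groups is
#' squared, giving F with dof (1, N - 2). For two-level factors this is
#' exact and free of sum-of-squares-type ambiguity, including with
#' unbalanced groups. Effect size is partial eta squared,
#' F / (F + df2).
#'
#' @param values_a,values_b numeric vectors: each subject's measurement
#'   in the two within-factor cells (same subject order).
#' @param groups factor/character of length `length(values_a)` with
#'   exactly 2 levels.
#' @return a `stat_result` with `statistic` = F.
#' @examples
#' g <- rep(c("s", "b"), each = 10)
#' a <- rnorm(20) + (g == "b") * 1
#' mixed_anova_interaction(a, rnorm(20), g)
#' @export
mixed_anova_interaction <- function(values_a, values_b, groups) {
  n <- length(values_a)
  if (length(values_b) != n || length(groups) != n) {
    stop("values_a, values_b and groups must have equal length")
  }
  keep <- stats::complete.cases(values_a, values_b, groups)
  if (any(!keep)) {
    warning(sum(!keep), " subject(s) with missing cells dropped")
    values_a <- values_a[keep]; values_b <- values_b[keep]
    groups <- groups[keep]
  }
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly 2 levels")
  ns <- table(groups)
  if (any(ns < 2L)) stop("each group needs at least 2 subjects")
  d <- values_a - values_b
  d1 <- d[groups == levels(groups)[1]]
  d2 <- d[groups == levels(groups)[2]]
  n1 <- length(d1); n2 <- length(d2)
  sp2 <- ((n1 - 1) * stats::var(d1) + (n2 - 1) * stats::var(d2)) /
    (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled variance of difference scores")
  tval <- (mean(d1) - mean(d2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  fval <- tval^2
  df2 <- n1 + n2 - 2
  p <- stats::pf(fval, 1, df2, lower.tail = FALSE)
  stat_result("group_by_condition_interaction", fval, c(1, df2), p,
              effect_size = fval / (fval + df2),
              effect_name = "partial_eta_sq")
}

#' Paired t-test with Cohen's d
#'
#' Two-sided paired t on `values_a - values_b`: t = mean(d) /
#' (sd(d) / sqrt(n)) with dof n - 1. Cohen's d = mean(d) / sd(d)
#' (sample SD, n - 1 denominator).
#'
#' @param values_a,values_b paired numeric vectors, length >= 3.
#' @return a `stat_result` with `statistic` = t, `effect_size` = d.
#' @examples
#' paired_ttest_cohend(c(2, 4, 6), c(1, 2, 3))
#' @export
paired_ttest_cohend <- function(values_a, values_b) {
  n <- length(values_a)
  if (length(values_b) != n) stop("paired vectors must have equal length")
  if (n < 3L) stop("need at least 3 pairs")
  d <- values_a - values_b
  sdd <- stats::sd(d)
  if (sdd == 0) stop("zero variance of paired differences")
  tval <- mean(d) / (sdd / sqrt(n))
  p <- 2 * stats::pt(abs(tval), n - 1, lower.tail = FALSE)
  stat_result("paired_t", tval, n - 1, p,
              effect_size = mean(d) / sdd, effect_name = "cohen_d")
}

#' Bonferroni adjustment
#'
#' p_adj = min(1, m * p). `m` defaults to the number of p-values
#' supplied (the family executed together).
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @param m family size (default `length(p_values)`).
#' @return adjusted p-values, clipped at 1.
#' @examples
#' bonferroni_adjust(c(0.02, 0.5), m = 3)
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  if (m < 1) stop("family size m must be >= 1")
  pmin(1, m * p_values)
}

#' Pearson-Filon z for two dependent overlapping correlations
#'
#' Tests r_jk against r_hk when both correlations share the variable k
#' (e.g. each adult group's connectivity matrix correlated with the
#' infant matrix). With
#' kappa = r_jh (1 - r_jk^2 - r_hk^2) -
#'         (r_jk r_hk / 2) (1 - r_jk^2 - r_hk^2 - r_jh^2),
#' the statistic is
#' z = sqrt(n) (r_jk - r_hk) /
#'     sqrt((1 - r_jk^2)^2 + (1 - r_hk^2)^2 - 2 kappa),
#' two-sided p from the standard normal. `n` is the number of paired
#' observations the correlations were computed from; for matrix-profile
#' correlations this is the number of vectorized cells.
#'
#' @param r_jk,r_hk the two correlations being compared (each with k).
#' @param r_jh correlation between the two non-shared variables.
#' @param n sample size (>= 4).
#' @return a `stat_result` with `statistic` = z.
#' @examples
#' pearson_filon_z(0.721, 0.524, 0.6, 45)
#' @export
pearson_filon_z <- function(r_jk, r_hk, r_jh, n) {
  for (r in list(r_jk = r_jk, r_hk = r_hk, r_jh = r_jh)) {
    check_scalar(r, "correlation", lower = -1, upper = 1,
                 strict_lower = TRUE, strict_upper = TRUE)
  }
  if (n < 4) stop("need n >= 4")
  kappa <- r_jh * (1 - r_jk^2 - r_hk^2) -
    0.5 * r_jk * r_hk * (1 - r_jk^2 - r_hk^2 - r_jh^2)
  disc <- (1 - r_jk^2)^2 + (1 - r_hk^2)^2 - 2 * kappa
  if (disc <= 0) {
    stop("degenerate correlation configuration: nonpositive variance ",
         "term (", signif(disc, 4), ")")
  }
  z <- sqrt(n) * (r_jk - r_hk) / sqrt(disc)
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  stat_result("pearson_filon_z", z, NA_real_, p)
}

#' One-way ANOVA with partial eta squared
#'
#' Standard one-way F across g groups: dof (g - 1, N - g); partial eta
#' squared = SS_between / (SS_between + SS_within) (equal to eta squared
#' in the one-way design).
#'
#' @param groups list of numeric vectors, one per group, each length
#'   >= 2.
#' @return a `stat_result` with `statistic` = F.
#' @examples
#' oneway_anova_eta(list(c(1, 2), c(3, 4)))
#' @export
oneway_anova_eta <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of at least 2 groups")
  }
  ns <- lengths(groups)
  if (any(ns < 2L)) stop("every group needs at least 2 observations")
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ss_b <- sum(ns * (vapply(groups, mean, numeric(1)) - grand)^2)
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups) - 1L
  df2 <- length(all_v) - length(groups)
  if (ss_w == 0) stop("zero within-group variance")
  fval <- (ss_b / df1) / (ss_w / df2)
  p <- stats::pf(fval, df1, df2, lower.tail = FALSE)
  stat_result("oneway_anova", fval, c(df1, df2), p,
              effect_size = ss_b / (ss_b + ss_w),
              effect_name = "partial_eta_sq")
}
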