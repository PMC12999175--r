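# explicit cell-means sum-of-squares oracle for the balanced 2x2
# mixed design (between: group, within: condition): interaction
# MS over the subject-by-condition error MS
ss_interaction_f <- function(a, b, g) {
  y <- c(a, b)
  cond <- rep(c("A", "B"), each = length(a))
  subj <- rep(seq_along(a), 2)
  g2 <- rep(as.character(g), 2)
  grand <- mean(y)
  cells <- tapply(y, list(g2, cond), mean)
  gm <- tapply(y, g2, mean)
  cm <- tapply(y, cond, mean)
  ns <- as.numeric(table(as.character(g)))
  ss_int <- sum(ns * (cells - outer(gm, cm, "+") + grand)^2)
  subj_mean <- tapply(y, subj, mean)
  # within-cell deviation net of each subject's own mean
  fitted_dev <- cells[cbind(g2, cond)] - gm[g2]
  resid <- (y - subj_mean[as.character(subj)]) - fitted_dev
  ss_err <- sum(resid^2)
  df_err <- length(a) - length(ns)
  (ss_int / (length(ns) - 1)) / (ss_err / df_err)
}

test_that("2x2 mixed interaction equals the difference-score t squared", {
  set.seed(1)
  for (i in 1:100) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    g <- rep(c("x", "y"), c(n1, n2))
    a <- rnorm(n1 + n2, mean = (g == "y") * rnorm(1))
    b <- rnorm(n1 + n2)
    res <- mixed_anova_interaction(a, b, g)
    d <- a - b
    tt <- t.test(d[g == "x"], d[g == "y"], var.equal = TRUE)
    expect_equal(res$statistic, unname(tt$statistic)^2, tolerance = 1e-8)
    expect_equal(res$p, tt$p.value, tolerance = 1e-8)
    expect_equal(res$dof, c(1, n1 + n2 - 2))
  }
})

test_that("mixed interaction matches the cell-means SS oracle", {
  set.seed(2)
  for (i in 1:50) {
    n <- sample(c(4, 6, 8), 1)          # balanced
    g <- rep(c("x", "y"), each = n)
    a <- rnorm(2 * n); b <- rnorm(2 * n)
    f_oracle <- ss_interaction_f(a, b, g)
    expect_equal(mixed_anova_interaction(a, b, g)$statistic, f_oracle,
                 tolerance = 1e-8)
  }
  # null-by-construction: identical mean difference scores
  g <- rep(c("x", "y"), each = 5)
  a <- c(1:5, 1:5) + 2   # same a-b pattern in both groups
  b <- c(1:5, 1:5)
  a[1] <- a[1] + 1e-3; a[6] <- a[6] + 1e-3  # avoid zero variance, keep equal means
  expect_lt(mixed_anova_interaction(a, b, g)$statistic, 1e-20)
  # contracts
  expect_error(mixed_anova_interaction(1:4, 1:4, c("x", "x", "y", "z")),
               "2 levels")
  expect_warning(mixed_anova_interaction(c(1, NA, 3, 4, 5, 6), rnorm(6),
                                         rep(c("x", "y"), each = 3)),
                 "dropped")
  expect_error(mixed_anova_interaction(1:3, 1:3, c("x", "y", "y")),
               "at least 2")
})

test_that("paired t and Cohen's d match hand arithmetic", {
  res <- paired_ttest_cohend(c(1, 2, 3) + c(5, 5, 5), c(5, 5, 5))
  expect_equal(res$statistic, 2 * sqrt(3))
  expect_equal(res$dof, 2)
  expect_equal(res$effect_size, 2)
  expect_equal(res$p, t.test(c(1, 2, 3))$p.value)
  # antisymmetry
  set.seed(3)
  a <- rnorm(20); b <- rnorm(20)
  r1 <- paired_ttest_cohend(a, b); r2 <- paired_ttest_cohend(b, a)
  expect_equal(r1$statistic, -r2$statistic)
  expect_equal(r1$effect_size, -r2$effect_size)
  expect_equal(r1$p, r2$p)
  # stats::t.test oracle on random data
  for (i in 1:50) {
    a <- rnorm(sample(3:15, 1)); b <- rnorm(length(a))
    res <- paired_ttest_cohend(a, b)
    tt <- t.test(a, b, paired = TRUE)
    expect_equal(res$statistic, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  }
  expect_error(paired_ttest_cohend(1:5, 1:5), "zero variance")
  expect_error(paired_ttest_cohend(1:2, 1:2), "3 pairs")
  # constant shift: d carries the sign of the shift
  expect_gt(paired_ttest_cohend(rnorm(9) + 5, rnorm(9))$effect_size, 0)
})

test_that("Bonferroni adjustment is min(1, m p) and never decreases p", {
  expect_equal(bonferroni_adjust(0.02, m = 3), 0.06)
  expect_equal(bonferroni_adjust(0.5, m = 4), 1)
  expect_equal(bonferroni_adjust(c(0.1, 0.2), m = 1), c(0.1, 0.2))
  set.seed(4)
  p <- runif(100)
  expect_true(all(bonferroni_adjust(p) >= p))
  expect_equal(bonferroni_adjust(p), stats::p.adjust(p, "bonferroni"),
               tolerance = 1e-12)
  expect_error(bonferroni_adjust(1.2), "0, 1")
  expect_error(bonferroni_adjust(0.5, m = 0), "m")
})

test_that("Pearson-Filon z follows its closed form and symmetries", {
  # equal correlations: z = 0, p = 1
  r0 <- pearson_filon_z(0.5, 0.5, 0.3, 100)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  # closed-form check at arbitrary values
  rjk <- 0.721; rhk <- 0.524; rjh <- 0.4; n <- 45
  k <- rjh * (1 - rjk^2 - rhk^2) -
    0.5 * rjk * rhk * (1 - rjk^2 - rhk^2 - rjh^2)
  z <- sqrt(n) * (rjk - rhk) / sqrt((1 - rjk^2)^2 + (1 - rhk^2)^2 - 2 * k)
  got <- pearson_filon_z(rjk, rhk, rjh, n)
  expect_equal(got$statistic, z, tolerance = 1e-12)
  expect_equal(got$p, 2 * pnorm(-abs(z)), tolerance = 1e-12)
  # antisymmetry under swapping j and h
  set.seed(5)
  for (i in 1:50) {
    r <- runif(3, -0.7, 0.7)
    z1 <- pearson_filon_z(r[1], r[2], r[3], 60)$statistic
    z2 <- pearson_filon_z(r[2], r[1], r[3], 60)$statistic
    expect_equal(z1, -z2, tolerance = 1e-12)
  }
  expect_error(pearson_filon_z(1, 0.5, 0.3, 50), "range")
  expect_error(pearson_filon_z(0.5, 0.4, 0.3, 3), "n >= 4")
})

test_that("one-way ANOVA with eta squared matches the SS oracle", {
  res <- oneway_anova_eta(list(c(1, 2), c(3, 4)))
  expect_equal(res$statistic, 8)
  expect_equal(res$dof, c(1, 2))
  expect_equal(res$effect_size, 0.8)
  # identical groups: F = 0
  z <- oneway_anova_eta(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(z$statistic, 0)
  expect_equal(z$effect_size, 0)
  # oracle: stats::oneway.test with equal variances, plus explicit SS
  set.seed(6)
  for (i in 1:50) {
    gs <- lapply(seq_len(sample(2:5, 1)),
                 function(...) rnorm(sample(2:10, 1), sd = runif(1, 0.5, 2)))
    res <- oneway_anova_eta(gs)
    y <- unlist(gs)
    g <- factor(rep(seq_along(gs), lengths(gs)))
    ref <- anova(lm(y ~ g))
    expect_equal(res$statistic, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(res$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
    expect_equal(res$effect_size,
                 ref$`Sum Sq`[1] / sum(ref$`Sum Sq`), tolerance = 1e-10)
  }
  expect_error(oneway_anova_eta(list(1:3)), "2 groups")
  expect_error(oneway_anova_eta(list(1:3, 2)), "2 observations")
})
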