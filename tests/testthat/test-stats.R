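test_that("global rank transform ranks the pooled values with average ties", {
  tab <- expand.grid(subject = c("s1", "s2"), condition = c("a", "b"),
                     time_min = c(1, 5), stringsAsFactors = FALSE)
  tab$gamma_deg <- c(3, 1, 2, 5, 5, 1.5, 0.5, 4)
  rt <- rank_transform(tab)
  expect_equal(rt$gamma_deg, c(5, 2, 4, 7.5, 7.5, 3, 1, 6))
  # rank sum conservation
  expect_equal(sum(rt$gamma_deg), 8 * 9 / 2)
  # invariance to strictly monotone transforms
  tab2 <- tab; tab2$gamma_deg <- exp(tab$gamma_deg / 2)
  expect_equal(rank_transform(tab2)$gamma_deg, rt$gamma_deg)
})

test_that("incomplete or duplicated designs are rejected", {
  tab <- expand.grid(subject = c("s1", "s2", "s3"), condition = c("a", "b"),
                     time_min = c(1, 5), stringsAsFactors = FALSE)
  tab$gamma_deg <- rnorm(nrow(tab))
  expect_silent(validate_rm_table(tab))
  expect_error(validate_rm_table(tab[-3, ]), "missing cells")
  expect_error(validate_rm_table(rbind(tab, tab[1, ])), "duplicated")
})

test_that("the two-way within-subject ANOVA matches the brute-force SS oracle", {
  cases <- expand.grid(n = c(3, 5, 7), a = 2:4, b = 2:4)
  seeds <- seq_len(nrow(cases))
  worst <- 0
  for (i in seeds) {
    tab <- random_rm_table(cases$n[i], cases$a[i], cases$b[i], seed = 100 + i,
                           round_digits = if (i %% 3 == 0) 1 else NULL)
    fit <- rm_anova_two_way(tab)
    ora <- oracle_rm_anova(tab)
    expect_equal(fit$effects$F, ora$F, tolerance = 1e-10)
    expect_equal(fit$effects$df1, as.integer(ora$df1))
    expect_equal(fit$effects$df2, as.integer(ora$df2))
    worst <- max(worst, max(abs(fit$effects$F - ora$F)))
  }
  expect_lt(worst, 1e-8)
})

test_that("the ANOVA agrees with aov error strata on a reference design", {
  tab <- random_rm_table(6, 3, 4, seed = 31)
  fit <- rm_anova_two_way(tab)
  av <- summary(stats::aov(
    gamma_deg ~ condition * factor(time_min) +
      Error(subject / (condition * factor(time_min))), data = tab))
  f_aov <- c(av[["Error: subject:condition"]][[1]]["condition", "F value"],
             av[["Error: subject:factor(time_min)"]][[1]][1, "F value"],
             av[["Error: subject:condition:factor(time_min)"]][[1]][1, "F value"])
  expect_equal(fit$effects$F, unname(f_aov), tolerance = 1e-10)
})

test_that("sphericity diagnostics agree with car::Anova", {
  tab <- random_rm_table(8, 3, 4, seed = 57)
  fit <- rm_anova_two_way(tab)
  sp <- split(seq_len(nrow(tab)),
              list(tab$condition, tab$time_min))   # condition varies fastest
  Y <- sapply(sp, function(ix) tab$gamma_deg[ix][order(tab$subject[ix])])
  idata <- expand.grid(condition = letters[1:3], time_min = factor(1:4))
  A <- car::Anova(stats::lm(Y ~ 1), idata = idata,
                  idesign = ~condition * time_min, type = 3)
  s <- suppressWarnings(summary(A, multivariate = FALSE))  # HF eps > 1 note
  expect_equal(unname(fit$sphericity$mauchly_W[1:2]),
               unname(s$sphericity.tests[c("condition", "time_min"), 1]),
               tolerance = 1e-8)
  # Mauchly p: second-order Box term conventions differ slightly by package
  expect_equal(unname(fit$sphericity$p[1:2]),
               unname(s$sphericity.tests[c("condition", "time_min"), 2]),
               tolerance = 0.05)
  gg <- s$pval.adjustments
  expect_equal(unname(fit$effects$gg_epsilon[1:2]),
               unname(gg[c("condition", "time_min"), "GG eps"]),
               tolerance = 1e-8)
  expect_equal(unname(fit$effects$p_gg[1:2]),
               unname(gg[c("condition", "time_min"), "Pr(>F[GG])"]),
               tolerance = 1e-8)
  # uncorrected F as well
  ut <- s$univariate.tests
  expect_equal(unname(fit$effects$F),
               unname(ut[c("condition", "time_min", "condition:time_min"),
                         "F value"]),
               tolerance = 1e-8)
})

test_that("sphericity is vacuous for two-level factors", {
  tab <- random_rm_table(6, 2, 5, seed = 12)
  fit <- rm_anova_two_way(tab)
  expect_equal(fit$sphericity$mauchly_W[1], 1)
  expect_equal(fit$effects$gg_epsilon[1], 1)
})

test_that("aligned-rank (per-effect) fits run and agree qualitatively", {
  tab <- random_rm_table(8, 3, 3, seed = 77)
  glob <- rm_anova_two_way(tab, ranks = "global")
  art <- rm_anova_two_way(tab, ranks = "per-effect")
  expect_equal(art$effects$df1, glob$effects$df1)
  expect_equal(art$effects$df2, glob$effects$df2)
  expect_true(all(art$effects$F >= 0))
})

test_that("pairwise Bonferroni tests adjust, cap and degenerate correctly", {
  tab <- random_rm_table(6, 4, 3, seed = 21)
  pw <- pairwise_bonferroni(tab, "condition")
  expect_equal(nrow(pw), 6)                       # k(k-1)/2 for k = 4
  expect_equal(pw$p_bonferroni, pmin(1, 6 * pw$p))
  # hand-computed paired t for one pair
  agg <- with(tab, tapply(gamma_deg, list(subject, condition), mean))
  d <- agg[, "a"] - agg[, "b"]
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  row_ab <- pw[pw$level_a == "a" & pw$level_b == "b", ]
  expect_equal(row_ab$t, t_hand, tolerance = 1e-10)
  expect_equal(row_ab$df, length(d) - 1)
  # identical paired samples: t = 0, raw p = 1
  tab0 <- tab
  tab0$gamma_deg <- as.numeric(factor(tab0$subject))  # constant per subject
  pw0 <- pairwise_bonferroni(tab0, "condition")
  expect_true(all(pw0$t == 0))
  expect_true(all(pw0$p == 1))
  expect_true(all(pw0$p_bonferroni == 1))
})

test_that("Spearman's rho matches rank-then-Pearson and exact enumeration", {
  expect_equal(spearman_rho(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_rho(1:8, -(1:8))$rho, -1)
  # tie case against manually assigned average ranks
  x <- c(1, 2, 2, 3, 4); y <- c(10, 9, 12, 11, 20)
  rx <- c(1, 2.5, 2.5, 4, 5); ry <- c(2, 1, 4, 3, 5)
  expect_equal(spearman_rho(x, y)$rho, cor(rx, ry))
  # exact permutation p equals cor.test's exact p for untied data
  set.seed(3); xx <- rnorm(7); yy <- rnorm(7)
  sr <- spearman_rho(xx, yy)
  ct <- cor.test(xx, yy, method = "spearman")
  expect_equal(sr$rho, unname(ct$estimate))
  expect_equal(sr$p, ct$p.value, tolerance = 1e-12)
  expect_equal(sr$method, "exact permutation")
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("Mann-Whitney W follows the first-sample U convention", {
  set.seed(10)
  x <- rnorm(10); y <- x   # identical multisets
  expect_equal(mann_whitney(x, sample(y))$W, 50)   # n1 n2 / 2
  expect_equal(mann_whitney(c(4, 5, 6), c(1, 2, 3))$W, 9)   # n1 n2
  # statistic matches wilcox.test in all regimes
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(6) + 0.5
    expect_equal(mann_whitney(x, y)$W,
                 unname(suppressWarnings(wilcox.test(x, y))$statistic))
  }
})

test_that("exact Mann-Whitney p equals the null-distribution oracle", {
  set.seed(22)
  for (i in 1:5) {
    x <- rnorm(4); y <- rnorm(4) + 1
    mw <- mann_whitney(x, y)
    # independent oracle: symmetric two-sided tail from the exact Wilcoxon
    # null distribution
    u_all <- 0:16
    pr <- dwilcox(u_all, 4, 4)
    p_oracle <- sum(pr[abs(u_all - 8) >= abs(mw$W - 8) - 1e-9])
    expect_equal(mw$p, p_oracle, tolerance = 1e-12)
    expect_equal(mw$p, wilcox.test(x, y)$p.value, tolerance = 1e-12)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("median/IQR descriptives follow the documented quantile rule", {
  expect_equal(median_iqr(1:5)$median, 3)
  expect_equal(median_iqr(rep(7, 4))$iqr, 0)
  set.seed(5)
  x <- rnorm(6)
  mi <- median_iqr(x)
  expect_equal(mi$median, oracle_quantile7(x, 0.5))
  expect_equal(mi$iqr, oracle_quantile7(x, 0.75) - oracle_quantile7(x, 0.25))
  expect_equal(mi$n, 6)
  expect_equal(c(mi$min, mi$max), range(x))
  expect_error(median_iqr(numeric(0)), "empty")
})
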