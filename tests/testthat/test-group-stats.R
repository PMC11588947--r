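test_that("rank-sum W is the half-weighted Mann-Whitney count for the first group", {
  # four cross pairs with one half-weighted tie
  res <- rank_sum_test(c(0.1, 0.2), c(0.1, 0.0))
  expect_equal(res$w_statistic, 3.5)
  expect_equal(res$r_estimator, 0.875)

  # complete separation
  res <- rank_sum_test(11:15, 1:5)
  expect_equal(res$w_statistic, 25)
  expect_equal(res$r_estimator, 1)

  # brute-force oracle over random instances, with and without ties
  set.seed(17)
  for (i in 1:20) {
    x <- sample(1:8, 7, replace = TRUE) + if (i %% 2) 0 else rnorm(7)
    y <- sample(1:8, 5, replace = TRUE) + if (i %% 2) 0 else rnorm(5)
    res <- rank_sum_test(x, y)
    expect_equal(res$w_statistic, oracle_mw_count(x, y))
    # W agrees with the standard implementation's statistic
    expect_equal(res$w_statistic,
                 unname(suppressWarnings(stats::wilcox.test(x, y)$statistic)))
  }
  expect_error(rank_sum_test(numeric(0), 1:3), "nonempty")
})

test_that("exact p is used for small untied samples, approximation otherwise", {
  x <- c(1.2, 3.4, 5.1, 7.7); y <- c(2.2, 4.4, 6.6)
  res <- rank_sum_test(x, y)
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, stats::wilcox.test(x, y, exact = TRUE)$p.value)
  # ties force the approximation
  res_t <- rank_sum_test(c(x, 2.2), y)
  expect_equal(res_t$method, "normal approximation")
  # combined n above the threshold forces it too
  res_l <- rank_sum_test(rnorm(20), rnorm(10))
  expect_equal(res_l$method, "normal approximation")
})

test_that("Cliff's delta and Vargha-Delaney A follow the dominance algebra", {
  expect_equal(cliffs_delta(1:3, 11:13), -1)   # all y above all x
  expect_equal(cliffs_delta(5, 5), 0)
  expect_equal(vd_a(0), 0.5)
  expect_equal(vd_a(0.754), 0.877)
  set.seed(23)
  for (i in 1:20) {
    x <- sample(1:6, 8, replace = TRUE); y <- sample(1:6, 6, replace = TRUE)
    expect_equal(cliffs_delta(x, y), oracle_cliffs_delta(x, y))
  }
})

test_that("identity chain r = A = AUC and delta = 2A - 1 on shared inputs", {
  set.seed(29)
  for (i in 1:10) {
    x <- rnorm(12, 0.4); y <- c(rnorm(8), x[1])   # force a tie sometimes
    r <- rank_sum_test(x, y)$r_estimator
    delta <- cliffs_delta(x, y)
    a <- vd_a(delta)
    expect_equal(r, a, tolerance = 1e-12)
    expect_equal(auc_mw(x, y), a, tolerance = 1e-12)
    expect_equal(delta, 2 * a - 1, tolerance = 1e-12)
  }
})

test_that("Welch t and pooled Cohen's d behave on constructed samples", {
  x <- c(1, 2, 3, 4)
  expect_equal(welch_t(x, x)$t_statistic, 0)
  expect_equal(welch_t(x, x)$cohens_d, 0)
  # shifting by one common SD gives d = 1 exactly
  y <- x - sd(x)
  expect_equal(welch_t(x, y)$cohens_d, 1)
  # cross-check against the standard implementation
  set.seed(37)
  a <- rnorm(15); b <- rnorm(12, 0.8, 1.6)
  got <- welch_t(a, b)
  ref <- t.test(a, b)
  expect_equal(got$t_statistic, unname(ref$statistic))
  expect_equal(got$t_df, unname(ref$parameter))
  expect_equal(got$p_value, ref$p.value)
  expect_error(welch_t(rep(1, 3), rep(2, 3)), "zero variance")
  # summary-moment route agrees with the raw route on the same data
  got2 <- welch_t_summary(mean(a), sd(a), length(a), mean(b), sd(b), length(b))
  expect_equal(got2$t_statistic, got$t_statistic, tolerance = 1e-12)
  expect_equal(got2$cohens_d, got$cohens_d, tolerance = 1e-12)
})

test_that("one-sample t handles degenerate inputs as specified", {
  expect_equal(one_sample_t(rep(0, 5))$t_statistic, 0)
  expect_equal(one_sample_t(rep(0, 5))$p_value, 1)
  expect_error(one_sample_t(rep(1, 4)), "unbounded")
  set.seed(41)
  x <- rnorm(10, 0.5)
  got <- one_sample_t(x)
  expect_equal(got$t_statistic, mean(x) / (sd(x) / sqrt(10)), tolerance = 1e-12)
})

test_that("Spearman rho is the Pearson correlation of midranks", {
  expect_equal(spearman_rho(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_rho(1:10, -(1:10))$rho, -1)
  set.seed(43)
  a <- sample(1:5, 12, replace = TRUE); b <- sample(1:5, 12, replace = TRUE)
  expect_equal(spearman_rho(a, b)$rho, oracle_spearman(a, b), tolerance = 1e-12)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("split-plot SS match the balanced cell-means oracle on a toy set", {
  scores <- matrix(c(1.0, 1.2, 0.8, 1.4,
                     0.9, 1.1, 0.7, 1.2,
                     1.1, 1.3, 0.9, 1.5,
                     0.2, 0.5, 0.1, 0.6,
                     0.3, 0.4, 0.2, 0.8,
                     0.1, 0.6, 0.3, 0.5), nrow = 6, byrow = TRUE)
  groups <- rep(c("a", "b"), each = 3)
  fit <- split_plot_anova(scores, groups)
  oracle <- oracle_split_plot_ss(scores, groups)
  tab <- fit$table
  expect_equal(tab$sum_sq[tab$effect == "group"], oracle$group, tolerance = 1e-10)
  expect_equal(tab$sum_sq[tab$effect == "measure"], oracle$measure, tolerance = 1e-10)
  expect_equal(tab$sum_sq[tab$effect == "interaction"], oracle$interaction,
               tolerance = 1e-10)
  expect_equal(fit$ss_resid, oracle$residual, tolerance = 1e-10)
  # SS components sum to the total SS
  expect_equal(sum(tab$sum_sq) + fit$ss_subjects_within + fit$ss_resid,
               oracle$total, tolerance = 1e-10)
  # df pattern for 2 groups x 4 measures at N = 6
  expect_equal(tab$df_num, c(3, 1, 3))
  expect_equal(tab$df_den, c(12, 4, 12))
  # permuting participants changes nothing
  perm <- sample(6)
  fit2 <- split_plot_anova(scores[perm, ], groups[perm])
  expect_equal(fit2$table, fit$table, tolerance = 1e-10)
})

test_that("split-plot F tests equal the REML mixed-model tests on unbalanced groups", {
  skip_if_not_installed("lmerTest")
  set.seed(47)
  n <- c(9, 6)
  scores <- rbind(
    matrix(rnorm(n[1] * 4, rep(c(0.4, 0.3, -0.1, -0.2), each = n[1]), 0.4), n[1]) +
      rnorm(n[1], 0, 0.3),
    matrix(rnorm(n[2] * 4, rep(c(0.0, -0.4, -0.8, -0.6), each = n[2]), 0.4), n[2]) +
      rnorm(n[2], 0, 0.3))
  groups <- rep(c("straight", "lesbian"), n)
  fit <- split_plot_anova(scores, groups)

  long <- data.frame(y = as.vector(scores),
                     tt = factor(rep(1:4, each = sum(n))),
                     grp = factor(rep(groups, 4)),
                     id = factor(rep(seq_len(sum(n)), 4)))
  lmm <- lmerTest::lmer(y ~ grp * tt + (1 | id), data = long)
  ref <- as.data.frame(stats::anova(lmm, type = 3))   # Satterthwaite

  tab <- fit$table
  expect_equal(tab$F[tab$effect == "group"], ref["grp", "F value"], tolerance = 1e-6)
  expect_equal(tab$F[tab$effect == "measure"], ref["tt", "F value"], tolerance = 1e-6)
  expect_equal(tab$F[tab$effect == "interaction"], ref["grp:tt", "F value"],
               tolerance = 1e-6)
  expect_equal(tab$df_den[tab$effect == "group"], ref["grp", "DenDF"],
               tolerance = 1e-6)
  expect_equal(tab$df_den[tab$effect == "measure"], ref["tt", "DenDF"],
               tolerance = 1e-6)

  # degenerate and unbalanced inputs are reported, not silently fixed
  expect_error(split_plot_anova(cbind(scores[, 1:3], NA), groups), "mixed")
  const <- matrix(1, 6, 4)
  fit0 <- split_plot_anova(const, rep(c("a", "b"), 3))
  expect_true(all(is.na(fit0$table$F)))
})

test_that("pairwise contrasts agree with the oracle decomposition and emmeans", {
  set.seed(53)
  n <- c(8, 6)
  # participant intercepts keep the subject variance component interior,
  # so the mixed-model cross-check does not hit a boundary fit
  scores <- rbind(matrix(rnorm(n[1] * 4, 0.3, 0.4), n[1]) + rnorm(n[1], 0, 0.5),
                  matrix(rnorm(n[2] * 4, -0.4, 0.4), n[2]) + rnorm(n[2], 0, 0.5))
  colnames(scores) <- paste0("tt", 1:4)
  groups <- rep(c("a", "b"), n)
  fit <- split_plot_anova(scores, groups)
  ctr <- pairwise_contrasts(fit)

  # estimates are plain cell-mean differences
  cm <- fit$cell_means
  first <- ctr$within[ctr$within$group == "a" & ctr$within$contrast == "tt1 - tt2", ]
  expect_equal(first$estimate, cm["a", "tt1"] - cm["a", "tt2"], tolerance = 1e-12)
  expect_equal(first$se, sqrt(2 * fit$ms_resid / n[1]), tolerance = 1e-12)

  # two identical measure columns give t = 0 and the family-maximum p
  scores2 <- scores; scores2[, 2] <- scores2[, 1]
  ctr2 <- pairwise_contrasts(split_plot_anova(scores2, groups))
  row <- ctr2$within[ctr2$within$contrast == "tt1 - tt2", ]
  expect_equal(row$t, c(0, 0))
  expect_equal(row$p_tukey, c(1, 1))

  # Tukey adjustment is monotone: adjusted p >= unadjusted p
  p_unadj <- 2 * pt(-abs(ctr$within$t), ctr$within$df)
  expect_true(all(ctr$within$p_tukey >= p_unadj - 1e-12))

  skip_if_not_installed("emmeans")
  skip_if_not_installed("lmerTest")
  long <- data.frame(y = as.vector(scores),
                     tt = factor(rep(paste0("tt", 1:4), each = sum(n))),
                     grp = factor(rep(groups, 4)),
                     id = factor(rep(seq_len(sum(n)), 4)))
  lmm <- lmerTest::lmer(y ~ grp * tt + (1 | id), data = long)
  em <- emmeans::emmeans(lmm, ~ tt | grp)
  ref <- as.data.frame(graphics::pairs(em, adjust = "tukey"))
  ref_a <- ref[ref$grp == "a", ]
  expect_equal(ctr$within$estimate[ctr$within$group == "a"], ref_a$estimate,
               tolerance = 1e-6)
  expect_equal(ctr$within$t[ctr$within$group == "a"], ref_a$t.ratio,
               tolerance = 1e-6)
})
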