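#' Wilcoxon rank-sum test with the W/(n1*n2) effect-size estimator
#'
#' W is the Mann-Whitney count for the first group: the number of
#' (x, y) pairs with x above y, ties half-weighted. The effect-size
#' estimator is r = W / (n1 * n2), which equals the probability-of-
#' superiority (Vargha-Delaney A) statistic for the same direction. The
#' p value is exact by enumeration when the combined sample size is at
#' most \code{exact_threshold} and no ties are present, and otherwise
#' uses the tie-corrected normal approximation with continuity
#' correction.
#'
#' @param x first-group values (by convention the straight group).
#' @param y second-group values.
#' @param exact_threshold combined-n switch for the exact p (default 25).
#' @return an object of class \code{"effect_report"}: list with
#'   \code{w_statistic}, \code{r_estimator}, \code{p_value}, sample
#'   sizes, and the p-value method used.
#' @export
rank_sum_test <- function(x, y, exact_threshold = 25) {
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be nonempty", call. = FALSE)
  n1 <- as.numeric(length(x)); n2 <- as.numeric(length(y))
  r_all <- rank(c(x, y))
  w <- sum(r_all[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (n1 + n2) <= exact_threshold && !has_ties
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value)
  structure(list(w_statistic = w, r_estimator = w / (n1 * n2), p_value = p,
                 n1 = n1, n2 = n2,
                 method = if (use_exact) "exact" else "normal approximation"),
            class = "effect_report")
}

#' @export
print.effect_report <- function(x, digits = 3, ...) {
  cat(sprintf("Wilcoxon rank-sum: W = %g, p = %.*g (%s)\n",
              x$w_statistic, digits, x$p_value, x$method))
  cat(sprintf("  r = W/(n1*n2) = %.*f  (n1 = %g, n2 = %g)\n",
              digits, x$r_estimator, x$n1, x$n2))
  invisible(x)
}

#' Cliff's delta dominance statistic
#'
#' delta = (#\{x > y\} - #\{x < y\}) / (n1 * n2), computed by direct
#' pair counting (via the empirical distribution for large samples).
#' Ranges from -1 (complete dominance of y) to +1 (complete dominance
#' of x).
#'
#' @param x,y numeric samples.
#' @return delta in [-1, 1].
#' @export
cliffs_delta <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be nonempty", call. = FALSE)
  ys <- sort(y)
  n_gt <- sum(findInterval(x, ys, left.open = TRUE))          # y strictly below x
  n_lt <- sum(length(ys) - findInterval(x, ys))               # y strictly above x
  (n_gt - n_lt) / (as.numeric(length(x)) * length(y))
}

#' Vargha-Delaney A from Cliff's delta
#'
#' A = (delta + 1) / 2: the probability that a random first-group value
#' exceeds a random second-group value, ties half-weighted. Numerically
#' identical to the rank-sum r estimator and to the ROC AUC for the same
#' direction.
#'
#' @param delta Cliff's delta.
#' @return A in [0, 1].
#' @export
vd_a <- function(delta) (delta + 1) / 2

#' Welch two-sample t test with pooled-SD Cohen's d
#'
#' The t statistic and fractional degrees of freedom use the
#' unequal-variance (Welch-Satterthwaite) form; Cohen's d uses the
#' pooled SD with (n1-1, n2-1) weights, so d remains comparable across
#' studies even when the test itself does not pool.
#'
#' @param x,y numeric samples (each of size >= 2).
#' @return list with \code{t_statistic}, \code{t_df}, \code{p_value},
#'   \code{cohens_d}, and the two group means.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("each group needs n >= 2", call. = FALSE)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("zero variance in both groups", call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2))
  list(t_statistic = unname(ht$statistic), t_df = unname(ht$parameter),
       p_value = ht$p.value, cohens_d = (mean(x) - mean(y)) / sp,
       mean_x = mean(x), mean_y = mean(y))
}

#' Welch t and Cohen's d from summary moments
#'
#' Same quantities as [welch_t()] computed from group means, SDs and
#' sizes, for checking published tables whose raw data are unavailable.
#'
#' @param m1,s1,n1 first-group mean, SD, size.
#' @param m2,s2,n2 second-group mean, SD, size.
#' @return list as in [welch_t()].
#' @export
welch_t_summary <- function(m1, s1, n1, m2, s2, n2) {
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  se <- sqrt(v1 + v2)
  df <- se^4 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  t <- (m1 - m2) / se
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  list(t_statistic = t, t_df = df,
       p_value = 2 * stats::pt(-abs(t), df),
       cohens_d = (m1 - m2) / sp, mean_x = m1, mean_y = m2)
}

#' One-sample t test against zero
#'
#' @param x numeric sample, n >= 2.
#' @param mu null value (default 0).
#' @return list with \code{t_statistic}, \code{df}, \code{p_value},
#'   \code{mean}.
#' @export
one_sample_t <- function(x, mu = 0) {
  if (length(x) < 2L) stop("n >= 2 required", call. = FALSE)
  if (stats::sd(x) == 0) {
    if (mean(x) == mu) {
      return(list(t_statistic = 0, df = length(x) - 1L, p_value = 1, mean = mean(x)))
    }
    stop("zero variance with nonzero mean difference: t is unbounded", call. = FALSE)
  }
  ht <- stats::t.test(x, mu = mu)
  list(t_statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean = mean(x))
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks, with the asymptotic t-approximation
#' p value (appropriate in the presence of ties).
#'
#' @param a,b paired numeric vectors, n >= 3.
#' @return list with \code{rho}, \code{p_value}, \code{n}.
#' @export
spearman_rho <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3L) stop("n >= 3 required", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("rank correlation undefined for a constant vector", call. = FALSE)
  }
  rho <- stats::cor(rank(a), rank(b))
  p <- stats::cor.test(a, b, method = "spearman", exact = FALSE)$p.value
  list(rho = rho, p_value = p, n = length(a))
}

#' Split-plot (mixed within-between) analysis of variance
#'
#' Classical two-stratum decomposition for a design with one
#' between-subjects factor (group) and one complete within-subjects
#' factor (measure), e.g. D scores at the 4 IRAP trial types by
#' orientation. The group effect is tested in the between-subjects
#' stratum against subjects-within-groups; the measure and interaction
#' effects are tested in the within stratum against the residual, using
#' Type III (sum-to-zero) sums of squares so unequal group sizes are
#' handled as the mixed-model analysis would. For complete balanced-
#' within data these F tests coincide with the REML random-intercept
#' mixed-model tests (at N participants and m measures the df are
#' (G-1, N-G) and ((m-1)(G-1), (m-1)(N-G))). Incomplete data are
#' rejected: this decomposition has no missing-data analogue, and a
#' genuine mixed model should be used instead.
#'
#' @param scores numeric matrix, one row per participant, one column per
#'   within-subject measure (no missing values).
#' @param groups factor/character of group labels, one per row.
#' @return an object of class \code{"split_plot_anova"}: the ANOVA
#'   table plus the variance components needed by
#'   [pairwise_contrasts()].
#' @export
split_plot_anova <- function(scores, groups) {
  scores <- as.matrix(scores)
  if (anyNA(scores)) {
    stop(paste("incomplete within-subject data: the balanced split-plot",
               "decomposition requires every participant to have all measures;",
               "fit a mixed-effects model for unbalanced data"), call. = FALSE)
  }
  N <- nrow(scores); m <- ncol(scores)
  groups <- factor(groups)
  if (length(groups) != N) stop("one group label per row is required", call. = FALSE)
  G <- nlevels(groups)
  if (G < 2L || m < 2L || N <= G) stop("need >= 2 groups, >= 2 measures, and N > G", call. = FALSE)

  subj_means <- rowMeans(scores)
  grand <- mean(scores)
  group_means <- tapply(subj_means, groups, mean)
  n_g <- as.vector(table(groups))

  # Between-subjects stratum (per-observation scale).
  ss_group <- m * sum(n_g * (group_means - grand)^2)
  ss_sw <- m * sum((subj_means - group_means[as.integer(groups)])^2)
  df_group <- G - 1L
  df_sw <- N - G

  # Within stratum: OLS on within-participant deviations with
  # sum-to-zero contrasts; Type III SS by dropping each term's columns.
  dev <- scores - subj_means
  long <- data.frame(dev = as.vector(dev),
                     tt = factor(rep(seq_len(m), each = N)),
                     grp = rep(groups, m))
  contr <- list(tt = stats::contr.sum, grp = stats::contr.sum)
  X <- stats::model.matrix(~ tt * grp, long, contrasts.arg = contr)
  asn <- attr(X, "assign")          # 0 intercept, 1 tt, 2 grp, 3 interaction
  rss <- function(cols) {
    fit <- stats::lm.fit(X[, cols, drop = FALSE], long$dev)
    sum(fit$residuals^2)
  }
  rss_full <- rss(seq_len(ncol(X)))
  ss_tt  <- rss(which(asn != 1L)) - rss_full
  ss_int <- rss(which(asn != 3L)) - rss_full
  df_tt <- m - 1L
  df_int <- (m - 1L) * (G - 1L)
  df_res <- (m - 1L) * (N - G)
  ss_res <- rss_full
  ms_res <- ss_res / df_res
  ms_sw <- ss_sw / df_sw

  f_of <- function(ss, df, ms_err, df_err) {
    if (ms_err == 0) return(c(NA_real_, NA_real_))
    f <- (ss / df) / ms_err
    c(f, stats::pf(f, df, df_err, lower.tail = FALSE))
  }
  r1 <- f_of(ss_tt, df_tt, ms_res, df_res)
  r2 <- f_of(ss_group, df_group, ms_sw, df_sw)
  r3 <- f_of(ss_int, df_int, ms_res, df_res)

  table <- data.frame(
    effect = c("measure", "group", "interaction"),
    sum_sq = c(ss_tt, ss_group, ss_int),
    mean_sq = c(ss_tt / df_tt, ss_group / df_group, ss_int / df_int),
    df_num = c(df_tt, df_group, df_int),
    df_den = c(df_res, df_sw, df_res),
    F = c(r1[1], r2[1], r3[1]),
    p = c(r1[2], r2[2], r3[2]),
    stringsAsFactors = FALSE)

  cell_means <- matrix(NA_real_, nrow = G, ncol = m,
                       dimnames = list(levels(groups), colnames(scores)))
  for (g in seq_len(G)) {
    cell_means[g, ] <- colMeans(scores[groups == levels(groups)[g], , drop = FALSE])
  }

  structure(list(table = table, cell_means = cell_means, n_g = n_g,
                 group_levels = levels(groups), n_measures = m, n = N,
                 ms_resid = ms_res, df_resid = df_res,
                 ms_subjects = ms_sw, df_subjects = df_sw,
                 ss_total = sum((scores - grand)^2),
                 ss_subjects_within = ss_sw, ss_resid = ss_res),
            class = "split_plot_anova")
}

#' @export
print.split_plot_anova <- function(x, digits = 4, ...) {
  cat(sprintf("Split-plot ANOVA: %d participants x %d measures, groups: %s\n",
              x$n, x$n_measures, paste(x$group_levels, collapse = " vs ")))
  tab <- x$table
  tab$sum_sq <- signif(tab$sum_sq, digits)
  tab$mean_sq <- signif(tab$mean_sq, digits)
  tab$F <- signif(tab$F, digits)
  tab$p <- signif(tab$p, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

# Satterthwaite df for the combined (subjects + residual) error used by
# between-group cell-mean comparisons: the estimated per-cell variance is
# (MS_sw + (m-1) MS_res) / m.
.combined_error <- function(fit) {
  m <- fit$n_measures
  s2 <- (fit$ms_subjects + (m - 1) * fit$ms_resid) / m
  a <- fit$ms_subjects / m
  b <- (m - 1) * fit$ms_resid / m
  df <- (a + b)^2 / (a^2 / fit$df_subjects + b^2 / fit$df_resid)
  list(s2 = s2, df = df)
}

#' Pairwise contrasts for a split-plot fit
#'
#' Three families, mirroring the usual post-hoc report for this design:
#' within-group comparisons of the m measure means (residual error,
#' Tukey adjustment over the family of m estimates), between-group
#' comparisons at each measure (Satterthwaite combination of the two
#' error strata, unadjusted), and Bonferroni-adjusted confidence
#' intervals for all G x m cell means.
#'
#' @param fit a [split_plot_anova()] object.
#' @param conf_level confidence level for the cell-mean intervals.
#' @return list of class \code{"split_plot_contrasts"} with data.frames
#'   \code{within}, \code{between} and \code{cell_means}.
#' @export
pairwise_contrasts <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "split_plot_anova"))
  m <- fit$n_measures; G <- length(fit$group_levels)
  meas <- colnames(fit$cell_means)
  if (is.null(meas)) meas <- paste0("m", seq_len(m))

  within <- do.call(rbind, lapply(seq_len(G), function(g) {
    n_g <- fit$n_g[g]
    combs <- utils::combn(m, 2)
    do.call(rbind, lapply(seq_len(ncol(combs)), function(k) {
      i <- combs[1, k]; j <- combs[2, k]
      est <- fit$cell_means[g, i] - fit$cell_means[g, j]
      se <- sqrt(2 * fit$ms_resid / n_g)
      t <- if (se > 0) est / se else NA_real_
      p <- if (is.na(t)) NA_real_ else
        stats::ptukey(sqrt(2) * abs(t), m, fit$df_resid, lower.tail = FALSE)
      data.frame(group = fit$group_levels[g],
                 contrast = paste(meas[i], "-", meas[j]),
                 estimate = est, se = se, t = t, df = fit$df_resid,
                 p_tukey = p, stringsAsFactors = FALSE)
    }))
  }))

  comb <- .combined_error(fit)
  between <- NULL
  if (G == 2L) {
    between <- do.call(rbind, lapply(seq_len(m), function(j) {
      est <- fit$cell_means[1, j] - fit$cell_means[2, j]
      se <- sqrt(comb$s2 * sum(1 / fit$n_g))
      t <- est / se
      data.frame(measure = meas[j],
                 contrast = paste(fit$group_levels[1], "-", fit$group_levels[2]),
                 estimate = est, se = se, t = t, df = comb$df,
                 p = 2 * stats::pt(-abs(t), comb$df), stringsAsFactors = FALSE)
    }))
  }

  n_cells <- G * m
  alpha_adj <- (1 - conf_level) / n_cells
  crit <- stats::qt(1 - alpha_adj / 2, comb$df)
  cell <- do.call(rbind, lapply(seq_len(G), function(g) {
    se <- sqrt(comb$s2 / fit$n_g[g])
    data.frame(group = fit$group_levels[g], measure = meas,
               mean = fit$cell_means[g, ],
               lower = fit$cell_means[g, ] - crit * se,
               upper = fit$cell_means[g, ] + crit * se,
               stringsAsFactors = FALSE)
  }))
  rownames(cell) <- NULL

  structure(list(within = within, between = between, cell_means = cell,
                 error_df = comb$df, conf_level = conf_level),
            class = "split_plot_contrasts")
}

#' @export
print.split_plot_contrasts <- function(x, digits = 3, ...) {
  cat("Within-group measure contrasts (Tukey-adjusted):\n")
  print(format(x$within, digits = digits), row.names = FALSE)
  if (!is.null(x$between)) {
    cat("\nBetween-group contrasts per measure (Satterthwaite df",
        sprintf("%.1f):\n", x$error_df))
    print(format(x$between, digits = digits), row.names = FALSE)
  }
  cat(sprintf("\nCell means with Bonferroni-adjusted %d%% CIs:\n",
              round(100 * x$conf_level)))
  print(format(x$cell_means, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Full two-group comparison bundle for one measure
#'
#' Convenience wrapper running [rank_sum_test()], [cliffs_delta()],
#' [vd_a()] and [welch_t()] on the same two samples.
#'
#' @param x,y the two group samples (x first by direction convention).
#' @return list with every statistic, of class \code{"group_comparison"}.
#' @export
compare_groups <- function(x, y) {
  w <- rank_sum_test(x, y)
  delta <- cliffs_delta(x, y)
  t <- tryCatch(welch_t(x, y), error = function(e) NULL)
  structure(list(w_statistic = w$w_statistic, r_estimator = w$r_estimator,
                 w_p_value = w$p_value, cliffs_delta = delta, vd_a = vd_a(delta),
                 t_statistic = t$t_statistic, t_df = t$t_df,
                 t_p_value = t$p_value, cohens_d = t$cohens_d,
                 n1 = length(x), n2 = length(y),
                 mean_x = mean(x), mean_y = mean(y),
                 sd_x = stats::sd(x), sd_y = stats::sd(y)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("Group comparison (n1 = %d, n2 = %d)\n", x$n1, x$n2))
  cat(sprintf("  means (SD): %.*f (%.*f) vs %.*f (%.*f)\n",
              digits, x$mean_x, digits, x$sd_x, digits, x$mean_y, digits, x$sd_y))
  cat(sprintf("  W = %g, p = %.2g, r = %.*f;  Cliff's delta = %.*f, A = %.*f\n",
              x$w_statistic, x$w_p_value, digits, x$r_estimator,
              digits, x$cliffs_delta, digits, x$vd_a))
  if (!is.null(x$t_statistic)) {
    cat(sprintf("  Welch t(%.1f) = %.*f, p = %.2g;  Cohen's d = %.*f\n",
                x$t_df, digits, x$t_statistic, x$t_p_value, digits, x$cohens_d))
  }
  invisible(x)
}
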