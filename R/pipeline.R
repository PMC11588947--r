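#' Analyze a cohort end to end
#'
#' The package's central fitting function: scores every measure and runs
#' the full inference battery on an \code{irap_cohort}. Analysis
#' denominators are derived per measure: participants excluded from the
#' IRAP (practice gate or fast-responder rule) still contribute FAST and
#' KSOG data, so the three measures may legitimately analyse different
#' subsets.
#'
#' Components of the returned object:
#' \itemize{
#'   \item \code{scores}: merged per-participant table (orientation, KSOG,
#'     FAST slopes, D scores, exclusion reason).
#'   \item \code{comparisons}: per measure (\code{ksog}, \code{fast_slope_diff},
#'     \code{d_avg}, \code{d_tt1..4}, \code{d_male}, \code{d_female}), the
#'     straight-vs-lesbian [compare_groups()] bundle.
#'   \item \code{anova}, \code{contrasts}: split-plot decomposition of the
#'     4 trial-type D scores by orientation and its post-hoc contrasts.
#'   \item \code{one_sample}: per group and trial type, D-score t tests
#'     against zero.
#'   \item \code{roc}: one [roc_curve()] per predictor (lesbian = cases,
#'     direction controls > cases; the female-picture predictor is
#'     sign-flipped first, which is AUC-equivalent to swapping the case
#'     role), plus DeLong comparisons of averaged D vs FAST (unpaired:
#'     different participant sets) and male vs female pictures.
#'   \item \code{spearman}: rank correlations of each predictor with KSOG.
#'   \item \code{power}: minimal detectable d at the realized IRAP group
#'     sizes and minimal detectable interaction f at the realized IRAP N.
#'   \item \code{exclusions}: participant-by-participant exclusion log.
#' }
#'
#' @param cohort an \code{irap_cohort}.
#' @param alpha type-I error rate used by the power-sensitivity block.
#' @param rho assumed repeated-measure correlation for the interaction
#'   sensitivity computation.
#' @return an object of class \code{"cohort_analysis"}.
#' @export
analyze_cohort <- function(cohort, alpha = 0.05, rho = 0.5) {
  stopifnot(inherits(cohort, "irap_cohort"))
  manifest <- cohort$participants
  dscores <- score_irap(cohort$irap)
  slopes <- score_fast(cohort$fast)
  ksog <- score_ksog(cohort$ksog)

  scores <- merge(manifest, dscores, by = "participant_id", all.x = TRUE)
  scores <- merge(scores, slopes, by = "participant_id", all.x = TRUE)
  scores <- merge(scores, ksog, by = "participant_id", all.x = TRUE)
  scores <- scores[order(scores$participant_id), , drop = FALSE]
  rownames(scores) <- NULL

  straight <- scores$orientation == "straight"
  measures <- c(ksog = "ksog_score", fast_slope_diff = "slope_difference",
                d_avg = "d_avg", d_tt1 = "d_tt1", d_tt2 = "d_tt2",
                d_tt3 = "d_tt3", d_tt4 = "d_tt4",
                d_male = "d_male", d_female = "d_female")
  comparisons <- lapply(measures, function(col) {
    x <- scores[[col]][straight]; y <- scores[[col]][!straight]
    compare_groups(x[!is.na(x)], y[!is.na(y)])
  })

  ## split-plot ANOVA on the 4 trial-type D scores (IRAP-complete subset)
  d_cols <- c("d_tt1", "d_tt2", "d_tt3", "d_tt4")
  have_d <- stats::complete.cases(scores[d_cols])
  dmat <- as.matrix(scores[have_d, d_cols])
  groups <- factor(scores$orientation[have_d], ORIENTATION_LEVELS)
  anova_fit <- split_plot_anova(dmat, groups)
  contrasts <- pairwise_contrasts(anova_fit)

  one_sample <- do.call(rbind, lapply(ORIENTATION_LEVELS, function(g) {
    do.call(rbind, lapply(seq_along(d_cols), function(tt) {
      x <- dmat[groups == g, tt]
      res <- one_sample_t(x)
      data.frame(group = g, trial_type = tt, mean = res$mean,
                 t = res$t_statistic, df = res$df, p = res$p_value,
                 stringsAsFactors = FALSE)
    }))
  }))

  ## ROC per predictor: lesbian participants are the cases and the
  ## direction is controls > cases. The display-layer inversion of the
  ## female-picture scores composed with a swapped case role is
  ## AUC-identical to the raw scores with the default roles, so every
  ## predictor enters the sweep unmodified.
  roc_measures <- measures[names(measures) != "ksog"]
  rocs <- lapply(names(roc_measures), function(nm) {
    v <- scores[[roc_measures[[nm]]]]
    keep <- !is.na(v)
    roc_curve(v[keep], scores$orientation[keep], case_level = "lesbian")
  })
  names(rocs) <- names(roc_measures)
  delong <- list(
    d_avg_vs_fast = delong_test(rocs$d_avg, rocs$fast_slope_diff, paired = FALSE),
    male_vs_female = delong_test(rocs$d_male, rocs$d_female, paired = FALSE))

  spearman <- lapply(roc_measures, function(col) {
    spearman_rho(scores[[col]], scores$ksog_score)
  })

  n1 <- sum(straight & !is.na(scores$d_avg))
  n2 <- sum(!straight & !is.na(scores$d_avg))
  power <- list(
    mde_d = as.numeric(mde_two_sample_t(n1, n2, alpha = alpha, power = 0.80)),
    mde_f = as.numeric(mde_wb_interaction(N = n1 + n2, n_groups = 2,
                                          n_measures = 4, rho = rho,
                                          alpha = alpha, power = 0.80)))
  power$mde_eta2p <- f_to_eta2p(power$mde_f)

  excl <- scores[scores$excluded_reason != "none" | is.na(scores$d_avg),
                 c("participant_id", "orientation", "excluded_reason")]
  rownames(excl) <- NULL

  structure(list(scores = scores, comparisons = comparisons,
                 anova = anova_fit, contrasts = contrasts,
                 one_sample = one_sample, roc = rocs, delong = delong,
                 spearman = spearman, power = power, exclusions = excl,
                 n_irap = n1 + n2, n_fast = sum(!is.na(scores$slope_difference)),
                 n_ksog = sum(!is.na(scores$ksog_score)), alpha = alpha),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, digits = 3, ...) {
  cat("Cohort analysis of implicit-measure data\n")
  cat(sprintf("  denominators: IRAP %d, FAST %d, KSOG %d participants\n",
              x$n_irap, x$n_fast, x$n_ksog))
  for (nm in c("ksog", "fast_slope_diff", "d_avg")) {
    cmp <- x$comparisons[[nm]]
    cat(sprintf("  %-16s W = %g (p = %.2g), r = %.*f, delta = %.*f, d = %.*f\n",
                nm, cmp$w_statistic, cmp$w_p_value, digits, cmp$r_estimator,
                digits, cmp$cliffs_delta, digits, cmp$cohens_d))
  }
  aucs <- vapply(x$roc, function(r) r$auc, numeric(1L))
  cat("  AUCs:", paste(sprintf("%s=%.*f", names(aucs), digits, aucs),
                       collapse = " "), "\n")
  cat(sprintf("  sensitivity: d >= %.2f (t test), f >= %.2f (interaction)\n",
              x$power$mde_d, x$power$mde_f))
  invisible(x)
}

#' @export
summary.cohort_analysis <- function(object, ...) {
  cat(render_report(object), sep = "\n")
  invisible(object)
}

#' @export
plot.cohort_analysis <- function(x, which = c("d_avg", "fast_slope_diff"), ...) {
  cols <- grDevices::hcl.colors(length(which), "Dark 3")
  first <- TRUE
  for (i in seq_along(which)) {
    plot(x$roc[[which[i]]], add = !first, col = cols[i],
         main = if (first) "ROC curves (lesbian = cases)" else NULL, ...)
    first <- FALSE
  }
  graphics::legend("bottomright",
                   legend = sprintf("%s (AUC %.3f)", which,
                                    vapply(x$roc[which], `[[`, 0, "auc")),
                   col = cols, lwd = 2, bty = "n")
  invisible(x)
}

#' Render a markdown summary of an analysis
#'
#' Produces the human-readable report: group descriptives and tests per
#' measure, the ANOVA and contrast tables, AUCs with DeLong
#' comparisons, Spearman correlations, the exclusion log, and the
#' picture-gender panel in which the female-picture trial types are
#' sign-inverted for display (stored scores are never modified).
#'
#' @param analysis a \code{cohort_analysis}.
#' @return character vector of markdown lines.
#' @export
render_report <- function(analysis) {
  stopifnot(inherits(analysis, "cohort_analysis"))
  x <- analysis
  fmt <- function(v, d = 3) formatC(v, digits = d, format = "f")
  out <- c("# Implicit-measure cohort report", "",
           sprintf("Participants analysed: IRAP %d, FAST %d, KSOG %d.",
                   x$n_irap, x$n_fast, x$n_ksog), "",
           "## Group comparisons (straight vs lesbian)", "",
           "| measure | mean (SD) straight | mean (SD) lesbian | W | p | r | Cliff's delta | A | Welch t | Cohen's d |",
           "|---|---|---|---|---|---|---|---|---|---|")
  for (nm in names(x$comparisons)) {
    cmp <- x$comparisons[[nm]]
    out <- c(out, sprintf("| %s | %s (%s) | %s (%s) | %g | %.2g | %s | %s | %s | %s | %s |",
      nm, fmt(cmp$mean_x, 2), fmt(cmp$sd_x, 2), fmt(cmp$mean_y, 2), fmt(cmp$sd_y, 2),
      cmp$w_statistic, cmp$w_p_value, fmt(cmp$r_estimator), fmt(cmp$cliffs_delta),
      fmt(cmp$vd_a), if (is.null(cmp$t_statistic)) "-" else fmt(cmp$t_statistic, 2),
      if (is.null(cmp$cohens_d)) "-" else fmt(cmp$cohens_d, 2)))
  }
  tab <- x$anova$table
  out <- c(out, "", "## Split-plot ANOVA of trial-type D scores", "",
           "| effect | Sum Sq | Mean Sq | df | den df | F | p |",
           "|---|---|---|---|---|---|---|",
           sprintf("| %s | %s | %s | %d | %d | %s | %.2g |",
                   tab$effect, fmt(tab$sum_sq), fmt(tab$mean_sq),
                   tab$df_num, tab$df_den, fmt(tab$F, 2), tab$p))
  cm <- x$contrasts$cell_means
  out <- c(out, "", "## Cell means (Bonferroni-adjusted CIs)", "",
           "| group | trial type | mean | lower | upper |", "|---|---|---|---|---|",
           sprintf("| %s | %s | %s | %s | %s |", cm$group, cm$measure,
                   fmt(cm$mean), fmt(cm$lower), fmt(cm$upper)))
  ## picture-gender panel: female-picture scores displayed inverted
  pm <- x$scores
  inv <- data.frame(
    group = rep(ORIENTATION_LEVELS, each = 2L),
    panel = rep(c("male pictures", "female pictures (inverted)"), 2L),
    mean = unlist(lapply(ORIENTATION_LEVELS, function(g) {
      sel <- pm$orientation == g
      c(mean(pm$d_male[sel], na.rm = TRUE), -mean(pm$d_female[sel], na.rm = TRUE))
    })))
  out <- c(out, "", "## Picture-gender biases (display inversion only)", "",
           "| group | panel | mean |", "|---|---|---|",
           sprintf("| %s | %s | %s |", inv$group, inv$panel, fmt(inv$mean)))
  aucs <- vapply(x$roc, function(r) r$auc, numeric(1L))
  out <- c(out, "", "## ROC (lesbian = cases, controls > cases)", "",
           "| predictor | AUC |", "|---|---|",
           sprintf("| %s | %s |", names(aucs), fmt(aucs)), "",
           sprintf("DeLong averaged D vs FAST: D(%.2f) = %s, p = %.3g.",
                   x$delong$d_avg_vs_fast$df, fmt(x$delong$d_avg_vs_fast$statistic, 3),
                   x$delong$d_avg_vs_fast$p_value),
           sprintf("DeLong male vs female pictures: D(%.2f) = %s, p = %.3g.",
                   x$delong$male_vs_female$df, fmt(x$delong$male_vs_female$statistic, 3),
                   x$delong$male_vs_female$p_value))
  rho <- vapply(x$spearman, function(s) s$rho, numeric(1L))
  rp <- vapply(x$spearman, function(s) s$p_value, numeric(1L))
  out <- c(out, "", "## Spearman correlations with KSOG", "",
           "| predictor | rho | p |", "|---|---|---|",
           sprintf("| %s | %s | %.2g |", names(rho), fmt(rho), rp), "",
           sprintf(paste("Sensitivity at the realized sample sizes: smallest",
                         "detectable d = %.2f, interaction f = %.2f",
                         "(eta2p = %.3f) at alpha = %.2f, power 0.80."),
                   x$power$mde_d, x$power$mde_f, x$power$mde_eta2p, x$alpha))
  if (nrow(x$exclusions) > 0L) {
    out <- c(out, "", "## Exclusions", "",
             sprintf("- %s (%s): %s", x$exclusions$participant_id,
                     x$exclusions$orientation, x$exclusions$excluded_reason))
  }
  out
}

#' Run the full pipeline and write a report bundle
#'
#' Generate (or load) a cohort, score every measure, run the analysis
#' battery, and write \code{dscores.csv}, \code{slopes.csv},
#' \code{ksog_scores.csv}, \code{stats_report.json},
#' \code{roc_report.json}, \code{power_report.json}, \code{report.md}
#' and \code{run_log.txt} into \code{output_dir}. Deterministic for a
#' fixed seed.
#'
#' @param output_dir directory for the bundle (created if needed).
#' @param input_dir directory with the four interchange CSVs; omit to
#'   simulate a cohort instead.
#' @param config generator configuration for the synthetic route.
#' @param seed overrides \code{config$seed} when given.
#' @param alpha type-I error rate for the sensitivity block.
#' @return the \code{cohort_analysis}, invisibly.
#' @export
run_pipeline <- function(output_dir, input_dir = NULL, config = cohort_config(),
                         seed = NULL, alpha = 0.05) {
  if (is.null(input_dir)) {
    if (!is.null(seed)) config$seed <- seed
    cohort <- generate_cohort(config)
  } else {
    cohort <- read_cohort(input_dir)
  }
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  analysis <- analyze_cohort(cohort, alpha = alpha)
  sc <- analysis$scores

  utils::write.csv(sc[c("participant_id", "d_tt1", "d_tt2", "d_tt3", "d_tt4",
                        "d_avg", "d_male", "d_female", "excluded_reason")],
                   file.path(output_dir, "dscores.csv"), row.names = FALSE)
  utils::write.csv(sc[c("participant_id", "slope_straight", "slope_lesbian",
                        "slope_difference")],
                   file.path(output_dir, "slopes.csv"), row.names = FALSE)
  utils::write.csv(sc[c("participant_id", "ksog_score", "n_cells_used")],
                   file.path(output_dir, "ksog_scores.csv"), row.names = FALSE)

  stats_report <- lapply(analysis$comparisons, function(cmp) {
    cmp <- unclass(cmp)
    cmp[!vapply(cmp, is.null, logical(1L))]
  })
  stats_report$anova <- analysis$anova$table
  stats_report$one_sample <- analysis$one_sample
  jsonlite::write_json(stats_report, file.path(output_dir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  roc_report <- list(
    auc = lapply(analysis$roc, function(r) r$auc),
    delong = lapply(analysis$delong, function(d) d[c("statistic", "df", "p_value",
                                                     "auc1", "auc2")]))
  jsonlite::write_json(roc_report, file.path(output_dir, "roc_report.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(analysis$power, file.path(output_dir, "power_report.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(render_report(analysis), file.path(output_dir, "report.md"))

  log_lines <- c(sprintf("participants: %d", nrow(sc)),
                 sprintf("IRAP analysed: %d; FAST analysed: %d; KSOG analysed: %d",
                         analysis$n_irap, analysis$n_fast, analysis$n_ksog),
                 if (nrow(analysis$exclusions) > 0L) {
                   sprintf("excluded %s (%s): %s",
                           analysis$exclusions$participant_id,
                           analysis$exclusions$orientation,
                           analysis$exclusions$excluded_reason)
                 } else "no exclusions")
  writeLines(log_lines, file.path(output_dir, "run_log.txt"))
  invisible(analysis)
}
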