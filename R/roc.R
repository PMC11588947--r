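#' Mann-Whitney AUC
#'
#' Tie-corrected pair-count AUC: the probability that a random control
#' scores above a random case, ties half-weighted. Computed from
#' midranks so it scales to large samples, and numerically identical to
#' the rank-sum r estimator and Vargha-Delaney A on the same inputs.
#'
#' @param controls,cases numeric score vectors.
#' @return AUC in [0, 1].
#' @export
auc_mw <- function(controls, cases) {
  n1 <- as.numeric(length(controls)); n2 <- as.numeric(length(cases))
  if (n1 == 0 || n2 == 0) stop("both classes must be present", call. = FALSE)
  r_all <- rank(c(controls, cases))
  (sum(r_all[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' ROC curve for a two-class predictor
#'
#' Sweeps every threshold of the score and records (specificity,
#' sensitivity) pairs, with sensitivity the true-positive rate for the
#' cases and the specificity axis running from 1 down to 0. Under the
#' default direction, controls are expected to score above cases; the
#' opposite direction flips the score sign, which leaves the AUC
#' complementary. The AUC is the Mann-Whitney pair-count statistic,
#' which equals the trapezoidal area under the returned step curve.
#'
#' @param scores numeric predictor values.
#' @param labels class labels parallel to \code{scores}.
#' @param case_level the label value identifying cases.
#' @param direction \code{"controls_gt_cases"} (default) or
#'   \code{"cases_gt_controls"}.
#' @return an object of class \code{"roc_report"}: list with
#'   \code{points} (threshold, specificity, sensitivity), \code{auc},
#'   \code{direction}, and the control/case scores used.
#' @export
roc_curve <- function(scores, labels, case_level,
                      direction = c("controls_gt_cases", "cases_gt_controls")) {
  direction <- match.arg(direction)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  is_case <- labels == case_level
  if (all(is_case) || !any(is_case)) {
    stop("both classes must be present", call. = FALSE)
  }
  oriented <- if (direction == "controls_gt_cases") scores else -scores
  controls <- oriented[!is_case]
  cases <- oriented[is_case]
  # Decision rule: predict "case" when score < threshold (controls high).
  thr <- c(-Inf, sort(unique(oriented)), Inf)
  sens <- vapply(thr, function(t) mean(cases < t), numeric(1L))
  spec <- vapply(thr, function(t) mean(controls >= t), numeric(1L))
  ord <- order(spec, -sens, decreasing = TRUE)   # specificity 1 -> 0
  points <- data.frame(threshold = thr[ord], specificity = spec[ord],
                       sensitivity = sens[ord])
  structure(list(points = points, auc = auc_mw(controls, cases),
                 direction = direction, controls = controls, cases = cases,
                 n_controls = length(controls), n_cases = length(cases)),
            class = "roc_report")
}

#' @export
print.roc_report <- function(x, digits = 3, ...) {
  cat(sprintf("ROC curve: %d controls vs %d cases (direction %s)\n",
              x$n_controls, x$n_cases, x$direction))
  cat(sprintf("  AUC = %.*f\n", digits, x$auc))
  invisible(x)
}

#' @export
plot.roc_report <- function(x, add = FALSE, col = "black", lwd = 2, ...) {
  if (!add) {
    plot(NA, xlim = c(1, 0), ylim = c(0, 1), xlab = "Specificity",
         ylab = "Sensitivity", ...)
    graphics::abline(1, -1, col = "grey70", lty = 2)
  }
  graphics::lines(x$points$specificity, x$points$sensitivity,
                  type = "s", col = col, lwd = lwd)
  invisible(x)
}

# DeLong structural components ("placements"): for each control, the
# proportion of cases it beats (ties half), and vice versa.
.delong_placements <- function(roc) {
  x <- roc$controls; y <- roc$cases
  v10 <- vapply(x, function(xi) (sum(xi > y) + 0.5 * sum(xi == y)) / length(y),
                numeric(1L))
  v01 <- vapply(y, function(yj) (sum(x > yj) + 0.5 * sum(x == yj)) / length(x),
                numeric(1L))
  list(v10 = v10, v01 = v01, theta = roc$auc)
}

#' DeLong variance of an AUC
#'
#' Structural-components (placement) estimator: var(AUC) = S10/m +
#' S01/n with m controls and n cases, where S10 and S01 are the sample
#' variances of the control-side and case-side placements.
#'
#' @param roc a [roc_curve()] object.
#' @return the estimated variance of the AUC.
#' @export
delong_variance <- function(roc) {
  stopifnot(inherits(roc, "roc_report"))
  pl <- .delong_placements(roc)
  stats::var(pl$v10) / length(pl$v10) + stats::var(pl$v01) / length(pl$v01)
}

#' DeLong comparison of two AUCs
#'
#' Paired mode (both curves computed on the same participants) uses the
#' placement covariance and a standard-normal reference. Unpaired mode
#' (curves from different participant sets, as when one measure excludes
#' participants the other keeps) divides the AUC difference by the root
#' of the summed independent variances and refers it to a t distribution
#' with Welch-Satterthwaite fractional degrees of freedom, hence the
#' fractional df in reported comparisons.
#'
#' @param roc1,roc2 [roc_curve()] objects.
#' @param paired logical; paired mode requires equal class sizes in the
#'   same participant order.
#' @return list with \code{statistic}, \code{df} (\code{Inf} when
#'   paired), \code{p_value}, and the two AUCs.
#' @export
delong_test <- function(roc1, roc2, paired = FALSE) {
  stopifnot(inherits(roc1, "roc_report"), inherits(roc2, "roc_report"))
  p1 <- .delong_placements(roc1)
  p2 <- .delong_placements(roc2)
  if (paired) {
    if (length(p1$v10) != length(p2$v10) || length(p1$v01) != length(p2$v01)) {
      stop("paired comparison requires identical participant sets", call. = FALSE)
    }
    m <- length(p1$v10); n <- length(p1$v01)
    v <- stats::var(p1$v10) / m + stats::var(p1$v01) / n +
         stats::var(p2$v10) / m + stats::var(p2$v01) / n -
         2 * (stats::cov(p1$v10, p2$v10) / m + stats::cov(p1$v01, p2$v01) / n)
    if (v <= 0) {
      # identical placement vectors (e.g. a curve against itself): the
      # difference is exactly zero with zero spread
      if (roc1$auc == roc2$auc) {
        return(list(statistic = 0, df = Inf, p_value = 1,
                    auc1 = roc1$auc, auc2 = roc2$auc, paired = TRUE))
      }
      stop("degenerate variance: AUC difference has no sampling spread",
           call. = FALSE)
    }
    z <- (roc1$auc - roc2$auc) / sqrt(v)
    return(list(statistic = z, df = Inf, p_value = 2 * stats::pnorm(-abs(z)),
                auc1 = roc1$auc, auc2 = roc2$auc, paired = TRUE))
  }
  s1 <- stats::var(p1$v10) / length(p1$v10) + stats::var(p1$v01) / length(p1$v01)
  s2 <- stats::var(p2$v10) / length(p2$v10) + stats::var(p2$v01) / length(p2$v01)
  if (s1 + s2 <= 0) stop("degenerate variance: AUC difference has no sampling spread",
                         call. = FALSE)
  n1 <- length(p1$v10) + length(p1$v01)
  n2 <- length(p2$v10) + length(p2$v01)
  d <- (roc1$auc - roc2$auc) / sqrt(s1 + s2)
  df <- (s1 + s2)^2 / (s1^2 / (n1 - 1) + s2^2 / (n2 - 1))
  list(statistic = d, df = df, p_value = 2 * stats::pt(-abs(d), df),
       auc1 = roc1$auc, auc2 = roc2$auc, paired = FALSE)
}
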