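#' Achieved power of a two-sample t test
#'
#' Exact noncentral-t power for a two-tailed two-sample t test with
#' pooled df = n1 + n2 - 2 and noncentrality d * sqrt(n1 n2 / (n1 + n2)).
#'
#' @param d standardized mean difference (Cohen's d).
#' @param n1,n2 group sizes.
#' @param alpha two-tailed type-I error rate.
#' @return the power.
#' @export
power_two_sample_t <- function(d, n1, n2, alpha = 0.05) {
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  crit <- stats::qt(1 - alpha / 2, df)
  stats::pt(crit, df, ncp, lower.tail = FALSE) + stats::pt(-crit, df, ncp)
}

#' Minimal detectable effect for a two-sample t test
#'
#' Smallest Cohen's d whose two-tailed two-sample t test reaches the
#' target power at the given sample sizes (sensitivity analysis).
#' The monotone noncentral-t power function is inverted by root finding
#' to within 1e-6 of the target power.
#'
#' @param n1,n2 group sizes (>= 2).
#' @param alpha two-tailed type-I error rate.
#' @param power target power in (alpha, 1).
#' @return the minimal detectable d, with the achieved power as
#'   attribute \code{"power"}.
#' @export
mde_two_sample_t <- function(n1, n2, alpha = 0.05, power = 0.80) {
  if (n1 < 2 || n2 < 2) stop("n1, n2 >= 2 required", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("alpha and power must lie in (0, 1)", call. = FALSE)
  }
  if (power <= alpha) return(structure(0, power = alpha))
  f <- function(d) power_two_sample_t(d, n1, n2, alpha) - power
  upper <- 1
  while (f(upper) < 0 && upper < 1e3) upper <- upper * 2
  if (f(upper) < 0) stop("target power unattainable", call. = FALSE)
  d <- stats::uniroot(f, c(0, upper), tol = 1e-9)$root
  structure(d, power = power_two_sample_t(d, n1, n2, alpha))
}

#' Achieved power of the within-between interaction F test
#'
#' Noncentral-F power for the group-by-measure interaction of a mixed
#' (split-plot) ANOVA under the convention used by common power
#' software: df1 = (G-1)(m-1) eps, df2 = (N-G)(m-1) eps, and
#' noncentrality lambda = f^2 N m eps / (1 - rho), where rho is the
#' assumed correlation among repeated measures and eps the
#' nonsphericity correction.
#'
#' @param f Cohen's f for the interaction.
#' @param N total sample size.
#' @param n_groups,n_measures design dimensions.
#' @param rho repeated-measure correlation in [0, 1).
#' @param epsilon nonsphericity correction in (0, 1].
#' @param alpha type-I error rate.
#' @return the power.
#' @export
power_wb_interaction <- function(f, N, n_groups = 2, n_measures = 4,
                                 rho = 0.5, epsilon = 1, alpha = 0.05) {
  df1 <- (n_groups - 1) * (n_measures - 1) * epsilon
  df2 <- (N - n_groups) * (n_measures - 1) * epsilon
  lambda <- f^2 * N * n_measures * epsilon / (1 - rho)
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Minimal detectable effect for the within-between interaction
#'
#' Smallest Cohen's f whose interaction F test reaches the target power
#' under [power_wb_interaction()]'s conventions (defaults rho = 0.5,
#' epsilon = 1).
#'
#' @inheritParams power_wb_interaction
#' @param power target power.
#' @return the minimal detectable f, with achieved power as attribute
#'   \code{"power"}.
#' @export
mde_wb_interaction <- function(N, n_groups = 2, n_measures = 4, rho = 0.5,
                               epsilon = 1, alpha = 0.05, power = 0.80) {
  if (N <= n_groups) stop("N must exceed the number of groups", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  if (epsilon <= 0 || epsilon > 1) stop("epsilon must lie in (0, 1]", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("alpha and power must lie in (0, 1)", call. = FALSE)
  }
  if (power <= alpha) return(structure(0, power = alpha))
  g <- function(f) power_wb_interaction(f, N, n_groups, n_measures, rho,
                                        epsilon, alpha) - power
  upper <- 1
  while (g(upper) < 0 && upper < 1e3) upper <- upper * 2
  if (g(upper) < 0) stop("target power unattainable", call. = FALSE)
  f <- stats::uniroot(g, c(0, upper), tol = 1e-9)$root
  structure(f, power = power_wb_interaction(f, N, n_groups, n_measures, rho,
                                            epsilon, alpha))
}

#' Convert between Cohen's f and partial eta squared
#'
#' eta2p = f^2 / (1 + f^2) and f = sqrt(eta2p / (1 - eta2p)).
#'
#' @param f Cohen's f (>= 0).
#' @param eta2p partial eta squared in [0, 1).
#' @rdname f_eta2p
#' @export
f_to_eta2p <- function(f) {
  stopifnot(all(f >= 0))
  f^2 / (1 + f^2)
}

#' @rdname f_eta2p
#' @export
eta2p_to_f <- function(eta2p) {
  stopifnot(all(eta2p >= 0 & eta2p < 1))
  sqrt(eta2p / (1 - eta2p))
}
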