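# In-code fixture builders: everything the suite needs is generated here.

# One IRAP block (24 trials) with given latencies (length 24, recycled)
# and accuracy pattern.
make_irap_block <- function(pid, phase, pair, rule, latencies,
                            correct = TRUE, trial_types = rep(1:4, each = 6)) {
  data.frame(participant_id = pid, phase = phase, pair_index = pair,
             block_rule = rule, trial_type = trial_types,
             latency_ms = rep_len(latencies, 24L),
             first_response_correct = rep_len(correct, 24L),
             stringsAsFactors = FALSE)
}

# A full test phase (3 pairs x 2 blocks) where the latency in each
# (pair, trial_type, rule) cell is drawn by `cell_fun(pair, tt, rule)`
# returning 6 latencies.
make_irap_test <- function(pid, cell_fun) {
  do.call(rbind, lapply(1:3, function(p) {
    do.call(rbind, lapply(c("straight_block", "lesbian_block"), function(rule) {
      lat <- unlist(lapply(1:4, function(tt) cell_fun(p, tt, rule)))
      make_irap_block(pid, "test", p, rule, lat,
                      trial_types = rep(1:4, each = 6))
    }))
  }))
}

# Passing practice pair: high accuracy, fast medians.
make_practice_pair <- function(pid, pair, accuracy = 0.9, median_ms = 1500) {
  do.call(rbind, lapply(c("straight_block", "lesbian_block"), function(rule) {
    make_irap_block(pid, "practice", pair, rule,
                    latencies = median_ms + seq(-100, 130, by = 10),
                    correct = rep(c(TRUE, FALSE),
                                  c(round(24 * accuracy), 24 - round(24 * accuracy))))
  }))
}

# Simple complete IRAP participant: practice pass + lognormal test latencies.
make_irap_participant <- function(pid, effect = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  test <- make_irap_test(pid, function(p, tt, rule) {
    mu <- log(1500) + if (rule == "lesbian_block") effect else 0
    exp(rnorm(6, mu, 0.4))
  })
  rbind(make_practice_pair(pid, 1), test)
}

# One FAST test block with a given correctness vector (length 50).
make_fast_block <- function(pid, rule, correct, phase = "test",
                            timeout = FALSE) {
  n <- length(correct)
  data.frame(participant_id = pid, phase = phase, block_rule = rule,
             trial_index = seq_len(n),
             stimulus_class = rep_len(c("male_pic", "female_pic",
                                        "pos_word", "neg_word"), n),
             correct = correct & !timeout, timeout = rep_len(timeout, n),
             stringsAsFactors = FALSE)
}

make_fast_participant <- function(pid, correct_straight, correct_lesbian) {
  rbind(make_fast_block(pid, "straight_block", rep_len(TRUE, 16), phase = "practice"),
        make_fast_block(pid, "straight_block", correct_straight),
        make_fast_block(pid, "lesbian_block", correct_lesbian))
}

make_ksog_grid <- function(pid, ratings) {
  data.frame(participant_id = pid, item = rep(1:7, 3),
             timeframe = rep(c("past", "present", "ideal"), each = 7),
             rating = as.integer(rep_len(ratings, 21L)),
             stringsAsFactors = FALSE)
}

# Brute-force oracles -------------------------------------------------------

# Mann-Whitney count by explicit pair enumeration, ties half-weighted.
oracle_mw_count <- function(x, y) {
  w <- 0
  for (xi in x) for (yj in y) w <- w + (xi > yj) + 0.5 * (xi == yj)
  w
}

oracle_cliffs_delta <- function(x, y) {
  gt <- 0; lt <- 0
  for (xi in x) for (yj in y) { gt <- gt + (xi > yj); lt <- lt + (xi < yj) }
  (gt - lt) / (length(x) * length(y))
}

# Straight-line D-score reimplementation materializing all 12 SDs and
# 24 means explicitly.
oracle_d_scores <- function(trials) {
  per_pair <- matrix(NA_real_, 3, 4)
  for (p in 1:3) for (tt in 1:4) {
    s <- trials$latency_ms[trials$pair_index == p & trials$trial_type == tt &
                             trials$block_rule == "straight_block"]
    l <- trials$latency_ms[trials$pair_index == p & trials$trial_type == tt &
                             trials$block_rule == "lesbian_block"]
    per_pair[p, tt] <- (mean(l) - mean(s)) / sd(c(s, l))
  }
  list(per_pair = per_pair, per_type = colMeans(per_pair),
       averaged = mean(colMeans(per_pair)))
}

# Closed-form OLS slope for a 0/1 correctness sequence.
oracle_slope <- function(correct) {
  y <- cumsum(correct); x <- seq_along(correct)
  unname(coef(lm(y ~ x))[2])
}

# Balanced split-plot sums of squares from explicit marginal means
# (equal group sizes only).
oracle_split_plot_ss <- function(scores, groups) {
  N <- nrow(scores); m <- ncol(scores)
  groups <- factor(groups); G <- nlevels(groups)
  stopifnot(length(unique(table(groups))) == 1L)
  grand <- mean(scores)
  subj <- rowMeans(scores)
  gm <- tapply(subj, groups, mean)                       # group means
  tm <- colMeans(scores)                                 # measure means
  cm <- apply(scores, 2, function(col) tapply(col, groups, mean))  # G x m cells
  n_g <- unname(table(groups)[1])
  ss_group <- m * sum(n_g * (gm - grand)^2)
  ss_sw <- m * sum((subj - gm[as.integer(groups)])^2)
  ss_tt <- N * sum((tm - grand)^2)
  ss_int <- n_g * sum((cm - outer(gm, rep(1, m)) -
                         outer(rep(1, G), tm) + grand)^2)
  ss_total <- sum((scores - grand)^2)
  list(group = ss_group, subjects_within = ss_sw, measure = ss_tt,
       interaction = ss_int, residual = ss_total - ss_group - ss_sw -
         ss_tt - ss_int, total = ss_total)
}

# Midrank Spearman oracle.
oracle_spearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}
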