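#' Practice-criterion gate for one IRAP participant
#'
#' A participant qualifies for the test phase when some practice block
#' pair (among at most three attempts) satisfies, in each of its two
#' blocks, first-response accuracy of at least 80\% and a median
#' response latency strictly below 2000 ms. The accuracy bound is
#' inclusive and the latency bound exclusive, read literally from the
#' task's "at least 80\% ... within a median response time of less than
#' 2000 ms" criterion. Participants who never pass keep their FAST and
#' KSOG data but have no D scores.
#'
#' @param trials IRAP trials of a single participant (any phases; only
#'   the practice phase is used).
#' @param accuracy_min inclusive accuracy criterion (default 0.80).
#' @param median_max exclusive median-latency criterion in ms (default 2000).
#' @return list with \code{eligible} (logical) and \code{pairs_used}
#'   (index of the first passing pair, or the number of pairs attempted
#'   when none passes).
#' @export
practice_gate <- function(trials, accuracy_min = 0.80, median_max = 2000) {
  practice <- trials[trials$phase == "practice", , drop = FALSE]
  if (nrow(practice) == 0L) {
    stop("no practice-phase trials: eligibility cannot be adjudicated",
         call. = FALSE)
  }
  pairs <- sort(unique(practice$pair_index))
  for (k in seq_along(pairs)) {
    pp <- practice[practice$pair_index == pairs[k], , drop = FALSE]
    rules <- unique(pp$block_rule)
    if (length(rules) < 2L) next   # incomplete pair cannot pass
    pass <- vapply(BLOCK_RULE_LEVELS, function(rule) {
      blk <- pp[pp$block_rule == rule, , drop = FALSE]
      nrow(blk) > 0L &&
        mean(blk$first_response_correct) >= accuracy_min &&
        stats::median(blk$latency_ms) < median_max
    }, logical(1L))
    if (all(pass)) return(list(eligible = TRUE, pairs_used = k))
  }
  list(eligible = FALSE, pairs_used = length(pairs))
}

#' Long-latency trial filter
#'
#' Removes test trials with latencies strictly above 10,000 ms; a
#' latency of exactly 10,000 ms is retained. Trials faster than 300 ms
#' are kept here (they feed the participant-level fast-responder rule
#' instead).
#'
#' @param trials test-phase IRAP trials.
#' @param max_latency exclusive upper bound in ms (default 10000).
#' @return the retained trials.
#' @export
apply_trial_filter <- function(trials, max_latency = 10000) {
  trials[trials$latency_ms <= max_latency, , drop = FALSE]
}

#' Fast-responder participant exclusion
#'
#' A participant is excluded when strictly more than 10\% of her
#' test-block trials carry latencies shorter than 300 ms. The proportion
#' is computed over all test trials, before the long-latency filter.
#'
#' @param trials test-phase IRAP trials of one participant.
#' @param fast_cutoff latency bound in ms (default 300, exclusive).
#' @param max_proportion exclusive proportion bound (default 0.10).
#' @return logical: \code{TRUE} when the participant must be excluded.
#' @export
fast_responder_check <- function(trials, fast_cutoff = 300, max_proportion = 0.10) {
  if (nrow(trials) == 0L) return(FALSE)
  mean(trials$latency_ms < fast_cutoff) > max_proportion
}

#' D scores for one participant's IRAP test trials
#'
#' Implements the D-score algorithm on retained test-phase latencies.
#' For each of the 3 test block pairs and each of the 4 trial types, the
#' latencies of the pair's two blocks are pooled and their sample
#' (n-1 denominator) standard deviation computed; the score is the mean
#' latency of the "Lesbian woman" block minus the mean latency of the
#' "Straight woman" block, divided by that pooled SD. This yields 12
#' pair-by-trial-type scores; averaging over pairs gives one score per
#' trial type, and averaging those gives the overall score. Positive
#' values indicate faster responding under the "Straight woman" rule.
#'
#' @param trials retained test-phase trials of one participant (after
#'   [apply_trial_filter()]).
#' @return an object of class \code{"dscore_set"}: list with
#'   \code{per_pair} (3 x 4 matrix), \code{per_type} (length 4),
#'   \code{averaged}, \code{d_male} (mean of trial types 1-2) and
#'   \code{d_female} (mean of trial types 3-4).
#' @export
compute_d_scores <- function(trials) {
  pairs <- sort(unique(as.integer(trials$pair_index)))
  if (!identical(pairs, 1:3)) {
    stop("expected exactly 3 test block pairs, got indices {",
         paste(pairs, collapse = ","), "}", call. = FALSE)
  }
  per_pair <- matrix(NA_real_, nrow = 3L, ncol = 4L,
                     dimnames = list(pair = 1:3, trial_type = 1:4))
  for (p in 1:3) {
    for (tt in 1:4) {
      cell <- trials[trials$pair_index == p & trials$trial_type == tt, , drop = FALSE]
      lat_straight <- cell$latency_ms[cell$block_rule == "straight_block"]
      lat_lesbian  <- cell$latency_ms[cell$block_rule == "lesbian_block"]
      if (length(lat_straight) < 2L || length(lat_lesbian) < 2L) {
        stop(sprintf("too few retained latencies in pair %d, trial type %d", p, tt),
             call. = FALSE)
      }
      pooled_sd <- stats::sd(c(lat_straight, lat_lesbian))
      if (pooled_sd == 0) {
        stop(sprintf("zero pooled SD in pair %d, trial type %d", p, tt),
             call. = FALSE)
      }
      per_pair[p, tt] <- (mean(lat_lesbian) - mean(lat_straight)) / pooled_sd
    }
  }
  per_type <- colMeans(per_pair)
  structure(list(per_pair = per_pair,
                 per_type = per_type,
                 averaged = mean(per_type),
                 d_male   = mean(per_type[1:2]),
                 d_female = mean(per_type[3:4])),
            class = "dscore_set")
}

#' @export
print.dscore_set <- function(x, digits = 3, ...) {
  cat("IRAP D scores (positive = faster under the straight-block rule)\n")
  cat("  per trial type:", paste(sprintf("tt%d=%.*f", 1:4, digits, x$per_type),
                                 collapse = "  "), "\n")
  cat(sprintf("  averaged: %.*f   male pictures: %.*f   female pictures: %.*f\n",
              digits, x$averaged, digits, x$d_male, digits, x$d_female))
  invisible(x)
}

#' Score the IRAP for a whole cohort
#'
#' Applies the fixed pipeline per participant: discard practice trials
#' from scoring, adjudicate the practice gate, apply the fast-responder
#' participant rule (over all test trials), drop long-latency trials,
#' then compute D scores. Excluded participants keep a row with missing
#' scores and an \code{excluded_reason} of \code{practice_fail} or
#' \code{fast_responder}.
#'
#' @param trials IRAP trial data.frame for any number of participants.
#' @param require_practice if \code{TRUE} (default) participants without
#'   practice trials are treated as ineligible; set \code{FALSE} to score
#'   logs that only contain the test phase.
#' @return data.frame with one row per participant: \code{participant_id},
#'   \code{excluded_reason} (\code{none}/\code{practice_fail}/
#'   \code{fast_responder}), \code{pairs_used}, \code{d_tt1..d_tt4},
#'   \code{d_avg}, \code{d_male}, \code{d_female}.
#' @export
score_irap <- function(trials, require_practice = TRUE) {
  ids <- unique(trials$participant_id)
  rows <- lapply(ids, function(pid) {
    tp <- trials[trials$participant_id == pid, , drop = FALSE]
    out <- data.frame(participant_id = pid, excluded_reason = "none",
                      pairs_used = NA_integer_,
                      d_tt1 = NA_real_, d_tt2 = NA_real_,
                      d_tt3 = NA_real_, d_tt4 = NA_real_,
                      d_avg = NA_real_, d_male = NA_real_, d_female = NA_real_,
                      stringsAsFactors = FALSE)
    has_practice <- any(tp$phase == "practice")
    if (require_practice || has_practice) {
      gate <- practice_gate(tp)
      out$pairs_used <- gate$pairs_used
      if (!gate$eligible) {
        out$excluded_reason <- "practice_fail"
        return(out)
      }
    }
    test <- tp[tp$phase == "test", , drop = FALSE]
    if (fast_responder_check(test)) {
      out$excluded_reason <- "fast_responder"
      return(out)
    }
    ds <- compute_d_scores(apply_trial_filter(test))
    out[c("d_tt1", "d_tt2", "d_tt3", "d_tt4")] <- as.list(ds$per_type)
    out$d_avg <- ds$averaged
    out$d_male <- ds$d_male
    out$d_female <- ds$d_female
    out
  })
  do.call(rbind, rows)
}
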