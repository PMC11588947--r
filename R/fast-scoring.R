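#' Cumulative record of correct responses for one FAST block
#'
#' Orders the trials of a single test block by trial index and returns
#' the running count of correct responses (timeouts count as incorrect).
#' The count at trial i includes trial i.
#'
#' @param trials the trials of exactly one FAST block.
#' @return data.frame with \code{trial_index} and \code{cumulative_correct}.
#' @export
cumulative_record <- function(trials) {
  idx <- as.integer(trials$trial_index)
  if (anyDuplicated(idx)) stop("duplicated trial_index in block", call. = FALSE)
  if (!identical(sort(idx), seq_len(nrow(trials)))) {
    stop("missing trial_index in block: expected 1..", nrow(trials), call. = FALSE)
  }
  ord <- order(idx)
  correct <- trials$correct[ord] & !trials$timeout[ord]
  data.frame(trial_index = idx[ord], cumulative_correct = cumsum(correct))
}

#' Learning slope of a cumulative record
#'
#' Ordinary least-squares slope of the cumulative correct count on trial
#' order; the intercept is estimated but discarded. For a unit-increment
#' staircase the slope always lies in [0, 1]: it is the weighted share of
#' correct responses, so it doubles as a learning-rate index.
#'
#' @param record output of [cumulative_record()] (or any data.frame with
#'   \code{trial_index} and \code{cumulative_correct}).
#' @return the slope (correct responses per trial).
#' @export
learning_slope <- function(record) {
  if (nrow(record) < 2L) stop("record must have length >= 2", call. = FALSE)
  x <- record$trial_index
  y <- record$cumulative_correct
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Block-slope difference
#'
#' The FAST score: slope of the "Straight woman" block minus slope of
#' the "Lesbian woman" block. Positive values indicate faster learning
#' when male pictures share a response key with positive words.
#'
#' @param slope_straight,slope_lesbian per-block learning slopes.
#' @return list with the two slopes and \code{slope_difference}.
#' @export
slope_difference <- function(slope_straight, slope_lesbian) {
  if (is.na(slope_straight) || is.na(slope_lesbian)) {
    stop("both test-block slopes are required", call. = FALSE)
  }
  list(slope_straight = slope_straight, slope_lesbian = slope_lesbian,
       slope_difference = slope_straight - slope_lesbian)
}

#' Score the FAST for a whole cohort
#'
#' Builds each participant's two test-block cumulative records, fits the
#' learning slopes, and takes straight-block minus lesbian-block
#' differences. Practice trials never contribute.
#'
#' @param trials FAST trial data.frame for any number of participants.
#' @return data.frame with one row per participant: \code{participant_id},
#'   \code{slope_straight}, \code{slope_lesbian}, \code{slope_difference}.
#' @export
score_fast <- function(trials) {
  test <- trials[trials$phase == "test", , drop = FALSE]
  ids <- unique(trials$participant_id)
  rows <- lapply(ids, function(pid) {
    tp <- test[test$participant_id == pid, , drop = FALSE]
    slopes <- vapply(BLOCK_RULE_LEVELS, function(rule) {
      blk <- tp[tp$block_rule == rule, , drop = FALSE]
      if (nrow(blk) == 0L) {
        stop(sprintf("participant %s: missing %s test block", pid, rule),
             call. = FALSE)
      }
      learning_slope(cumulative_record(blk))
    }, numeric(1L))
    data.frame(participant_id = pid,
               slope_straight = slopes[["straight_block"]],
               slope_lesbian = slopes[["lesbian_block"]],
               slope_difference = slopes[["straight_block"]] - slopes[["lesbian_block"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
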