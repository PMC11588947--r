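#' Configuration for the synthetic cohort generator
#'
#' Defines every knob of the trial-level simulator: cohort composition,
#' the log-normal IRAP latency model, the exponential-learning FAST
#' accuracy model, and the KSOG rating model. The defaults emulate the
#' study conditions the analysis pipeline targets: 33 straight and 25
#' lesbian participants; IRAP latencies log-normal with a participant
#' random intercept and a per-trial-type log-latency increment applied
#' in each participant's history-incoherent block; FAST accuracy rising
#' from a floor to a ceiling at a block- and orientation-specific rate;
#' and 21-cell KSOG grids on the 1-7 integer scale. Default effect
#' parameters are calibrated by moment matching to the published group
#' moments (averaged D 0.10 (0.29) vs -0.43 (0.35); FAST slope
#' difference 0.02 (0.15) vs -0.20 (0.17); lesbian block slopes
#' 0.633/0.430) and are versioned in
#' \code{inst/extdata/default_config.yaml}.
#'
#' @param n_straight,n_lesbian group sizes.
#' @param seed RNG seed used by [generate_cohort()].
#' @param base_log_latency grand mean of log latency (log ms).
#' @param participant_sd SD of the participant random intercept (log ms).
#' @param residual_log_sd trial-level residual SD (log ms).
#' @param irap_effect_matrix 4 x 2 matrix (rows = trial types, columns =
#'   \code{straight}, \code{lesbian}) of mean log-latency increments
#'   applied in the history-incoherent block (the lesbian-rule block for
#'   straight participants and vice versa).
#' @param irap_effect_sd participant-level SD of a shift added to all
#'   four increments (individual bias heterogeneity); one value per
#'   orientation.
#' @param long_latency_rate per-trial probability of an aberrant >10 s
#'   latency (exercises the trial filter).
#' @param fast_responder_rate probability that a participant is a fast
#'   responder emitting sub-300 ms latencies at an elevated rate.
#' @param practice_fail_rate per-pair probability of failing the IRAP
#'   practice criteria (at most 3 attempts; all three failing makes the
#'   participant ineligible).
#' @param fast_p0,fast_p_inf floor and ceiling of FAST accuracy.
#' @param fast_learn_rate 2 x 2 matrix (rows = orientation, columns =
#'   block rule) of learning-rate constants kappa.
#' @param fast_kappa_sd participant-level log-normal jitter SD on kappa.
#' @param fast_timeout_rate per-trial timeout probability (timeouts are
#'   scored incorrect).
#' @param ksog_group_means,ksog_group_sds participant-level latent KSOG
#'   means and SDs, named \code{straight}/\code{lesbian}.
#' @param ksog_cell_sd cell-level rating noise before rounding to 1..7.
#' @param ksog_missing_lesbian number of lesbian participants whose KSOG
#'   grids are lost entirely (emulating recorded data loss).
#' @return an object of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_straight = 33, n_lesbian = 25, seed = 1,
                          base_log_latency = log(1500),
                          participant_sd = 0.20,
                          residual_log_sd = 0.45,
                          irap_effect_matrix = default_irap_effects(),
                          irap_effect_sd = c(straight = 0.127, lesbian = 0.174),
                          long_latency_rate = 0.01,
                          fast_responder_rate = 0,
                          practice_fail_rate = 0.557,
                          fast_p0 = 0.35, fast_p_inf = 0.95,
                          fast_learn_rate = default_fast_kappa(),
                          fast_kappa_sd = 0.65,
                          fast_timeout_rate = 0.02,
                          ksog_group_means = c(straight = 1.20, lesbian = 4.32),
                          ksog_group_sds = c(straight = 0.80, lesbian = 0.56),
                          ksog_cell_sd = 0.5,
                          ksog_missing_lesbian = 4) {
  cfg <- list(n_straight = n_straight, n_lesbian = n_lesbian, seed = seed,
              base_log_latency = base_log_latency,
              participant_sd = participant_sd,
              residual_log_sd = residual_log_sd,
              irap_effect_matrix = irap_effect_matrix,
              irap_effect_sd = irap_effect_sd,
              long_latency_rate = long_latency_rate,
              fast_responder_rate = fast_responder_rate,
              practice_fail_rate = practice_fail_rate,
              fast_p0 = fast_p0, fast_p_inf = fast_p_inf,
              fast_learn_rate = fast_learn_rate,
              fast_kappa_sd = fast_kappa_sd,
              fast_timeout_rate = fast_timeout_rate,
              ksog_group_means = ksog_group_means,
              ksog_group_sds = ksog_group_sds,
              ksog_cell_sd = ksog_cell_sd,
              ksog_missing_lesbian = ksog_missing_lesbian)
  rates <- c(long_latency_rate, fast_responder_rate, practice_fail_rate,
             fast_timeout_rate, fast_p0, fast_p_inf)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  if (n_straight < 2 || n_lesbian < 2) stop("group sizes must be >= 2", call. = FALSE)
  if (any(c(participant_sd, residual_log_sd) <= 0)) {
    stop("latency SDs must be positive", call. = FALSE)
  }
  if (!is.matrix(irap_effect_matrix) || !all(dim(irap_effect_matrix) == c(4L, 2L))) {
    stop("irap_effect_matrix must be 4 trial-types x 2 orientations", call. = FALSE)
  }
  if (!is.matrix(fast_learn_rate) || !all(dim(fast_learn_rate) == c(2L, 2L)) ||
      any(fast_learn_rate < 0)) {
    stop("fast_learn_rate must be a nonnegative 2 x 2 matrix", call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

#' Default IRAP incoherence increments (log-latency units)
#'
#' Rows are trial types 1-4 (male-attractive, male-unattractive,
#' female-attractive, female-unattractive), columns the participant's
#' orientation. Values are increments applied in the history-incoherent
#' block, so a positive straight-column entry yields a positive D score
#' for straight participants, and a positive lesbian-column entry a
#' negative one. The straight column concentrates the effect on the
#' male-picture trial types, reproducing the published pattern in which
#' straight participants show no significant female-picture effect.
#'
#' @return a 4 x 2 numeric matrix.
#' @export
default_irap_effects <- function() {
  matrix(c(0.1875, 0.1313, -0.0609, -0.0703,  # straight participants
           -0.0208, 0.2031, 0.4062, 0.3021),  # lesbian participants
         nrow = 4L, dimnames = list(trial_type = 1:4,
                                    orientation = ORIENTATION_LEVELS))
}

#' Default FAST learning-rate constants
#'
#' Rows are orientations, columns block rules. Straight participants
#' learn both contingencies at a similar rate; lesbian participants
#' learn the lesbian-rule block markedly faster, reproducing the
#' published block-slope asymmetry (0.633 vs 0.430).
#'
#' @return a 2 x 2 numeric matrix of kappa values.
#' @export
default_fast_kappa <- function() {
  matrix(c(0.0153, 0.0053,  # straight_block column: straight, lesbian rows
           0.0132, 0.0269),  # lesbian_block column
         nrow = 2L, dimnames = list(orientation = ORIENTATION_LEVELS,
                                    block_rule = BLOCK_RULE_LEVELS))
}

#' A no-effect configuration
#'
#' All group effects removed: zero incoherence increments, identical
#' learning rates everywhere, identical KSOG distributions. Useful for
#' null calibration checks (false-positive rates, AUC near 0.5).
#'
#' @param ... overrides passed on to [cohort_config()].
#' @return a \code{cohort_config}.
#' @export
null_cohort_config <- function(...) {
  kap <- matrix(0.012, 2, 2, dimnames = dimnames(default_fast_kappa()))
  cohort_config(irap_effect_matrix = matrix(0, 4, 2,
                                            dimnames = dimnames(default_irap_effects())),
                fast_learn_rate = kap,
                ksog_group_means = c(straight = 2.8, lesbian = 2.8),
                ksog_group_sds = c(straight = 0.6, lesbian = 0.6),
                ksog_missing_lesbian = 0, ...)
}

# One 24-trial IRAP block: trial types randomized 6 each.
.irap_block_tts <- function() sample(rep(1:4, 6L))

# Latencies for one test or passing-practice block.
.irap_block_latency <- function(cfg, intercept, increments, incoherent) {
  tts <- .irap_block_tts()
  mu <- cfg$base_log_latency + intercept +
    (if (incoherent) increments[tts] else 0)
  lat <- exp(stats::rnorm(24L, mu, cfg$residual_log_sd))
  long <- stats::runif(24L) < cfg$long_latency_rate
  lat[long] <- stats::runif(sum(long), 10500, 14000)
  list(tts = tts, latency = lat)
}

#' Generate a synthetic trial-level cohort
#'
#' Draws a complete cohort - participant manifest, IRAP practice and
#' test trials, FAST practice and test trials, and KSOG grids - from a
#' [cohort_config()]. Fully reproducible: the same configuration (seed
#' included) yields byte-identical data. Structure always satisfies the
#' interchange invariants (3 IRAP test pairs of 2 x 24 trials with each
#' trial type 6 per block; one 16-trial FAST practice block and two
#' 50-trial test blocks; at most 21 KSOG cells).
#'
#' @param config a \code{cohort_config}.
#' @return an \code{irap_cohort} object (see [as_cohort()]).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_straight + cfg$n_lesbian
  ids <- sprintf("P%03d", seq_len(n))
  orientation <- rep(ORIENTATION_LEVELS, c(cfg$n_straight, cfg$n_lesbian))
  participants <- data.frame(participant_id = ids, orientation = orientation,
                             stringsAsFactors = FALSE)

  irap_rows <- vector("list", n)
  fast_rows <- vector("list", n)
  ksog_rows <- vector("list", n)

  for (i in seq_len(n)) {
    pid <- ids[i]
    orient <- orientation[i]
    intercept <- stats::rnorm(1L, 0, cfg$participant_sd)
    shift <- stats::rnorm(1L, 0, .per_orient(cfg$irap_effect_sd, orient))
    increments <- cfg$irap_effect_matrix[, orient] + shift
    incoherent_rule <- if (orient == "straight") "lesbian_block" else "straight_block"
    fast_responder <- stats::runif(1L) < cfg$fast_responder_rate

    ## --- IRAP practice: up to 3 pair attempts -------------------------
    blocks <- list()
    eligible <- FALSE
    for (attempt in 1:3) {
      pass <- stats::runif(1L) >= cfg$practice_fail_rate
      for (rule in sample(BLOCK_RULE_LEVELS)) {
        tts <- .irap_block_tts()
        if (pass) {
          lat <- exp(stats::rnorm(24L, log(1300), 0.25))
          acc <- stats::runif(24L) < 0.95
        } else {
          lat <- exp(stats::rnorm(24L, log(2600), 0.25))
          acc <- stats::runif(24L) < 0.65
        }
        blocks[[length(blocks) + 1L]] <- data.frame(
          participant_id = pid, phase = "practice", pair_index = attempt,
          block_rule = rule, trial_type = tts, latency_ms = lat,
          first_response_correct = acc, stringsAsFactors = FALSE)
      }
      if (pass) { eligible <- TRUE; break }
    }

    ## --- IRAP test: exactly 3 pairs (only run for eligible women) -----
    if (eligible) {
      for (pair in 1:3) {
        for (rule in sample(BLOCK_RULE_LEVELS)) {
          blk <- .irap_block_latency(cfg, intercept, increments,
                                     incoherent = rule == incoherent_rule)
          lat <- blk$latency
          if (fast_responder) {
            quick <- stats::runif(24L) < 0.15
            lat[quick] <- stats::runif(sum(quick), 150, 295)
          }
          blocks[[length(blocks) + 1L]] <- data.frame(
            participant_id = pid, phase = "test", pair_index = pair,
            block_rule = rule, trial_type = blk$tts, latency_ms = lat,
            first_response_correct = stats::runif(24L) < 0.90,
            stringsAsFactors = FALSE)
        }
      }
    }
    irap_rows[[i]] <- do.call(rbind, blocks)

    ## --- FAST: 16 practice + 2 x 50 test trials -----------------------
    fast_blocks <- list(data.frame(
      participant_id = pid, phase = "practice", block_rule = "straight_block",
      trial_index = 1:16, stimulus_class = sample(STIMULUS_LEVELS, 16L, TRUE),
      correct = stats::runif(16L) < 0.6, timeout = stats::runif(16L) < cfg$fast_timeout_rate,
      stringsAsFactors = FALSE))
    for (rule in sample(BLOCK_RULE_LEVELS)) {
      kappa <- cfg$fast_learn_rate[orient, rule] *
        exp(stats::rnorm(1L, 0, cfg$fast_kappa_sd))
      acc <- fast_accuracy_model(kappa, n_trials = 50L, p0 = cfg$fast_p0,
                                 p_inf = cfg$fast_p_inf,
                                 timeout_rate = cfg$fast_timeout_rate)
      fast_blocks[[length(fast_blocks) + 1L]] <- data.frame(
        participant_id = pid, phase = "test", block_rule = rule,
        trial_index = seq_len(50L),
        stimulus_class = sample(STIMULUS_LEVELS, 50L, TRUE),
        correct = acc$correct, timeout = acc$timeout, stringsAsFactors = FALSE)
    }
    fast <- do.call(rbind, fast_blocks)
    fast$correct <- fast$correct & !fast$timeout
    fast_rows[[i]] <- fast

    ## --- KSOG: 7 items x 3 timeframes ---------------------------------
    latent <- stats::rnorm(1L, cfg$ksog_group_means[orient],
                           cfg$ksog_group_sds[orient])
    latent <- min(max(latent, 1), 7)
    ratings <- round(latent + stats::rnorm(21L, 0, cfg$ksog_cell_sd))
    ratings <- pmin(pmax(ratings, 1L), 7L)
    ksog_rows[[i]] <- data.frame(
      participant_id = pid, item = rep(1:7, times = 3L),
      timeframe = rep(TIMEFRAME_LEVELS, each = 7L),
      rating = as.integer(ratings), stringsAsFactors = FALSE)
  }

  ksog <- do.call(rbind, ksog_rows)
  if (cfg$ksog_missing_lesbian > 0L) {
    lesbian_ids <- ids[orientation == "lesbian"]
    lost <- sample(lesbian_ids, min(cfg$ksog_missing_lesbian, length(lesbian_ids)))
    ksog <- ksog[!(ksog$participant_id %in% lost), , drop = FALSE]
  }
  rownames(ksog) <- NULL

  as_cohort(participants,
            do.call(rbind, irap_rows),
            do.call(rbind, fast_rows),
            ksog)
}

#' Read / write a generator configuration as YAML
#'
#' @param path file path.
#' @param config a \code{cohort_config}.
#' @rdname config_io
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$irap_effect_matrix)) {
    raw$irap_effect_matrix <- matrix(unlist(raw$irap_effect_matrix), nrow = 4L,
                                     dimnames = dimnames(default_irap_effects()))
  }
  if (!is.null(raw$fast_learn_rate)) {
    raw$fast_learn_rate <- matrix(unlist(raw$fast_learn_rate), nrow = 2L,
                                  dimnames = dimnames(default_fast_kappa()))
  }
  for (nm in c("ksog_group_means", "ksog_group_sds", "irap_effect_sd")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(cohort_config, raw)
}

#' @rdname config_io
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  out <- unclass(config)
  out$irap_effect_matrix <- apply(config$irap_effect_matrix, 2L, as.list,
                                  simplify = FALSE)
  out$fast_learn_rate <- apply(config$fast_learn_rate, 2L, as.list,
                               simplify = FALSE)
  out$ksog_group_means <- as.list(config$ksog_group_means)
  out$ksog_group_sds <- as.list(config$ksog_group_sds)
  out$irap_effect_sd <- as.list(config$irap_effect_sd)
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort configuration: %d straight + %d lesbian, seed %s\n",
              x$n_straight, x$n_lesbian, format(x$seed)))
  cat("  IRAP incoherence increments (log-latency):\n")
  print(round(x$irap_effect_matrix, 3))
  cat("  FAST learning rates (kappa):\n")
  print(round(x$fast_learn_rate, 3))
  invisible(x)
}

# Recycle a scalar or pick the orientation-specific entry of a length-2
# (straight, lesbian) parameter vector.
.per_orient <- function(x, orient) {
  if (length(x) == 1L) return(x)
  if (!is.null(names(x))) return(x[[orient]])
  x[[match(orient, ORIENTATION_LEVELS)]]
}

#' FAST accuracy model for one block
#'
#' Draws trial-by-trial correctness for a feedback-driven block: the
#' probability of a correct response rises from the floor p0 toward the
#' ceiling p_inf as P(correct at t) = p_inf - (p_inf - p0) exp(-kappa t).
#' Timeouts are drawn independently and force the trial incorrect, as
#' in the task (no response within the deadline scores as wrong).
#'
#' @param kappa learning-rate constant (>= 0); larger values mean the
#'   contingency is acquired faster.
#' @param n_trials number of trials in the block.
#' @param p0,p_inf accuracy floor and ceiling.
#' @param timeout_rate per-trial timeout probability.
#' @return data.frame with logical columns \code{correct} and
#'   \code{timeout}.
#' @export
fast_accuracy_model <- function(kappa, n_trials = 50L, p0 = 0.35,
                                p_inf = 0.95, timeout_rate = 0.02) {
  stopifnot(kappa >= 0, n_trials >= 1)
  t <- seq_len(n_trials)
  p <- p_inf - (p_inf - p0) * exp(-kappa * t)
  correct <- stats::runif(n_trials) < p
  timeout <- stats::runif(n_trials) < timeout_rate
  data.frame(correct = correct & !timeout, timeout = timeout)
}
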