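#' @keywords internal
"_PACKAGE"

## Closed vocabularies shared by the whole package.
ORIENTATION_LEVELS <- c("straight", "lesbian")
BLOCK_RULE_LEVELS  <- c("straight_block", "lesbian_block")
PHASE_LEVELS       <- c("practice", "test")
STIMULUS_LEVELS    <- c("male_pic", "female_pic", "pos_word", "neg_word")
TIMEFRAME_LEVELS   <- c("past", "present", "ideal")

# Column schemas for the four interchange CSVs. type is one of
# "character", "integer", "real", "logical", "enum"; enums carry levels.
.irap_schema <- list(
  participant_id = list(type = "character"),
  phase          = list(type = "enum", levels = PHASE_LEVELS),
  pair_index     = list(type = "integer", min = 1L),
  block_rule     = list(type = "enum", levels = BLOCK_RULE_LEVELS),
  trial_type     = list(type = "integer", min = 1L, max = 4L),
  latency_ms     = list(type = "real", min = 0, exclusive_min = TRUE),
  first_response_correct = list(type = "logical")
)

.fast_schema <- list(
  participant_id = list(type = "character"),
  phase          = list(type = "enum", levels = PHASE_LEVELS),
  block_rule     = list(type = "enum", levels = BLOCK_RULE_LEVELS),
  trial_index    = list(type = "integer", min = 1L),
  stimulus_class = list(type = "enum", levels = STIMULUS_LEVELS),
  correct        = list(type = "logical"),
  timeout        = list(type = "logical")
)

.ksog_schema <- list(
  participant_id = list(type = "character"),
  item           = list(type = "integer", min = 1L, max = 7L),
  timeframe      = list(type = "enum", levels = TIMEFRAME_LEVELS),
  rating         = list(type = "integer", min = 1L, max = 7L, na_ok = TRUE)
)

.manifest_schema <- list(
  participant_id = list(type = "character"),
  orientation    = list(type = "enum", levels = ORIENTATION_LEVELS)
)

# Parse one raw character column against its schema entry. Returns the
# coerced vector or stops with a message naming the first offending data
# row (1-based, excluding the header line).
.parse_column <- function(raw, name, spec) {
  na_ok <- isTRUE(spec$na_ok)
  missing_mask <- is.na(raw) | raw == ""
  if (any(missing_mask) && !na_ok) {
    stop(sprintf("column '%s': missing value on row %d", name,
                 which(missing_mask)[1L]), call. = FALSE)
  }
  out <- switch(spec$type,
    character = raw,
    enum = {
      bad <- !missing_mask & !(raw %in% spec$levels)
      if (any(bad)) {
        stop(sprintf("column '%s': unknown value '%s' on row %d (allowed: %s)",
                     name, raw[which(bad)[1L]], which(bad)[1L],
                     paste(spec$levels, collapse = ", ")), call. = FALSE)
      }
      raw
    },
    logical = {
      bad <- !missing_mask & !(raw %in% c("true", "false", "TRUE", "FALSE"))
      if (any(bad)) {
        stop(sprintf("column '%s': unparseable boolean '%s' on row %d",
                     name, raw[which(bad)[1L]], which(bad)[1L]), call. = FALSE)
      }
      raw %in% c("true", "TRUE")
    },
    integer = ,
    real = {
      num <- suppressWarnings(as.numeric(raw))
      bad <- !missing_mask & is.na(num)
      if (any(bad)) {
        stop(sprintf("column '%s': unparseable number '%s' on row %d",
                     name, raw[which(bad)[1L]], which(bad)[1L]), call. = FALSE)
      }
      if (spec$type == "integer") {
        off <- !is.na(num) & num != round(num)
        if (any(off)) {
          stop(sprintf("column '%s': non-integer value '%s' on row %d",
                       name, raw[which(off)[1L]], which(off)[1L]), call. = FALSE)
        }
        num <- as.integer(round(num))
      }
      if (!is.null(spec$min)) {
        lo <- if (isTRUE(spec$exclusive_min)) num <= spec$min else num < spec$min
        lo[is.na(lo)] <- FALSE
        if (any(lo)) {
          stop(sprintf("column '%s': value %s below admissible range on row %d",
                       name, raw[which(lo)[1L]], which(lo)[1L]), call. = FALSE)
        }
      }
      if (!is.null(spec$max)) {
        hi <- num > spec$max
        hi[is.na(hi)] <- FALSE
        if (any(hi)) {
          stop(sprintf("column '%s': value %s above admissible range on row %d",
                       name, raw[which(hi)[1L]], which(hi)[1L]), call. = FALSE)
        }
      }
      num
    },
    stop("unknown schema type"))
  if (na_ok) out[missing_mask] <- NA
  out
}

.read_log <- function(path, schema, what) {
  if (!file.exists(path)) stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  missing_cols <- setdiff(names(schema), names(raw))
  if (length(missing_cols) > 0L) {
    stop(sprintf("%s file %s: missing column(s) %s", what, path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  out <- lapply(names(schema), function(nm) .parse_column(raw[[nm]], nm, schema[[nm]]))
  names(out) <- names(schema)
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Read trial-level IRAP logs
#'
#' Reads a CSV with one row per IRAP trial (columns \code{participant_id,
#' phase, pair_index, block_rule, trial_type, latency_ms,
#' first_response_correct}). The file is parsed strictly: a malformed
#' value rejects the whole file with a message naming the offending row.
#' Structural deviations (a participant whose test phase is not 3 block
#' pairs of 2 x 24 trials with each trial type 6 times per block) are
#' reported as warnings, not errors, because real sessions can be aborted.
#'
#' @param path path to the CSV file.
#' @return a data.frame of trials, one row per trial.
#' @seealso [write_irap_log()], [validate_irap_structure()]
#' @export
read_irap_log <- function(path) {
  trials <- .read_log(path, .irap_schema, "IRAP log")
  msgs <- validate_irap_structure(trials)
  for (m in msgs) warning(m, call. = FALSE)
  trials
}

#' Read trial-level FAST logs
#'
#' One row per FAST trial (\code{participant_id, phase, block_rule,
#' trial_index, stimulus_class, correct, timeout}). A timeout trial must
#' be recorded as incorrect; violations reject the file. Test blocks that
#' do not hold exactly 50 trials raise a structure warning.
#'
#' @inheritParams read_irap_log
#' @return a data.frame of trials.
#' @export
read_fast_log <- function(path) {
  trials <- .read_log(path, .fast_schema, "FAST log")
  bad <- trials$timeout & trials$correct
  if (any(bad)) {
    stop(sprintf("FAST log: timeout trial marked correct on row %d",
                 which(bad)[1L]), call. = FALSE)
  }
  msgs <- validate_fast_structure(trials)
  for (m in msgs) warning(m, call. = FALSE)
  trials
}

#' Read KSOG rating grids
#'
#' Long format: one row per grid cell (\code{participant_id, item,
#' timeframe, rating}) with 7 items crossed with the past/present/ideal
#' timeframes; ratings are integers 1-7 or empty (missing).
#'
#' @inheritParams read_irap_log
#' @return a data.frame of grid cells.
#' @export
read_ksog <- function(path) {
  cells <- .read_log(path, .ksog_schema, "KSOG grid")
  dup <- duplicated(cells[c("participant_id", "item", "timeframe")])
  if (any(dup)) {
    stop(sprintf("KSOG grid: duplicated cell on row %d", which(dup)[1L]),
         call. = FALSE)
  }
  cells
}

#' Read the participant manifest
#'
#' Columns \code{participant_id, orientation}; orientation is a closed
#' two-level vocabulary (\code{straight}, \code{lesbian}) mirroring the
#' study design, so any other label rejects the file.
#'
#' @inheritParams read_irap_log
#' @return a data.frame with one row per participant.
#' @export
read_manifest <- function(path) {
  manifest <- .read_log(path, .manifest_schema, "manifest")
  dup <- duplicated(manifest$participant_id)
  if (any(dup)) {
    stop(sprintf("manifest: duplicated participant_id on row %d",
                 which(dup)[1L]), call. = FALSE)
  }
  manifest
}

.format_csv_col <- function(x) {
  if (is.logical(x)) return(ifelse(x, "true", "false"))
  if (is.double(x)) {
    out <- vapply(x, function(v) if (is.na(v)) "" else sprintf("%.17g", v), "")
    # trim to shortest representation that round-trips exactly
    short <- vapply(x, function(v) if (is.na(v)) "" else format(v, digits = 15), "")
    back <- suppressWarnings(as.numeric(short))
    same <- !is.na(back) & back == x
    out[same] <- short[same]
    return(out)
  }
  ifelse(is.na(x), "", as.character(x))
}

.write_log <- function(df, path, schema) {
  out <- df[names(schema)]
  for (nm in names(out)) out[[nm]] <- .format_csv_col(out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write interchange CSVs
#'
#' Serialize trial and rating collections back to the documented CSV
#' schemas (booleans as \code{true}/\code{false}, decimal point, UTF-8).
#' Writing then reading is the identity on every collection.
#'
#' @param trials,cells,manifest data.frame in the corresponding schema.
#' @param path output file path.
#' @return the path, invisibly.
#' @rdname write_logs
#' @export
write_irap_log <- function(trials, path) .write_log(trials, path, .irap_schema)

#' @rdname write_logs
#' @export
write_fast_log <- function(trials, path) .write_log(trials, path, .fast_schema)

#' @rdname write_logs
#' @export
write_ksog <- function(cells, path) .write_log(cells, path, .ksog_schema)

#' @rdname write_logs
#' @export
write_manifest <- function(manifest, path) .write_log(manifest, path, .manifest_schema)

#' Check IRAP test-phase structure
#'
#' A complete IRAP test phase has exactly 3 block pairs, each pair with
#' both block rules, 24 trials per block, and each of the 4 trial types
#' presented 6 times per block. Returns zero or more human-readable
#' deviation messages (empty character vector when the structure is clean).
#'
#' @param trials IRAP trial data.frame (any mix of participants/phases).
#' @return character vector of deviation messages.
#' @export
validate_irap_structure <- function(trials) {
  msgs <- character(0)
  test <- trials[trials$phase == "test", , drop = FALSE]
  for (pid in unique(trials$participant_id)) {
    tp <- test[test$participant_id == pid, , drop = FALSE]
    if (nrow(tp) == 0L) {
      msgs <- c(msgs, sprintf("participant %s: no test-phase IRAP trials", pid))
      next
    }
    pairs <- sort(unique(as.integer(tp$pair_index)))
    if (!identical(pairs, 1:3)) {
      msgs <- c(msgs, sprintf("participant %s: test pair indices are {%s}, expected {1,2,3}",
                              pid, paste(pairs, collapse = ",")))
    }
    counts <- table(factor(tp$block_rule, BLOCK_RULE_LEVELS),
                    factor(tp$pair_index, pairs),
                    factor(tp$trial_type, 1:4))
    if (length(pairs) > 0L && !all(counts == 6L)) {
      msgs <- c(msgs, sprintf(
        "participant %s: test-trial counts deviate from 6 per (pair, block, trial-type); got %d trials, expected %d",
        pid, nrow(tp), length(pairs) * 48L))
    }
  }
  msgs
}

#' Check FAST test-phase structure
#'
#' A complete FAST has exactly one test block per block rule, each with
#' trial indices 1..50, and a 16-trial practice block.
#'
#' @param trials FAST trial data.frame.
#' @return character vector of deviation messages.
#' @export
validate_fast_structure <- function(trials) {
  msgs <- character(0)
  for (pid in unique(trials$participant_id)) {
    tp <- trials[trials$participant_id == pid & trials$phase == "test", , drop = FALSE]
    for (rule in BLOCK_RULE_LEVELS) {
      idx <- sort(as.integer(tp$trial_index[tp$block_rule == rule]))
      if (!identical(idx, 1:50)) {
        msgs <- c(msgs, sprintf(
          "participant %s: %s test block has %d trials, expected indices 1..50",
          pid, rule, length(idx)))
      }
    }
  }
  msgs
}

#' Bundle the four record collections into one cohort object
#'
#' @param participants manifest data.frame (participant_id, orientation).
#' @param irap,fast,ksog trial / grid data.frames in the interchange schemas.
#' @return an object of class \code{"irap_cohort"}.
#' @export
as_cohort <- function(participants, irap, fast, ksog) {
  structure(list(participants = participants, irap = irap,
                 fast = fast, ksog = ksog),
            class = "irap_cohort")
}

#' Read / write a whole cohort directory
#'
#' A cohort directory holds \code{manifest.csv}, \code{irap.csv},
#' \code{fast.csv} and \code{ksog.csv}.
#'
#' @param dir directory path.
#' @param cohort an \code{irap_cohort} object.
#' @rdname cohort_dir
#' @export
read_cohort <- function(dir) {
  need <- file.path(dir, c("manifest.csv", "irap.csv", "fast.csv", "ksog.csv"))
  absent <- need[!file.exists(need)]
  if (length(absent) > 0L) {
    stop("cohort directory is missing: ", paste(basename(absent), collapse = ", "),
         call. = FALSE)
  }
  as_cohort(read_manifest(need[1L]), read_irap_log(need[2L]),
            read_fast_log(need[3L]), read_ksog(need[4L]))
}

#' @rdname cohort_dir
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "irap_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_manifest(cohort$participants, file.path(dir, "manifest.csv"))
  write_irap_log(cohort$irap, file.path(dir, "irap.csv"))
  write_fast_log(cohort$fast, file.path(dir, "fast.csv"))
  write_ksog(cohort$ksog, file.path(dir, "ksog.csv"))
  invisible(dir)
}

#' @export
print.irap_cohort <- function(x, ...) {
  n <- table(factor(x$participants$orientation, ORIENTATION_LEVELS))
  cat("Implicit-measure cohort\n")
  cat(sprintf("  participants: %d (%d straight, %d lesbian)\n",
              nrow(x$participants), n[["straight"]], n[["lesbian"]]))
  cat(sprintf("  IRAP trials:  %d (%d test)\n", nrow(x$irap),
              sum(x$irap$phase == "test")))
  cat(sprintf("  FAST trials:  %d (%d test)\n", nrow(x$fast),
              sum(x$fast$phase == "test")))
  cat(sprintf("  KSOG cells:   %d from %d grids\n", nrow(x$ksog),
              length(unique(x$ksog$participant_id))))
  invisible(x)
}
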