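#' Score one KSOG grid
#'
#' The Klein grid rates 7 orientation components against 3 timeframes
#' (past, present, ideal) on a 1-7 scale; the score is the arithmetic
#' mean of all non-missing cells, so 1 reads strictly heterosexual, 3.5
#' strictly bisexual, and 7 strictly homosexual. Missing cells are
#' dropped from the mean rather than imputed; an all-missing grid yields
#' a missing score.
#'
#' @param ratings integer vector of cell ratings (NA for missing cells).
#' @return the mean rating, or \code{NA} when no cell is present.
#' @export
ksog_score <- function(ratings) {
  if (length(ratings) > 21L) stop("a KSOG grid has at most 21 cells", call. = FALSE)
  present <- ratings[!is.na(ratings)]
  if (length(present) == 0L) return(NA_real_)
  if (any(present < 1 | present > 7)) stop("ratings must lie in 1..7", call. = FALSE)
  mean(present)
}

#' Score KSOG grids for a whole cohort
#'
#' @param cells long-format KSOG data.frame (\code{participant_id, item,
#'   timeframe, rating}).
#' @return data.frame with \code{participant_id}, \code{ksog_score} and
#'   \code{n_cells_used}.
#' @export
score_ksog <- function(cells) {
  ids <- unique(cells$participant_id)
  rows <- lapply(ids, function(pid) {
    r <- cells$rating[cells$participant_id == pid]
    data.frame(participant_id = pid, ksog_score = ksog_score(r),
               n_cells_used = sum(!is.na(r)), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
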