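#' Read and write session logs as CSV
#'
#' The session-log exchange format is one row per presentation with header
#' `subject_id,age,sex,position,picture_id,is_repeat,responded,rt_ms`
#' (`rt_ms` empty on non-responded trials). Reading validates the records:
#' missing columns abort, and malformed rows -- a response time without a
#' response, a responded trial without a response time, or an RT outside
#' (0, 3000) ms -- are rejected with their row numbers.
#'
#' @param path CSV file path.
#' @return `read_sessions()` returns the validated trial data frame (class
#'   `crt_sessions`); `write_sessions()` returns `path` invisibly.
#' @examples
#' sessions <- simulate_cohort(population_config(n_subjects = 2, seed = 1))
#' tmp <- tempfile(fileext = ".csv")
#' write_sessions(sessions, tmp)
#' identical(nrow(read_sessions(tmp)), nrow(sessions))
#' @export
read_sessions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_if_missing_cols(df, c("subject_id", "age", "sex", "position", "picture_id",
                             "is_repeat", "responded", "rt_ms"),
                       sprintf("sessions file '%s'", path))
  df$subject_id <- as.character(df$subject_id)
  df$is_repeat <- as.logical(df$is_repeat)
  df$responded <- as.logical(df$responded)
  df$rt_ms <- suppressWarnings(as.numeric(df$rt_ms))
  bad_rt <- which(df$responded & is.na(df$rt_ms))
  if (length(bad_rt)) {
    stop("responded rows without rt_ms at row(s): ",
         paste(utils::head(bad_rt, 10), collapse = ", "))
  }
  bad_orphan <- which(!df$responded & !is.na(df$rt_ms))
  if (length(bad_orphan)) {
    stop("rt_ms present on non-responded row(s): ",
         paste(utils::head(bad_orphan, 10), collapse = ", "))
  }
  bad_range <- which(!is.na(df$rt_ms) & (df$rt_ms <= 0 | df$rt_ms >= 3000))
  if (length(bad_range)) {
    stop("rt_ms outside (0, 3000) at row(s): ",
         paste(utils::head(bad_range, 10), collapse = ", "))
  }
  class(df) <- c("crt_sessions", "data.frame")
  df
}

#' @rdname read_sessions
#' @param sessions A trial data frame as from [simulate_cohort()].
#' @export
write_sessions <- function(sessions, path) {
  cols <- c("subject_id", "age", "sex", "position", "picture_id",
            "is_repeat", "responded", "rt_ms")
  utils::write.csv(as.data.frame(sessions)[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write scored subject records as CSV
#'
#' Scores tables round-trip with header `subject_id,age,sex,hits,misses,
#' crs,fas,tc,n_responses,pct_correct,mean_rt_hit,mean_rt_fa`.
#'
#' @param path CSV file path.
#' @param scores A scores data frame as from [score_sessions()].
#' @return `read_scores()` returns the data frame; `write_scores()`
#'   returns `path` invisibly.
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stop_if_missing_cols(df, c("subject_id", "age", "sex", "hits", "misses", "crs",
                             "fas", "tc", "n_responses", "pct_correct",
                             "mean_rt_hit", "mean_rt_fa"),
                       sprintf("scores file '%s'", path))
  df$subject_id <- as.character(df$subject_id)
  df
}

#' @rdname read_scores
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, na = "")
  invisible(path)
}
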