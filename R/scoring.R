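#' Classify a trial outcome
#'
#' Applies the CRT outcome definitions. On a repeat trial, a response with
#' RT between 50 and 2,900 ms is a HIT; anything else (no response, or a
#' response outside that window) is a MISS. On a first showing, any
#' response is an FA and no response over the full 3,000 ms exposure is a
#' CR. Vectorized over trials.
#'
#' @param is_repeat Logical: is the trial a repeat presentation?
#' @param responded Logical: did the subject respond?
#' @param rt_ms Response time in ms; must be present exactly when
#'   `responded` is `TRUE`.
#' @return Character vector with values `"HIT"`, `"MISS"`, `"CR"`, `"FA"`.
#' @examples
#' classify_trial(TRUE, TRUE, 800)    # HIT
#' classify_trial(TRUE, TRUE, 2950)   # MISS (outside the window)
#' classify_trial(FALSE, FALSE, NA)   # CR
#' @export
classify_trial <- function(is_repeat, responded, rt_ms = NA_real_) {
  n <- max(length(is_repeat), length(responded), length(rt_ms))
  is_repeat <- rep_len(as.logical(is_repeat), n)
  responded <- rep_len(as.logical(responded), n)
  rt_ms <- rep_len(as.numeric(rt_ms), n)
  if (any(responded & is.na(rt_ms))) {
    stop("rt_ms must be present for every responded trial")
  }
  if (any(!responded & !is.na(rt_ms))) {
    stop("rt_ms must be missing for non-responded trials")
  }
  out <- character(n)
  hit <- is_repeat & responded & rt_ms >= 50 & rt_ms <= 2900
  out[is_repeat] <- ifelse(hit[is_repeat], "HIT", "MISS")
  out[!is_repeat] <- ifelse(responded[!is_repeat], "FA", "CR")
  out
}

#' Score a single CRT session
#'
#' Tabulates HITs, MISSes, CRs, and FAs for one session log, along with the
#' total correct (TC = HITs + CRs), the response count, percent correct out
#' of 50, and the arithmetic mean RT over HITs and over FAs. The log must
#' contain exactly 25 repeat and 25 new trials.
#'
#' @param log A session log: data frame with columns `is_repeat`,
#'   `responded`, `rt_ms` (plus optional subject metadata `subject_id`,
#'   `age`, `sex`, carried through).
#' @return An object of class `crt_score`: a list with counts `hits`,
#'   `misses`, `crs`, `fas`, `tc`, `n_responses`, `pct_correct`,
#'   `mean_rt_hit`, `mean_rt_fa` (`NA` when there are no qualifying
#'   trials), per-trial `outcomes`, and any subject metadata.
#' @examples
#' sched <- generate_schedule(schedule_config(seed = 1))
#' subj <- sample_subject(population_config(), 40, "male", "S1", seed = 1)
#' score_session(simulate_session(sched, subj, seed = 1))
#' @export
score_session <- function(log) {
  stop_if_missing_cols(log, c("is_repeat", "responded", "rt_ms"), "session log")
  n_rep <- sum(log$is_repeat)
  n_new <- sum(!log$is_repeat)
  if (n_rep != 25 || n_new != 25) {
    stop(sprintf("session must have 25 repeat and 25 new trials (got %d/%d)", n_rep, n_new))
  }
  outcomes <- classify_trial(log$is_repeat, log$responded, log$rt_ms)
  hits <- sum(outcomes == "HIT")
  fas <- sum(outcomes == "FA")
  crs <- sum(outcomes == "CR")
  misses <- sum(outcomes == "MISS")
  structure(
    list(subject_id = log$subject_id[1] %||% NA_character_,
         age = log$age[1] %||% NA_real_,
         sex = log$sex[1] %||% NA_character_,
         hits = hits, misses = misses, crs = crs, fas = fas,
         tc = hits + crs, n_responses = sum(log$responded),
         pct_correct = (hits + crs) / 50,
         mean_rt_hit = if (hits > 0) mean(log$rt_ms[outcomes == "HIT"]) else NA_real_,
         mean_rt_fa = if (fas > 0) mean(log$rt_ms[outcomes == "FA"]) else NA_real_,
         outcomes = outcomes),
    class = "crt_score")
}

#' @export
print.crt_score <- function(x, ...) {
  cat(sprintf("CRT session score (%s, age %s, %s)\n", x$subject_id, x$age, x$sex))
  cat(sprintf("  HITs %d  MISSes %d  CRs %d  FAs %d  TC %d/50 (%.0f%%)\n",
              x$hits, x$misses, x$crs, x$fas, x$tc, 100 * x$pct_correct))
  cat(sprintf("  responses %d, mean RT-HIT %s ms, mean RT-FA %s ms\n",
              x$n_responses,
              ifelse(is.na(x$mean_rt_hit), "-", sprintf("%.0f", x$mean_rt_hit)),
              ifelse(is.na(x$mean_rt_fa), "-", sprintf("%.0f", x$mean_rt_fa))))
  invisible(x)
}

#' Score every session in a cohort
#'
#' Splits a long trial table by subject and scores each session, returning
#' the standard scores table used by the filtering, norms, and relations
#' stages.
#'
#' @param sessions A long trial data frame as produced by
#'   [simulate_cohort()] or [read_sessions()].
#' @return A data frame with one row per subject: `subject_id`, `age`,
#'   `sex`, `hits`, `misses`, `crs`, `fas`, `tc`, `n_responses`,
#'   `pct_correct`, `mean_rt_hit`, `mean_rt_fa`.
#' @examples
#' sessions <- simulate_cohort(population_config(n_subjects = 5, seed = 1))
#' score_sessions(sessions)
#' @export
score_sessions <- function(sessions) {
  stop_if_missing_cols(sessions, c("subject_id", "is_repeat", "responded", "rt_ms"),
                       "sessions table")
  if (!nrow(sessions)) {
    return(data.frame(subject_id = character(), age = numeric(), sex = character(),
                      hits = integer(), misses = integer(), crs = integer(),
                      fas = integer(), tc = integer(), n_responses = integer(),
                      pct_correct = numeric(), mean_rt_hit = numeric(),
                      mean_rt_fa = numeric(), stringsAsFactors = FALSE))
  }
  parts <- split(sessions, factor(sessions$subject_id, levels = unique(sessions$subject_id)))
  rows <- lapply(parts, function(log) {
    s <- score_session(log)
    data.frame(subject_id = s$subject_id, age = s$age, sex = s$sex,
               hits = s$hits, misses = s$misses, crs = s$crs, fas = s$fas,
               tc = s$tc, n_responses = s$n_responses, pct_correct = s$pct_correct,
               mean_rt_hit = s$mean_rt_hit, mean_rt_fa = s$mean_rt_fa,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Expected scores under random responding
#'
#' Reference lines for purely random performance: if `n_responses`
#' responses are placed uniformly at random over the 50 trials, the
#' expected number of HITs is `25 * n/50`, the expected CRs is
#' `25 * (1 - n/50)`, and the expected total correct is always 25 --
#' random responding cannot beat 25/50 in expectation regardless of how
#' many responses are made.
#'
#' @param n_responses Number of responses, in `[0, 50]`; vectorized.
#' @return A data frame with columns `n_responses`, `hits`, `crs`, `tc`.
#' @examples
#' expected_random_performance(c(0, 25, 50))
#' @export
expected_random_performance <- function(n_responses) {
  if (any(is.na(n_responses)) || any(n_responses < 0 | n_responses > 50)) {
    stop("`n_responses` must be in [0, 50]")
  }
  data.frame(n_responses = n_responses,
             hits = 25 * n_responses / 50,
             crs = 25 * (1 - n_responses / 50),
             tc = rep(25, length(n_responses)))
}
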