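# Shared fixtures built in code.

# Minimal 4-trial schedule A, B, A, B (repeats at 3 and 4, lags 1 and 1)
# and its matching configuration.
mini_schedule_config <- function() {
  schedule_config(n_categories = 1, pictures_per_category = 2, n_trials = 4,
                  repeat_plan = c(twice = 0, once = 2, never = 0),
                  lag_min = 1, lag_max = 2)
}

mini_schedule <- function() {
  structure(
    data.frame(position = 1:4,
               picture_id = c("C1P1", "C1P2", "C1P1", "C1P2"),
               category_id = 1L,
               presentation_index = c(1L, 1L, 2L, 2L),
               is_repeat = c(FALSE, FALSE, TRUE, TRUE),
               lag = c(NA, NA, 1L, 1L),
               stringsAsFactors = FALSE),
    class = c("crt_schedule", "data.frame"))
}

# Hand-built 50-trial session log: `hit_rts` HITs (the remaining repeats are
# MISSes), `fa_rts` FAs (the remaining new trials are CRs). Repeats occupy
# positions 3..27.
make_session_log <- function(hit_rts = numeric(), fa_rts = numeric(),
                             subject_id = "T1", age = 40, sex = "male") {
  is_repeat <- rep(FALSE, 50)
  is_repeat[3:27] <- TRUE
  responded <- rep(FALSE, 50)
  rt <- rep(NA_real_, 50)
  rep_pos <- which(is_repeat)
  new_pos <- which(!is_repeat)
  stopifnot(length(hit_rts) <= 25, length(fa_rts) <= 25)
  if (length(hit_rts)) {
    responded[rep_pos[seq_along(hit_rts)]] <- TRUE
    rt[rep_pos[seq_along(hit_rts)]] <- hit_rts
  }
  if (length(fa_rts)) {
    responded[new_pos[seq_along(fa_rts)]] <- TRUE
    rt[new_pos[seq_along(fa_rts)]] <- fa_rts
  }
  data.frame(subject_id = subject_id, age = age, sex = sex,
             position = 1:50, picture_id = sprintf("P%02d", 1:50),
             is_repeat = is_repeat, responded = responded, rt_ms = rt,
             stringsAsFactors = FALSE)
}

# A crt_subject built directly from known parameters (bypassing the
# anchored population model), for known-truth simulations.
make_subject <- function(p_recognize, p_false_alarm, rt_onset = 550,
                         rt_scale = 300, fa_rt_onset = 250, fa_rt_scale = 700,
                         subject_id = "K1", age = 40, sex = "male") {
  structure(list(subject_id = subject_id, age = age, sex = sex,
                 p_recognize = p_recognize, p_false_alarm = p_false_alarm,
                 rt_onset_ms = rt_onset, rt_scale_ms = rt_scale,
                 fa_rt_onset_ms = fa_rt_onset, fa_rt_scale_ms = fa_rt_scale),
            class = "crt_subject")
}

# Scored-record table for filter and relations tests.
make_scores <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(subject_id = sprintf("R%04d", seq_len(n)),
             age = sample(21:90, n, replace = TRUE),
             sex = sample(c("male", "female"), n, replace = TRUE),
             hits = sample(15:25, n, replace = TRUE),
             crs = sample(15:25, n, replace = TRUE),
             n_responses = sample(10:30, n, replace = TRUE),
             mean_rt_hit = 550 + rexp(n, 1 / 330),
             mean_rt_fa = 250 + rexp(n, 1 / 700),
             stringsAsFactors = FALSE) -> df
  df$misses <- 25 - df$hits
  df$fas <- 25 - df$crs
  df$tc <- df$hits + df$crs
  df$pct_correct <- df$tc / 50
  df
}
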