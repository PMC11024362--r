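test_that("sample_subject validates age and is deterministic under a seed", {
  pop <- population_config()
  expect_error(sample_subject(pop, 20, "male"), "21")
  expect_error(sample_subject(pop, 101, "male"), "100")
  a <- sample_subject(pop, 30, "female", "S1", seed = 11)
  b <- sample_subject(pop, 30, "female", "S1", seed = 11)
  expect_identical(a, b)
  expect_true(a$p_recognize >= 0 && a$p_recognize <= 1)
  expect_true(a$rt_scale_ms > 0)
})

test_that("zero dispersion collapses every subject in a cell to identical parameters", {
  pop <- population_config(p_rec_sigma = 0, p_fa_sigma = 0, rt_dispersion = 0,
                           fa_rt_dispersion = 0, ability_speed_cor = 0,
                           fa_zero_fraction = 0)
  subs <- lapply(1:5, function(i) sample_subject(pop, 45, "male", seed = i))
  for (s in subs[-1]) {
    expect_equal(s$p_recognize, subs[[1]]$p_recognize)
    expect_equal(s$p_false_alarm, subs[[1]]$p_false_alarm)
    expect_equal(s$rt_scale_ms, subs[[1]]$rt_scale_ms)
    expect_equal(s$fa_rt_scale_ms, subs[[1]]$fa_rt_scale_ms)
  }
  # and the collapsed parameters hit the anchors exactly (no censoring slack
  # beyond the deadline adjustment)
  expect_equal(subs[[1]]$rt_onset_ms + subs[[1]]$rt_scale_ms,
               memcrt:::interpolate_anchor(pop$anchors$rt_cohorts, "rt_hit", "male", 45),
               tolerance = 1e-3)
})

test_that("degenerate subjects produce the forced response patterns", {
  sched <- generate_schedule(schedule_config(seed = 2))
  perfect <- make_subject(p_recognize = 1, p_false_alarm = 0,
                          rt_onset = 700, rt_scale = 0)
  log <- simulate_session(sched, perfect, seed = 1)
  expect_identical(sum(log$responded), 25L)
  expect_true(all(log$responded == log$is_repeat))
  expect_true(all(log$rt_ms[log$responded] == 700))

  silent <- make_subject(p_recognize = 0, p_false_alarm = 0)
  log2 <- simulate_session(sched, silent, seed = 1)
  expect_identical(sum(log2$responded), 0L)
})

test_that("response fraction matches the closed-form censoring probability", {
  # 10,000 repeat trials, p_recognize 0.9, onset 550 ms, scale 300 ms:
  # responses occur iff the drawn RT is at most 2,900 ms.
  fake <- data.frame(position = 1:10000, picture_id = "X", is_repeat = TRUE)
  subj <- make_subject(p_recognize = 0.9, p_false_alarm = 0,
                       rt_onset = 550, rt_scale = 300)
  log <- simulate_session(fake, subj, seed = 3)
  p_true <- 0.9 * pexp(2900 - 550, rate = 1 / 300)
  ci <- 2.576 * sqrt(p_true * (1 - p_true) / 10000)
  expect_lt(abs(mean(log$responded) - p_true), ci)
  # censoring consistency: MISS rate complements the response rate
  expect_equal(mean(!log$responded), 1 - mean(log$responded))
})

test_that("known parameters are recovered from simulated trials by moments", {
  fake <- data.frame(position = 1:10000, picture_id = "X", is_repeat = TRUE)
  subj <- make_subject(p_recognize = 0.9, p_false_alarm = 0,
                       rt_onset = 600, rt_scale = 300)
  log <- simulate_session(fake, subj, seed = 8)
  rts <- log$rt_ms[log$responded]
  c_resp <- pexp(2900 - 600, rate = 1 / 300)
  p_hat <- mean(log$responded) / c_resp
  scale_hat <- sd(rts)
  onset_hat <- mean(rts) - scale_hat
  expect_lt(abs(p_hat - 0.9) / 0.9, 0.05)
  expect_lt(abs(scale_hat - 300) / 300, 0.05)
  expect_lt(abs(onset_hat - 600) / 600, 0.05)
})

test_that("a simulated cell reproduces its age/sex anchors", {
  # 5,000 male subjects at age 25 (the 21-31 bin): cohort mean HITs within
  # 0.1 of 23.5 and mean RT-HIT within 10 ms of 879, the anchor values.
  pop <- population_config(seed = 7)
  sched <- generate_schedule(schedule_config(seed = 1))
  set.seed(7)
  n <- 5000
  hits <- numeric(n); mrt <- numeric(n); fas <- numeric(n)
  for (i in seq_len(n)) {
    s <- sample_subject(pop, 25, "male", sprintf("S%d", i))
    log <- simulate_session(sched, s)
    out <- classify_trial(log$is_repeat, log$responded, log$rt_ms)
    hits[i] <- sum(out == "HIT")
    mrt[i] <- if (hits[i] > 0) mean(log$rt_ms[out == "HIT"]) else NA
    fas[i] <- sum(out == "FA")
  }
  expect_lt(abs(mean(hits) - 23.5), 0.1)
  expect_lt(abs(mean(mrt, na.rm = TRUE) - 879), 10)
  expect_lt(abs((25 - mean(fas)) - 24.1), 0.1)
})

test_that("simulate_cohort is reproducible, handles n = 0, and tracks age trends", {
  a <- simulate_cohort(population_config(n_subjects = 100, seed = 11))
  b <- simulate_cohort(population_config(n_subjects = 100, seed = 11))
  expect_identical(as.data.frame(a), as.data.frame(b))
  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  write_sessions(a, fa); write_sessions(b, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)), readBin(fb, "raw", file.size(fb)))

  empty <- simulate_cohort(population_config(n_subjects = 0, seed = 1))
  expect_identical(nrow(empty), 0L)
})

test_that("per-subject mean RT-HITs form a RevEx-compatible cohort with age slowing", {
  pop <- population_config(n_subjects = 5000, seed = 23)
  scores <- score_sessions(simulate_cohort(pop))
  rt <- scores$mean_rt_hit[!is.na(scores$mean_rt_hit)]
  fit <- fit_revex(rt)
  expect_gte(fit$r2, 0.99)
  # mean RT-HIT increases across coarse age bands (anchor trend)
  band <- cut(scores$age, c(21, 41, 61, 91), right = FALSE)
  mm <- tapply(scores$mean_rt_hit, band, mean, na.rm = TRUE)
  expect_true(all(diff(mm) > 0))
  # mean HITs decline with age band
  hh <- tapply(scores$hits, band, mean)
  expect_true(all(diff(hh) < 0))
})
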