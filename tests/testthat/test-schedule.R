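test_that("generated schedules satisfy every design constraint", {
  for (s in c(1, 2, 17, 101, 4242)) {
    sched <- generate_schedule(schedule_config(seed = s))
    expect_identical(nrow(sched), 50L)
    expect_identical(sum(sched$is_repeat), 25L)
    expect_identical(sum(!sched$is_repeat), 25L)
    expect_false(any(sched$is_repeat[1:2]))
    expect_true(all(sched$lag[sched$is_repeat] >= 1))
    expect_true(all(sched$lag[sched$is_repeat] <= 45))
    expect_lte(max(rle(sched$is_repeat)$lengths), 4)
    expect_identical(nrow(validate_schedule(sched)), 0L)
    # per-category repeat multiplicities follow the plan
    mult <- tapply(sched$presentation_index, sched$picture_id, max)
    cats <- substr(names(mult), 1, 2)
    for (cc in unique(cats)) {
      expect_equal(as.vector(sort(mult[cats == cc])), c(1, 2, 2, 2, 3))
    }
  }
})

test_that("each picture's presentations are 1, 2, (3) at increasing positions", {
  sched <- generate_schedule(schedule_config(seed = 9))
  for (p in unique(sched$picture_id)) {
    rows <- sched[sched$picture_id == p, ]
    rows <- rows[order(rows$position), ]
    expect_identical(rows$presentation_index, seq_len(nrow(rows)))
  }
})

test_that("schedule generation is deterministic and serializes byte-identically", {
  a <- generate_schedule(schedule_config(seed = 5))
  b <- generate_schedule(schedule_config(seed = 5))
  expect_identical(a, b)
  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  write_schedule(a, fa); write_schedule(b, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)), readBin(fb, "raw", file.size(fb)))
  back <- read_schedule(fa)
  expect_equal(as.data.frame(back), as.data.frame(a), ignore_attr = TRUE)
  # a different seed gives a different schedule
  expect_false(identical(a, generate_schedule(schedule_config(seed = 6))))
})

test_that("validate_schedule accepts a hand-built mini schedule and names violations", {
  cfg <- mini_schedule_config()
  good <- mini_schedule()
  expect_identical(nrow(validate_schedule(good, cfg)), 0L)

  first_repeat <- good
  first_repeat$is_repeat[1] <- TRUE
  first_repeat$presentation_index[1] <- 2L
  first_repeat$lag[1] <- 1L
  v <- validate_schedule(first_repeat, cfg)
  expect_true("first-two-new" %in% v$rule)

  big_lag <- generate_schedule(schedule_config(seed = 3))
  i <- which(big_lag$is_repeat)[1]
  big_lag$lag[i] <- 46L
  v2 <- validate_schedule(big_lag)
  # the recorded lag no longer matches positions, and would be out of range
  expect_true(any(v2$rule %in% c("lag-range", "lag-consistency")))
  expect_true(i %in% v2$position[v2$rule %in% c("lag-range", "lag-consistency")])

  # A,B,A,B,A,B: a run of four repeats violates max_run = 3
  run4 <- data.frame(position = 1:6,
                     picture_id = rep(c("C1P1", "C1P2"), 3),
                     category_id = 1L,
                     presentation_index = rep(1:3, each = 2),
                     is_repeat = rep(c(FALSE, TRUE, TRUE), each = 2),
                     lag = c(NA, NA, 1L, 1L, 1L, 1L))
  v3 <- validate_schedule(run4, schedule_config(
    n_categories = 1, pictures_per_category = 2, n_trials = 6,
    repeat_plan = c(twice = 2, once = 0, never = 0), max_run = 3, lag_max = 5))
  expect_true("max-run" %in% v3$rule)
})

test_that("infeasible configurations are rejected", {
  expect_error(schedule_config(repeat_plan = c(twice = 2, once = 3, never = 1)),
               "sum")
  expect_error(schedule_config(repeat_plan = c(twice = 2, once = 3, never = 0)),
               "repeat presentations")
  # structurally valid config that cannot be scheduled: lags may only be 0
  bad <- schedule_config(n_categories = 1, pictures_per_category = 2, n_trials = 4,
                         repeat_plan = c(twice = 0, once = 2, never = 0),
                         lag_min = 3, lag_max = 3, retry_budget = 50)
  expect_error(generate_schedule(bad), "infeasible|constraints")
})
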