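test_that("z_from_percentile matches the printed transform and round-trips", {
  expect_equal(z_from_percentile(86.65, digits = 2), 1.11)
  expect_equal(z_from_percentile(9.4, digits = 1), -1.3)
  expect_equal(z_from_percentile(50), 0)
  ps <- c(0.04, 0.5, 9.4, 27.71, 50, 86.65, 99.9)
  expect_true(all(abs(pnorm(z_from_percentile(ps)) - ps / 100) < 1e-10))
  expect_error(z_from_percentile(0), "between")
  expect_error(z_from_percentile(100), "between")
})

test_that("percentile_table handles degenerate and tiny cohorts per the cap rules", {
  deg <- percentile_table(rep(50, 200), "tc")
  expect_identical(nrow(deg), 1L)
  expect_equal(deg$percentile, 99.90)
  expect_equal(round(deg$z, 2), 3.09)

  two <- percentile_table(c(40, 50), "tc")
  expect_equal(two$percentile[two$score == 40], 50)
  expect_equal(two$z[two$score == 40], 0)
  expect_equal(two$percentile[two$score == 50], 99.90)
  expect_error(percentile_table(numeric(0)), "no non-missing")
})

test_that("percentile_table equals a brute-force rank computation", {
  set.seed(61)
  tc <- pmin(50, 25 + rbinom(10000, 25, 0.92))
  tab <- percentile_table(tc, "tc", "higher_better")
  for (i in seq_len(nrow(tab))) {
    frac <- sum(tc <= tab$score[i]) / length(tc)
    expect_equal(tab$percentile[i], min(100 * frac, 99.90))
    if (frac < 1) expect_equal(tab$z[i], qnorm(frac))
  }
  # monotone along the direction: worse scores get lower percentiles
  expect_true(all(diff(tab$percentile) <= 0))

  rts <- 550 + rexp(5000, 1 / 330)
  rtab <- percentile_table(rts, "mean_rt_hit", "lower_better")
  expect_equal(diff(rtab$score)[1], 20)  # default 20 ms bins
  for (i in sample(nrow(rtab), 10)) {
    frac <- sum(rts >= rtab$score[i]) / length(rts)
    expect_equal(rtab$percentile[i], min(100 * frac, 99.90))
  }
})

test_that("cohort_table computes direction-aware SD bands", {
  # two RT values chosen to give mean 879, SD 163 exactly
  rec <- data.frame(age = c(25, 25), sex = "male",
                    mean_rt_hit = c(879 - 163 / sqrt(2), 879 + 163 / sqrt(2)))
  tab <- cohort_table(rec, "mean_rt_hit", "lower_better")
  row <- tab[tab$age_bin == "21-31", ]
  expect_equal(row$mean, 879)
  expect_equal(row$band_1, 1042)
  expect_equal(row$band_1p5, round(879 + 1.5 * 163))
  expect_equal(row$band_2, 1205)

  # zero-SD bin collapses the bands onto the mean
  rec0 <- data.frame(age = c(35, 35), sex = "female", hits = c(23, 23))
  tab0 <- cohort_table(rec0, "hits", "higher_better")
  row0 <- tab0[tab0$sex == "female" & tab0$age_bin == "31-40", ]
  expect_equal(row0$band_2, row0$mean)

  # singleton bin: mean but no bands
  rec1 <- data.frame(age = 45, sex = "male", hits = 20)
  t1 <- cohort_table(rec1, "hits", "higher_better")
  r1 <- t1[t1$sex == "male" & t1$age_bin == "41-51", ]
  expect_equal(r1$mean, 20)
  expect_true(is.na(r1$band_2))
})

test_that("cohort tables are internally consistent on simulated data", {
  scores <- make_scores(800, seed = 8)
  tab <- cohort_table(scores, "mean_rt_hit", "lower_better")
  ok <- !is.na(tab$band_1) & abs(tab$band_1 - tab$mean) > 20
  ratio15 <- (tab$band_1p5[ok] - tab$mean[ok]) / (tab$band_1[ok] - tab$mean[ok])
  ratio2 <- (tab$band_2[ok] - tab$mean[ok]) / (tab$band_1[ok] - tab$mean[ok])
  expect_true(all(abs(ratio15 - 1.5) < 0.05))
  expect_true(all(abs(ratio2 - 2) < 0.05))
  # count tables band downward
  htab <- cohort_table(scores, "hits", "higher_better")
  expect_true(all(htab$band_2 <= htab$mean, na.rm = TRUE))
})

test_that("impairment_flag applies the published band conventions", {
  norms <- reference_norms()
  hits_row <- norms$count_cohorts[norms$count_cohorts$metric == "hits" &
                                  norms$count_cohorts$sex == "male" &
                                  norms$count_cohorts$age_bin == "21-31", ]
  expect_identical(impairment_flag(18, hits_row, "higher_better"), "abnormal")
  expect_identical(impairment_flag(hits_row$mean, hits_row, "higher_better"), "normal")
  expect_identical(impairment_flag(20, hits_row, "higher_better"), "possible_impairment")

  rt_row <- norms$rt_cohorts[norms$rt_cohorts$metric == "rt_hit" &
                             norms$rt_cohorts$sex == "male" &
                             norms$rt_cohorts$age_bin == "21-31", ]
  expect_identical(impairment_flag(1150, rt_row, "lower_better"), "possible_impairment")
  expect_identical(impairment_flag(1300, rt_row, "lower_better"), "abnormal")
  expect_identical(impairment_flag(900, rt_row, "lower_better"), "normal")

  bad <- hits_row; bad$band_2 <- NA
  expect_error(impairment_flag(20, bad, "higher_better"), "missing")
})
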