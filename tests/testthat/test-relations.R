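# Known-truth records where mean RT-HIT depends on the HIT count only:
# recognition ability drives both, FA propensity is independent.
known_truth_records <- function(n = 3000, rt_per_miss = 40, noise_sd = 60, seed = 71) {
  set.seed(seed)
  ability <- rnorm(n)
  hits <- pmin(25, pmax(0, round(23.5 + 1.5 * ability)))
  crs <- 25 - rbinom(n, 4, 0.25)
  data.frame(subject_id = sprintf("K%04d", 1:n),
             age = sample(21:90, n, replace = TRUE),
             sex = sample(c("male", "female"), n, replace = TRUE),
             hits = hits, crs = crs, tc = hits + crs,
             misses = 25 - hits, fas = 25 - crs,
             n_responses = hits + (25 - crs),
             mean_rt_hit = 900 + rt_per_miss * (25 - hits) + rnorm(n, 0, noise_sd),
             mean_rt_fa = 250 + rexp(n, 1 / 700),
             stringsAsFactors = FALSE)
}

test_that("per_age_summary is exact per age", {
  one <- data.frame(age = 40, mean_rt_hit = 900)
  res <- per_age_summary(one, "mean_rt_hit")
  expect_equal(unlist(res), c(age = 40, mean = 900, sd = NA, n = 1))

  set.seed(3)
  flat <- data.frame(age = sample(30:35, 600, replace = TRUE),
                     v = rnorm(600, 100, 5))
  s <- per_age_summary(flat, "v")
  expect_true(all(abs(s$mean - 100) < 5 * 5 / sqrt(pmax(s$n, 1))))
  expect_identical(sum(s$n), 600)
  expect_error(per_age_summary(flat[0, ], "v"), "no non-missing")
})

test_that("fit_polynomial matches lm and handles degenerate inputs", {
  x <- seq(-3, 3, length.out = 40)
  y <- 2 + 3 * x - 0.5 * x^2
  f <- fit_polynomial(x, y, 2)
  expect_equal(f$coefficients, c(2, 3, -0.5), tolerance = 1e-10)
  expect_equal(f$r2, 1, tolerance = 1e-12)

  const <- fit_polynomial(x, rep(4, 40), 2)
  expect_equal(const$coefficients, c(4, 0, 0))
  expect_equal(const$r2, 0)

  set.seed(5)
  yn <- 2 + 3 * x - 0.5 * x^2 + rnorm(40, 0, 0.3)
  f2 <- fit_polynomial(x, yn, 2)
  ref <- lm(yn ~ x + I(x^2))
  expect_equal(f2$coefficients, unname(coef(ref)), tolerance = 1e-8)
  expect_equal(f2$r2, summary(ref)$r.squared, tolerance = 1e-8)
  se <- summary(ref)$coefficients[, "Std. Error"]
  expect_true(all(abs(f2$coefficients - c(2, 3, -0.5)) < 3 * se))
  # shifted screening line sits 2 population SDs lower
  expect_equal(f2$coefficients[1] - f2$coefficients_minus_2sd[1], 2 * f2$sd_y)

  expect_error(fit_polynomial(1:3, 1:3, 2), "points")
  expect_error(fit_polynomial(rep(1, 10), rnorm(10), 2), "rank")
})

test_that("the correctness-RT decomposition reproduces the HITs/CRs dichotomy", {
  rec <- known_truth_records()
  d <- rt_correct_decomposition(rec)
  expect_gt(d$r2["hits"], d$r2["tc"])
  expect_gt(d$r2["tc"], d$r2["crs"])
  expect_lt(d$r2["crs"], 0.01)
  expect_identical(d$r2_order[1], "hits")

  # RT independent of everything: all three relationships vanish
  rec0 <- rec
  set.seed(72)
  rec0$mean_rt_hit <- 900 + rnorm(nrow(rec0), 0, 60)
  d0 <- rt_correct_decomposition(rec0)
  expect_true(all(d0$r2 < 0.01))
})

test_that("slice analysis finds a slope over HITs but not over CRs", {
  rec <- known_truth_records(n = 6000, seed = 73)
  fix_crs <- slice_analysis(rec, fix = "crs")
  s1 <- fix_crs[[1]]  # CRs = 25
  expect_false(s1$underdetermined)
  expect_lt(s1$slope, -20)  # more HITs, faster (true slope -40)

  # with HITs fixed the true slope over CRs is exactly 0; each estimated
  # slope must sit within 3 standard errors of 0 (residual sd is 60 by
  # construction, so the slope SE follows from the cell sizes)
  fix_hits <- slice_analysis(rec, fix = "hits")
  for (s in fix_hits) {
    cells <- s$cells[s$cells$n > 0 & !is.na(s$cells$mean_rt_hit), ]
    if (nrow(cells) < 3) next
    x <- cells$level
    w <- (x - mean(x)) / sum((x - mean(x))^2)
    slope_se <- sqrt(sum(w^2 * 60^2 / cells$n))
    expect_lt(abs(s$slope), 3 * slope_se + 1e-9)
  }

  # degenerate single-cell input is flagged, not fitted
  single <- rec[rec$hits == 25 & rec$crs == 25, ][1, ]
  sd1 <- slice_analysis(single, fix = "crs")
  expect_true(sd1[[1]]$underdetermined)
})

test_that("FA/HIT speed comparison matches forced orderings and closed form", {
  rec <- known_truth_records(n = 500, seed = 74)
  faster <- rec
  faster$mean_rt_fa <- faster$mean_rt_hit - 10
  expect_equal(fa_hit_rt_comparison(faster)$fraction_fa_faster, 1)
  slower <- rec
  slower$mean_rt_fa <- slower$mean_rt_hit + 10
  expect_equal(fa_hit_rt_comparison(slower)$fraction_fa_faster, 0)

  # equal onsets, FA scale 2.5x HIT scale: P(FA < HIT) = 1 / (1 + 2.5)
  set.seed(75)
  n <- 20000
  sim <- data.frame(mean_rt_hit = 550 + rexp(n, 1 / 300),
                    mean_rt_fa = 550 + rexp(n, 1 / 750))
  frac <- fa_hit_rt_comparison(sim)$fraction_fa_faster
  p_true <- 1 / 3.5
  expect_lt(abs(frac - p_true), 3 * sqrt(p_true * (1 - p_true) / n))

  rec$mean_rt_fa <- NA_real_
  expect_error(fa_hit_rt_comparison(rec), "no subjects")
})

test_that("cumulative correctness fits are exponential for geometric scores", {
  # counts chosen so the cumulative at-or-below is exactly 2^(10-k): the
  # log-cumulative is exactly linear in the score
  scores <- rep(25:15, times = c(2^(9:0), 1))
  f <- cumulative_correct_expfit(scores, "hits")
  expect_gt(f$r2, 0.999)

  unif <- rep(21:25, each = 100)
  fu <- cumulative_correct_expfit(unif, "hits")
  expect_lt(fu$r2 + 0.02, f$r2)

  expect_error(cumulative_correct_expfit(rep(25, 100)), "distinct")
})
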