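#' Per-age summary of a metric
#'
#' One row per observed integer age with the exact mean, SD, and count of
#' the metric over that age's subjects -- the year-by-year view in which
#' the age trend of RTs stands out against between-subject variability.
#'
#' @param records Data frame with `age` and the metric column.
#' @param metric Column name to summarize.
#' @return Data frame with columns `age`, `mean`, `sd` (`NA` for single
#'   subjects), `n`, ordered by age.
#' @examples
#' scores <- score_sessions(simulate_cohort(population_config(n_subjects = 100, seed = 1)))
#' head(per_age_summary(scores, "mean_rt_hit"))
#' @export
per_age_summary <- function(records, metric) {
  stop_if_missing_cols(records, c("age", metric), "records")
  v <- records[[metric]]
  keep <- !is.na(v) & !is.na(records$age)
  if (!any(keep)) stop("no non-missing (age, ", metric, ") pairs")
  v <- v[keep]
  age <- records$age[keep]
  ages <- sort(unique(age))
  out <- data.frame(
    age = ages,
    mean = vapply(ages, function(a) mean(v[age == a]), numeric(1)),
    sd = vapply(ages, function(a) if (sum(age == a) >= 2) stats::sd(v[age == a]) else NA_real_,
                numeric(1)),
    n = vapply(ages, function(a) sum(age == a), numeric(1)))
  out
}

#' Least-squares polynomial regression
#'
#' Fits a degree-`degree` polynomial (default quadratic, the age model used
#' throughout the cohort analyses) by ordinary least squares and reports
#' R-squared on the input points. For screening plots the regression line
#' shifted down by 2 population SDs of the response is also returned: the
#' conventional "watch below this line" reference for count metrics.
#'
#' @param x,y Numeric vectors of equal length; requires
#'   `length(x) > degree + 1`.
#' @param degree Polynomial degree, at least 1.
#' @return An object of class `crt_polyfit`: a list with `coefficients`
#'   (intercept first), `degree`, `r2`, `n`, `sd_y` (population SD of `y`)
#'   and `coefficients_minus_2sd` (the same polynomial with the intercept
#'   lowered by `2 * sd_y`).
#' @examples
#' x <- 1:20
#' fit_polynomial(x, 2 + 3 * x - 0.1 * x^2)$r2  # 1
#' @export
fit_polynomial <- function(x, y, degree = 2) {
  stopifnot(degree >= 1)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n <= degree + 1) stop("need more than degree + 1 points")
  X <- stats::poly(x, degree, raw = TRUE)
  if (qr(cbind(1, X))$rank < degree + 1) stop("design matrix is rank deficient")
  fit <- stats::lm.fit(cbind(1, X), y)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else 0
  coefs <- unname(fit$coefficients)
  if (sst == 0) coefs <- c(mean(y), rep(0, degree))
  sd_y <- stats::sd(y) * sqrt((n - 1) / n)  # population SD
  shifted <- coefs
  shifted[1] <- shifted[1] - 2 * sd_y
  structure(list(coefficients = coefs, degree = degree, r2 = r2, n = n,
                 sd_y = sd_y, coefficients_minus_2sd = shifted),
            class = "crt_polyfit")
}

#' @export
print.crt_polyfit <- function(x, ...) {
  cat(sprintf("Polynomial fit (degree %d, n = %d): R^2 = %.4f\n", x$degree, x$n, x$r2))
  cat("  coefficients (intercept first):", signif(x$coefficients, 5), "\n")
  invisible(x)
}

#' Decompose the RT--correctness relationship into HITs and CRs
#'
#' Fits three linear regressions of per-subject mean RT-HIT -- on total
#' correct, on HITs, and on CRs -- over the same subjects, and reports the
#' R-squared ordering. The diagnostic claim this reproduces: the
#' correctness--RT link is carried by the HITs (slow responders make more
#' MISSes), while CRs are essentially unrelated to RT-HITs, so the TC
#' regression is a diluted version of the HITs regression.
#'
#' @param records Scored subject records with `mean_rt_hit`, `tc`, `hits`,
#'   `crs`.
#' @return An object of class `crt_rt_decomposition`: a list with
#'   `fit_tc`, `fit_hits`, `fit_crs` (each a [fit_polynomial()] of degree
#'   1), `r2` (named vector), and `r2_order` (metric names, decreasing
#'   R-squared).
#' @examples
#' scores <- score_sessions(simulate_cohort(population_config(n_subjects = 300, seed = 1)))
#' rt_correct_decomposition(scores)$r2
#' @export
rt_correct_decomposition <- function(records) {
  stop_if_missing_cols(records, c("mean_rt_hit", "tc", "hits", "crs"), "records")
  keep <- !is.na(records$mean_rt_hit)
  r <- records[keep, ]
  fit_tc <- fit_polynomial(r$tc, r$mean_rt_hit, degree = 1)
  fit_hits <- fit_polynomial(r$hits, r$mean_rt_hit, degree = 1)
  fit_crs <- fit_polynomial(r$crs, r$mean_rt_hit, degree = 1)
  r2 <- c(tc = fit_tc$r2, hits = fit_hits$r2, crs = fit_crs$r2)
  structure(list(fit_tc = fit_tc, fit_hits = fit_hits, fit_crs = fit_crs,
                 r2 = r2, r2_order = names(sort(r2, decreasing = TRUE)), n = nrow(r)),
            class = "crt_rt_decomposition")
}

#' @export
print.crt_rt_decomposition <- function(x, ...) {
  cat(sprintf("RT-HIT vs correctness decomposition (n = %d)\n", x$n))
  cat(sprintf("  R^2: HITs %.4f, TC %.4f, CRs %.4f (order: %s)\n",
              x$r2["hits"], x$r2["tc"], x$r2["crs"], paste(x$r2_order, collapse = " > ")))
  invisible(x)
}

#' Conditional slices of RT-HIT by HITs and CRs
#'
#' Holds one count metric fixed (CRs or HITs, at each level of
#' `fixed_levels`) and examines mean RT-HIT as a function of the other
#' metric over `vary_levels`, with a linear fit across the level means.
#' With CRs fixed, RT-HITs fall steeply as HITs rise; with HITs fixed,
#' RT-HITs barely move with CRs -- the slice view of the HITs/CRs
#' dichotomy.
#'
#' @param records Scored subject records.
#' @param fix `"crs"` or `"hits"`: the metric held constant.
#' @param fixed_levels Levels of the fixed metric (default 25 down to 21).
#' @param vary_levels Levels of the varying metric (default 21 to 25).
#' @return A list of class `crt_slice_analysis`; one element per fixed
#'   level, each a list with `fixed_metric`, `fixed_value`, `cells` (data
#'   frame `level`, `mean_rt_hit`, `n`; empty cells have `n = 0` and `NA`
#'   mean), `slope`, `intercept`, `r2`, and `underdetermined` (`TRUE` when
#'   fewer than 2 non-empty cells).
#' @examples
#' scores <- score_sessions(simulate_cohort(population_config(n_subjects = 500, seed = 1)))
#' sa <- slice_analysis(scores, fix = "crs")
#' sa[[1]]$slope  # RT-HIT vs HITs at CRs = 25
#' @export
slice_analysis <- function(records, fix = c("crs", "hits"),
                           fixed_levels = 25:21, vary_levels = 21:25) {
  fix <- match.arg(fix)
  vary <- if (fix == "crs") "hits" else "crs"
  stop_if_missing_cols(records, c("mean_rt_hit", "hits", "crs"), "records")
  out <- lapply(fixed_levels, function(L) {
    sub <- records[!is.na(records$mean_rt_hit) & records[[fix]] == L &
                     records[[vary]] %in% vary_levels, ]
    cells <- data.frame(
      level = vary_levels,
      mean_rt_hit = vapply(vary_levels, function(v) {
        x <- sub$mean_rt_hit[sub[[vary]] == v]
        if (length(x)) mean(x) else NA_real_
      }, numeric(1)),
      n = vapply(vary_levels, function(v) sum(sub[[vary]] == v), numeric(1)))
    ok <- !is.na(cells$mean_rt_hit)
    if (sum(ok) >= 3) {
      fit <- fit_polynomial(cells$level[ok], cells$mean_rt_hit[ok], degree = 1)
      res <- list(slope = fit$coefficients[2], intercept = fit$coefficients[1],
                  r2 = fit$r2, underdetermined = FALSE)
    } else if (sum(ok) == 2) {
      slope <- diff(cells$mean_rt_hit[ok]) / diff(cells$level[ok])
      res <- list(slope = slope,
                  intercept = cells$mean_rt_hit[ok][1] - slope * cells$level[ok][1],
                  r2 = 1, underdetermined = FALSE)
    } else {
      res <- list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
                  underdetermined = TRUE)
    }
    c(list(fixed_metric = fix, fixed_value = L, varying_metric = vary, cells = cells), res)
  })
  class(out) <- "crt_slice_analysis"
  out
}

#' Compare each subject's FA and HIT response speeds
#'
#' Among subjects with both a mean RT-FA and a mean RT-HIT, reports the
#' fraction whose FAs were on average faster than their HITs, plus an
#' overlay table of the two cumulative distributions. In the reference
#' cohort this fraction is close to one half: FA RTs are broader than HIT
#' RTs, faster for about 45% of users and slower for the rest.
#'
#' @param records Scored subject records with `mean_rt_hit` and
#'   `mean_rt_fa`.
#' @return A list with `fraction_fa_faster`, `n`, and `overlay` (data
#'   frame `prob`, `q_rt_hit`, `q_rt_fa`).
#' @examples
#' scores <- score_sessions(simulate_cohort(population_config(n_subjects = 300, seed = 1)))
#' fa_hit_rt_comparison(scores)$fraction_fa_faster
#' @export
fa_hit_rt_comparison <- function(records) {
  stop_if_missing_cols(records, c("mean_rt_hit", "mean_rt_fa"), "records")
  both <- !is.na(records$mean_rt_hit) & !is.na(records$mean_rt_fa)
  if (!any(both)) stop("no subjects with both mean RT-HIT and mean RT-FA")
  h <- records$mean_rt_hit[both]
  f <- records$mean_rt_fa[both]
  probs <- seq(0.01, 0.99, by = 0.01)
  list(fraction_fa_faster = mean(f < h), n = sum(both),
       overlay = data.frame(prob = probs,
                            q_rt_hit = unname(stats::quantile(h, probs)),
                            q_rt_fa = unname(stats::quantile(f, probs))))
}

#' Exponential fit to a cumulative correctness distribution
#'
#' The cumulative percent of subjects at or below each score rises
#' steeply and near-exponentially toward the score ceiling. This fits
#' `log(cumulative percent)` linearly in the score by least squares and
#' reports R-squared on the log scale, the form in which the cumulative
#' HITs distribution explains over 99% of its variance.
#'
#' @param scores Integer metric values across the cohort (e.g. HITs in
#'   `[0, 25]` or TC in `[0, 50]`).
#' @param metric Name stored on the result.
#' @return A list of class `crt_cumexp_fit` with `intercept` and `rate`
#'   (of `log(cum pct) = intercept + rate * score`), `r2`, `n`, and
#'   `table` (score, cumulative percent).
#' @examples
#' set.seed(1)
#' hits <- 25 - rgeom(2000, 0.6)
#' cumulative_correct_expfit(hits[hits >= 0], "hits")$r2
#' @export
cumulative_correct_expfit <- function(scores, metric = "metric") {
  scores <- scores[!is.na(scores)]
  if (length(unique(scores)) < 3) {
    stop("need at least 3 distinct scores for a cumulative exponential fit")
  }
  grid <- sort(unique(scores))
  cum <- vapply(grid, function(s) 100 * mean(scores <= s), numeric(1))
  keep <- cum > 0
  fit <- fit_polynomial(grid[keep], log(cum[keep]), degree = 1)
  structure(list(metric = metric, intercept = fit$coefficients[1],
                 rate = fit$coefficients[2], r2 = fit$r2, n = length(scores),
                 table = data.frame(score = grid, cumulative_pct = cum)),
            class = "crt_cumexp_fit")
}

#' @export
print.crt_cumexp_fit <- function(x, ...) {
  cat(sprintf("Cumulative exponential fit for %s (n = %d): rate %.3f per point, R^2 = %.4f\n",
              x$metric, x$n, x$rate, x$r2))
  invisible(x)
}
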