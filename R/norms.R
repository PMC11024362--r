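#' Z-score from an empirical percentile
#'
#' Maps a cumulative percent to a standard-normal quantile,
#' `qnorm(percentile / 100)`. This is the transform behind the Z-score
#' columns of the normative tables: the Z is the normal quantile of the
#' empirical percentile, not a (x - mean)/SD standard score -- the two
#' differ for the skewed score distributions this task produces.
#'
#' @param percentile Percent in the open interval (0, 100); vectorized.
#' @param digits Optional rounding of the result (the printed tables use 2
#'   decimals for counts and 1 for RTs); `NULL` returns the exact quantile.
#' @return Numeric Z-score(s).
#' @examples
#' z_from_percentile(86.65, digits = 2)  # 1.11
#' z_from_percentile(50)                 # 0
#' @export
z_from_percentile <- function(percentile, digits = NULL) {
  if (any(is.na(percentile)) || any(percentile <= 0 | percentile >= 100)) {
    stop("`percentile` must be strictly between 0 and 100")
  }
  z <- stats::qnorm(percentile / 100)
  if (!is.null(digits)) z <- round(z, digits) else z
}

#' Build a normative percentile/Z table for one metric
#'
#' For each score (or RT bin), the percentile is the cumulative percent of
#' the reference cohort performing at or worse than that value along the
#' metric's direction: at-or-below for count metrics (`higher_better`),
#' at-or-above for RTs (`lower_better`). Percentiles are capped at 99.90
#' (Z = 3.09) at the extreme, matching the printed convention for the top
#' row; Z-scores are computed from the uncapped fraction whenever it is
#' below 1.
#'
#' @param values Metric values across the reference cohort (integer scores,
#'   or RT means which will be binned).
#' @param metric Name stored on the table.
#' @param direction `"higher_better"` (counts) or `"lower_better"` (RTs).
#' @param bin_width Bin width for continuous metrics; default `NULL` leaves
#'   integer scores unbinned and uses 20 ms for `lower_better` metrics.
#' @param cap Extreme-percentile cap (default 99.90).
#' @return An object of class `crt_percentile_table`: a data frame with
#'   columns `metric`, `score`, `n_at_or_worse`, `percentile` (capped) and
#'   `z`, ordered from best to worst score.
#' @examples
#' set.seed(1)
#' tc <- pmin(50, 25 + rbinom(500, 25, 0.9))
#' head(percentile_table(tc, "tc"))
#' @export
percentile_table <- function(values, metric = "metric",
                             direction = c("higher_better", "lower_better"),
                             bin_width = NULL, cap = 99.90) {
  direction <- match.arg(direction)
  values <- values[!is.na(values)]
  if (!length(values)) stop("no non-missing values to tabulate")
  n <- length(values)
  if (direction == "lower_better") {
    bw <- bin_width %||% 20
    grid <- seq(floor(min(values) / bw) * bw, ceiling(max(values) / bw) * bw, by = bw)
    worse <- vapply(grid, function(g) sum(values >= g), numeric(1))
  } else {
    grid <- sort(unique(values), decreasing = TRUE)
    worse <- vapply(grid, function(g) sum(values <= g), numeric(1))
  }
  frac <- worse / n
  pct <- pmin(100 * frac, cap)
  # Z from the uncapped fraction where it exists; the cap's quantile when
  # the whole cohort is at-or-worse (the printed top-row convention).
  z <- ifelse(frac < 1, stats::qnorm(frac), stats::qnorm(cap / 100))
  out <- data.frame(metric = metric, score = grid, n_at_or_worse = worse,
                    percentile = pct, z = z, stringsAsFactors = FALSE)
  class(out) <- c("crt_percentile_table", "data.frame")
  out
}

norm_age_bins <- list(
  breaks = c(21, 31, 41, 51, 61, 71, 81, 91),
  labels = c("21-31", "31-40", "41-51", "51-60", "61-70", "71-81", "81-90"))

#' Build an age-by-sex cohort table with SD bands
#'
#' Computes, per 10-year age bin and sex, the mean of a metric and its 1,
#' 1.5, and 2 SD bands in the "worse" direction: below the mean for count
#' metrics, above it for RTs. Bins follow the printed cohort-table layout
#' (ages 21--90 in seven bins); count values are rounded to 0.1 and RTs to
#' 1 ms. Bins with fewer than 2 subjects get `NA` bands.
#'
#' @param records Data frame with columns `age`, `sex`, and the metric.
#' @param metric Column name to summarize.
#' @param direction `"higher_better"` (bands below the mean) or
#'   `"lower_better"` (bands above).
#' @return An object of class `crt_cohort_table`: a data frame with columns
#'   `metric`, `sex`, `age_bin`, `n`, `mean`, `band_1`, `band_1p5`,
#'   `band_2`.
#' @examples
#' scores <- score_sessions(simulate_cohort(population_config(n_subjects = 200, seed = 1)))
#' cohort_table(scores, "hits", "higher_better")
#' @export
cohort_table <- function(records, metric,
                         direction = c("higher_better", "lower_better")) {
  direction <- match.arg(direction)
  stop_if_missing_cols(records, c("age", "sex", metric), "records")
  sgn <- if (direction == "higher_better") -1 else 1
  digits <- if (direction == "higher_better") 1 else 0
  bins <- cut(records$age, breaks = norm_age_bins$breaks,
              labels = norm_age_bins$labels, right = FALSE, include.lowest = FALSE)
  rows <- list()
  for (sx in intersect(c("male", "female"), unique(records$sex))) {
    for (b in norm_age_bins$labels) {
      v <- records[[metric]][records$sex == sx & !is.na(bins) & bins == b]
      v <- v[!is.na(v)]
      m <- if (length(v)) mean(v) else NA_real_
      s <- if (length(v) >= 2) stats::sd(v) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, sex = sx, age_bin = b, n = length(v),
        mean = round(m, digits),
        band_1 = round(m + sgn * s, digits),
        band_1p5 = round(m + sgn * 1.5 * s, digits),
        band_2 = round(m + sgn * 2 * s, digits),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "direction") <- direction
  class(out) <- c("crt_cohort_table", "data.frame")
  out
}

#' Flag a score against a cohort row's SD bands
#'
#' Applies the clinical convention attached to the cohort tables: a value
#' more than 2 SD in the worse direction from the cohort mean is
#' `"abnormal"`, beyond 1.5 SD is `"possible_impairment"`, otherwise
#' `"normal"`. The published convention requires *two* observations
#' outside 1.5 SD before reading "possible impairment"; this single-value
#' flag reports the band the value falls in, to be combined across repeat
#' tests by the caller.
#'
#' @param value The observed metric value.
#' @param cohort_row A single row of a [cohort_table()] (with `mean`,
#'   `band_1p5`, `band_2`).
#' @param direction `"higher_better"` or `"lower_better"`; defaults to the
#'   direction stored on the table the row came from, if present.
#' @return `"normal"`, `"possible_impairment"`, or `"abnormal"`.
#' @examples
#' norms <- reference_norms()
#' row <- norms$count_cohorts[norms$count_cohorts$metric == "hits" &
#'                            norms$count_cohorts$sex == "male" &
#'                            norms$count_cohorts$age_bin == "21-31", ]
#' impairment_flag(18, row, "higher_better")  # abnormal
#' @export
impairment_flag <- function(value, cohort_row,
                            direction = c("higher_better", "lower_better")) {
  direction <- match.arg(direction)
  if (nrow(cohort_row) != 1) stop("`cohort_row` must be a single table row")
  b15 <- cohort_row$band_1p5
  b2 <- cohort_row$band_2
  if (is.na(b15) || is.na(b2)) stop("cohort row has missing SD bands")
  worse_than <- function(v, band) {
    if (direction == "higher_better") v < band else v > band
  }
  if (worse_than(value, b2)) "abnormal"
  else if (worse_than(value, b15)) "possible_impairment"
  else "normal"
}
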