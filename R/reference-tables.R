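#' Published normative reference tables
#'
#' Returns the published normative tables for the 50-trial CRT, transcribed
#' from the original large-cohort study (n = 18,265 online users aged
#' 21--100): percentile/Z-score rows for the count metrics (TC, HITs, CRs)
#' and for mean RT-HITs in 20 ms bins, and age-by-sex cohort tables giving
#' the mean and the 1, 1.5, and 2 SD bands for HITs, CRs, RT-HITs, and
#' RT-FAs by 10-year age cohort. Count bands lie below the mean (fewer
#' correct is worse); RT bands lie above it (slower is worse).
#'
#' These tables serve two roles: they are the executable reference against
#' which the package's percentile/Z arithmetic is tested, and they anchor
#' the synthetic-cohort generator's age and sex effects
#' (see [population_config()]).
#'
#' @return A list of four data frames:
#' \describe{
#'   \item{count_percentiles}{columns `metric` (`"tc"`, `"hits"`, `"crs"`),
#'     `score`, `percentile`, `z`.}
#'   \item{count_cohorts}{columns `metric` (`"hits"`, `"crs"`), `sex`,
#'     `age_bin`, `mean`, `band_1`, `band_1p5`, `band_2` (bands below the
#'     mean).}
#'   \item{rt_percentiles}{columns `rt_ms` (20 ms bin), `percentile`, `z`.}
#'   \item{rt_cohorts}{columns as `count_cohorts` but for `"rt_hit"` and
#'     `"rt_fa"`, bands above the mean, in ms.}
#' }
#' @examples
#' norms <- reference_norms()
#' head(norms$count_percentiles)
#' @export
reference_norms <- function() {
  read_ref <- function(file) {
    path <- system.file("extdata", file, package = "memcrt", mustWork = TRUE)
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  list(
    count_percentiles = read_ref("norms_count_percentiles.csv"),
    count_cohorts     = read_ref("norms_count_cohorts.csv"),
    rt_percentiles    = read_ref("norms_rt_percentiles.csv"),
    rt_cohorts        = read_ref("norms_rt_cohorts.csv")
  )
}

# Midpoint of a printed age-bin label such as "21-31" or "81-90".
bin_midpoint <- function(label) {
  parts <- strsplit(label, "-", fixed = TRUE)
  vapply(parts, function(p) mean(as.numeric(p)), numeric(1))
}

# Interpolate a cohort-table metric at exact ages for one sex. Linear
# between bin midpoints, constant beyond the first/last midpoint.
interpolate_anchor <- function(cohorts, metric, sex, age) {
  rows <- cohorts[cohorts$metric == metric & cohorts$sex == sex, ]
  if (!nrow(rows)) stop(sprintf("no anchor rows for metric '%s', sex '%s'", metric, sex))
  mids <- bin_midpoint(rows$age_bin)
  ord <- order(mids)
  stats::approx(mids[ord], rows$mean[ord], xout = age, rule = 2)$y
}
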