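#' Configuration for the end-to-end analysis pipeline
#'
#' Bundles the per-stage configurations: cohort simulation, scoring,
#' sample-selection filters, RevEx fitting (bounds and the median-age
#' split), and the normative tables to emit.
#'
#' @param population A [population_config()]; its seed is overridden by
#'   `seed` when given.
#' @param filters A [filter_config()], or `NULL` to skip filtering.
#' @param revex_bounds Survival-fraction bounds for [fit_revex()].
#' @param split_age Age for the young/old RevEx comparison (default 50,
#'   the reference cohort's median age).
#' @param out_dir Output directory for [run_pipeline()] artifacts.
#' @param seed Master seed for the whole run.
#' @param write_sessions_csv If `TRUE`, also write the (large) per-trial
#'   sessions CSV.
#' @return An object of class `crt_pipeline_config`.
#' @seealso [run_pipeline()]
#' @export
pipeline_config <- function(population = population_config(),
                            filters = filter_config(),
                            revex_bounds = c(0.005, 0.995),
                            split_age = 50,
                            out_dir = "crt-artifacts",
                            seed = 1,
                            write_sessions_csv = FALSE) {
  if (!is.null(seed)) population$seed <- seed
  structure(
    list(population = population, filters = filters,
         revex_bounds = revex_bounds, split_age = split_age,
         out_dir = out_dir, seed = seed,
         write_sessions_csv = write_sessions_csv),
    class = "crt_pipeline_config")
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Run the full CRT analysis pipeline
#'
#' Simulates (or accepts) a cohort, scores every session, applies the
#' sample-selection funnel, fits the RevEx model overall and split at the
#' configured age, builds the normative percentile and age-cohort tables,
#' runs the correctness--RT relationship analyses, and writes every
#' artifact plus a manifest to the output directory. Rerunning with the
#' same configuration reproduces the artifacts byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param sessions Optional pre-existing trial table (e.g. from
#'   [read_sessions()]); when omitted the cohort is simulated from
#'   `config$population`.
#' @return Invisibly, a list with the in-memory results: `scores`, `kept`,
#'   `funnel`, `revex`, `revex_split`, `percentiles`, `cohorts`,
#'   `relations`, and `manifest`. Artifacts written: `scores.csv`,
#'   `kept.csv`, `funnel.csv`, `percentile_*.csv`, `cohort_*.csv`,
#'   `revex.json`, `relations.json`, `manifest.json` (and `sessions.csv`
#'   if requested).
#' @examples
#' \donttest{
#' cfg <- pipeline_config(population_config(n_subjects = 200), seed = 42,
#'                        out_dir = tempfile())
#' res <- run_pipeline(cfg)
#' res$funnel
#' }
#' @export
run_pipeline <- function(config = pipeline_config(), sessions = NULL) {
  stopifnot(inherits(config, "crt_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- "simulate"
  res <- tryCatch({
    if (is.null(sessions)) sessions <- simulate_cohort(config$population)
    if (config$write_sessions_csv) write_sessions(sessions, out("sessions.csv"))

    stage <- "score"
    scores <- score_sessions(sessions)
    write_scores(scores, out("scores.csv"))

    stage <- "filter"
    if (!is.null(config$filters)) {
      flt <- apply_filters(scores, config$filters)
      kept <- flt$kept
      funnel <- flt$funnel
    } else {
      kept <- scores
      funnel <- data.frame(rule = character(), n_before = integer(),
                           n_removed = integer(), n_after = integer())
    }
    write_scores(kept, out("kept.csv"))
    utils::write.csv(funnel, out("funnel.csv"), row.names = FALSE)

    stage <- "revex"
    rt <- kept$mean_rt_hit[!is.na(kept$mean_rt_hit)]
    revex <- fit_revex(rt, config$revex_bounds)
    young <- kept$mean_rt_hit[!is.na(kept$mean_rt_hit) & kept$age < config$split_age]
    old <- kept$mean_rt_hit[!is.na(kept$mean_rt_hit) & kept$age >= config$split_age]
    revex_split <- compare_groups(young, old,
                                  labels = c(sprintf("under%d", config$split_age),
                                             sprintf("%dplus", config$split_age)),
                                  fit_bounds = config$revex_bounds)
    write_json_artifact(list(
      overall = unclass(revex),
      split = list(labels = revex_split$labels,
                   fit_a = unclass(revex_split$fit_a),
                   fit_b = unclass(revex_split$fit_b),
                   delta_scale_ms = revex_split$delta_scale_ms,
                   delta_onset_ms = revex_split$delta_onset_ms,
                   slower_tail = revex_split$slower_tail)),
      out("revex.json"))

    stage <- "norms"
    percentiles <- list(
      tc = percentile_table(kept$tc, "tc", "higher_better"),
      hits = percentile_table(kept$hits, "hits", "higher_better"),
      crs = percentile_table(kept$crs, "crs", "higher_better"),
      mean_rt_hit = percentile_table(kept$mean_rt_hit, "mean_rt_hit", "lower_better"))
    cohorts <- list(
      hits = cohort_table(kept, "hits", "higher_better"),
      crs = cohort_table(kept, "crs", "higher_better"),
      mean_rt_hit = cohort_table(kept, "mean_rt_hit", "lower_better"),
      mean_rt_fa = cohort_table(kept, "mean_rt_fa", "lower_better"))
    for (nm in names(percentiles)) {
      utils::write.csv(percentiles[[nm]], out(sprintf("percentile_%s.csv", nm)),
                       row.names = FALSE, na = "")
    }
    for (nm in names(cohorts)) {
      utils::write.csv(cohorts[[nm]], out(sprintf("cohort_%s.csv", nm)),
                       row.names = FALSE, na = "")
    }

    stage <- "relations"
    decomp <- rt_correct_decomposition(kept)
    relations <- list(
      decomposition = list(r2 = as.list(decomp$r2), r2_order = decomp$r2_order),
      fa_hit = fa_hit_rt_comparison(kept)["fraction_fa_faster"],
      cumexp = list(hits = cumulative_correct_expfit(kept$hits, "hits")$r2,
                    crs = cumulative_correct_expfit(kept$crs, "crs")$r2,
                    tc = cumulative_correct_expfit(kept$tc, "tc")$r2))
    write_json_artifact(relations, out("relations.json"))

    stage <- "manifest"
    manifest <- list(
      package = "memcrt",
      version = as.character(utils::packageVersion("memcrt")),
      seed = config$seed,
      n_subjects = config$population$n_subjects,
      n_trials = nrow(sessions),
      n_scored = nrow(scores),
      n_kept = nrow(kept),
      split_age = config$split_age,
      revex_bounds = config$revex_bounds)
    write_json_artifact(manifest, out("manifest.json"))

    list(scores = scores, kept = kept, funnel = funnel, revex = revex,
         revex_split = revex_split, percentiles = percentiles,
         cohorts = cohorts, relations = relations, manifest = manifest)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(res)
}
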