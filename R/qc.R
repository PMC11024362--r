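#' Sample-selection filter configuration
#'
#' Encodes the study's sample-selection funnel as an ordered list of
#' conjunctive rules applied to a scored cohort:
#' \describe{
#'   \item{`birthdate`}{drop records with no recorded age.}
#'   \item{`age_range`}{keep ages in `[min_age, max_age]` (defaults 21 and
#'     100).}
#'   \item{`dedupe`}{keep only the first record per `subject_id`.}
#'   \item{`zero_responses`}{drop sessions with no responses at all.}
#'   \item{`min_tc`}{keep total correct of at least `min_tc` (default 33;
#'     a TC of 32 or fewer -- below 65% correct -- is removed, so a TC of
#'     exactly 33 is kept).}
#'   \item{`max_rt`}{drop mean RT-HITs slower than `max_mean_rt_hit_ms`
#'     (default 2,000 ms).}
#'   \item{`min_rt`}{optional lower bound on mean RT-HIT, disabled by
#'     default: in the original cohort every implausibly fast responder
#'     already failed the TC rule.}
#' }
#' Rules are conjunctive, so the final kept set does not depend on
#' `rule_order`; the order only affects which rule is credited with each
#' removal in the attrition funnel.
#'
#' @param min_age,max_age Inclusive age bounds.
#' @param require_birthdate Enable the `birthdate` (non-missing age) rule.
#' @param dedupe_keep_first Enable the `dedupe` rule.
#' @param drop_zero_responses Enable the `zero_responses` rule.
#' @param min_tc Minimum total correct kept.
#' @param max_mean_rt_hit_ms Maximum mean RT-HIT kept, ms.
#' @param min_mean_rt_hit_ms Optional minimum mean RT-HIT kept, ms, or
#'   `NULL` to disable.
#' @param rule_order Character vector ordering the enabled rules.
#' @return An object of class `crt_filter_config`.
#' @seealso [apply_filters()]
#' @export
filter_config <- function(min_age = 21, max_age = 100,
                          require_birthdate = TRUE,
                          dedupe_keep_first = TRUE,
                          drop_zero_responses = TRUE,
                          min_tc = 33,
                          max_mean_rt_hit_ms = 2000,
                          min_mean_rt_hit_ms = NULL,
                          rule_order = c("birthdate", "age_range", "dedupe",
                                         "zero_responses", "min_tc", "max_rt", "min_rt")) {
  stopifnot(min_tc >= 0, min_tc <= 50, max_mean_rt_hit_ms > 0, min_age <= max_age)
  enabled <- c(birthdate = require_birthdate, age_range = TRUE,
               dedupe = dedupe_keep_first, zero_responses = drop_zero_responses,
               min_tc = TRUE, max_rt = TRUE, min_rt = !is.null(min_mean_rt_hit_ms))
  rule_order <- intersect(rule_order, names(enabled)[enabled])
  structure(
    list(min_age = min_age, max_age = max_age,
         require_birthdate = require_birthdate,
         dedupe_keep_first = dedupe_keep_first,
         drop_zero_responses = drop_zero_responses,
         min_tc = min_tc, max_mean_rt_hit_ms = max_mean_rt_hit_ms,
         min_mean_rt_hit_ms = min_mean_rt_hit_ms,
         rule_order = rule_order),
    class = "crt_filter_config")
}

filter_rule_fields <- c(birthdate = "age", age_range = "age", dedupe = "subject_id",
                        zero_responses = "n_responses", min_tc = "tc",
                        max_rt = "mean_rt_hit", min_rt = "mean_rt_hit")

# Which records pass one rule. Missing values only fail the rules that are
# about missingness (`birthdate`); comparison rules pass NA through so each
# removal is attributed to exactly one rule.
filter_rule_pass <- function(records, rule, config) {
  switch(rule,
    birthdate = !is.na(records$age),
    age_range = is.na(records$age) |
      (records$age >= config$min_age & records$age <= config$max_age),
    dedupe = !duplicated(records$subject_id),
    zero_responses = records$n_responses > 0,
    min_tc = records$tc >= config$min_tc,
    max_rt = is.na(records$mean_rt_hit) | records$mean_rt_hit <= config$max_mean_rt_hit_ms,
    min_rt = is.na(records$mean_rt_hit) | records$mean_rt_hit >= config$min_mean_rt_hit_ms,
    stop("unknown filter rule: ", rule))
}

#' Apply the sample-selection funnel to a scored cohort
#'
#' Runs the enabled filter rules in order and reports per-rule attrition.
#' The rules are conjunctive, so re-applying the filters to the kept set
#' removes nothing (idempotence), and reordering the rules changes only the
#' per-rule attribution of removals, never the final kept set.
#'
#' @param records Scored subject records (one row per subject), as from
#'   [score_sessions()].
#' @param config A [filter_config()].
#' @return A list with elements `kept` (the surviving records) and `funnel`
#'   (a data frame with columns `rule`, `n_before`, `n_removed`,
#'   `n_after`, consecutive rows chaining).
#' @examples
#' scores <- score_sessions(simulate_cohort(population_config(n_subjects = 50, seed = 1)))
#' res <- apply_filters(scores, filter_config())
#' res$funnel
#' @export
apply_filters <- function(records, config = filter_config()) {
  stopifnot(inherits(config, "crt_filter_config"))
  for (rule in config$rule_order) {
    field <- filter_rule_fields[[rule]]
    if (!field %in% names(records)) {
      stop(sprintf("rule '%s' requires column '%s'", rule, field))
    }
  }
  kept <- records
  funnel <- vector("list", length(config$rule_order))
  for (i in seq_along(config$rule_order)) {
    rule <- config$rule_order[i]
    pass <- filter_rule_pass(kept, rule, config)
    funnel[[i]] <- data.frame(rule = rule, n_before = nrow(kept),
                              n_removed = sum(!pass), n_after = sum(pass),
                              stringsAsFactors = FALSE)
    kept <- kept[pass, , drop = FALSE]
  }
  rownames(kept) <- NULL
  list(kept = kept,
       funnel = do.call(rbind, c(funnel, list(make.row.names = FALSE))))
}

#' Chance-band classification of a total-correct score
#'
#' The study's operational chance band: a TC of 30/50 (60%) or below is
#' treated as no better than random-chance responding and flagged
#' `"below_chance_margin"`. Note the band is deliberately wider than the
#' true random expectation of TC = 25 (see
#' [expected_random_performance()]); scores of 26--30 beat random in
#' expectation but fall inside the operational margin.
#'
#' @param tc Total correct, in `[0, 50]`; vectorized.
#' @return Character vector, `"below_chance_margin"` or `"above"`.
#' @examples
#' chance_band(c(25, 30, 31))
#' @export
chance_band <- function(tc) {
  if (any(is.na(tc)) || any(tc < 0 | tc > 50)) stop("`tc` must be in [0, 50]")
  ifelse(tc <= 30, "below_chance_margin", "above")
}
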