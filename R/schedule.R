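#' Configuration for a CRT stimulus schedule
#'
#' Describes the constrained pseudo-random design of a continuous recognition
#' task run: `n_trials` presentations of which `n_categories *
#' pictures_per_category` are first showings ("new") and the remainder are
#' repeats of earlier pictures. The defaults encode the standard 50-trial
#' design: 25 new pictures (5 categories x 5 pictures) and 25 repeats, the
#' first two trials always new, at most `max_run` consecutive trials of the
#' same type (new/repeat), and every repeat separated from the previous
#' showing of its picture by `lag_min` to `lag_max` intervening trials.
#'
#' @param n_categories Number of picture categories (default 5).
#' @param pictures_per_category Pictures per category (default 5).
#' @param n_trials Total trials (default 50).
#' @param max_run Maximum number of consecutive same-type (new or repeat)
#'   trials (default 4).
#' @param lag_min,lag_max Allowed range for the lag, the count of intervening
#'   trials between successive showings of the same picture (defaults 1 and
#'   45).
#' @param repeat_plan Named integer vector `c(twice = , once = , never = )`
#'   giving, per category, how many pictures are repeated twice, once, or
#'   never. The default `c(twice = 1, once = 3, never = 1)` yields 5 repeat
#'   presentations per category and hence 25 repeats in the default design.
#' @param seed Integer seed making [generate_schedule()] deterministic, or
#'   `NULL` to use the current RNG state.
#' @param retry_budget Maximum number of full rebuild attempts before
#'   generation gives up and signals an infeasible configuration.
#'
#' @return An object of class `crt_schedule_config` (a list).
#' @seealso [generate_schedule()], [validate_schedule()]
#' @examples
#' cfg <- schedule_config(seed = 1)
#' cfg$n_new
#' @export
schedule_config <- function(n_categories = 5,
                            pictures_per_category = 5,
                            n_trials = 50,
                            max_run = 4,
                            lag_min = 1,
                            lag_max = 45,
                            repeat_plan = c(twice = 1, once = 3, never = 1),
                            seed = NULL,
                            retry_budget = 10000) {
  repeat_plan <- repeat_plan[c("twice", "once", "never")]
  if (anyNA(repeat_plan)) {
    stop("`repeat_plan` must be a named vector with elements twice, once, never")
  }
  n_new <- n_categories * pictures_per_category
  n_repeats <- n_trials - n_new
  if (sum(repeat_plan) != pictures_per_category) {
    stop("`repeat_plan` entries must sum to `pictures_per_category`")
  }
  implied <- n_categories * (2 * repeat_plan[["twice"]] + repeat_plan[["once"]])
  if (implied != n_repeats) {
    stop(sprintf(
      "repeat_plan implies %d repeat presentations but the design needs %d (= n_trials - n_new)",
      implied, n_repeats))
  }
  if (n_repeats < 0) stop("`n_trials` must be at least n_categories * pictures_per_category")
  if (lag_min < 0 || lag_max < lag_min) stop("need 0 <= lag_min <= lag_max")
  if (max_run < 1) stop("`max_run` must be positive")
  structure(
    list(n_categories = n_categories,
         pictures_per_category = pictures_per_category,
         n_trials = n_trials, n_new = n_new, n_repeats = n_repeats,
         max_run = max_run, lag_min = lag_min, lag_max = lag_max,
         repeat_plan = repeat_plan, seed = seed,
         retry_budget = retry_budget),
    class = "crt_schedule_config")
}

#' @export
print.crt_schedule_config <- function(x, ...) {
  cat(sprintf(
    "CRT schedule config: %d trials (%d new + %d repeats), %d categories x %d pictures\n",
    x$n_trials, x$n_new, x$n_repeats, x$n_categories, x$pictures_per_category))
  cat(sprintf("  lags %d-%d, max run %d, repeat plan per category: %s\n",
              x$lag_min, x$lag_max, x$max_run,
              paste(names(x$repeat_plan), x$repeat_plan, sep = "=", collapse = " ")))
  invisible(x)
}

# Random new/repeat type sequence honoring the leading-new and max-run
# constraints; NULL if rejection sampling exhausts its local budget.
type_sequence <- function(config, tries = 500L) {
  lead <- min(2L, config$n_trials)
  body_new <- config$n_new - lead
  if (body_new < 0) return(NULL)
  pool <- c(rep(FALSE, body_new), rep(TRUE, config$n_repeats))
  for (i in seq_len(tries)) {
    types <- c(rep(FALSE, lead), sample(pool))
    if (max(rle(types)$lengths) <= config$max_run) return(types)
  }
  NULL
}

# Greedy randomized assignment of repeat presentations to repeat positions.
# Pictures within a category are exchangeable, so repeat multiplicities are
# chosen here purely on timing feasibility (with quota tracking); category
# labels are attached afterwards, which is always satisfiable. Returns the
# picture slot (index into first_pos) repeated at each repeat position, or
# NULL on a dead end (caller restarts).
assign_repeats <- function(rep_pos, first_pos, config) {
  plan <- config$repeat_plan
  quota_twice <- config$n_categories * plan[["twice"]]
  quota_ge1 <- config$n_categories * (plan[["twice"]] + plan[["once"]])
  n_slots <- length(first_pos)
  reps <- integer(n_slots)      # repeats placed so far per picture slot
  last_seen <- first_pos
  n_ge1 <- 0L
  n2 <- 0L
  chosen <- integer(length(rep_pos))
  for (k in seq_along(rep_pos)) {
    q <- rep_pos[k]
    in_window <- last_seen >= q - 1L - config$lag_max &
      last_seen <= q - 1L - config$lag_min
    can_first <- reps == 0L & n_ge1 < quota_ge1
    can_second <- reps == 1L & n2 < quota_twice
    cand <- which(in_window & (can_first | can_second))
    if (!length(cand)) return(NULL)
    i <- cand[sample.int(length(cand), 1L)]
    if (reps[i] == 0L) n_ge1 <- n_ge1 + 1L else n2 <- n2 + 1L
    reps[i] <- reps[i] + 1L
    last_seen[i] <- q
    chosen[k] <- i
  }
  # Final multiplicity profile must match the plan exactly.
  if (n2 != quota_twice || n_ge1 != quota_ge1) return(NULL)
  chosen
}

#' Generate a constrained pseudo-random CRT schedule
#'
#' Builds an ordered stimulus plan satisfying every design constraint in the
#' configuration: the exact new/repeat totals, leading new trials, the
#' maximum same-type run length, the per-category repeat multiplicities, and
#' the lag range between successive showings of a picture. Generation is
#' rejection sampling over random interleavings: a random new/repeat type
#' sequence is drawn, new pictures are placed in random order, and repeat
#' presentations are assigned by randomized backtracking; the whole build is
#' restarted on dead ends, up to `retry_budget` attempts.
#'
#' @param config A [schedule_config()].
#' @return A data frame of class `crt_schedule` with one row per trial and
#'   columns `position`, `picture_id`, `category_id`, `presentation_index`
#'   (1 for a first showing, then 2 and possibly 3), `is_repeat`, and `lag`
#'   (intervening trials since the previous showing; `NA` for first
#'   showings). The generating config is attached as attribute `config`.
#' @examples
#' sched <- generate_schedule(schedule_config(seed = 1))
#' table(sched$is_repeat)
#' nrow(validate_schedule(sched))  # 0
#' @export
generate_schedule <- function(config = schedule_config()) {
  stopifnot(inherits(config, "crt_schedule_config"))
  with_seed(config$seed, {
    for (attempt in seq_len(config$retry_budget)) {
      sched <- build_schedule_once(config)
      if (!is.null(sched)) return(sched)
    }
    stop("could not generate a schedule satisfying the constraints; ",
         "the configuration appears infeasible within the retry budget")
  })
}

build_schedule_once <- function(config) {
  n_pics <- config$n_new
  plan <- config$repeat_plan

  types <- type_sequence(config)
  if (is.null(types)) return(NULL)
  new_pos <- which(!types)
  rep_pos <- which(types)

  first_pos <- sample(new_pos)           # first showing of picture slot i
  chosen <- assign_repeats(rep_pos, first_pos, config)
  if (is.null(chosen)) return(NULL)

  # Attach category labels afterwards: distribute each repeat-multiplicity
  # class evenly over categories (the per-category plan), at random.
  reps_of <- tabulate(chosen, nbins = n_pics)
  cat_of <- integer(n_pics)
  for (m in c(2L, 1L, 0L)) {
    cls <- which(reps_of == m)
    per_cat <- plan[[c("never", "once", "twice")[m + 1L]]]
    cat_of[cls] <- sample(rep(seq_len(config$n_categories), each = per_cat))
  }
  pic_num <- stats::ave(seq_len(n_pics), cat_of, FUN = seq_along)
  pic_ids <- sprintf("C%dP%d", cat_of, pic_num)

  picture <- integer(config$n_trials)
  picture[first_pos] <- seq_len(n_pics)
  picture[rep_pos] <- chosen

  pres_index <- integer(config$n_trials)
  lag <- rep(NA_integer_, config$n_trials)
  prev_seen <- integer(n_pics)
  pres_so_far <- integer(n_pics)
  for (q in seq_len(config$n_trials)) {
    p <- picture[q]
    pres_so_far[p] <- pres_so_far[p] + 1L
    pres_index[q] <- pres_so_far[p]
    if (pres_so_far[p] > 1L) lag[q] <- q - prev_seen[p] - 1L
    prev_seen[p] <- q
  }

  out <- data.frame(
    position = seq_len(config$n_trials),
    picture_id = pic_ids[picture],
    category_id = cat_of[picture],
    presentation_index = pres_index,
    is_repeat = pres_index > 1L,
    lag = lag,
    stringsAsFactors = FALSE)
  attr(out, "config") <- config
  class(out) <- c("crt_schedule", "data.frame")
  out
}

#' Validate a CRT schedule against its design constraints
#'
#' Checks every schedule invariant and returns one row per violation, naming
#' the broken rule and the offending trial position(s). An empty result
#' means the schedule is valid. Malformed structure (wrong trial count,
#' non-contiguous positions, inconsistent repeat flags or lags) is reported
#' as violations rather than raised as errors.
#'
#' @param schedule A `crt_schedule` data frame (or anything with the same
#'   columns).
#' @param config The [schedule_config()] defining the constraints; defaults
#'   to the config attached to the schedule, or the standard design.
#' @return A data frame with columns `rule`, `position` (`NA` for
#'   schedule-wide rules), and `detail`; zero rows when the schedule
#'   satisfies every constraint.
#' @examples
#' sched <- generate_schedule(schedule_config(seed = 2))
#' validate_schedule(sched)        # zero rows
#' sched$lag[sched$is_repeat][1] <- 46L
#' validate_schedule(sched)$rule
#' @export
validate_schedule <- function(schedule, config = NULL) {
  config <- config %||% attr(schedule, "config") %||% schedule_config()
  v <- list()
  bad <- function(rule, position, detail) {
    v[[length(v) + 1L]] <<- data.frame(rule = rule, position = position,
                                       detail = detail, stringsAsFactors = FALSE)
  }
  need <- c("position", "picture_id", "presentation_index", "is_repeat", "lag")
  miss <- setdiff(need, names(schedule))
  if (length(miss)) {
    bad("structure", NA_integer_, paste("missing columns:", paste(miss, collapse = ", ")))
    return(do.call(rbind, v))
  }

  if (nrow(schedule) != config$n_trials) {
    bad("trial-count", NA_integer_,
        sprintf("%d trials, expected %d", nrow(schedule), config$n_trials))
  }
  if (!identical(as.integer(schedule$position), seq_len(nrow(schedule)))) {
    bad("positions-contiguous", NA_integer_, "positions are not 1..n in order")
  }
  n_rep <- sum(schedule$is_repeat)
  if (n_rep != config$n_repeats) {
    bad("repeat-count", NA_integer_,
        sprintf("%d repeats, expected %d", n_rep, config$n_repeats))
  }
  if (nrow(schedule) - n_rep != config$n_new) {
    bad("new-count", NA_integer_,
        sprintf("%d new trials, expected %d", nrow(schedule) - n_rep, config$n_new))
  }
  for (q in seq_len(min(2L, nrow(schedule)))) {
    if (isTRUE(schedule$is_repeat[q])) bad("first-two-new", q, "leading trial marked repeat")
  }
  flag_mismatch <- which(schedule$is_repeat != (schedule$presentation_index > 1L))
  for (q in flag_mismatch) {
    bad("repeat-flag", q, "is_repeat inconsistent with presentation_index")
  }

  runs <- rle(schedule$is_repeat)
  if (any(runs$lengths > config$max_run)) {
    ends <- cumsum(runs$lengths)
    for (i in which(runs$lengths > config$max_run)) {
      bad("max-run", ends[i] - runs$lengths[i] + 1L,
          sprintf("run of %d %s trials exceeds max_run %d", runs$lengths[i],
                  if (runs$values[i]) "repeat" else "new", config$max_run))
    }
  }

  # Per-picture presentation structure and lag bookkeeping.
  ord <- order(schedule$position)
  prev_seen <- list()
  prev_pres <- list()
  for (idx in ord) {
    q <- schedule$position[idx]
    p <- schedule$picture_id[idx]
    k <- schedule$presentation_index[idx]
    expected <- (prev_pres[[p]] %||% 0L) + 1L
    if (k != expected) {
      bad("presentation-order", q,
          sprintf("picture %s shown with presentation_index %d, expected %d", p, k, expected))
    }
    if (k > 1L) {
      prev <- prev_seen[[p]]
      if (is.null(prev)) {
        bad("presentation-order", q, sprintf("repeat of %s before any first showing", p))
      } else {
        true_lag <- q - prev - 1L
        if (is.na(schedule$lag[idx]) || schedule$lag[idx] != true_lag) {
          bad("lag-consistency", q,
              sprintf("recorded lag %s, actual %d", schedule$lag[idx], true_lag))
        }
        if (true_lag < config$lag_min || true_lag > config$lag_max) {
          bad("lag-range", q,
              sprintf("lag %d outside [%d, %d]", true_lag, config$lag_min, config$lag_max))
        }
      }
    } else if (!is.na(schedule$lag[idx])) {
      bad("lag-on-first-showing", q, "first showing carries a non-missing lag")
    }
    prev_seen[[p]] <- q
    prev_pres[[p]] <- k
  }

  if (length(v)) do.call(rbind, v) else
    data.frame(rule = character(), position = integer(), detail = character(),
               stringsAsFactors = FALSE)
}

#' Write / read a schedule as CSV
#'
#' The serialization is the plain-text exchange format for schedules: header
#' `position,picture_id,category_id,presentation_index,is_repeat,lag`, with
#' `lag` empty on first showings. Writing then reading restores the schedule
#' exactly; a fixed-seed schedule therefore serializes byte-identically.
#'
#' @param schedule A `crt_schedule`.
#' @param path File path.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns a `crt_schedule` data frame.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule)[, c("position", "picture_id", "category_id",
                                               "presentation_index", "is_repeat", "lag")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(position = "integer", picture_id = "character",
                                       category_id = "integer",
                                       presentation_index = "integer",
                                       is_repeat = "logical", lag = "integer"))
  class(df) <- c("crt_schedule", "data.frame")
  df
}
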