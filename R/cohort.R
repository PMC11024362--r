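#' Configuration of a synthetic CRT cohort
#'
#' Describes the generative model for a simulated population of test takers.
#' Each subject carries a recognition probability, a false-alarm propensity,
#' and shifted-exponential response-time laws for HITs and FAs; age and sex
#' effects enter through the published age-by-sex cohort means
#' (see [reference_norms()]), linearly interpolated between 10-year bin
#' midpoints. The between-subject structure is:
#'
#' \itemize{
#'   \item per-subject HIT RT scale `tau` drawn so that the cohort
#'     distribution of per-subject mean RT-HITs is a shifted exponential --
#'     the signature of the RevEx survival model -- with onset
#'     `hit_rt_onset_ms` and mean equal to the age/sex anchor;
#'   \item recognition probability logit-normal around a location calibrated
#'     numerically so the cohort mean HITs matches the anchor after deadline
#'     censoring;
#'   \item a Gaussian-copula correlation `ability_speed_cor` between low
#'     recognition ability and slow RTs (slower subjects tend to make more
#'     MISSes), driving the observed HITs--RT-HIT relationship;
#'   \item false alarms zero-inflated (`fa_zero_fraction` of subjects never
#'     respond to new images) with a broader, independent RT law.
#' }
#'
#' All calibrations account for the response deadline: a recognition whose
#' RT would exceed 2,900 ms is a censored MISS, and an FA impulse beyond
#' 2,999 ms is not registered.
#'
#' @param n_subjects Number of subjects to simulate.
#' @param age_range Integer age range sampled uniformly (default 21--90, the
#'   span of the published cohort tables).
#' @param female_fraction Fraction of female subjects (default 0.68,
#'   matching the roughly 2:1 female:male user base).
#' @param anchors Optional list with elements `count_cohorts` and
#'   `rt_cohorts` overriding the published anchor tables.
#' @param hit_rt_onset_ms Onset (shift) of the HIT RT law in ms (default
#'   550, the approximate floor of retained mean RT-HITs).
#' @param fa_rt_onset_ms Onset of the FA RT law in ms (default 250,
#'   matching the fastest observed FAs).
#' @param p_rec_sigma,p_fa_sigma Between-subject SD on the logit of the
#'   recognition / false-alarm probability.
#' @param rt_dispersion,fa_rt_dispersion Between-subject dispersion of the
#'   RT scale in `[0, 1]`: 1 draws the per-subject scale from a
#'   mean-preserving exponential (full RevEx heterogeneity), 0 gives every
#'   subject the anchor scale.
#' @param rt_within_frac,fa_rt_within_frac Within-subject share of each
#'   subject's RT spread, in `(0, 1]`: a subject with between-subject draw
#'   `tau` responds with RT `onset + (1 - w) * tau + Exp(w * tau)`, keeping
#'   the subject's target mean at `onset + tau` while splitting its spread
#'   between a person-specific onset and trial-to-trial noise. The cohort
#'   tables pin down only between-subject spread, so the split is a
#'   modeling choice (defaults 0.25 for HITs, 0.5 for FAs).
#' @param ability_speed_cor Copula correlation between slow RT and low
#'   recognition probability (default 0.35).
#' @param fa_zero_fraction Fraction of subjects with structurally zero
#'   false-alarm propensity (default 0.37; roughly the observed share of
#'   users with no FAs).
#' @param shared_schedule If `TRUE` (default) all subjects are tested on one
#'   generated schedule, mirroring a deployment with fixed order sets; if
#'   `FALSE` each subject gets an independent schedule.
#' @param schedule A [schedule_config()] used to generate schedules.
#' @param seed Integer seed for full reproducibility of
#'   [simulate_cohort()].
#' @return An object of class `crt_population_config`.
#' @seealso [sample_subject()], [simulate_cohort()]
#' @examples
#' pop <- population_config(n_subjects = 50, seed = 1)
#' sessions <- simulate_cohort(pop)
#' nrow(sessions)  # 50 subjects x 50 trials
#' @export
population_config <- function(n_subjects = 1000,
                              age_range = c(21, 90),
                              female_fraction = 0.68,
                              anchors = NULL,
                              hit_rt_onset_ms = 550,
                              fa_rt_onset_ms = 250,
                              p_rec_sigma = 0.5,
                              p_fa_sigma = 0.8,
                              rt_dispersion = 1,
                              fa_rt_dispersion = 1,
                              rt_within_frac = 0.25,
                              fa_rt_within_frac = 0.5,
                              ability_speed_cor = 0.35,
                              fa_zero_fraction = 0.37,
                              shared_schedule = TRUE,
                              schedule = schedule_config(),
                              seed = NULL) {
  if (is.null(anchors)) {
    norms <- reference_norms()
    anchors <- list(count_cohorts = norms$count_cohorts,
                    rt_cohorts = norms$rt_cohorts)
  }
  stopifnot(age_range[1] >= 21, age_range[2] <= 100, age_range[1] <= age_range[2],
            female_fraction >= 0, female_fraction <= 1,
            rt_dispersion >= 0, rt_dispersion <= 1,
            fa_rt_dispersion >= 0, fa_rt_dispersion <= 1,
            rt_within_frac > 0, rt_within_frac <= 1,
            fa_rt_within_frac > 0, fa_rt_within_frac <= 1,
            abs(ability_speed_cor) <= 1,
            fa_zero_fraction >= 0, fa_zero_fraction < 1)
  check_anchor_monotone(anchors)
  structure(
    list(n_subjects = n_subjects, age_range = age_range,
         female_fraction = female_fraction, anchors = anchors,
         hit_rt_onset_ms = hit_rt_onset_ms, fa_rt_onset_ms = fa_rt_onset_ms,
         p_rec_sigma = p_rec_sigma, p_fa_sigma = p_fa_sigma,
         rt_dispersion = rt_dispersion, fa_rt_dispersion = fa_rt_dispersion,
         rt_within_frac = rt_within_frac, fa_rt_within_frac = fa_rt_within_frac,
         ability_speed_cor = ability_speed_cor,
         fa_zero_fraction = fa_zero_fraction,
         shared_schedule = shared_schedule, schedule = schedule, seed = seed,
         cache = new.env(parent = emptyenv())),
    class = "crt_population_config")
}

# The published tables are monotone in specific stretches; reject anchor
# sets that break those orderings (mean HITs non-increasing with age bin,
# mean RT-HITs non-decreasing above the second bin).
check_anchor_monotone <- function(anchors) {
  for (sx in c("male", "female")) {
    h <- anchors$count_cohorts
    h <- h[h$metric == "hits" & h$sex == sx, ]
    h <- h[order(bin_midpoint(h$age_bin)), ]
    if (nrow(h) && any(diff(h$mean) > 1e-9)) {
      stop("anchor mean HITs must be non-increasing with age bin (", sx, ")")
    }
    r <- anchors$rt_cohorts
    r <- r[r$metric == "rt_hit" & r$sex == sx, ]
    r <- r[order(bin_midpoint(r$age_bin)), ]
    if (nrow(r) > 2 && any(diff(r$mean[-1]) < -1e-9)) {
      stop("anchor mean RT-HITs must be non-decreasing above the second age bin (", sx, ")")
    }
  }
  invisible(anchors)
}

#' @export
print.crt_population_config <- function(x, ...) {
  cat(sprintf("CRT population config: %d subjects, ages %d-%d, %.0f%% female\n",
              x$n_subjects, x$age_range[1], x$age_range[2], 100 * x$female_fraction))
  cat(sprintf("  HIT RT onset %g ms, FA RT onset %g ms, ability-speed copula %.2f\n",
              x$hit_rt_onset_ms, x$fa_rt_onset_ms, x$ability_speed_cor))
  invisible(x)
}

# ---- calibration ------------------------------------------------------

# Equal-probability standard-normal grid for smooth expectations.
znodes <- function(k) stats::qnorm((seq_len(k) - 0.5) / k)

# Per-subject RT scale as a function of its latent normal score:
# mean-preserving mixture between the anchor scale and an exponential draw.
tau_map <- function(z, scale, dispersion) {
  scale * (1 - dispersion) + dispersion * stats::qexp(stats::pnorm(z), rate = 1 / scale)
}

# Expected *observed* (deadline-truncated) mean of a shifted-exponential RT
# beyond its onset: E[X | X <= horizon] - onset for X - onset ~ Exp(tau),
# horizon measured from the onset. Vectorized over tau and horizon; a
# non-positive horizon (deadline before the onset) contributes 0.
truncated_exp_mean <- function(tau, horizon) {
  horizon <- rep_len(horizon, length(tau))
  out <- tau
  out[horizon <= 0] <- 0
  pos <- tau > 0 & horizon > 0
  r <- exp(-horizon[pos] / tau[pos])
  out[pos] <- tau[pos] - horizon[pos] * r / (1 - r)
  out
}

# Per-subject observed mean RT (beyond the population onset) and response
# probability under the within/between split: subject onset
# onset + (1 - w) tau, trial scale w tau, deadline `hi` (absolute ms).
split_observed_gap <- function(tau, onset, w, hi) {
  (1 - w) * tau + truncated_exp_mean(w * tau, hi - onset - (1 - w) * tau)
}

split_window_prob <- function(tau, onset, w, lo, hi) {
  window_prob(w * tau, onset + (1 - w) * tau, lo, hi)
}

# Probability that a drawn RT lands inside a response window [lo, hi]
# (absolute ms), for onset + Exp(tau).
window_prob <- function(tau, onset, lo, hi) {
  ifelse(tau > 0,
         stats::pexp(pmax(hi - onset, 0), rate = 1 / tau) -
           stats::pexp(pmax(lo - onset, 0), rate = 1 / tau),
         as.numeric(onset >= lo & onset <= hi))
}

# Solve E[plogis(mu + sigma * Z)] = target for mu, optionally with weights
# w over the z grid (used for the censoring x copula coupling).
calibrate_logit_location <- function(target, sigma, zg, w = NULL) {
  if (target <= 0 || target >= 1) stop("calibration target must be in (0, 1)")
  if (sigma == 0) return(stats::qlogis(target))
  w <- w %||% rep(1 / length(zg), length(zg))
  f <- function(mu) sum(w * stats::plogis(mu + sigma * zg)) / sum(w) - target
  stats::uniroot(f, interval = c(-30, 30), tol = 1e-10)$root
}

# Calibrate the generative parameters for one (age, sex) cell so the cohort
# means reproduce the interpolated anchors after deadline censoring.
# Memoized on the population's cache environment.
calibrate_cell <- function(population, age, sex) {
  key <- sprintf("%s:%.6f", sex, age)
  cached <- population$cache[[key]]
  if (!is.null(cached)) return(cached)

  cc <- population$anchors$count_cohorts
  rc <- population$anchors$rt_cohorts
  m_hits <- interpolate_anchor(cc, "hits", sex, age)
  m_crs <- interpolate_anchor(cc, "crs", sex, age)
  m_rth <- interpolate_anchor(rc, "rt_hit", sex, age)
  m_rtf <- interpolate_anchor(rc, "rt_fa", sex, age)

  onset <- population$hit_rt_onset_ms
  fa_onset <- population$fa_rt_onset_ms
  d <- population$rt_dispersion
  d_fa <- population$fa_rt_dispersion
  rho <- population$ability_speed_cor
  zg <- znodes(201L)

  # HIT RT scale: match the anchor mean of *observed* per-subject means.
  w <- population$rt_within_frac
  w_fa <- population$fa_rt_within_frac
  target_gap <- m_rth - onset
  if (target_gap <= 0) stop("RT-HIT anchor must exceed the onset")
  obs_gap <- function(s) mean(split_observed_gap(tau_map(zg, s, d), onset, w, 2900))
  s_hit <- stats::uniroot(function(s) obs_gap(s) - target_gap,
                          interval = c(target_gap, 6 * target_gap),
                          extendInt = "upX", tol = 1e-6)$root

  # Recognition probability: E[p_rec * P(RT in window)] = mean HITs / 25,
  # with p_rec coupled to the RT latent through the copula.
  c_hit <- split_window_prob(tau_map(zg, s_hit, d), onset, w, 50, 2900)
  target_rec <- m_hits / 25
  sig <- population$p_rec_sigma
  if (sig == 0 || rho == 0) {
    mu_rec <- calibrate_logit_location(target_rec / mean(c_hit), sig, zg)
  } else {
    ug <- znodes(151L)
    f <- function(mu) {
      inner <- vapply(zg, function(zs) {
        mean(stats::plogis(mu + sig * (-rho * zs + sqrt(1 - rho^2) * ug)))
      }, numeric(1))
      mean(inner * c_hit) - target_rec
    }
    mu_rec <- stats::uniroot(f, interval = c(-30, 30), tol = 1e-9)$root
  }

  # FA RT scale, same censoring treatment.
  fa_gap <- m_rtf - fa_onset
  if (fa_gap <= 0) stop("RT-FA anchor must exceed the FA onset")
  obs_fa <- function(s) mean(split_observed_gap(tau_map(zg, s, d_fa), fa_onset, w_fa, 2999))
  s_fa <- stats::uniroot(function(s) obs_fa(s) - fa_gap,
                         interval = c(fa_gap, 6 * fa_gap),
                         extendInt = "upX", tol = 1e-6)$root

  # FA propensity among FA-prone subjects; the FA RT latent is independent
  # of the propensity latent, so the expectation factorizes.
  c_fa <- mean(split_window_prob(tau_map(zg, s_fa, d_fa), fa_onset, w_fa, 0, 2999))
  target_fa <- (25 - m_crs) / 25 / (1 - population$fa_zero_fraction)
  if (target_fa >= c_fa) stop("FA anchor unreachable given the zero fraction and deadline")
  mu_fa <- calibrate_logit_location(target_fa / c_fa, population$p_fa_sigma, zg)

  out <- list(m_hits = m_hits, m_crs = m_crs, m_rth = m_rth, m_rtf = m_rtf,
              s_hit = s_hit, mu_rec = mu_rec, s_fa = s_fa, mu_fa = mu_fa)
  population$cache[[key]] <- out
  out
}

# ---- subject and session simulation -----------------------------------

#' Sample one subject's generative parameters
#'
#' Draws a subject from the population model at an exact age and sex: a
#' recognition probability, a false-alarm propensity, and shifted-exponential
#' RT laws for HITs and FAs, all calibrated so cohort-level expectations
#' reproduce the age/sex anchors (see [population_config()]). The subject's
#' target mean RT-HIT is `rt_onset_ms + rt_scale_ms`.
#'
#' @param population A [population_config()].
#' @param age Age in years, within `[21, 100]`; ages beyond the anchor-table
#'   span use the nearest bin.
#' @param sex `"male"` or `"female"`.
#' @param subject_id Optional identifier stored on the result.
#' @param seed Optional seed for a deterministic draw.
#' @return An object of class `crt_subject`: a list with `subject_id`,
#'   `age`, `sex`, `p_recognize`, `p_false_alarm`, `rt_onset_ms`,
#'   `rt_scale_ms`, `fa_rt_onset_ms`, `fa_rt_scale_ms`.
#' @examples
#' pop <- population_config()
#' sample_subject(pop, age = 25, sex = "male", seed = 1)
#' @export
sample_subject <- function(population, age, sex, subject_id = NULL, seed = NULL) {
  stopifnot(inherits(population, "crt_population_config"))
  if (!is.numeric(age) || length(age) != 1L || is.na(age) || age < 21 || age > 100) {
    stop("`age` must be a single value in [21, 100]")
  }
  sex <- match.arg(sex, c("male", "female"))
  cal <- calibrate_cell(population, age, sex)
  with_seed(seed, {
    z <- stats::rnorm(5)  # speed, ability residual, FA propensity, FA speed, FA zero
    rho <- population$ability_speed_cor
    z_speed <- z[1]
    z_mem <- -rho * z_speed + sqrt(1 - rho^2) * z[2]
    tau <- tau_map(z_speed, cal$s_hit, population$rt_dispersion)
    p_rec <- stats::plogis(cal$mu_rec + population$p_rec_sigma * z_mem)
    fa_zero <- stats::pnorm(z[5]) < population$fa_zero_fraction
    p_fa <- if (fa_zero) 0 else stats::plogis(cal$mu_fa + population$p_fa_sigma * z[3])
    tau_fa <- tau_map(z[4], cal$s_fa, population$fa_rt_dispersion)
    w <- population$rt_within_frac
    w_fa <- population$fa_rt_within_frac
    structure(
      list(subject_id = subject_id %||% NA_character_, age = age, sex = sex,
           p_recognize = p_rec, p_false_alarm = p_fa,
           rt_onset_ms = population$hit_rt_onset_ms + (1 - w) * tau,
           rt_scale_ms = w * tau,
           fa_rt_onset_ms = population$fa_rt_onset_ms + (1 - w_fa) * tau_fa,
           fa_rt_scale_ms = w_fa * tau_fa),
      class = "crt_subject")
  })
}

#' @export
print.crt_subject <- function(x, ...) {
  cat(sprintf("CRT subject %s: age %g %s\n", x$subject_id, x$age, x$sex))
  cat(sprintf("  p(recognize) %.3f, p(false alarm) %.3f\n", x$p_recognize, x$p_false_alarm))
  cat(sprintf("  HIT RT ~ %g + Exp(%.0f) ms; FA RT ~ %g + Exp(%.0f) ms\n",
              x$rt_onset_ms, x$rt_scale_ms, x$fa_rt_onset_ms, x$fa_rt_scale_ms))
  invisible(x)
}

rexp_scale <- function(n, scale) {
  if (scale <= 0) rep(0, n) else stats::rexp(n, rate = 1 / scale)
}

#' Simulate one test session
#'
#' Plays a subject through a schedule. On each repeat trial the picture is
#' recognized with probability `p_recognize`; a recognition draws an RT of
#' `rt_onset_ms + Exp(rt_scale_ms)` and registers a response only if the RT
#' is at most 2,900 ms (a slower recognition is a censored MISS). On each
#' first showing, a false-alarm impulse occurs with probability
#' `p_false_alarm`, draws from the FA RT law, and registers only if at most
#' 2,999 ms.
#'
#' @param schedule A `crt_schedule` from [generate_schedule()].
#' @param subject A `crt_subject` from [sample_subject()].
#' @param seed Optional seed for a deterministic session.
#' @return A session log: data frame with columns `subject_id`, `age`,
#'   `sex`, `position`, `picture_id`, `is_repeat`, `responded`, `rt_ms`
#'   (`NA` unless responded).
#' @examples
#' sched <- generate_schedule(schedule_config(seed = 1))
#' subj <- sample_subject(population_config(), 30, "female", "S1", seed = 2)
#' log <- simulate_session(sched, subj, seed = 3)
#' table(log$is_repeat, log$responded)
#' @export
simulate_session <- function(schedule, subject, seed = NULL) {
  stopifnot(inherits(subject, "crt_subject"))
  n <- nrow(schedule)
  rep_trial <- schedule$is_repeat
  with_seed(seed, {
    impulse <- stats::runif(n) < ifelse(rep_trial, subject$p_recognize, subject$p_false_alarm)
    rt <- numeric(n)
    rt[rep_trial] <- subject$rt_onset_ms + rexp_scale(sum(rep_trial), subject$rt_scale_ms)
    rt[!rep_trial] <- subject$fa_rt_onset_ms + rexp_scale(sum(!rep_trial), subject$fa_rt_scale_ms)
    deadline <- ifelse(rep_trial, 2900, 2999)
    responded <- impulse & rt <= deadline
    data.frame(subject_id = subject$subject_id, age = subject$age, sex = subject$sex,
               position = schedule$position, picture_id = schedule$picture_id,
               is_repeat = rep_trial, responded = responded,
               rt_ms = ifelse(responded, rt, NA_real_),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a full cohort of sessions
#'
#' Draws ages (uniform integers over the configured range) and sexes,
#' samples each subject's parameters, and simulates one session per subject
#' on a shared or per-subject schedule. Fully reproducible under the
#' population seed.
#'
#' @param population A [population_config()].
#' @return A long data frame of trials (class `crt_sessions`), one row per
#'   presentation, with the per-subject true parameters attached as
#'   attribute `subjects` and the population as attribute `population`.
#' @examples
#' sessions <- simulate_cohort(population_config(n_subjects = 20, seed = 42))
#' length(unique(sessions$subject_id))
#' @export
simulate_cohort <- function(population) {
  stopifnot(inherits(population, "crt_population_config"))
  n <- population$n_subjects
  empty <- data.frame(subject_id = character(), age = integer(), sex = character(),
                      position = integer(), picture_id = character(),
                      is_repeat = logical(), responded = logical(), rt_ms = numeric(),
                      stringsAsFactors = FALSE)
  if (n == 0) {
    class(empty) <- c("crt_sessions", "data.frame")
    return(empty)
  }
  with_seed(population$seed, {
    age_levels <- seq(population$age_range[1], population$age_range[2])
    ages <- age_levels[sample.int(length(age_levels), n, replace = TRUE)]
    sexes <- ifelse(stats::runif(n) < population$female_fraction, "female", "male")
    ids <- sprintf("S%05d", seq_len(n))
    shared <- if (population$shared_schedule) generate_schedule(population$schedule)
    cols <- vector("list", n)
    subjects <- vector("list", n)
    for (i in seq_len(n)) {
      subj <- sample_subject(population, ages[i], sexes[i], subject_id = ids[i])
      sched <- if (population$shared_schedule) shared else generate_schedule(population$schedule)
      cols[[i]] <- simulate_session(sched, subj)
      subjects[[i]] <- data.frame(subject_id = ids[i], age = ages[i], sex = sexes[i],
                                  p_recognize = subj$p_recognize,
                                  p_false_alarm = subj$p_false_alarm,
                                  rt_onset_ms = subj$rt_onset_ms,
                                  rt_scale_ms = subj$rt_scale_ms,
                                  fa_rt_onset_ms = subj$fa_rt_onset_ms,
                                  fa_rt_scale_ms = subj$fa_rt_scale_ms,
                                  stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, c(cols, list(make.row.names = FALSE)))
    attr(out, "subjects") <- do.call(rbind, c(subjects, list(make.row.names = FALSE)))
    attr(out, "population") <- population
    class(out) <- c("crt_sessions", "data.frame")
    out
  })
}
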