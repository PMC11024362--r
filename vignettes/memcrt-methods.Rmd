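---
title: "Methods: CRT simulation, RevEx response-time modeling, and norms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CRT simulation, RevEx response-time modeling, and norms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the models and procedures behind `memcrt`: the task
design the schedule generator enforces, the generative model of the
synthetic cohort and how it is calibrated to the published age-by-sex
tables, the RevEx response-time survival model, the normative-table
arithmetic, and the numerical and design choices made where the published
description leaves the design open.

## 1. The task and its scoring

The task presents 50 pictures: 25 first showings ("new") and 25 repeats,
drawn from 5 categories of 5 pictures. The subject responds only to
repeats. Scoring is fixed by the task definitions:

* a **HIT** is a response on a repeat trial with RT in [50, 2,900] ms;
* a **MISS** is a repeat trial without such a response — including the
  rare case of a response outside the window, which still counts toward
  the response total;
* a **CR** is a first showing with no response over the 3,000 ms exposure;
* a **FA** is any response to a first showing (responses are physically
  possible up to the 3,000 ms cutoff; the package registers them below
  2,999 ms).

`score_session()` requires the full 25/25 structure and refuses partial
sessions rather than rescaling: percent correct is always out of 50.
A session with no responses at all scores TC = 25 (25 CRs, 0 HITs); the
`chance_band()` helper flags TC ≤ 30 as the operational "no better than
chance" margin used in sample selection, which deliberately sits above the
true random expectation E[TC] = 25 (`expected_random_performance()`
returns the exact reference lines: E[HITs] = n/2 and E[CRs] = 25 − n/2
for n responses placed at random).

## 2. Schedule generation

A valid schedule satisfies: exactly 25 new and 25 repeat trials; the first
two trials new; no more than 4 consecutive trials of the same type; every
repeat separated from the previous showing of its picture by 1–45
intervening trials ("lag"); and per category, 1 picture repeated twice, 3
once, 1 never (5 × 5 = 25 repeat presentations).

Two published statements about repeat multiplicity conflict (four pictures
repeated once plus one twice per category would give 30 repeats, not 25);
the package defaults to the 1/3/1 plan because the 50-trial, 25 + 25
structure anchors all scoring and is stated repeatedly. The alternative
plan remains expressible through `schedule_config(repeat_plan = ...)`,
which will reject it for the 50-trial design since its totals are
inconsistent.

Generation is rejection sampling over random interleavings: draw a random
new/repeat type sequence (rejecting run-length violations), place the 25
new pictures in random order, then walk the repeat positions in order
choosing uniformly among feasible repeat assignments (lag window and
multiplicity quotas), restarting on dead ends up to `retry_budget`
(default 10,000) full attempts. Because pictures within a category are
exchangeable, repeat multiplicities are assigned on timing feasibility
alone and category labels are attached afterwards, which is always
satisfiable; this keeps dead ends rare and generation fast (roughly
6–7 ms per schedule). Two further interpretation choices: the "up to 4 in
a row" bound is applied to the new/repeat type, as it is described; and a
lag of `k` means `k` intervening trials (positional difference minus
one), so `lag_min = 1` forbids immediate re-presentation.

`validate_schedule()` re-derives every constraint from scratch and reports
violations by rule name and position; the generator's tests require zero
violations over 1,000 seeds, and determinism is byte-level on the CSV
serialization.

## 3. The synthetic cohort

No public raw data exist for the reference cohort, so every downstream
stage is exercised against a generative model whose cohort-level
expectations are pinned to the published age-by-sex tables (shipped as
plain CSV under `inst/extdata/` and exposed by `reference_norms()`).

**Anchors.** For each sex, the mean HITs, CRs, RT-HITs and RT-FAs by
10-year age cohort are linearly interpolated between bin midpoints
(constant beyond the first/last midpoint). A validity check enforces the
orderings the tables themselves show (mean HITs non-increasing with age;
mean RT-HITs non-decreasing above the second bin).

**Response times.** The central modeling commitment is the RevEx law: the
cohort distribution of per-subject mean RT-HITs is a shifted exponential
with onset near 550 ms. Each subject draws a latent gap `tau` from a
mean-preserving exponential whose mean equals the interpolated anchor
minus the 550 ms onset; the subject's own RT law is
`onset + (1 - w) tau + Exp(w tau)`, so the subject's target mean is
exactly `550 + tau` while only a fraction `w` of the spread is
trial-to-trial. The tables pin down between-subject spread only, so `w`
(`rt_within_frac`, default 0.25) is a free choice: it was set small
because a full within-subject exponential (w = 1) lets the 2,900 ms
response deadline censor the slow tail of recognitions, compressing slow
subjects' observed means enough to visibly bend the cohort survival curve
(measured R² ≈ 0.94 versus ≈ 0.999 at the default). The printed SD
columns of the RT tables are *not* used by the generator: an exponential
with the anchored mean implies a larger SD than printed, and the RevEx
shape — which the published analysis demonstrates directly — was given
priority over the SD columns (which still serve the normative-table
arithmetic tests).

**Correctness.** Each repeat is recognized with probability
`p_recognize`, logit-normal between subjects (`p_rec_sigma`, default
0.5); a recognition whose drawn RT exceeds 2,900 ms becomes a censored
MISS. The logit location is calibrated numerically (equal-probability
normal grids and `uniroot`) so that the cohort mean of `25 x p_recognize x
P(RT in window)` equals the anchor mean HITs exactly — a mean-calibrated
logit-normal, since the nonlinearity would otherwise bias the cohort mean.
A Gaussian copula (`ability_speed_cor`, default 0.35) ties low recognition
ability to slow RTs: this is what generates the observed HITs–RT-HIT
relationship and its slice structure; 0.35 was chosen to produce a
relationship of the same order as the reference cohort's (R² of a few to
~13 percent, against enormous between-subject RT variability).

**False alarms.** A fraction `fa_zero_fraction` (default 0.37, matching
the published share of users with no FAs) has structurally zero FA
propensity; the rest draw a logit-normal propensity calibrated so the
cohort mean CRs matches its anchor. FA RTs use a broader, independent
shifted-exponential law with onset 250 ms (the fastest observed FAs) and
scale anchored to the RT-FA table; independence reflects the published
finding of essentially no FA–HIT speed relationship. Because FA-prone
subjects can also record zero FAs in 25 trials, the *observed* zero-FA
share of a simulated cohort exceeds the structural 0.37.

**What the generator does not emulate.** Practice effects, education,
within-subject drift, the 50 ms minimum inter-stimulus interval, monthly
picture-set rotation, and any non-exponential fine structure of real RT
distributions. Passing tests therefore demonstrate that the analysis
pipeline recovers the structure this model plants — not that real data
have that structure.

## 4. The RevEx model and its estimator

`survival_curve()` computes the empirical survival fraction with the
strictly-greater convention, so `-ln S` is finite everywhere except at the
maximum (always excluded). `fit_revex()` performs ordinary least squares
of `-ln S(t)` on `t` over curve points with survival inside
`fit_bounds = [0.005, 0.995]`; the slope and intercept give the scale
`tau = 1/b` and onset `t0 = -a/b`, and R² is reported on the transformed
(linear) scale — the form in which the published result states its
better-than-99% variance explained. The "2-factor exponential" is read as
this two-parameter shifted exponential: it is the only reading under
which the negative-log survival plot is linear. (The published text once
prints the R² with a stray negative sign; it is treated as R² > 0.99.)

Numerical properties asserted by the tests: exact recovery on quantile
grids (±0.2 ms at 10,000 grid points); shift invariance and scale
equivariance; unbiased recovery from random samples (sampling SD of the
fitted scale ≈ 1.4% at n = 10,000, so recovery is asserted on the mean of
five replicates); and tail-trimming that never hurts on samples with 1%
slow contamination. The default fit is applied to *per-subject mean*
RT-HITs — the published distribution is across users — with trial-level
pooling available by passing pooled RTs.

One systematic effect is documented rather than hidden: the
sample-selection ceiling (mean RT-HIT ≤ 2,000 ms) truncates the retained
cohort's survival curve inside the default fit bounds, bending the last
stretch upward — the analog of the published "notable fall-off at the
longer RTs". On simulated cohorts of 4,000–5,000 the unfiltered fit
reaches R² ≥ 0.99 while the retained-set fit sits slightly lower
(≈ 0.985–0.992); the end-to-end tests assert both at their observed
levels.

## 5. Sample-selection funnel

`apply_filters()` applies conjunctive rules in a configurable order and
reports a per-rule attrition funnel. Because the rules are conjunctive,
order affects only attribution, never the final kept set — a property the
tests assert directly, which is also why the unknowable original
processing order (e.g. whether the age filter preceded deduplication) is
exposed as configuration rather than guessed. The published attrition
counts are internally inconsistent in places, so the package reproduces
the *rules*, not the counts. No lower RT floor is applied by default: in
the reference cohort every implausibly fast responder already failed the
TC rule (a configurable floor exists for other datasets). Boundary
semantics: TC = 33 is kept ("32 or fewer" removed); mean RT-HIT exactly
2,000 ms is kept ("slower than 2,000" removed).

## 6. Normative tables

Percentiles are cumulative percents *at or worse* than a value along the
metric's direction: at-or-below for counts, at-or-above for RTs (binned
at 20 ms). Whether interior rows of the published tables used "at or
worse" or "strictly worse" cannot be determined without the raw data; the
at-or-worse convention is adopted and tested against a brute-force rank
oracle. The extreme row is capped at 99.90 (Z = 3.09), matching the top
row of every published table; Z-scores elsewhere come from the *uncapped*
fraction via the normal quantile.

Z-scores are normal quantiles of empirical percentiles — not
`(x − mean)/SD` standard scores. This is the only reading that reproduces
the published pairs (e.g. percentile 86.65 → Z = 1.11) for these heavily
skewed distributions, despite the table caption's "relative to the mean"
wording; the executable check over every transcribed (percentile, Z) pair
allows for both columns having been rounded independently.

Cohort tables report, per sex and 10-year bin, the mean and the 1, 1.5,
and 2 SD bands in the worse direction (below the mean for counts, above
for RTs), rounded as printed (0.1 for counts, 1 ms for RTs); bins with
fewer than 2 subjects get missing bands. `impairment_flag()` applies the
published conventions — beyond 2 SD "abnormal", beyond 1.5 SD "possible
impairment" — with the caveat that the published possible-impairment rule
contemplates *two* observations outside 1.5 SD; the single-value flag
reports the band, leaving aggregation across repeat tests to the caller.
The printed bin labels overlap at their edges ("21–31", "31–40", ...);
binning uses half-open decade intervals [21, 31), [31, 41), ..., [81, 91)
and keeps the printed labels.

## 7. Relationship analyses

Age models default to quadratic polynomials (the form used throughout the
published figures), with degree configurable; `fit_polynomial()` also
returns the regression line lowered by 2 population SDs — population
rather than residual SD, since the published description does not
distinguish them, and the choice is labeled. The decomposition fits mean
RT-HIT linearly on TC, HITs, and CRs over the same subjects and reports
the R² ordering; slice analyses hold HITs (or CRs) fixed at 21–25 and fit
across the other count's level means, flagging underdetermined slices
instead of fitting them. Cumulative correctness fits are least squares of
log cumulative percent on the score, with R² on the log scale. A published
regression line whose R² appears implausibly large next to "essentially no
relationship" (0.29 vs a male counterpart of 0.025) is treated as a typo
and not used as an anchor.

## 8. Problem sizes and reproducibility

The test suite simulates cohorts of 150–5,000 subjects and samples of
10,000–100,000 for estimator checks; the schedule sweep validates 1,000
seeds. The acceptance script simulates 10,000 per-subject means. All
randomness flows through explicit seeds; `run_pipeline()` reruns
byte-identically under a fixed configuration, and every per-subject
sub-seed is derived deterministically from the master seed. Calibrations
are memoized per (age, sex) cell, so cohort simulation costs roughly 1–2
ms per subject plus a one-off few milliseconds per distinct age-sex cell.

## 9. Known limitations

* The generator's anchors stop at the 81–90 bin; ages 91–100 are accepted
  but use the last bin's values.
* Anchored simulations reproduce the *qualitative* published relationships
  (orderings of R², slice slopes, group scale differences), not their
  exact magnitudes, which depend on unpublished features of the real
  cohort.
* The zero-FA share, FA RT tail, and within-subject RT variance are
  modeling choices constrained only loosely by the published summaries.
* Percentile tables from small cohorts are exact but noisy; no smoothing
  is applied, by design.
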