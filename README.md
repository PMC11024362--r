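# memcrt

Simulation, scoring, and normative modeling for a 50-trial **continuous
recognition task (CRT)** of episodic memory.

In this task 50 complex pictures stream past (25 new, 25 repeats of earlier
pictures, in a constrained pseudo-random order) and the subject taps a
sensor whenever a picture is a repeat. Each trial is one of four outcomes:

| outcome | trial type | response | window |
|---|---|---|---|
| HIT | repeat | yes | 50–2,900 ms |
| MISS | repeat | no (or outside the window) | — |
| CR (correct rejection) | first showing | no | full 3,000 ms |
| FA (false alarm) | first showing | any response | < 3,000 ms |

Total correct is TC = HITs + CRs out of 50, and the per-session mean
response times over HITs (RT-HITs) and FAs (RT-FAs) are the speed metrics.
Such tasks are used for large-scale screening of episodic-memory
impairment, and large online cohorts show a characteristic structure: HITs
(not CRs) carry the correctness–speed relationship, performance declines
mildly with age relative to huge between-subject variability, and the
cumulative distribution of per-subject mean RT-HITs follows a
**reverse-exponential ("RevEx") survival law**.

## The RevEx model

For response times `t`, RevEx posits a two-parameter shifted exponential:

    S(t) = exp(-(t - t0) / tau),   so   -ln S(t) = (t - t0) / tau

where `S` is the survival fraction (proportion of the sample slower than
`t`), `t0` is the onset (a hard floor near 550 ms for this task) and `tau`
the scale. The package fits `-ln S(t)` by ordinary least squares over the
survival range [0.005, 0.995], reporting `t0 = -a/b`, `tau = 1/b`, and the
R² of the linear fit. In the reference cohort (18,265 online users aged
21–100), this model explains more than 99% of the variance of per-subject
mean RT-HITs.

## What the package provides

- `generate_schedule()` / `validate_schedule()` — constrained pseudo-random
  stimulus plans (25+25, first two new, same-type runs ≤ 4, repeat lags
  1–45, per-category repeat multiplicities).
- `population_config()` / `simulate_cohort()` — a synthetic cohort
  generator anchored to the published age-by-sex normative tables
  (`reference_norms()`), with deadline censoring, zero-inflated false
  alarms, and an ability–speed copula.
- `classify_trial()` / `score_session()` / `score_sessions()` — HIT / MISS
  / CR / FA tabulation and per-session metrics; plus
  `expected_random_performance()` reference lines (random responding has
  E[TC] = 25 regardless of response count).
- `filter_config()` / `apply_filters()` — the sample-selection funnel
  (ages 21–100, deduplication, zero-response and TC ≥ 33 rules, mean
  RT-HIT ≤ 2,000 ms) with a per-rule attrition report.
- `survival_curve()` / `fit_revex()` / `compare_groups()` — the RevEx
  model and the median-age (50) group comparison.
- `percentile_table()` / `cohort_table()` / `z_from_percentile()` /
  `impairment_flag()` — normative percentile/Z tables and age×sex mean ±
  {1, 1.5, 2} SD tables with the clinical banding conventions.
- `rt_correct_decomposition()`, `slice_analysis()`,
  `fa_hit_rt_comparison()`, `cumulative_correct_expfit()`,
  `per_age_summary()`, `fit_polynomial()` — the correctness–RT
  relationship analyses.
- `run_pipeline()` — the whole chain, reproducibly, into an artifact
  directory (CSV tables, JSON fits, manifest).

## Worked example

```r
library(memcrt)

res <- run_pipeline(pipeline_config(population_config(n_subjects = 2000),
                                    seed = 42, out_dir = "crt-artifacts"))
res$funnel
#>             rule n_before n_removed n_after
#> 1      birthdate     2000         0    2000
#> 2      age_range     2000         0    2000
#> 3         dedupe     2000         0    2000
#> 4 zero_responses     2000         2    1998
#> 5         min_tc     1998         5    1993
#> 6         max_rt     1993        49    1944

res$revex
#> RevEx fit: -ln S(t) = a + b t
#>   onset t0 = 570.1 ms, scale tau = 323.9 ms, R^2 = 0.9922
#>   fitted on 1925 survival points (S in [0.005, 0.995]) from n = 1944

res$revex_split
#> RevEx comparison: under50 vs 50plus
#>   under50: tau 288.5 ms, t0 557.4 ms, R^2 0.9982
#>   50plus: tau 343.2 ms, t0 585.1 ms, R^2 0.9836
#>   slower tail: 50plus (delta tau 54.8 ms)

rt_correct_decomposition(res$kept)
#> RT-HIT vs correctness decomposition (n = 1944)
#>   R^2: HITs 0.0383, TC 0.0173, CRs 0.0001 (order: hits > tc > crs)
```

Reading the output: the funnel shows which selection rule removed how many
subjects (here mostly the slow-responder rule). The RevEx fit says the
cohort's mean RT-HITs behave as 570 ms plus an exponential tail with a
324 ms scale, and the linear `-ln S` fit captures 99.2% of the variance;
the over-50 group's larger scale (343 vs 288 ms) reproduces the
age-slowing of the slow tail. The decomposition shows the correctness–RT
link runs through HITs — CRs are unrelated to HIT speed.

Normative lookups against the published tables:

```r
norms <- reference_norms()
z_from_percentile(86.65, digits = 2)   # 1.11 (the TC = 49 row)
row <- subset(norms$rt_cohorts, metric == "rt_hit" & sex == "male" & age_bin == "21-31")
impairment_flag(1150, row, "lower_better")  # "possible_impairment"
```

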