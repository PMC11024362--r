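Package: memcrt
Title: Continuous Recognition Task Simulation, Scoring, and Normative Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing a 50-trial continuous recognition task (CRT)
    of episodic memory: constrained pseudo-random stimulus schedule generation,
    synthetic cohort simulation of cognitive aging anchored to published
    age-by-sex norms, per-session HIT/MISS/CR/FA scoring, sample-selection
    filtering with attrition funnels, reverse-exponential (RevEx) response-time
    survival modeling, normative percentile/Z-score and age-cohort tables, and
    correctness-response-time relationship analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
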