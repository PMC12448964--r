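Package: oclr
Title: Outcome-Based Curriculum Learning for Behavioral Shaping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and algorithm library for outcome-based curriculum
    learning, a teacher-student framework for shaping behavior. Provides a
    tabular temporal-difference sequence-learning student with hidden innate
    biases, teacher algorithms that choose task difficulty from binary
    success/failure transcripts (incremental, random, adaptive decision-tree,
    learning-progress baselines, and a POMCP planner with particle-filter
    inference of the student's hidden parameters), differential evolution of
    the adaptive teacher's decision thresholds, a continuous-difficulty
    extension with a K-step TD student, and a reproducible benchmark harness
    with tidy outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
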