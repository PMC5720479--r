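Package: jbtddm
Title: Drift-Diffusion Modelling of the Rodent Judgement Bias Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of the rodent ambiguous-cue (judgement
    bias) task with a full Wiener drift-diffusion model. Provides first-
    passage-time densities, distribution functions and exact trial
    simulation with inter-trial variability; Kolmogorov-Smirnov parameter
    estimation from probe-session response times in the style of fast-dm;
    a synthetic session generator matching the task's baseline (100-trial)
    and probe (120-trial, randomly reinforced midpoint tone) structure;
    cognitive bias index (CBI) metrics with baseline normalisation and
    quality-control filtering; and the associated inferential battery
    (one-sample t-tests, repeated-measures and mixed ANOVA with
    Huynh-Feldt correction, Levene-gated post-hoc t-tests with Bonferroni
    adjustment). Designed so drug-like manipulations of decision
    parameters (drift rate, starting point) can be injected into synthetic
    cohorts, recovered by fitting, and analysed end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    yaml,
    jsonlite,
    car,
    withr,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
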