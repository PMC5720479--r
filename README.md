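# jbtddm

Drift-diffusion modelling of the rodent judgement bias task.

In the judgement bias (ambiguous-cue interpretation) task, a rat learns that
one tone predicts a high-value reward on one lever and another tone a
low-value reward on the other. Probe sessions insert an ambiguous midpoint
tone whose outcome is randomly reinforced; which lever the animal chooses
indexes its affective bias. The field summarises choice with the cognitive
bias index,

    CBI = (high-lever responses − low-lever responses) / lever responses ∈ [−1, 1],

over midpoint trials, and models choices + response times jointly with the
Wiener drift-diffusion model: evidence accumulates from a relative starting
point `zr·a` with drift `v` between boundaries `0` and `a`, plus non-decision
time `t0` (parameters `d`, `szr`, `sv`, `st0` capture execution differences
and inter-trial variability). The modelling matters because two different
mechanisms produce the same behavioural bias: a change in midpoint evidence
evaluation (drift rate) — the signature of rapid-acting treatments like
ketamine — versus a pre-stimulus response predisposition (starting point) —
the signature of delayed-acting antidepressants.

`jbtddm` is for researchers who want that whole analysis chain as tested,
seedable code without animal data: exact Wiener first-passage densities,
CDFs and trial simulation; a synthetic session/cohort generator matching the
task's structure (100-trial baseline, 120-trial probe with 40 randomly
reinforced midpoint tones, 20 s response window, omissions and prematures);
per-session parameter estimation (maximum likelihood by default, fast-dm
style Kolmogorov-Smirnov as an option); CBI and behavioural percentages with
quality-control filtering (>60% reference accuracy); and the inferential
battery (one-sample t, repeated-measures and mixed ANOVA with Huynh-Feldt
correction, Levene-gated post-hoc t-tests with Bonferroni adjustment).

## Worked example: injecting and recovering a ketamine-like effect

Simulate a 13-subject cohort whose drug sessions carry a +0.6 shift in
midpoint drift rate (`v_shift`), then ask the pipeline which decision
parameter changed:

```r
library(jbtddm)

coh <- simulate_cohort(n_subjects = 13, preset = "v_shift", seed = 7)
cbi(coh)
#> # A tibble: 26 × 5
#>   subject_id session_id    condition     cbi n_responded
#> 1 r01        probe_drug    drug       0.167           36
#> 2 r01        probe_vehicle vehicle   -0.6             35
#> 3 r02        probe_drug    drug       0.487           39
#> 4 r02        probe_vehicle vehicle    0.0270          37
#> # ...

d_cbi <- change_from_baseline(cbi(coh))
one_sample_t(d_cbi$delta, label = "delta_cbi")
#>   effect    statistic    df     p_value
#> 1 delta_cbi      10.5    12 0.000000215

fits <- fit_cohort(coh, n_restarts = 2, seed = 7)
one_sample_t(cohort_param_changes(fits, "v")$delta,  label = "delta_v_mid")
#>   effect      statistic    df    p_value
#> 1 delta_v_mid      8.13    12 0.00000320
one_sample_t(cohort_param_changes(fits, "zr")$delta, label = "delta_zr")
#>   effect   statistic    df p_value
#> 1 delta_zr     0.303    12   0.767
```

Reading the output: the drug sessions show a strongly positive change in CBI
(t(12) = 10.5), the diffusion fits attribute it to the drift rate
(t(12) = 8.13) and not to the starting point (p = 0.77) — the injected
mechanism, recovered. A `zr_shift` cohort produces the mirror image.
`run_experiment(run_config(...))` packages this chain (simulate → QC → fit →
metrics → stats) into reproducible CSV artifacts with a manifest.

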