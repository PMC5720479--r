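---
title: "Modelling judgement bias with the drift-diffusion model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling judgement bias with the drift-diffusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jbtddm)
library(dplyr)
```

## The task and the model

In the rodent judgement bias task an animal learns that one auditory tone
(e.g. 2 kHz) predicts a large food reward on one lever and another tone
(8 kHz) a small reward on the other lever. Baseline sessions present 100
reference tones (50 high-reward, 50 low-reward, pseudorandomly ordered);
probe sessions present 120 tones, adding 40 ambiguous midpoint tones
(4999/5001 Hz, 20 of each) whose outcome is randomly assigned to the high or
low contingency so that nothing specific can be learned about them. The
animal's lever choice on the midpoint tone indexes its affective bias, and
the **cognitive bias index** (CBI) summarises it:

$$\mathrm{CBI} = \frac{n_\text{high lever} - n_\text{low lever}}
                      {n_\text{high lever} + n_\text{low lever}}
  \in [-1, 1],$$

computed over midpoint-tone lever responses. The package treats omissions
(no press within the 20 s tone) and premature responses as uninformative
about choice, so they are excluded from the CBI denominator; the alternative
(counting omissions) cannot be settled from task descriptions alone, and the
choice is kept explicit here.

Choices and response times together are modelled with the Wiener
drift-diffusion model (DDM): evidence accumulates from a relative starting
point $z_r \in (0,1)$ (a fraction of the boundary separation $a$) with drift
$v$ until it reaches boundary $a$ (mapped to the high-reward lever
throughout) or 0 (low-reward lever). The observed response time adds a
non-decision time $t_0$, with $d$ the difference in response-execution time
between the two levers (upper $t_0 + d/2$, lower $t_0 - d/2$). Inter-trial
variability is available for the starting point (uniform range `szr`), drift
(normal sd `sv`) and non-decision time (uniform range `st0`). The diffusion
coefficient is fixed at 1 (the fast-dm scaling); parameter values are only
comparable under a single scale convention.

The model separates two routes to the same behavioural bias: a change in how
midpoint evidence is evaluated (drift rate $v_\text{mid}$) versus a
pre-stimulus response predisposition (starting point $z_r$). Acute
rapid-acting treatments (ketamine, amphetamine) present as drift-rate
changes, whereas delayed-acting antidepressants present as starting-point
changes; the package exists to make that dissociation testable end to end on
synthetic data.

## Numerics

The first-passage-time density is evaluated by switching between the
small-time and large-time series expansions of the Wiener density with an
analytically chosen truncation (tolerance `1e-7` per evaluation); both
expansions are exposed through `ddm_density(..., method =)` and are checked
against each other to `1e-6` in the tests. The distribution function uses
the large-time tail series with adaptive truncation; its small-$t$
cancellation stays orders of magnitude below the evaluation tolerance and
the value is clamped to $[0, P(\text{boundary})]$. Normal drift variability
integrates in closed form for the density; uniform starting-point and
non-decision-time variability use 10-node Gauss-Legendre quadrature, and the
distribution function under drift variability uses 10-node Gauss-Hermite.

`ddm_sample()` draws trials exactly: trial-level variability is realised
first, the boundary is drawn from the analytic absorption probability, and
the decision time inverts the conditional first-passage CDF by bisection
(60 halvings, i.e. to machine-level time resolution). An Euler-Maruyama
simulator is deliberately *not* used for production sampling: naive EM at
`dt = 1e-4` carries a measurable discrete-monitoring bias (about +0.002 in
an absorption probability of 0.82), which is why the test-suite oracle uses
a Brownian-bridge crossing correction.

## Fitting

`fit_ddm()` estimates parameters per probe session. The default sharing
follows what the stimulus can causally influence: drift rate varies by tone;
boundary separation, starting point and non-decision time are session-level
(boundaries and start point are set before the tone is heard, so a per-tone
$a$ or $z_r$ is mechanistically incoherent in a randomly interleaved
session); $d$ and the variability parameters default to 0 because 120-trial
sessions cannot constrain them. All of this is configurable through the
`spec` argument.

Two objectives are provided. The default is joint **maximum likelihood**
over tones. The **Kolmogorov-Smirnov** criterion of fast-dm (lower-boundary
RTs negated onto one signed axis; sup-distance between empirical and model
combined distributions) is available via `objective = "ks"` and as the
exported `ks_objective()`. Two practical findings from the package's own
simulation studies drove the defaults:

* As a *search* criterion, the maximum of per-tone KS distances is
  defective: only the currently worst tone informs the optimiser, leaving
  flat ridges that pin the shared starting point at its initial value. The
  KS fit therefore minimises the *sum* of per-tone distances and reports the
  maximum at the optimum as the goodness-of-fit statistic.
* Even so, the KS criterion is too inefficient at 40 trials per tone to
  recover starting-point changes reliably (per-session noise in $\hat z_r$
  of about 0.07-0.1). Maximum likelihood at the same trial counts recovers
  injected starting-point shifts essentially without attenuation and with
  roughly half the noise, which is what makes the drift/start dissociation
  detectable at realistic cohort sizes. This matches the general guidance
  for fast-dm-style estimation that likelihood-based criteria are preferred
  at small trial counts.

Optimisation is Nelder-Mead from 5 seeded restarts (each followed by a
restarted polish pass), initial values taken from the data (logistic
inversion of choice fractions for drifts; 85% of the fastest RT for $t_0$),
with restarts spreading the starting-point initialisation — the weakest
identified parameter. Domain violations return a finite penalty so the
simplex can recover. A fitted condition requires at least 20 responded
trials (`min_trials`); omissions and prematures are removed before fitting
and their counts reported in the fit object.

## The synthetic-data generator

`simulate_cohort()` emulates the study conditions: paired vehicle/drug probe
sessions per subject (120 trials, 40/40/40; baseline sessions 100 trials,
50/50; no same-tone run longer than 4), midpoint outcomes reinforced 50/50,
omissions as an explicit per-tone probability (default 0.05) plus natural
censoring at the 20 s window, prematures as a flat per-trial probability
(default 0.03). Per-subject baseline parameters are drawn once per subject
from ranges chosen to mimic a well-trained, mildly negatively biased rat:
$a \sim U(1.4, 2.2)$, $z_r \sim U(0.42, 0.58)$, $t_0 \sim U(0.6, 1.0)$ s,
$v_\text{high} \sim U(0.9, 1.6)$, $v_\text{low} \sim -U(0.9, 1.6)$,
$v_\text{mid} \sim -U(0.4, 1.2)$. These give reference-tone accuracies
around 85-95% (comfortably above the 60% inclusion threshold), midpoint
CBIs around $-0.2$ to $-0.6$, and median lever latencies of 1.5-3 s within
the 20 s window.

Presets inject the treatment effect: `v_shift` adds $\delta$ (default 0.6)
to the midpoint drift; `zr_shift` adds $\delta$ (default 0.05) to the
session-wide starting point; `vehicle` injects nothing and generates an
identically parameterised second session, so its change-from-baseline
scores are genuine nulls. The defaults were chosen once as plausible
pharmacological effect sizes on those scales.

What the generator does **not** emulate: training-stage shaping,
session-to-session drift in motivation, tone-lever counterbalancing,
slow-RT lapses or any non-diffusion contamination process, and
reward-magnitude asymmetries beyond what the per-tone drifts encode. Tests
passing on this generator therefore certify the pipeline's statistical
machinery — recovery, dissociation, calibration — under the model's own
assumptions, not the behaviour of real rats.

## Statistics

Change-from-baseline scores are defined as drug minus baseline, so a
positive delta is a more positive bias. (Task descriptions sometimes print
the subtraction the other way around while describing positive effects as
positive changes; the package fixes the convention and documents it rather
than guessing a plotting transform.) Weekly aggregation for chronic designs
averages the two probe sessions of each week (`average_by_week()`).

The inferential battery mirrors standard usage: `one_sample_t()` against
zero for per-dose changes; `rm_anova()` for session x tone within-subject
designs; `mixed_anova()` adding a between-subjects group factor;
`posthoc()` paired or independent t-tests with Levene's test routing the
independent form (Welch when Levene's p < 0.05) and Bonferroni adjustment.
ANOVA computation delegates to `car::Anova()` (type III, sum-to-zero
contrasts); the Huynh-Feldt epsilon is clipped at 1 and applied when
Mauchly's test has p < 0.05 — whether the original SPSS analyses gated the
correction or applied it unconditionally is not stated anywhere, so the
gate is explicit and both raw and corrected p-values are always reported.
Incomplete repeated-measures tables are refused outright rather than
silently reduced.

## Problem sizes and reproducibility

The packaged simulation studies use: 100 sessions of 120 trials for
parameter recovery (median absolute errors: $z_r$ 0.02, $a$ 3.5%,
$v_\text{mid}$ 19% in the shipped run); 100 replicate cohorts of n = 13 per
preset for the dissociation property (cohort-scale fits use 2 restarts,
which prototype runs showed to give the same detection behaviour as 5 at
less than half the cost); and 500 replicates for each null-calibration
check. Every stage takes an explicit integer seed, and `run_experiment()`
expands one master seed into fixed per-stage streams so that a rerun with
the same config reproduces every CSV byte for byte.

## Known limitations

* The fitted model excludes collapsing bounds, leakage/race dynamics and
  hierarchical shrinkage across subjects; estimates at 120 trials are
  deliberately simple per-session fits.
* `ks_statistic` from an ML fit is a goodness-of-fit summary, not the
  quantity that was minimised.
* Inter-trial variability parameters can be freed in `spec`, but at
  task-scale trial counts they are practically unidentifiable; the
  machinery integrates them correctly (verified by quadrature oracles), yet
  standard errors will be enormous.
* CBI assumes the midpoint lever responses exhaust the informative
  behaviour; sessions with zero midpoint lever responses have no defined
  bias and raise typed errors rather than returning 0.
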