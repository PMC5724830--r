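---
title: "Stop-signal race-model metrics and insulin-resistance mediation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stop-signal race-model metrics and insulin-resistance mediation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sstmediate)
```

# The scientific problem

Impulsivity in the stop-signal task (SST) is summarized by three quantities.
The **median go response time** (mGRT) measures how quickly a prepared motor
response is executed.  The **critical stop-signal delay** (cSSD) is the delay
between the go cue and stop cue at which half of the go responses can still
be countermanded: a longer cSSD means a wider window for stopping, i.e.
better overall impulse control.  The **stop-signal response time**

$$\mathrm{SSRT} = \mathrm{mGRT} - \mathrm{cSSD}$$

is the latency of the covert stopping process itself.  Overall performance
(cSSD) can therefore degrade for two distinct reasons: the go process speeds
up (shorter mGRT) or the stop process slows down (longer SSRT).

In obese adults with type 2 diabetes, insulin resistance — indexed
peripherally by HOMA-IR — is hypothesized to accelerate go responses through
its effect on striatal circuits, with regional activation contrasts (e.g. the
stop-error-minus-stop-success contrast in right putamen) mediating the
HOMA-IR → mGRT association.  This package implements that full inference
chain on tabular inputs: race-model scoring of trial logs, HOMA-IR,
covariate-adjusted regression screens, and bootstrapped single-mediator
analysis with the $\kappa^2$ effect size, together with a synthetic cohort
generator embodying the assumed causal structure so every stage is testable
without access to human data.

# The independent horse-race model

Each trial races two independent processes.  The go process finishing time is
**ex-Gaussian**, the standard response-time model: a Gaussian stage
$N(\mu_{go}, \sigma_{go})$ plus an exponential tail of mean $\tau_{go}$.  The
stop latency is Gaussian $N(\mu_{stop}, \sigma_{stop})$ truncated at zero.
On a stop trial with delay $s$, a response escapes iff
$\mathrm{goRT} < s + \mathrm{stopRT}$.  Neither distributional family is
dictated by the task itself; the ex-Gaussian was chosen because it fits
empirical RT distributions well and makes the race integral tractable: since
$\mathrm{goRT} - \mathrm{stopRT}$ is again ex-Gaussian with mean
$\mu_{go}-\mu_{stop}$ and Gaussian SD
$\sqrt{\sigma_{go}^2+\sigma_{stop}^2}$,

$$P(\text{respond} \mid s) \;=\; (1-p_{om})\,
F_{exG}\!\left(s;\ \mu_{go}-\mu_{stop},\ \sqrt{\sigma_{go}^2+\sigma_{stop}^2},\ \tau_{go}\right),$$

which `cssd_true()` inverts at one half to obtain the generating cSSD.  Two
approximations are knowingly made there: the truncation of the stop process
at zero is ignored (for the defaults, $\mu_{stop}/\sigma_{stop} \approx 10$,
so the truncated mass is ~$10^{-21}$) and so is the response window
(`max_rt`; under 0.3% of go mass lies beyond it for every parameter set used
here).  The test suite checks the closed form against direct numerical
integration of the race integral.

Go trials additionally admit **omissions** (probability `p_go_omission`; the
go process never finishes) and **premature responses** (probability
`p_premature`; a press during the fore-period, stored with a negative RT and
scored as a go error).  Premature presses are modelled on go trials only: on
a stop trial a press before the stop cue is simply a stop error under the
race rule, so a separate mechanism would be redundant.  Omissions apply on
stop trials too, where they surface as (trivially) successful stops.

## Task structure and the SSD schedule

A session is `n_runs = 3` runs of 75 go + 25 stop trials in pseudo-random
order, a 1–5 s fore-period, a 1 s response window and a fixed 2 s
inter-trial interval.  The stop-signal delay follows a **one-up/one-down
staircase** (default: start 200 ms, step 50 ms, clamp [0, 900] ms): up after
a successful stop, down after a failed one.  For a continuous go-RT
distribution this tracking rule converges on the 50%-inhibition delay — the
cSSD itself — which is why it is the default.  Because the schedule is not
uniquely determined by the task description, a fixed pseudo-random SSD list
is also supported (`ssd_schedule`, cycled over stop trials with no
tracking); everything downstream is agnostic to which mode produced the log.

## Race-model defaults

The cohort-level defaults (`race_params()`: $\mu_{go}=535$, $\sigma_{go}=60$,
$\tau_{go}=100$, $\mu_{stop}=290$, $\sigma_{stop}=30$ ms) were set once so
that a default synthetic cohort lands near the group means reported for
obese T2DM adults on this task — mGRT ≈ 605 ms, cSSD ≈ 310 ms, SSRT ≈ 295 ms
— and are configuration, not constants.

# Scoring: mGRT, the inhibition function, cSSD, SSRT

`compute_go_metrics()` takes the median RT over **successful** go trials
only (even-sized sets use the mean of the two central order statistics) and
counts premature / late / absent go errors.  `inhibition_function()` groups
stop trials by SSD — exactly, or into fixed-width bins for staircase data —
and computes the stop-success proportion per group, merging groups below a
minimum count into their nearest neighbour.

`estimate_cssd()` exposes three estimators because the underlying
computation is not uniquely determined by the definition:

* **interpolate** (default).  The empirical inhibition function need not be
  monotone in finite samples, while the race model implies it is, so the
  curve is first regularized to be non-increasing by trial-count-weighted
  pool-adjacent-violators (written in-package: the regularization must be
  weighted and non-increasing).  The 50% point is then linearly interpolated
  between the adjacent delays bracketing it.  If the regularized curve is
  flat at exactly 0.5, the shortest such delay is returned (the first
  crossing from short delays); if it never crosses 0.5 the participant gets
  `NA` with a warning and drops out of cSSD-dependent analyses.
* **logistic**.  A two-parameter logistic fit to the per-bin success counts
  by weighted maximum likelihood (`stats::glm`, binomial); the cSSD is its
  50% point $-\beta_0/\beta_1$.  Useful when bins are sparse.
* **staircase_mean**.  The mean SSD after discarding the first 10 stop
  trials (configurable burn-in).  Valid only for tracking schedules, which
  hover around the 50% point.

On long sessions the first two agree to well under 25 ms and land within a
few ms of the generating delay; the suite asserts both.

`compute_ssrt()` is the exact difference mGRT − cSSD, so the identity
`ssrt + cssd = mgrt` holds bit-exactly for every scored participant.  A
negative SSRT is arithmetically legitimate but diagnostically alarming, so
it is **returned with a warning rather than clamped** — silently flooring it
would hide estimation failure.

## Inclusion filters

Participants are included iff stop success lies in 25–75% of stop trials
(read as a closed interval), the go response rate exceeds 60% (strict
inequality, as written), and the race-model consistency check holds (mean
stop-error RT below mGRT; with no stop-error trials the check cannot be
falsified and passes with a warning).  `apply_inclusion_filters()` reports
every failed criterion by name.  The inclusion flag reflects only these
rules; a participant whose inhibition function never crosses 0.5 is excluded
from cSSD-dependent models by listwise deletion instead.

# HOMA-IR

`homa_ir()` implements the Matthews mass-unit formulation,
glucose [mg/dl] × insulin [µU/ml] / 405, equivalently
glucose [mmol/l] × insulin / 22.5 (`glucose_units = "mmol/l"`); the constant
is calibrated so a normal fasting pair (90 mg/dl, 4.5 µU/ml) scores 1.0.
The score is linear in each argument, which the suite asserts.  The HOMA2
computer model and OGTT-derived indices are out of scope.

# Regression screens

`fit_regression()` is ordinary least squares with intercept, listwise
deletion, per-term $t$ and two-sided $p$ on residual degrees of freedom.
Two reporting choices deserve a note:

* the per-predictor correlation is the **partial correlation** obtained by
  the conventional transform $r = t/\sqrt{t^2 + df}$
  (`partial_r_from_t()`), which is how a per-predictor $r$ from a
  multi-predictor model is conventionally reported;
* because a printed $R^2$ can mean the full model or the focal predictor's
  increment, both are emitted: `r_squared` for the model and `delta_r2` per
  term (the drop in $R^2$ when that column is removed).

Predictors are not standardized, sex is coded 0/1, interactions are off by
default, and no multiple-testing correction is applied by default
(`adjust_bh = TRUE` appends Benjamini–Hochberg q-values over the predictor
terms for reuse).  Rank-deficient designs raise an error naming the aliased
columns rather than silently dropping them.

# Mediation

`estimate_paths()` fits the three OLS sub-models of the single-mediator
chain — $M \sim X + Z$, $Y \sim X + M + Z$, $Y \sim X + Z$ — on one common
complete-case set with the covariates $Z$ entering every sub-model
identically.  That symmetric placement is what makes the decomposition
$c = c' + ab$ an algebraic identity (asserted to $10^{-10}$ on every dataset
in the suite) rather than an approximation.  Whether the covariates belong
inside all three sub-models is genuinely open in this design; symmetric
inclusion was chosen precisely because it preserves the identity.

`bootstrap_indirect()` resamples participants with replacement and
re-estimates the paths per resample.  The **percentile** interval is the
default — matching the PROCESS-era convention — with BCa available by flag
(`ci_type = "bca"`; bias correction from the draw distribution, acceleration
from the jackknife).  The default `n_boot` is 5000 and everything is
seedable.  Resamples with a rank-deficient sub-model (e.g. a binary
covariate going constant) are redrawn and counted; more than 10% redraws
aborts, because at that point resampling inference is not meaningful.
Simulation places the null exclusion rate of the percentile interval near
its nominal 5% at $n = 200$ (the suite checks 5% ± 2%); percentile
intervals for products are known to run slightly liberal at moderate $n$,
which is worth remembering when reading borderline results.

Deterministic chains ($M$ an exact linear function of $X$) leave $b$
unidentified; the test suite admits them only via a documented jitter.  The
jitter scale is $10^{-6}$: QR decompositions flag columns as collinear at a
relative tolerance near $10^{-7}$, so anything much smaller is
indistinguishable from exact collinearity.

## The $\kappa^2$ effect size

$\kappa^2$ expresses the observed indirect effect as a fraction of the
largest indirect effect the data could have carried:

$$\kappa^2 = \frac{|ab|}{|a_{\max}\,b_{\max}|},$$

where the maxima are taken over path coefficients consistent with the sample
variances of $X$, $M$, $Y$ and the observed $X$–$Y$ correlation, subject to
the implied $3\times3$ correlation matrix staying positive semidefinite
(the Preacher–Kelley construction).  One subtlety dictated the
implementation: maximizing $|ab|$ **jointly** over $(r_{XM}, r_{MY})$ on the
PSD region is unbounded — as $|r_{XM}| \to 1$ the admissible
$|b| \sim \sqrt{(1-r_{XY}^2)/(1-r_{XM}^2)}$ diverges faster than $|a|$ is
capped — so the maximum is taken **coordinate-wise**: $a_{\max}$ is the
sign-consistent PSD boundary of $r_{XM}$ holding the observed $r_{MY}$ and
$r_{XY}$ fixed, and $b_{\max}$ the boundary of $r_{MY}$ holding $r_{XM}$ and
$r_{XY}$ fixed.  This keeps the denominator finite and $\kappa^2 \in [0,1]$,
and is what the closed forms in `kappa2_point` implement.  The test suite
verifies them against a brute-force grid search of the same boundaries.
With covariates, $X$, $M$, $Y$ are residualized on them first.  A zero
indirect effect yields $\kappa^2 = 0$ outright; zero variance in any
variable, or a mediator collinear with the predictor, is an explicit error.
$\kappa^2$ is also known not to be monotone in the underlying paths in all
regimes; it is reported here as the conventional companion to the CI, not as
a standalone criterion.

The **evidence rule** declares mediation when the bootstrap CI for the
indirect effect excludes zero *and* the $\kappa^2$ point estimate reaches
0.1.

# The synthetic cohort generator

`simulate_cohort()` draws, per participant: HOMA-IR log-normal
(median ≈ 6.7, log-SD 0.52 — reproducing quartiles near 5 and 10), BMI
$N(37, 4.5^2)$ kg/m², age $N(47, 7^2)$ truncated to 31–60 y, sex Bernoulli
(p(male) = 0.4), metformin dose uniform on {0, 500, …, 2500} mg, fasting
glucose $N(133, 41^2)$ mg/dl floored at 70 — marginals typical of an obese
T2DM imaging cohort — and back-computes fasting insulin so that
glucose × insulin / 405 reproduces the drawn HOMA-IR exactly (a round-trip
the suite checks).  The causal chain is

$$M = a\,X + \varepsilon_M, \qquad
\mathbb{E}[\mathrm{mGRT}] = \beta_0 + b\,M + c'\,X + \varepsilon_Y,$$

with defaults $a = 0.5$ activation units per HOMA-IR unit, $b = -40$ ms per
activation unit, $c' = 0$, $\sigma_M = 1$, $\sigma_Y = 20$ ms and
$\beta_0 = 760$ ms (the intercept that puts the default cohort's mean mGRT
near 605 ms).  In full-session mode the participant's $\mu_{go}$ is shifted
by the targeted mGRT change — exact, because $\mu_{go}$ is a location
parameter of the go distribution — and the whole trial log is simulated;
`sessions = "none"` skips the logs and writes the latent expected mGRT
directly, which is what large simulation studies of the downstream
statistics use.

Reproducibility: each participant consumes one RNG stream seeded from
(cohort seed, participant index), so cohorts are bit-identical given the
seed and stable participant-wise under reordering.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: no BOLD signal or hemodynamics (the ROI
"activation" is a scalar); no RT autocorrelation, fatigue or practice
effects within a session; go and stop parameters constant across runs;
covariates mutually independent apart from the modelled paths (real BMI,
age and metformin are not); and the mediator truly is a single scalar cause,
whereas regional activations are many and correlated.  Recovery of the
planted paths here validates the estimators, not the causal claim on any
real cohort.

# The pipeline

`run_pipeline()` executes simulate → score → homa → regress → mediate under
one seed, writing every intermediate table and a JSON report (row counts per
stage, exclusions with reasons, all regression and mediation results, a
config hash and the package version).  Reports from identical configurations
are identical except for the timestamp.  Behavioural screens use all
included participants; if the cohort carries a logical `fmri_included`
column, ROI-level regressions and the mediation stage are restricted to that
subgroup — a documented stand-in for head-motion exclusion, which cannot be
computed without images.  A thin command-line wrapper
(`inst/scripts/sstpipe.R`) exposes the stages as subcommands.

# Problem sizes and numerical choices in the test suite

The suite's simulation sizes were fixed as the package's own trade-off
between statistical resolution and a test run measured in minutes: staircase
convergence and cSSD accuracy use one $10^4$-stop-trial session (estimator
error there is ~1–3 ms against a 15 ms assertion); null calibration of the
bootstrap uses 1000 replicates × 1000 resamples at $n = 200$; the
evidence-rule power check uses 100 cohorts at $n = 500$; parameter recovery
uses $n = 500$ with small noise.  Oracles are independent routes: numerical
integration for the race integral, normal-equations solves for OLS, a grid
search for $\kappa^2$, and `boot`-style resampling semantics were
cross-checked during development.

# Known limitations

* SSRT is defined here only as mGRT − cSSD; the integration-method family
  ("nth-percentile RT minus mean SSD") is deliberately out of scope.
* The percentile bootstrap for products is mildly liberal at moderate $n$;
  BCa is available but not a cure-all for that.
* $\kappa^2$ inherits the non-monotonicity criticisms in the effect-size
  literature.
* The generator's covariates are independent by construction; screens run
  on synthetic cohorts will not exhibit realistic collinearity between,
  say, BMI and insulin resistance unless configured to.
* The fMRI subgroup filter is a boolean column, not a motion computation.
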