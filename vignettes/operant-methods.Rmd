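---
title: "Dissociating perseveration from apathy in touchscreen operant data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissociating perseveration from apathy in touchscreen operant data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(operant)
library(dplyr)
```

## The problem this package addresses

A high progressive-ratio (PR) breakpoint is the canonical signature of
high motivation: the animal keeps paying a growing response price for
reward. But a *perseverative* animal — one that keeps responding because
it is insensitive to the declining payoff — produces the same high
breakpoint while actually being *less* motivated. Breakpoint alone cannot
tell these apart. Two refinements can:

1. **Within-session response-rate analysis.** Converting each trial's
   total response time (TRT) to a rate and fitting an exponential decay
   across trials yields a peak rate $a$ (activational motivation at the
   start of the session) and a decay rate $b$ (how fast motivation
   wanes). An apathetic-but-perseverative animal shows *low* $a$ with
   *slow* $b$: it starts slowly but keeps grinding.
2. **Task battery cross-checks.** Early-session omissions in extinction
   index failure to *initiate* responding (activational apathy), and
   errors before re-reaching criterion after a visual-discrimination
   reversal index stimulus-bound perseveration.

The package implements this analysis pipeline for tidy trial-level
touchscreen logs, together with a generative agent simulator that
produces cohorts with exactly the statistical structure the analysis
assumes — so the whole chain is testable end to end without animal data.

## The rate-decay model

For each completed trial $x$ (1-based index) of a PR session,
$y = \mathrm{requirement} / (\mathrm{TRT}/60)$ gives the response rate in
responses/min, and the model

$$y = a \, e^{-b x}$$

is fitted by bounded nonlinear least squares (Levenberg–Marquardt via
**minpack.lm**), initialised from the log-linear regression of
$\ln y$ on $x$ and constrained to $a > 0$, $b \ge 0$. A flat series
therefore returns the boundary solution $b = 0$. Data that lie exactly
on a decay curve (including the flat case) are returned directly from
the closed-form log-linear solution, which is the least-squares optimum
there.

Some reports print the model in the base-$a$ form $y = a^{-bx}$. That
form fixes $y(0) = 1$ — so no peak-rate parameter exists — and the curve
depends on $a$ and $b$ only through the product $b \ln a$: the two
parameters are not separately identifiable. `fit_options(form =
"power_base")` therefore estimates that single decay constant and
reports it in the unit-base convention $a = e$. The exponential form,
in which $a$ is literally the curve's maximum, is the default and the
one every downstream summary uses.

Fits on fewer than `min_points = 5` completed trials are refused and
flagged `reliable = FALSE` rather than attempted: very sparse sessions
(e.g. steep schedules that collapse after a handful of trials) cannot
identify a two-parameter curve, and silent garbage estimates are worse
than recorded exclusions. Refusals carry a reason string and are
excluded from group comparisons by default, never dropped silently.

TRT is defined as stimulus onset to requirement completion, so it
includes the pre-first-touch latency and excludes reward collection and
the inter-trial interval. Vendor logs differ here, so
`fit_options(include_first_latency = FALSE)` subtracts the recorded
response latency before rate conversion.

## Task structural rules

* **PR requirement**: trial $k$ demands $\mathrm{start} + n(k-1)$
  target touches (PR4: 1, 5, 9, 13, ...). Sessions end after 5 min
  without a screen touch or magazine entry, or at the session cap
  (default 3600 s; the inactivity rule, not the cap, is the intended
  terminator).
* **Breakpoint**: requirement of the last completed trial; 0 if no
  trial was completed (the degenerate value preserves ordering).
* **Extinction**: 30 trials per session, 10-s stimulus, 4.5-s ITI, no
  reward; the series ends when omissions reach at least 77% on two
  consecutive sessions. Sessions partition into early/middle/late
  phases of 10 trials each.
* **Discrimination / reversal**: acquisition criterion is at least 80%
  accuracy on two consecutive sessions (correction trials follow each
  error and are excluded from accuracy denominators); animals not
  reaching criterion within 20 sessions are flagged excluded. After
  reversal there are no correction trials and the criterion is 50% on
  two consecutive sessions.
* **Criterion indexing**: `detect_criterion()` returns the *closing*
  session of the first qualifying run, so sessions-to-criterion equals
  the returned index. Thresholds are inclusive. Perseverative errors
  are summed over sessions strictly before the *first* session of the
  qualifying pair — the epoch in which responding is still dominated
  by the old contingency.

## The group-comparison gate

Endpoint measures are compared between two groups with the field's
conventional gate: each group is screened with the D'Agostino–Pearson
omnibus $K^2$ test (implemented in-package from the skewness and
kurtosis transformations and validated against an independent reference
implementation); if both groups are consistent with normality at
$\alpha = 0.05$ the comparison is Welch's $t$, otherwise the
Mann–Whitney $U$. The omnibus moment approximations need $n \ge 8$, so
smaller groups are screened with Shapiro–Wilk instead. No
multiple-testing correction is applied across measures — batch reports
carry an explicit note. Repeated-measures modelling is deliberately out
of scope; the trial-level tables are ready for **lme4** if a user wants
mixed models.

## The cohort simulator

Each synthetic animal is a stochastic agent with parameters
(`agent_params()`):

| parameter | meaning | WT | MUT |
|---|---|---|---|
| `peak_rate_A` | peak response rate (resp/min) | 100 | 70 |
| `decay_B` | per-trial rate decay | 0.25 | 0.15 |
| `persev_rho` | perseveration | 0.15 | 0.45 |
| `init_deficit_eps` | initiation deficit | 0.15 | 0.6 |
| `learn_alpha` | learning rate | 0.35 | 0.18 |
| `noise_sigma` | lognormal rate noise | 0.15 | 0.15 |
| `intake_mu_ml` | 60-min free intake (ml) | 1.2 | 0.9 |

The preset values are illustrative calibrations chosen once to produce
realistic session structure (breakpoints of a few dozen, one to two
dozen completed PR4 trials, extinction in roughly 7–16 sessions,
reversal in 4–8); they are not estimates from any real cohort, and the
mutant-like preset differs from wild-type only in the documented
directions: lower peak rate, slower decay, stronger perseveration and
initiation deficit, slower learning, lower intake.

**Ratio schedules.** The latent rate on trial $k$ is
$A e^{-B_{\mathrm{eff}} k}\,\eta_k$ with lognormal noise $\eta_k$ and

$$B_{\mathrm{eff}} = B \bigl(1 - \rho\,(1 - d)\bigr),$$

where $d$ is the running reinforcement density (rewards per target
touch so far). A single perseveration parameter $\rho$ thus damps the
decay exactly when reinforcement is sparse — which is what lets a
perseverative agent post comparable breakpoints on dense schedules but
*higher* ones on lean schedules, where the density penalty bites.
Within a trial, inter-response intervals are exponential with mean
$60/r$ seconds plus an irreducible motor floor (a shifted exponential
with unchanged mean): without the floor, a single near-zero draw on a
requirement-1 trial produces physically impossible instantaneous rates
and unstable per-animal fits. The initiation deficit multiplies the
first interval of trial $k$ by $1 + \varepsilon e^{-(k-1)/3}$ — the
deficit is localised to roughly the first three trials of a session,
with a fixed time constant because only the localisation, not its
scale, is empirically constrained. Fixed-ratio sessions decay with
rewards earned (satiation) instead of trial number; reinstatement
sessions reward only the first three completions.

**Extinction.** Response probability on trial $k$ of session $s$ is
$(1-\mathrm{base}) \cdot \mathrm{logistic}(\theta_s) \cdot (1 -
\varepsilon e^{-k/3})$, with the drive $\theta$ (initially 2.5)
declining by $0.1\,\alpha$ per emitted, unrewarded response. The same
$\varepsilon$ that slows trial initiation in PR inflates early-session
omissions here.

**Choice tasks.** A two-armed value learner: stimulus values update as
$Q \mathrel{+}= \alpha_c (r - Q)$ with $\alpha_c = 0.15\,\alpha$ on
reward and $0.3 \alpha_c$ on non-reward, and
$P(\text{choose } 1) = \lambda/2 + (1-\lambda)\,
\mathrm{logistic}\bigl(5\,[(Q_1 - Q_2) + \rho\,\mathrm{pref}]\bigr)$
with an exponentially weighted choice trace `pref` (rate 0.2) and lapse
$\lambda = 0.08$. The slow unlearning and the $\rho$-weighted choice
trace are jointly what make a previously reinforced choice persist for
several sessions after the contingency flips; with $\rho = 0$ and a
high learning rate, reversal completes within two sessions. Correction
trials are generated (and flagged) in acquisition only.

**Determinism.** Every simulation function takes a seed and restores
the caller's RNG state. Cohorts derive per-animal and per-task child
seeds from the master seed through a counter-based 31-bit mix, so
streams are reproducible and independent of evaluation order. Setting
`noise_sigma = 0` collapses every magnitude draw (intervals, latencies,
blank touches, beam breaks) to its mean, giving a fully deterministic
session whose rate series is exactly $a e^{-bx}$ — the mode used by the
exact-recovery tests. Choice sampling stays stochastic in that mode: it
is the agent's behaviour, not measurement noise.

**What the generator does *not* emulate.** Real data have
between-animal parameter heterogeneity beyond the preset contrast,
within-animal day-to-day drift, sequential dependencies between tasks
run months apart, and vendor-specific event-log quirks. Passing tests
therefore certify that the *analysis* recovers what the *model*
generates under realistic noise — not that the model captures every
property of mouse behaviour.

## Numerical and design choices

* Trial and session indices are 1-based; absent values are empty CSV
  cells, never 0. Genotype is a free label; the lexicographically first
  is the default comparison reference.
* PR4, prefed PR4, PR8 and PR12 share the `"PR"` task label and take
  session indices 1, 2, 3, 4, keeping `(animal, task, session)` unique.
* Prefeeding is modelled as a 45% reduction in peak rate with longer
  collection latencies (the satiety signature), recorded via the
  `prefed` flag; prefed sessions are excluded from decay fits by
  default.
* The initiation-deficit contrast in extinction is cleanest on the
  first session, where both groups share the same starting drive;
  later sessions confound the deficit with group differences in
  extinction speed. The phase denominators default to 10 (phase
  trials), with a session-denominator option.
* Monte-Carlo problem sizes used by the test-suite experiments: the
  parameter-recovery grid runs $\{50,100,150\} \times \{0.1,0.3,0.6\}$
  at 200 replicates of 13 points with $\sigma = 0.15$; its pass metric
  is the relative error of the *median* estimate (a bias measure; the
  per-replicate error spread is reported alongside, and at these noise
  settings is intrinsically around 6% even for an efficient
  estimator). Preset-contrast checks use 100 seeded cohorts of 16
  animals per group; the comparison gate's type-I error is checked on
  2000 null pairs.

## Known limitations

* Per-animal fits from a single session inherit the heavy-tailed
  variance of early-trial rates; group summaries are means over 16
  animals and stay stable, but individual $\hat a$ values can be
  noisy.
* The simulator's choice model uses fixed mechanism constants
  (inverse temperature, trace rate, lapse, unlearning asymmetry);
  they are documented but not exposed as user parameters.
* Mixed-effects replication of repeated-measures statistics is out of
  scope, as are vendor event-stream parsers and any plotting beyond
  matrix/CSV exports.
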