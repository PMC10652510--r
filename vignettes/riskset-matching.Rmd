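---
title: "Time-dependent propensity scores and sequential risk-set matching for resuscitation registries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-dependent propensity scores and sequential risk-set matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskmatch)
```

## The problem

Extracorporeal cardiopulmonary resuscitation (ECPR) is started *during*
ongoing cardiac arrest, typically tens of minutes after hospital arrival.
A naive comparison of ever-treated versus never-treated patients is therefore
distorted by **resuscitation-time bias**, a form of immortal-time and
selection bias: a patient can only receive ECPR by remaining in arrest long
enough for the team to cannulate, and time spent in arrest is itself one of
the strongest prognostic factors. Patients who achieve return of spontaneous
circulation (ROSC) quickly — who tend to have the best outcomes — can never
appear in the treated group.

`riskmatch` implements the trial-emulation design used to address this bias
in observational resuscitation research:

1. a **time-dependent propensity score** for treatment initiation at each
   minute after arrival, fitted as a subdistribution-hazard (Fine–Gray type)
   regression that treats ROSC and termination of resuscitation before ECPR
   as competing risks, with administrative censoring at 120 minutes;
2. **sequential risk-set matching**: each treated patient is matched, at the
   minute treatment started, to a patient still undergoing resuscitation who
   had not received ECPR before or within that minute, with replacement and
   a caliper of 0.2 standard deviations of the score;
3. **conditional logistic regression** on the matched pairs for binary
   30-day outcomes (survival; favourable neurology, CPC 1–2).

Because real ECPR registries are not publicly available, the package ships a
seeded synthetic-cohort generator with known ground truth, and a simulation
bench that contrasts the matched estimator with the naive one.

## The propensity model

Time is an integer minute from hospital arrival; an event "at minute t"
occupies the half-open interval [t, t+1), and the horizon is fixed at 120
minutes. For patient $i$ at minute $t$ the linear predictor is

$$\eta_i(t) = \beta^\top \left[ X_i,\ Z_i(t) \right],$$

where $X_i$ collects the time-independent covariates (sex, age, witnessed
status, bystander CPR, initial rhythm, bystander AED, physician-staffed
unit, paramedic defibrillation, airway type, pre-hospital adrenaline count,
pre-hospital ROSC, call-to-hospital time, and the hospital's ECPR-volume
tertile) and $Z_i(t)$ the three in-hospital indicators (defibrillation,
intubation, adrenaline). $Z_i(t)$ switches on one minute *after* the
intervention occurs, so interventions during minute $t$ cannot predict
treatment at minute $t$, and it never switches off.

The coefficients maximize the Breslow-tied partial likelihood over treatment
minutes,

$$\ell(\beta) = \sum_{t \in \text{event minutes}} \left[ \sum_{i \in D_t} \eta_i(t) - d_t \log \sum_{j \in R_t} w_j(t)\, e^{\eta_j(t)} \right],$$

where $R_t$ is the **subdistribution risk set**: everyone not yet treated by
$t$, *including* patients whose resuscitation already ended in ROSC or
termination. Within the 0–120 minute window the only censoring is
administrative at the fixed horizon, so the Fine–Gray inverse-censoring
weights $w_j(t)$ are identically 1, and competing-event patients are carried
with covariates frozen at their last pre-event value (no interventions occur
after a terminal event, so the frozen value is simply $Z_i$ at the event
minute). Both conventions are package design decisions for a point the
published description of the method leaves open.

Numerics: Newton iterations with step-halving (the likelihood is concave on
non-separable data, so halved steps always restore ascent), convergence at
gradient norm $10^{-8}$, at most 100 iterations. A coefficient passing
$|\beta_k| > 10$ while the likelihood still climbs raises an explicit
*separation* error; a zero-variance column raises a *degenerate covariate*
error naming the column (the initial rhythm must therefore be dropped in the
shockable stratum, where it is constant — `ps_covariates(include_rhythm =
FALSE)`). Categorical covariates are reference-coded against the first level
of the documented dictionary order. With no competing events the likelihood
reduces exactly to a Cox partial likelihood, which the test suite exploits
as an independent oracle via `survival::coxph`.

The matching distance is the linear predictor itself (log-hazard scale), not
a transformed probability, and the caliper scale `score_sd` is its standard
deviation over treated patients evaluated at their own treatment minutes.
Which population's SD defines the caliper is unstated in the design this
package emulates; treated-at-treatment-time is the package's choice, being
the population whose neighbourhoods the caliper prunes.

## Matching

Minutes are processed in increasing order. Within a minute, treated patients
are processed in a seeded random order (a single `sample()` per risk set
with more than one treated patient after one `set.seed(seed)` at entry — the
contract an independent re-implementation must follow to reproduce pairs).
Candidates at minute $t$ are patients with a later disposition minute and no
ECPR before or within $t$; a terminal event during minute $t$ removes
candidacy at $t$, the strictest reading of "before or within the same
minute" applied to all terminal events alike. Each treated patient takes the
candidate minimizing the absolute score difference subject to the caliper,
exact ties going to the smaller patient id; matching is with replacement, so
a control remains available later and may itself be treated and matched
afterwards. Treated patients with no in-caliper candidate are dropped — the
emulated analysis reports fewer matched than treated ECPR patients without
stating a rule, and dropping is the only convention consistent with those
counts.

For the "% of controls later treated" summary the denominator is the set of
*unique* patients ever used as a control, matching the phrase "among the
control groups" in the design this package emulates.

## Effect estimation

For 1:1 pairs with one binary exposure the conditional ML odds ratio is the
discordant-pair ratio $n_{10}/n_{01}$; concordant pairs are ancillary. The
95% CI is Wald on the log scale ($\pm 1.96\sqrt{1/n_{10} + 1/n_{01}}$) — the
CI construction is not stated in the emulated analysis, and the closed-form
point estimate is verified internally against a numeric maximizer of the
full conditional likelihood. A zero discordant count yields an explicit
infinite/zero signal with a one-sided exact-binomial bound instead of a Wald
interval. Pairs sharing a control under replacement are treated as
independent, mirroring the emulated analysis; this understates the variance
when controls are reused heavily, and the package documents rather than
"fixes" it.

Balance is summarized by standardized mean differences: pooled-SD form for
continuous covariates, $p(1-p)$ variances for binary ones, and a
Mahalanobis-type multivariate form for categorical covariates with more than
two levels (one nonnegative number per variable, as balance tables print).
$|SMD| < 0.25$ is flagged as acceptable balance.

## The synthetic registry generator

`simulate_cohort()` draws covariates from marginals approximating a large
mixed-rhythm out-of-hospital cardiac-arrest registry (62% male, age ~70
(SD 15), 10% shockable initial rhythm, 48% bystander CPR, log-normal
call-to-hospital time with median 32 minutes, and so on — emulation choices,
not registry claims). Each patient then walks a discrete-minute clock from 0
to 119: intervention onsets are drawn per minute, then one categorical draw
selects at most one terminal event among ECPR, ROSC and termination, with
per-minute hazards that are inverse-logit linear in covariates, elapsed
time, the current intervention indicators, and an optional latent prognosis
variable. Survivors of the loop are censored at 120. A single categorical
draw per minute matches the minute-resolution matching grid and avoids
continuous-time tie handling.

The default hazards are calibrated to a clinically plausible sustained-arrest
cohort: ~45–50% ED ROSC concentrated early, ~35–40% termination mostly after
30–60 minutes (a per-minute termination hazard rising with elapsed time),
and ~10–17% ECPR starting no earlier than minute 5 with a median start
around 20–25 minutes. Treatment timing is prognosis-dependent but modest
(younger and witnessed patients are somewhat more likely to receive ECPR per
minute). Two calibration points matter for interpreting the bench:

* if ROSC is made very common and very fast, frozen competing-event rows
  dominate the subdistribution risk sets, the fitted score barely encodes
  the baseline covariates, and risk-set matching inherits a visible residual
  bias — an instructive failure mode, but not a realistic operating point;
* greedy nearest-neighbour matching has a small intrinsic positive bias
  under the null even with a correct score, because treated patients sit in
  the score's upper tail and their nearest in-caliper controls sit
  systematically below; its size grows with the strength of covariate-driven
  selection.

Thirty-day outcomes are logistic in treatment, covariates and the latent
variable. Potential outcomes under treated/untreated are drawn with a shared
uniform, so `beta_treat = 0` is an *exact* null (identical potential
outcomes patient-wise) and treated survival is monotone in `beta_treat`. The
generator returns both the cohort and the per-patient ground truth. An
optional linear decay of the treatment benefit with the treatment minute is
available but off by default — a "golden period" is plausible clinically but
no quantitative model for it is established. A deliberate simplification:
30-day survival is driven by the outcome model given realized treatment, not
by the terminal-event type, which keeps the true conditional log-odds effect
well-defined; the generator emulates the statistical structure the analysis
assumes, not resuscitation physiology.

`bias_scenario()` adds a latent prognosis variable that raises the
per-minute ECPR hazard, lowers the ROSC hazard and lowers survival, with
`beta_treat = 0`: clinicians escalate on refractory patients, so the naive
ever-versus-never odds ratio is biased well below 1 under the exact null,
while risk-set matching — comparing patients still in arrest at the same
minute — removes most (not all: the variable is unobserved) of the
selection.

Missingness can be injected MCAR, or MAR with the masking probability
driven by the always-observed disposition minute; event times, dispositions
and outcomes are never masked, since records with missing dispositions are
excluded rather than imputed.

## Imputation

`impute_missing()` is an iterative tree-ensemble imputer in the missForest
style: initialize missing cells with the observed mean/mode, revisit
variables in increasing order of missingness, refit a random forest
(`ranger`, 100 trees, `sqrt(p)` mtry, single-threaded for determinism) for
each on the currently completed other covariates, and stop when the
normalized change statistic first increases for every monitored variable
type, returning the previous sweep's values. Observed cells are never
modified, categorical imputations take values only from the observed level
set, and integer fields are rounded and clamped to their valid range. Single
imputation only — the emulated analysis does not pool over multiple
imputations.

## The simulation bench and problem sizes

`run_bench()` runs, per replicate: simulate → eligibility filter →
(optional) missingness injection and imputation → propensity fit → matching
→ conditional logistic estimate, alongside the naive 2×2 ever-versus-never
estimate, and aggregates mean log-OR, SD, absolute bias against the
configured truth, and 95% CI coverage. Replicate failures (separation, no
in-caliper matches, empty discordant cells) are counted and logged, never
silently dropped. The bench preset is an all-shockable cohort with
eligibility-violation rates set to zero, so the analysis set equals the
simulated set and the fitted covariates match the generator's
treatment-timing drivers.

Problem sizes, chosen as a balance between Monte-Carlo error and desk-scale
runtime and stated here as the package's own defaults: effect recovery uses
200 replicates of n = 2000 (true conditional log-OR ln 2), null coverage
200 replicates of n = 1000, and the bias contrast 60 replicates of n = 2000.
Under these conditions the matched estimator recovers ln 2 to within about
0.07 (crossover of controls to later treatment dilutes the contrast toward
the null — the same dilution the emulated design reports in its own matched
cohorts), null coverage sits near 0.95, and the naive estimator's absolute
bias under the latent scenario is roughly twice the matched estimator's.

## What passing tests do and do not show

The generator emulates the *structure* the analysis assumes:
minute-resolution competing events, prognosis-dependent treatment timing,
time-dependent interventions, binary endpoints, configurable missingness.
It does not emulate resuscitation physiology, hospital-level practice
variation, outcome dependence on total arrest duration beyond what the
covariates carry, misclassified neurological outcomes, or informative
censoring inside the 120-minute window. Green benches therefore show that
the estimator chain recovers known truths under the assumed structure — not
that any particular registry estimate is unbiased.

## Known limitations

* Greedy nearest-neighbour matching's tail bias under strong selection (see
  above); an optimal (non-greedy) matcher is out of scope.
* Reused controls are treated as independent in the conditional likelihood;
  a robust/clustered variance is not attempted.
* The caliper-scale population and the within-minute processing order are
  conventions; results can differ slightly under other conventions at the
  same seed.
* Hospital ECPR capability is inferred from the cohort itself (a hospital
  with no registered ECPR case is deemed non-capable), which makes the
  eligibility filter idempotent only when every capable hospital keeps at
  least one ECPR case through filtering — true by construction for
  simulated cohorts.
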