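---
title: "A Markov cost-utility model of FeNO-guided asthma management in children"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cost-utility model of FeNO-guided asthma management in children}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fenocea)
```

## The decision problem

Fractional exhaled nitric oxide (FeNO) is a noninvasive biomarker of airway
inflammation. Titrating a child's asthma therapy against FeNO instead of
symptoms alone reduces exacerbations, but the monitoring itself costs money.
`fenocea` implements a cost-utility comparison of FeNO-guided management
versus standard symptom-guided therapy for children with mild-to-moderate
allergic asthma, from a societal perspective (direct medical plus caregiver
productivity costs, US$ at a fixed COP$3,000 exchange rate), over a
12-month horizon with no discounting.

## Model structure

The cohort moves weekly among three mutually exclusive, non-absorbing
states:

* `W` — no symptoms / asthma controlled (utility 0.99),
* `S` — suboptimal control without exacerbation (utility 0.70),
* `A` — asthma exacerbation (utility 0.31).

The whole cohort starts in `W`. The weekly transition matrix holds the six
between-state probabilities; each stay probability is the row complement:

```{r}
cfg <- paper_fixture()
cfg$transitions
```

Expected QALYs over the horizon are the occupancy-weighted utilities times
the cycle length (1/52 year); expected costs are the occupancy-weighted
per-state weekly costs plus any per-cycle add-on. Occupancy is counted at
the end of each cycle (rows 1..52 of the trace); a trapezoidal half-cycle
correction is available (`half_cycle_correction = TRUE`) but off by
default, matching the original spreadsheet-style model. No discounting is
ever applied at this horizon.

The treatment effect is a pooled relative risk, RR 0.76 (95% CI
0.63–0.92), from a DerSimonian–Laird random-effects meta-analysis of eight
paediatric trials. The study-level effects behind that pooling were never
published as numbers, so `dl_pool()` is exercised against synthetic trials
(`simulate_trials()`) with the hierarchical structure the estimator
assumes, and the pooled values enter the model as inputs. The RR multiplies
both transitions *into* the exacerbation state (`W->A`, `S->A`), with the
difference absorbed into the stay probability; the exacerbation state is
the model's hospitalization analogue. A variant applying it to `W->A` only
is available through `rr_targets`.

## Costs and the calibration

The source study reports cost *components* (per-day line items and
ward/ED/PICU rates) and per-strategy *totals*, but never per-state costs.
The default recipe reconstructs them: a well-controlled week carries
maintenance drugs only; a suboptimal week adds a specialist referral and a
week of caregiver productivity loss; an exacerbation week carries an
emergency-department day plus seven days of ward stay, all fourteen
direct-medical per-day items and productivity loss. A PICU term weighted by
an admission fraction is available but defaults to zero — no admission
fraction is reported.

That reconstruction is deliberately under-determined, so
`calibrate_state_costs()` closes the gap in closed form: it solves the
2-by-2 linear system for scale factors on the `S` and `A` state costs
(leaving `W` at its few-cents recipe value) such that both strategies'
expected totals equal the published ones exactly. With the published
inputs the factors come out near 0.59 (`S`) and 1.21 (`A`) — the solve is
recorded on the returned configuration, never hard-coded.

Two reconstruction choices deserve mention:

* **FeNO add-on basis.** The monitoring cost is printed as US$2.20 per
  patient per *day*. Charged for all seven days of every cycle
  (US$15.40/week, the `"daily"` default reading), the annual outlay is
  US$800.8 — larger than any saving the model can generate, and the
  calibration solve then has no non-negative solution (the error message
  says so). The published totals are reachable only under the `"weekly"`
  reading — one monitored day per weekly cycle — which is the basis used
  by the paper-matching configuration.
* **The QALY gap.** A plain 52-cycle run of the published transition matrix
  yields 0.9511 QALYs (standard) and 0.9530 (FeNO), against published
  values of 0.9233 and 0.9395. No documented model choice (half-cycle
  correction, RR target set, initial state) moves the cohort QALYs to the
  published pair: the QALY gain attainable from RR 0.76 on the two
  exacerbation entries is bounded by the change in exacerbation occupancy
  times the utility spread, about 0.002, versus the published increment of
  0.0162. The package does not tune utilities to close this; the
  discrepancy is reported as-is, and the published per-strategy totals are
  themselves checked for internal consistency (ratio and increment
  identities) through `compare_strategies()`.

## Parameter uncertainty

`run_psa()` draws one joint parameter set per iteration and runs both
strategies on it:

* **Transition rows** — Dirichlet, with each row's effective sample size
  solved from the reported standard deviation of one reference transition
  (`W->S` 0.029, `S->W` 0.038, `A->W` 0.044; the first-listed transition of
  each row). A single-`n` Dirichlet cannot match all three reported
  marginal sds of a row at once; the reference choice is recorded in
  `dirichlet_reference`, and the implied sds of the remaining components
  follow from `sqrt(m(1-m)/(n+1))`. For `W->A` the implied sd (about
  0.006) is wider than the printed beta sd (0.002) — a direct consequence
  of the published row-level parameterization, and the main driver of
  incremental-cost spread in the probabilistic results.
* **Utilities** — beta, moment-matched; the well-controlled utility 0.99
  with sd 0.016 is feasible under the beta variance bound, so no
  truncation is applied anywhere (infeasible pairs are errors, not
  clamps).
* **Costs** — gamma, moment-matched; a zero sd is a point mass.
* **Relative risk** — lognormal. The table prints "LogN(SD 0.274)" while
  the printed CI implies a log-scale sd of 0.0966; the CI is the only
  internally consistent anchor (it reproduces 0.63–0.92 around 0.76), so
  sampling uses 0.0966 by default and `use_table_sd = TRUE` switches to
  the printed value.

Each draw is valid by construction (moment-matched families on their
natural supports), so no resampling or rejection is ever needed. One
master seed in the configuration feeds deterministic per-stage streams
(`derive_seed()`), making the PSA, the tornado and the synthetic trials
independently reproducible.

Decision outputs follow the standard value-of-information toolkit:
cost-effectiveness plane quadrants (`ce_plane_summary()`), acceptability
curves over a willingness-to-pay grid of 0–40,000 US$/QALY including the
study's US$20,000 threshold (`ceac()`, exact ties split equally), and
per-person EVPI (`evpi()`), with the population EVPI only computed when a
population size is supplied — the source study prints a population EVPI
but not the population behind it. Mean costs and QALYs are summarized with
normal-approximation confidence intervals of the mean (the published
intervals are far too tight to be percentile intervals of the outcome
distribution). Note that the PSA *mean* cost sits above the deterministic
base case by design: the Dirichlet and lognormal draws are right-skewed,
so the mean of the simulated totals need not reproduce the base-case
point.

## One-way sensitivity

`tornado_table()` sweeps every cost component over its published range
(mean ± 1 sd where no valid range is printed — the nebulization range in
the source table repeats the oxygen row and cannot bracket its mean),
every transition probability over mean ± 1 reported sd with the stay
probability absorbing the difference, and the RR over its 95% CI, all
other parameters held at base case. The holding-fixed contract is
auditable: each sweep attaches the full parameter vector it ran with. Under
the calibrated baseline, FeNO remains cost-saving at every bound of every
published cost range; the RR's upper confidence bound is the one input
that moves the comparison off dominance (to a positive incremental cost at
equal-or-better effectiveness).

## What the synthetic generators do and do not show

`simulate_trials()` emulates trial-level log relative risks with uniform
within-study standard errors on (0.15, 0.35) — chosen to straddle the
pooled-effect scale implied by the published interval — and Gaussian
between-study heterogeneity. It validates the estimator (parameter
recovery within Monte Carlo error), not the clinical literature: real
trials differ in size, outcome definitions and risk of bias in ways a
two-level Gaussian hierarchy does not capture. Likewise
`perturb_config()` establishes robustness of the dominance verdict to
moderate (5% relative) joint input shocks, not to structural changes such
as a different state space or time-varying transition probabilities.

## Problem sizes and numerical choices

The shipped analyses use the study's own sizes: 52 weekly cycles, 1000 PSA
iterations, a 41-point willingness-to-pay grid. Tolerances are strict where
arithmetic is exact (1e-12 for row-stochasticity and hand-traceable
propagation, 1e-9 for moment round-trips) and Monte Carlo-aware elsewhere
(three standard errors). The stationary distribution is obtained by a
linear solve of the balance equations and serves purely as an independent
oracle for the cohort engine; degenerate (reducible) matrices are rejected.

## Known limitations

* Per-state costs are a documented reconstruction plus a recorded
  two-factor calibration, not observed quantities.
* The published QALY pair cannot be derived from the published transition
  matrix and utilities (see above); QALY-side results therefore carry that
  structural uncertainty.
* The published probabilistic summaries are mutually inconsistent: with
  roughly 46% of iterations in quadrant 1, the acceptability curve cannot
  exceed 99% at low thresholds, and the expected value of perfect
  information cannot be of order US$0.07. The package reports what the
  simulation yields (an acceptability minimum near the quadrant-2 share,
  and an EVPI of a few tens of US$ at the US$20,000 threshold).
* Extended dominance, EVPPI, budget impact and discounting machinery are
  out of scope; the comparison is pairwise between two strategies.
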