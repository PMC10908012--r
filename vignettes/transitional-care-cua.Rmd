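---
title: "A Markov cohort cost-utility model of transitional care for older COPD inpatients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-utility model of transitional care for older COPD inpatients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcscea)
```

## The decision problem

Older patients discharged after a COPD hospitalisation are readmitted at
high rates, and a substantial share stop managing the disease entirely.
Transitional care services (TCS) — a bundled post-discharge intervention in
which a coordinator nurse screens the patient, builds a care plan, educates,
and follows up by home visit and telephone — aim to reduce both. `tcscea`
implements a cost-utility analysis of TCS versus usual care from the
healthcare-system perspective, for cohorts entering at ages 60, 70 and 80.

## Model structure

The model is a six-state Markov cohort model over 90-day cycles with a
10-year horizon (40 cycles). Each quarter a surviving patient occupies one
of five medical-use states — stable outpatient management of COPD
(`STABLE`), no management (`NO_MGMT`, no physician contact in the quarter),
or readmission for COPD, another respiratory disease, or a non-respiratory
disease — and `DEAD` is absorbing, with zero cost and zero utility.

Two structural choices deserve emphasis, because the published inputs
determine them:

* **Memoryless destinations.** The evidence base supplies a single
  per-cohort cross-sectional distribution over the five alive states, not a
  full 5×5 from→to matrix. Every alive state therefore shares the same
  destination distribution conditional on surviving the cycle. No
  state-history dependence (e.g. elevated risk after a prior readmission) is
  representable from these inputs, and none is modelled.
* **Death first, as a competing event.** From alive state $s$ at age $a$,
  the cycle death probability is
  $q_c(s, a) = 1 - \bigl(1 - \min\{1,\ m_s\, q(a)\}\bigr)^{1/4}$,
  where $q(a)$ is the annual all-cause death probability and $m_s$ the
  state's additional mortality ratio; survivors redistribute over the alive
  states. Rows of the resulting transition matrix sum to one by
  construction. The ratio multiplies the annual *probability* (capped at 1)
  rather than the hazard, matching how the source ratios are reported; for
  annual probabilities below 0.2 the two conventions differ by under 2% of
  the cycle probability.

The intervention arm is a one-time per-patient cost (251.25 USD, attached at
model entry, undiscounted — the service completes within the first cycle, so
discounting it would change results by about one US dollar) plus
multiplicative relative risks on the four unfavourable states
(0.704 for no management, 0.599 for COPD readmission, 0.720 for the two
other readmission states); `STABLE` absorbs the residual mass. The relative
risks persist for the whole horizon: the evidence gives no decay schedule,
so none is invented.

Aging is tracked by advancing the cohort's integer age one year every four
cycles, which drives the life-table lookup; destination distributions are
otherwise time-homogeneous.

## Parameters

All model inputs ship as plain-text tables under
`inst/extdata/paper_params/` and load through `paper_params()` with full
invariant checking (simplex constraints, component-sum consistency within
0.02 USD of printed totals, range containment, period-consistent
annualisation of mortality ratios).

| Parameter | Value | Units | Why |
|---|---|---|---|
| Cycle length | 0.25 | years | 90 days is the clinical follow-up window for post-discharge COPD outcomes |
| Horizon | 40 | cycles | 10 years, reflecting chronic disease course |
| Discount rate | 4.5 | %/year | national economic-evaluation guideline value, applied to costs and effects |
| WTP threshold | 23,050 | USD/QALY | KRW 30 million at 1,301.50 KRW/USD |
| Non-reimbursement share | 21.37 | % | imputed share of payments not visible in claims |
| TCS cost | 251.25 | USD, one-time | sum of the ten intervention items |
| PSA iterations | 10,000 | draws | full-scale probabilistic analysis |

Per-state quarterly costs (76–3,147 USD by cohort and state) combine
reimbursed claims, the imputed non-reimbursed share, a nursing fee priced at
the integrated-nursing-care daily rate (85.82 USD/day), and inhaler costs.
`NO_MGMT` costs zero by definition (the state means no medical contact);
`STABLE` costs the printed outpatient/inhaler total for the quarter.
Utilities are annual EQ-5D weights (0.795 stable or unmanaged, 0.61 COPD
readmission, 0.52 respiratory, 0.44 other); each cycle contributes
utility × 0.25 QALYs.

## Outcome accumulation

Rewards are accumulated with the trapezoid (life-table) half-cycle
correction: cycle $k$ contributes the average of the adjacent occupancies
valued at the mid-cycle discount factor,

$$V = \sum_{k=1}^{40} (1+r)^{-(k-\frac12)/4}\ \tfrac12\bigl(v(k{-}1)+v(k)\bigr),$$

with no separate full-weight cycle-0 term. The correction variant is not
dictated by the source; the trapezoid form is the standard recommendation of
the methods literature and is what the tests' closed-form oracles encode.
Half-cycle-corrected totals provably sit strictly between the
start-of-cycle and end-of-cycle accumulation conventions for non-constant
traces, and the suite asserts this on real traces.

Incremental results report ΔC, ΔE and, only in the trade-off quadrants, the
ICUR ΔC/ΔE. Dominant results are labelled `cost_saving_dominant` rather
than reported as a sign-ambiguous negative ratio. Boundary cases (exactly
zero ΔC or ΔE) receive their own labels so the quadrant definitions remain
strict.

## The synthetic data layer

Two inputs of the original analysis are not redistributable and are
replaced by generators:

* **Life table.** The national complete life table is emulated by a
  Gompertz–Makeham hazard $h(a) = \lambda + \alpha e^{\beta(a-60)}$ with
  defaults $\lambda = 0.001$, $\alpha = 0.005$, $\beta = 0.09$ per year,
  giving $q(60) \approx 0.6\%$, $q(80) \approx 3.7\%$, $q(100) \approx
  20\%$ — plausible for a contemporary East-Asian national table, whose
  exact vintage is unknown. Generation is deterministic; $q$ is forced to 1
  at the terminal age (110 by default) and the old-age monotonicity
  invariant is enforced.
* **Claims outcomes.** The claims substrate behind the transition
  proportions is emulated at outcome level only: one categorical 90-day
  outcome per patient, drawn from the cohort distribution with a mandatory
  seed. `estimate_distribution()` recovers proportions with normal-
  approximation 95% intervals; the suite verifies ~95% pooled per-state
  coverage over 200 seeded replicates. No longitudinal claims structure,
  readmission-linkage rules, or cause-specific mortality is generated,
  because the cohort model consumes none of it.

A green test therefore establishes that the *pipeline* reproduces its
stated arithmetic and distributional behaviour — not that the synthetic
mortality schedule equals the (unpublished) national table. Consequences
are quantified below.

## Sensitivity analysis

**One-way DSA.** Parameters are addressed by path
(`constants.discount_rate`, `tcs_cost`, `rr.<state>`, `utility.<state>`,
`cost.<cohort>.<state>`, `prob.<cohort>.<state>`; unknown paths are
rejected, never silently ignored). Default bands: published ranges for
relative risks and utilities, ±25% for costs and the TCS cost, 0–9% for the
discount rate, and ±1.96 binomial standard errors for transition
probabilities (others renormalised). The tornado outcome is net monetary
benefit at the 23,050 USD/QALY threshold — the ICUR itself is unstable near
ΔE ≈ 0. Setting a transition probability rescales the remaining four states
proportionally; setting a cost rescales its components; setting the TCS
cost rescales the item schedule.

**PSA.** Parametric Monte-Carlo: gamma for costs (published means;
coefficient of variation 0.2 by default, configurable — no cost standard
errors are published), beta for utilities (range half-width read as 1.96
standard deviations, moment-matched) and for per-state transition
probabilities (binomial standard errors from the source counts, draws
renormalised to the simplex), and log-normal for relative risks fitted to
their 95% CIs (the no-management relative risk has no printed CI, so its
table range is treated as one). Mortality ratios and the life table are
held fixed — no uncertainty is published for them. Draws are independent
across *parameters*; the stable and unmanaged states cite one and the same
published utility estimate, so they constitute a single parameter and
receive a common draw. The CEAC reports, per willingness-to-pay value, the
fraction of draws with strictly positive net monetary benefit (ties count
against the intervention).

The source text mentions both "Monte Carlo simulation" and "nonparametric
bootstrap resampling" for the same 10,000-iteration analysis; since
explicit parametric distributions are specified, this package implements
parametric Monte-Carlo and computes the CEAC over those draws.

## Numerical and degenerate-input conventions

* Currency arithmetic runs at full precision; rounding (half away from
  zero, 2 decimals) happens only at presentation, matching printed tables.
* A zero-width PSA range yields an explicit point mass, not a degenerate
  sampler; an infeasible beta variance is an error before iteration starts.
* An RR-adjusted alive mass exceeding 1 is reported as an error, not
  silently clamped.
* Hazards driving $q \ge 1$ before the nominal terminal age truncate the
  life table there.
* All stochastic entry points (`simulate_claims_cohort`, `run_psa`,
  `cmd_psa`) require a seed; there is no hidden RNG state.

## What reproduces and what does not

Running `baseline_analysis(paper_params())` yields incremental QALYs of
0.235 / 0.280 / 0.311 for the 60s/70s/80s cohorts — within 0.005–0.015 of
the published 0.231 / 0.275 / 0.296, with the published ordering — and
every cohort is cost-saving dominant, as published. Incremental *costs*,
however, are far larger here (≈ −7,900 to −8,900 USD versus the published
−225 to −2,252), and the 70s cohort's savings exceed the 80s cohort's by
about 0.1%, inverting the published tail ordering. Both discrepancies trace
to the substituted life table and to model-structure details the source
does not print: under the memoryless structure the intervention's large
shift of occupancy out of costly readmission states compounds every cycle,
and its survival benefit — largest in the 80s cohort — buys additional
cost-accruing cycles that partially offset savings. The acceptance suite
asserts the published ordering anyway and documents the failure rather than
recalibrating the generator toward it.

## Known limitations

* No indirect costs, protocol-development or training costs; the original
  analysis flags the same limitation.
* Relative risks and utilities are transported from non-Korean studies.
* No inhaler-compliance decay or learning effects over the horizon.
* Claims emulation is cross-sectional; operational readmission-linkage
  rules are out of scope.
* Expected-value cohort simulation only — no microsimulation, no
  value-of-information analysis.
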