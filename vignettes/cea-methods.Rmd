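---
title: "Model and methods: partitioned-survival cost-effectiveness analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: partitioned-survival cost-effectiveness analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melcea)
```

## The decision problem

melcea implements a monthly-cycle cohort model for comparing treatment
strategies in advanced cancer, built for the three-way comparison of
dacarbazine chemotherapy against the BRAF inhibitors dabrafenib and
vemurafenib in BRAF^V600E^ metastatic melanoma (2013 USD, societal
willingness-to-pay of \$100,000/QALY). The cohort moves through three
health states — stable disease, progression, death — and each strategy
accrues lifetime drug costs, toxicity-management costs, crossover costs
and quality-adjusted life years.

## State occupancy: partitioned survival, not a transition matrix

Although models of this family are conventionally called Markov models,
state membership here is defined directly from the survival endpoints:

* stable(t) = PFS(t)
* progressed(t) = OS(t) − PFS(t)
* dead(t) = 1 − OS(t)

so the package computes occupancy in the partitioned-survival style
rather than through a transition matrix. `transition_probabilities()`
derives one consistent set of per-cycle conditional probabilities as a
diagnostic (deaths are attributed to the progressed state first, which is
the only allocation that keeps a progressing cohort feasible when early
deaths exceed progressed occupancy), and a test verifies the derived
chain reproduces the trace; it is never used for computation.

Digitized curves can put PFS a hair above OS. Violations up to 1e-9 are
clipped silently (floating noise), up to 0.05 clipped with a warning,
and anything larger rejected: a violation that big means the two curves
are not from the same cohort.

## Lifetime extrapolation: DEALE

Observed curves cover months 0–8. Beyond an anchor month (default 8,
configurable per scenario) survival is extended with the declining
exponential approximation of life expectancy: a single constant hazard
`h = −log S(anchor) / anchor`, giving
`S(t) = S(anchor) · exp(−h (t − anchor))`. The approximation is
reasonable precisely because survival in this population is short
(median OS ≈ 9–10 months) relative to any background mortality trend.
The horizon runs to `max_cycles` (default 600 = 50 years) but the trace
is truncated once the cohort is effectively extinct
(dead ≥ 1 − 1e-6), which matters only for speed. For a pure exponential
curve the hazard is recovered exactly at any anchor; the Weibull option
of the curve generator exists to probe what DEALE does when the
constant-hazard assumption is wrong (with increasing hazard, the
extrapolated tail is optimistic).

## Accrual conventions

Costs and QALYs accrue for cycles t = 0 … T−1 on start-of-cycle
occupancy:

* cost(t) = (drug + expected AE cost) × alive(t) + crossover × progressed(t)
* qaly(t) = (u_stable × stable(t) + u_prog × progressed(t)) × cycle_length/12

Choices a maintainer should know about:

* **Drug and AE costs accrue on all alive occupancy** by default. The
  source analysis applies drug cost to every cycle alive and AE cost to
  every cycle "on drug", which it equates with being alive; the stricter
  stable-only reading is available as `ae_costs_on = "stable"`.
* **Crossover** (comparator-arm patients switching to the experimental
  drug on progression) is modelled purely as a cost: the chemotherapy
  arm is charged the dabrafenib monthly price per unit of progressed
  occupancy. Survival and utilities are untouched, mirroring the source
  accounting.
* **No discounting by default** (the source analysis reports
  undiscounted 2013 USD); an annual rate is available and applied as
  (1+r)^(−t/12).
* **No half-cycle correction by default**, again for fidelity. The
  trapezoidal option exists and is where the "totals stable under grid
  refinement" property genuinely holds: start-of-cycle (left-endpoint)
  accrual carries an O(h·Δ) bias — about +14% on a 2.5-month-median PFS
  integral at monthly cycles — which cancels in cost/QALY *differences*
  between strategies but shifts absolute totals by a few percent when
  the grid is refined. The test suite pins the <2% refinement-stability
  property under the trapezoidal setting and documents the ~2.5%
  left-endpoint shift instead of hiding it.
* Costs are charged **per cycle**: if you shorten cycles you must
  convert monthly rates yourself (the engine will not guess which of
  your cost inputs are rates).

Monetary values are kept as doubles internally and written at 2 decimals
at I/O boundaries; ICERs are reported at the nearest dollar, with
half-away-from-zero rounding (`round_half_up()`), matching how such
tables are conventionally printed.

## The frontier

Strategies are ordered from least to most expensive; strict dominance
(≥ cost and ≤ QALY, one strict; exact ties flag the later-listed
strategy, deterministically) is applied first, then extended dominance
is removed iteratively until frontier ICERs strictly increase. The
three-strategy melanoma case only needs strict dominance, but the
general algorithm is tested against an independent oracle that
characterizes the frontier as the set of unique net-monetary-benefit
maximizers over all positive thresholds. NMB is implemented in the
standard form λ×E − C. (The source text prints the dimensionally
inconsistent λ×(E − C); its acceptability-curve construction behaves as
the standard form, which is what we implement — recorded here
deliberately.)

`threshold_monthly_price()` exploits the fact that total cost is affine
in the monthly price (total = fixed + price × discounted alive-months)
to solve ICER = λ exactly rather than by search; the one-way DSA's
interpolated crossing and this closed form agree to 1e-6 and are tested
against each other.

## Probabilistic sensitivity analysis

Every parameter is a (base, low, high, family) quadruple. Fitting rules
(method of moments, mean always preserved):

* **gamma** (costs): sd = (high − low)/3.92, shape = mean²/var,
  scale = var/mean.
* **beta** (probabilities, utilities): same sd rule, α and β solved from
  mean and variance.
* **Ranges printed as 0–1** (the utilities) carry no information beyond
  the base value; sampling Uniform(0,1) would discard the base value, so
  we use a mean-preserving effective-sample-size beta with ν = 20
  (α = base·ν), a deliberately weakly-informative choice surfaced as the
  `ess` argument rather than hidden.
* **Probabilities printed without any range** (the adverse-event rates)
  get the same ν = 20 treatment, because the source PSA varies *all*
  variables; zero-width gamma specs degrade to point masses.
* **Haematological adverse events carry a fixed \$0 management cost**:
  no cost was published for them and we do not invent inputs; their
  probabilities remain in the model so a user can supply costs.

Draws are independent across parameters (no correlation structure is
stated anywhere), survival curves are *not* varied (distributions are
stated only for probabilities, utilities and costs), and each parameter
owns an RNG substream seeded from `hash(parameter path) ⊕ master seed`,
so results are bitwise-reproducible and invariant to declaration order.
The CEAC records, per willingness-to-pay point on a \$0–\$300,000 grid
(\$5,000 steps, covering the decision range), the share of iterations
in which each strategy maximizes NMB; ties go to the cheaper strategy.

## What the synthetic curves do and do not establish

The trial Kaplan-Meier curves exist only as published figures, so the
bundled scenario pairs the real economic table with synthetic
exponential curves calibrated by median survival: OS medians 8 / 9 / 10
months and PFS medians 2.5 / 5.1 / 5.3 months for dacarbazine /
dabrafenib / vemurafenib. The targeted-arm OS medians are the ones the
source quotes when justifying DEALE; the chemotherapy arm is set shorter,
and the PFS medians reflect the roughly twofold progression-free
advantage of BRAF inhibition reported in the registration trials. These
values were fixed before any acceptance measurement and are not tuned.

A green test on this scenario establishes that the *machinery* is right:
accrual matches an independent cycle-by-cycle oracle to 1e-6, DEALE
recovers ln2/median to 1e-12, the frontier matches its oracle, and the
10,000-iteration CEAC shows the qualitative published picture —
chemotherapy optimal in the clear majority at \$100,000/QALY
(≈ 65–67% here vs ≈ 85% published), dabrafenib taking over by
\$150,000/QALY, vemurafenib never in contention. It does **not**
establish the published lifetime totals (\$15,221 / \$38,547 / \$49,938;
0.1820 / 0.3385 / 0.2905 QALYs): exponential stand-ins are heavier in
the tail than the real curves, so absolute totals and exact CEAC
percentages are out of reach without digitized trial data. Users with
digitized curves can drop them in as `{csv: path}` references and keep
every other input.

Real Kaplan-Meier features the generator does not emulate: censoring
(and its step-width irregularity), number-at-risk-driven noise
heteroscedasticity, and any hazard change at the follow-up boundary.
The multiplicative log-normal noise option only mimics digitization
jitter, and is re-monotonized, so it cannot create crossing curves.

## Numerical choices and degenerate inputs

* Occupancy rows must sum to 1 within 1e-12 (enforced by construction,
  tested by property).
* `S(anchor) = 0` is an explicit error instructing the user to shorten
  the anchor, not an infinite hazard.
* Equal-QALY ICERs return `NA` so callers report dominance instead of a
  division artefact.
* The degenerate all-fixed PSA reproduces the deterministic totals to
  1e-12 relative (the vectorized PSA path reassociates sums relative to
  the per-cycle engine, so "exactly" means up to floating-point
  reassociation) and its CEAC is a step function at the frontier ICER.
* Scenario files carry `schema_version: 1`; unknown keys and unknown
  versions are rejected outright, because a silently ignored typo in a
  cost-effectiveness input is an audit failure, not a convenience.

## Known limitations

* Three states only; no AE-specific health states in the trace (their
  utilities are folded into the composite state utilities, as published).
* No parameter correlation in the PSA; no survival uncertainty by
  default.
* DEALE is a single constant hazard: it cannot represent cure fractions
  or late plateaus, and with the Weibull generator one can show it is
  optimistic under increasing hazard.
* The published absolute totals are not reproducible from public data,
  and this package does not pretend otherwise.
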