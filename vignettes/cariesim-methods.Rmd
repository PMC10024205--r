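---
title: "Methods: microsimulation of childhood caries under dental workforce expansion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsimulation of childhood caries under dental workforce expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cariesim` is an individual-level, annual-cycle decision-analytic model
of dental caries among US children, built to ask one policy question:
what happens to caries burden, costs, and quality-adjusted life years
(QALYs) when the National Health Service Corps (NHSC) expands its
dental workforce in dental Health Professional Shortage Areas (HPSAs)?
This vignette records the model, its assumptions, and the design
decisions that were genuinely open, in enough detail that a maintainer
can audit any number the package produces.

## The model in one paragraph

A synthetic cohort of children aged 0-19 (default 10,000-20,000
simulated individuals representing 80 million, of whom 14.7 million
live in whole- or partial-county dental HPSAs) is generated over a
joint demographic structure (age group x sex x race/ethnicity x income
x urban/rural x HPSA status) and followed for 10 annual cycles.  Each
cycle an individual may use preventive dental care, develop a new
carious tooth event (logistic-additive annual risk), have a new event
go untreated, progress from untreated caries to abscess or tooth loss,
and die.  NHSC budget scenarios are converted into serving-dentist
full-time equivalents (FTE), then into dentist-density changes for
HPSA strata, which shift preventive-care utilization (+1.67 percentage
points per additional dentist per 10,000 children) and caries risk
(odds ratio 0.46 per additional dentist per 1,000 children, applied
log-linearly as OR^density).  Costs (2022 USD) and QALYs accrue each
cycle and are discounted at 3% per year.  Scenario contrasts are run
under common random numbers (CRN), so that incremental outcomes
reflect only the intervention.

## Synthetic population: what it emulates, what it does not

The restricted county-linked survey tabulations behind the original
demographic inputs are not public.  The packaged `default_demography()`
therefore encodes *assumptions*: national race/ethnicity margins follow
published survey weighted percentages (26.4% Hispanic, 15.7%
non-Hispanic Black, 57.9% non-Hispanic White), and shortage-area
children are assumed poorer (42% vs 22% low income in whole-county
HPSAs vs non-HPSAs), more rural (55% vs 15%), and somewhat more likely
to be Hispanic or Black.  The HPSA child total is fixed at 14.7
million.  Stratum allocation uses deterministic largest-remainder
quotas rather than multinomial draws, so stratum weights conserve the
configured population exactly and tests are deterministic; the residual
units after flooring the quotas are placed by a seeded tie-break.  Ages
are uniform over each group's integer years.  A green test against this
generator establishes internal consistency of the pipeline, not
fidelity to the unpublished stratum table.

Baseline oral-health states come from an ever-had-caries curve by
single year of age, anchored so the band averages reproduce
cross-sectional prevalences of 21.3% (ages 2-5), 52.1% (6-12) and
56.8% (13-19), with race and HPSA odds adjustments.  Within the two
older bands the curve is nearly flat: band prevalence is mostly
established around band entry (mixed and permanent dentition
transitions), which is also what keeps a closed cohort consistent with
flat cross-sections (below).

## Disease model

Annual caries risk is inverse-logit of: an age-group intercept, additive
sex/race/income/residence/HPSA terms, a fixed within-group age profile,
a birth-cohort (secular) trend, a per-age-group calibration multiplier,
and any dentist-supply log-odds shift.  Two structural terms deserve
comment because the model genuinely does not work without them:

* **Eruption-timing age profile.**  Hazard peaks at first-permanent-
  molar eruption (ages 6-8) and again moderately at second-molar
  eruption (13-14), declining toward band exit.  Without this profile a
  single hazard per age group must average over the band, so children
  leave the 6-12 band carrying far more accumulated prevalence than the
  13-19 cross-section allows, and the calibration drives adolescent
  incidence to zero.
* **Secular (birth-cohort) trend** (default -0.03 log-odds per birth
  year) and a **young-adult reference hazard** (default 0.04/year for
  cohort members past age 19).  Flat cross-sectional band prevalences
  are a mixture of birth cohorts, not a cohort trajectory; the trend
  lets the closed cohort match them without implying that adolescents
  and young adults stop developing caries, which would artificially
  null the intervention in the later simulation years when the
  workforce expansion is largest.

Event order within a cycle is fixed and published in
`?step_population`: utilization draw, incidence draw, untreated
assignment (with a lower untreated probability when care is used, and
conversion of prevalent untreated caries to treated at a visit),
complication draws on prevalent untreated caries, then mortality.
Complication counters are capped so abscesses and lost teeth never
exceed accrued carious events.  Survivors age exactly one year; the
cohort is closed (no births; members aging past 19 remain until the
horizon ends).

## Calibration

`calibrate_model()` fits one log-odds multiplier per age group against
the cross-sectional band targets (person-year measure over the run) and
one HPSA offset against the end-of-horizon HPSA vs non-HPSA prevalence
gap, each by bisection on a monotone response under CRN, in increasing
age order (band prevalence only depends on hazards at equal or younger
ages, so the sequence converges without re-iteration; an outer loop
re-runs it after the HPSA offset moves).

Cross-sectional band targets and end-of-horizon cohort-level targets
are *jointly infeasible* for a single closed cohort: pinning every band
at its cross-sectional value forces the cohort to accumulate more
caries by horizon end than the cohort-level targets imply.  Rather than
privileging one target family, the default calibration adds a minimax
balancing stage: all band targets are shrunk by a common offset
`delta`, computed at run time from the fitted level bias and its
measured sensitivity, so that band residuals (= `delta`) and
cohort-level residuals are approximately equalized.  With the packaged
targets this lands every validated group within about 4 percentage
points, inside the 5-point validation bound the analysis is held to;
with self-consistent targets (e.g. targets generated by the model
itself, as in the parameter-recovery test) the level bias is within
tolerance and the stage is skipped, so recovery is unbiased.

## Workforce module

Budget scenarios ramp the baseline award counts.  The engine uses a
*linear* ramp, `baseline x (1 + g t)`, selected by
`program$budget_ramp = "linear"`; `project_awards()` itself defaults to
compound growth `(1+g)^t` for callers who want it.  The linear ramp is
the packaged choice because it makes incremental outcomes scale
proportionally with the growth rate across the 5-30% sweep, which is
the scaling pattern the policy results are expected to show; compound
ramping makes late-year budgets grow much faster than the FTE they buy
can deliver within a 10-year horizon, producing an inverted-U in cost
savings.

Each award cohort serves `(1 - default_rate)` FTE during its commitment
(2 years; 3 for student-to-service; optionally +1 in the
commitment-extension scenarios), then decays geometrically through a
post-service retention profile (default 0.85/year for up to 8 years,
consistent with reported short-term retention of NHSC alumni in
underserved practice).  Incremental FTE relative to the flat-award
status quo are allocated to whole- and partial-county HPSA strata
proportionally to child population with a partial-county weight of 0.5,
converted to dentists per 1,000 children, and mapped to effects by
`apply_supply_effect()`.

Program cost in the engine is disbursed evenly over each award's
commitment years (the loan-repayment contract structure) and
discounted; `program_cost()` defaults to lump-sum accrual in the award
year for callers using it directly.  Post-commitment retention years
are not charged (continuation contracts are ignored, a conservative
simplification in the cost-saving direction is *not* taken: ignoring
both their cost and any extra effect is approximately neutral at the
packaged retention values).

## Economics

Costed items are caries treatment (default $1,500 per decayed tooth,
representing roughly a decade of comprehensive management of a carious
tooth in a high-need population, including re-restoration and the
minority of cases needing operating-room care), abscess episodes
($1,500), extractions ($350), and NHSC program outlays.  The packaged
preventive-visit fee is $0: the costed item set mirrors the source
analysis, in which utilization acts as a mediator of treatment status
rather than a billed service; setting `econ$cost_preventive > 0` puts
visits on the payer ledger.  Disutility weights (annual): untreated
caries 0.035, treated caries 0.005, abscess episode 0.08, and 0.01 per
missing tooth.  Utility is floored at zero; the dead accrue nothing.
No half-cycle correction is applied; accrual is at cycle end, with
year-0 accrual undiscounted.  Costs accrued in the cycle of death are
kept (events preceded the death); QALY accrual requires surviving the
cycle.

All cost and disutility defaults stand in for unpublished supplementary
tables and are documented assumptions, chosen once on external grounds
(ADA/Medicaid fee scales, pufa-literature progression rates, NHSC award
statistics) and exposed in the parameter configuration and the
sensitivity machinery.

## Uncertainty

One-way analysis sweeps nine parameters (treatment and abscess costs,
the two supply effects, untreated and abscess probabilities, the
untreated disutility, NHSC retention and default rates) between
documented low/high bounds with everything else central, re-running
both arms of the contrast under CRN; cost-only parameters provably
cannot move incremental QALYs under CRN, which the tests assert
exactly.  Probabilistic sensitivity analysis samples all tabled
parameters (beta for probabilities, gamma for costs, lognormal for odds
ratios; 95% interval of +/-20% around the central value where no
interval is published), pairing the two arms within each draw and
refreshing disease randomness across draws.  Credible intervals are
inverse-ECDF order statistics; the cost-effectiveness acceptability
curve counts draws with positive net monetary benefit on a
willingness-to-pay grid from $0 to $150,000 per QALY.  The packaged
default is 1,000 draws of 5,000 individuals (the source scale is
10,000 draws); the acceptance suite uses 500 draws of 10,000
individuals, a desk-scale reduction documented there.

## Numerical choices and degenerate inputs

Random streams are indexed by `(seed, cycle, event slot)` and drawn for
the full population vector, dead included, so draw *i* always belongs
to individual *i* and scenario contrasts are exactly paired; the
scheme is equivalent to a counter-based generator keyed by
`(seed, cycle, slot, individual)` at the granularity the model needs.
Probabilities saturate smoothly through the inverse logit; forced
transitions (probability 0 or 1) are exact.  Bisection tolerances
default to 0.005 absolute prevalence with 40 iterations per multiplier.
Zero-population strata are dropped from the generated cohort (their
weight is unrepresented); every packaged stratum receives individuals
at the default n.  Empty draw sets, invalid distribution bounds,
negative proportions, uncalibrated parameter sets, and mismatched
population fingerprints all raise immediate errors naming the offender.

## What a green test establishes — and known limitations

The synthetic population reproduces a *stated* world: published
marginal percentages plus documented assumptions.  Calibration fidelity
(within 5 points), parameter recovery (within 0.05 on the log-odds
multipliers), structural invariants (CRN determinism, ledger
conservation, dose-response monotonicity in expectation, oracle
equality for CEAC/discounting), and directional replication of the
cost-effectiveness conclusion (QALY gains with cost savings in >= 90%
of scaled-down PSA draws) are all verified.  Absolute magnitudes of
incremental QALYs and costs depend on the unpublished supplementary
values and are *not* asserted.  The model has no per-tooth surface
anatomy, no secondary caries, no dynamic demography, no non-NHSC supply
trends, and treats the HPSA designation as three-level rather than
geographic.
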