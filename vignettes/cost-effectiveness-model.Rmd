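---
title: "The late-window thrombectomy cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The late-window thrombectomy cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokecea)
```

## The decision problem

Mechanical thrombectomy (MT) in the extended 6–24 hour window improves
90-day functional outcomes of acute ischemic stroke with large-vessel
occlusion, but it is resource-intensive: advanced imaging selection,
devices, and neuro-interventional staffing. Whether the short-term
functional benefit translates into value for money over a patient's
remaining lifetime — overall and within clinical subgroups — is a question
for decision-analytic modelling. `strokecea` implements the standard
two-stage structure used for this problem: a short-run decision tree
covering the 90-day acute phase, feeding a lifetime Markov cohort model in
3-month cycles, compared across two strategies (MT with standard medical
care, `MT_SMC`, versus standard medical care alone, `SMC`) from the US
health-care perspective in 2019 USD.

## Model structure and assumptions

**Acute phase.** The only stochastic node of the decision tree is the
90-day modified Rankin Scale (mRS) outcome, a 7-category distribution per
arm; resource use (imaging mix, IV-tPA frequency, the MT procedure) enters
as fixed expected quantities. The tree is therefore evaluated as a cohort
expectation — a dot product of the mRS distribution with tier costs and
utilities — which is algebraically identical to per-branch enumeration and
simpler. Treatment effects are assumed fully realised within the acute
phase. Deaths before day 90 receive the death-tier acute cost and zero
utility and never enter the Markov model.

Some trials report a combined "mRS 5 or 6" category; `split_mrs56()`
separates it using the relative mRS-5/mRS-6 proportions of a reference
distribution (conventionally the trial that reports all seven levels),
applied uniformly to all such subgroups.

**Long-run phase.** Survivors enter mRS 0–5 states and cycle every 3
months until cohort extinction. Within a cycle the competing risks are
ordered: background (non-stroke) mortality first, then stroke recurrence
among survivors. The ordering is a modelling choice — both risks are
specified per cycle but their within-cycle interleaving is not — and
applying background death first prevents double-counting deaths in the
recurring fraction. Mortality hazard ratios are applied on the rate scale
(`probability → rate → scale → probability`), the standard construction
that stays a probability even when `hr · q_x` approaches 1. A recurrent
stroke is fatal with a fixed probability (0.0513) that *replaces*, rather
than adds to, background mortality for the recurring fraction in that
cycle; otherwise the patient moves to a strictly worse alive state with
equal risk. The published transition table defines this redistribution
only for origin states mRS 0–4; for mRS 5 no worse alive state exists, so
a non-fatal recurrence leaves the patient in mRS 5.

Recurrent patients are managed with their original strategy: the cost and
utility of a recurrence cycle are the strategy-specific expected 90-day
cost and utility from the decision tree, recomputed per PSA draw rather
than sampled independently (they are derived quantities, not free
parameters). Only one recurrence can occur per cycle, recurrence risk is
equal across states, and there are no recovery (improvement) transitions
and no tunnel states — recurrence effects last a single cycle.

**Ages and sexes.** The cohort ages deterministically: it enters the
Markov model at the arm's mean age + 0.25 years (the life table applies
from the end of month 3) and advances 0.25 years per cycle; age is a
scalar, not a distribution. Annual death probabilities are mixed across
sexes by the arm's male proportion *before* rate conversion.

## Parameters

All inputs live in one validated object, `cea_parameters()`, whose
uncertain entries are registered in `params$dist` (id, family,
distribution parameters, one-way bounds). Key defaults, in 2019 USD:

* **Imaging** (per use): CT 198, CTA 774, MRI 625, MRA 1023, CTP 836,
  infarct-volume software 89. SMC patients receive CT + CTA; MT patients
  CT, then CTA or MRA (probability 0.5 each) and CTP or MRI (0.5 each),
  plus the software cost.
* **Treatment**: IV-tPA 8004 (weighted by per-arm usage frequency), MT
  procedure (devices, room personnel, overhead) 15,836, MT physician 2749.
* **Acute 90-day cost** by severity tier: mRS 0–2 14,382; mRS 3–5 17,879;
  death 23,498.
* **Long-term 3-monthly costs** by state: 2836, 2741, 3378, 5801, 11,742,
  17,262 for mRS 0–5.
* **Utilities** (time-trade-off): 0.85, 0.80, 0.70, 0.51, 0.30, 0.15 for
  mRS 0–5, death 0; constrained non-increasing in severity at
  construction.
* **Transitions**: recurrence 0.013 per cycle (Beta(13, 986)); fatal
  recurrence 0.0513; mortality hazard ratios 1, 1, 1.11, 1.27, 1.71, 2.37
  for mRS 0–5 (log-normal, SE 0.076 for mRS 0 and 0.46 otherwise).
* **Settings**: 3-month cycles, 3% annual discounting of costs and QALYs,
  age truncation at 110 years, extinction tolerance 1e-6, 2000 PSA draws,
  $100,000/QALY default willingness to pay.

The per-arm IV-tPA frequencies default to a synthetic 0.10 in both arms
(the per-arm trial frequencies are not available in the bundled sources)
and should be overridden with real values via the config file or the
efficacy table. Male proportions default to the printed trial values
(DAWN 39.3%/51.5%; DEFUSE 3 50.0%/48.9%).

The whole set round-trips through a human-editable YAML config
(`write_cea_config()` / `load_parameters()`) whose entries mirror the
published input table one-for-one, so the numbers stay diffable against
their source; life tables and efficacy distributions are separate CSVs.

## Distributions for the probabilistic analysis

* **beta-PERT** (costs): classic shape-4 PERT on the printed
  minimum/mode/maximum.
* **beta with explicit parameters** (recurrence Beta(13, 986); fatal
  recurrence Beta(5.1, 94.9), the complement of the published Beta(94.9,
  5.1) row for the mRS 4 → mRS 5 survival share).
* **beta from base + range** (utilities): the published table names the
  family and a range but not α/β. We pin the mean to the base value
  (α = m·ν, β = (1−m)·ν) and solve the concentration ν so the central 95%
  interval width equals the printed range width — preserving both the
  printed base and the printed spread. Because utilities are sampled
  independently, draws may transiently violate the cross-state
  monotonicity that the base values satisfy; monotonicity is therefore
  enforced on constructed inputs but deliberately not on PSA draws.
* **log-normal** (hazard ratios): median equal to the base HR, the printed
  SE on the log scale. The two HRs fixed at 1 (mRS 0, 1) still carry
  printed SEs; we sample all six — holding them at exactly 1 would ignore
  stated uncertainty, and the median remains 1.
* **uniform** (imaging mix frequencies, on [0, 1]).
* **Dirichlet** for compositions: each arm's 90-day mRS distribution is
  redrawn with concentration `n · p̂` (the multinomial conjugate at the
  arm's sample size — how efficacy uncertainty scales with subgroup size);
  the non-fatal post-recurrence split over worse states is redrawn from a
  flat Dirichlet conditional on the drawn death share. Both are
  assumptions where the source material is under-specified, and both can
  be switched off (`sample_efficacy = FALSE`; `split_family = "fixed"`).

One master seed drives everything; each PSA draw runs under a
deterministically derived sub-seed, so any single draw is reproducible in
isolation and the two strategies share one parameter draw (common random
numbers). Draws that fail validation are rejected and redrawn under a
perturbed sub-seed, with the count reported.

## Numerical choices

* **Accrual timing**: cycle-start accrual with no half-cycle correction by
  default (matching the conventional spreadsheet implementation of this
  model family); `cea_settings(half_cycle = TRUE)` applies a trapezoidal
  correction (removes half of the first cycle's accrual) for sensitivity.
* **Acute-phase QALYs**: whether the first 90 days contribute
  `0.25 × U_90` to lifetime QALYs is genuinely ambiguous in this model
  family; both modes are implemented
  (`cea_settings(include_acute_qaly = )`), defaulting to accrual. Acute
  cost and QALYs enter undiscounted at time zero.
* **Expected values vs PSA means**: headline tables can be produced either
  as deterministic base-case runs (`run_deterministic()`) or as means over
  PSA draws (`glance(run_psa(...))`); credibility intervals are always
  percentile-based (2.5th/97.5th) over the draws.
* **Termination**: a cohort is extinct when the alive fraction falls below
  1e-6; runs truncate at age 110 and warn only if more than 1% of the
  cohort is still alive there (with realistic life tables the remaining
  mass at 110 is ~1e-5).
* **Tornado bounds**: printed ranges where they exist (PERT, uniform,
  range-based betas); central 95% quantiles for parameters specified only
  by distribution parameters. Endpoints that fail validation are skipped
  with a message. ICER endpoints are reported (dominance-heavy subgroups
  can switch to an NMB tornado, whose endpoints are stable).
* **ICER semantics**: dominance cases keep their signed ratio alongside
  the `dominant`/`dominated` label, matching how published tables print
  them; |ΔE| < 1e-12 yields an `undefined` label rather than an exception.

## What the synthetic data emulate — and what they do not

`synth_efficacy()` draws arm-level 90-day mRS proportions from a Dirichlet
whose mean encodes a proportional-odds treatment effect on the cumulative
mRS scale — one interpretable effect-size knob, matching how ordinal trial
efficacy is conventionally summarised. The trial-like default preset
uses a control distribution with expected utility ≈ 0.31 and an effect of
1.16 log-odds, sized so the arms' expected utilities differ by ≈ 0.18 —
the separation implied by the published strategy-specific recurrence
utilities (0.49 vs 0.31). Both reporting dialects are emitted: full
7-level rows and combined-mRS-5/6 rows for split testing.
`synth_life_table()` is Gompertz-form, `q_x = min(1, q₀·e^{k(age−60)})`
with a female multiplier (defaults q₀ = 0.01, k = 0.09, 0.6), anchored so
a 60-year-old man has q_x = 0.01 — minimal realistic structure for
exercising hazard-ratio adjustment and age advancement.

Passing tests on these fixtures demonstrate that the machinery is correct
(probability conservation, oracle equivalence with a 200,000-patient
microsimulation, analytic discount sums, parameter recovery of an injected
effect). They do *not* validate the headline published ICERs, which
require the per-arm trial outcome tables and a real national life table;
with those supplied as CSVs the same pipeline reproduces that analysis,
and reproduction tolerance must absorb the unstated life-table vintage.

## Problem sizes used by the tests

The shipped suite runs the fixture study at 4 subgroups; property checks
use 100 randomised parameter sets for trace invariants, 3 fixtures ×
200,000 simulated patients for the microsimulation comparison, 100 seeds
for effect-recovery, 10⁵ draws for sampler means, and 25–500-draw PSAs
elsewhere — sizes chosen so each suite section completes in seconds while
keeping Monte-Carlo error well below the tested tolerances.

## Known limitations

* The cohort is homogeneous within an arm (scalar mean age, fixed sex
  mix); no patient-level heterogeneity beyond the mRS state.
* No recovery transitions, tunnel states, or time-varying recurrence risk;
  recurrence risk is equal across mRS states by assumption.
* Resource-use frequencies (imaging mix, tPA) are expectation-level, not
  sampled per patient.
* Costs are taken as already expressed in 2019 USD; there is no built-in
  inflation machinery.
* The synthetic tPA frequencies and any synthetic efficacy inputs are
  placeholders for real per-arm data and are labelled as such.
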