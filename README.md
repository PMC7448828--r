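# strokecea

Decision-analytic cost-effectiveness modelling of mechanical thrombectomy
(MT) with standard medical care (SMC) versus SMC alone for acute ischemic
stroke treated in the late (6–24 hour) window, from the US health-care
perspective. The package is aimed at health-economics and outcomes
researchers who want a tested, scriptable implementation of the standard
two-stage model for this decision problem — a 90-day decision tree feeding
a lifetime Markov cohort model — together with probabilistic and one-way
sensitivity analysis and subgroup orchestration, rather than a spreadsheet.

## The model

**Acute phase (decision tree, 90 days).** Each strategy arm allocates
patients over the seven modified Rankin Scale levels (mRS 0–6, with mRS 6 =
death) at 90 days using trial-style efficacy distributions. The expected
acute cost per patient is

```
C_90 = imaging(strategy) + f_tPA · c_tPA + 1{MT} · (c_proc + c_phys) + Σ_i p_i · c_acute(tier(i))
```

with severity tiers mRS 0–2, mRS 3–5 and death, and the expected 90-day
utility is `U_90 = Σ_i p_i · u_i` with `u(mRS 6) = 0`. These two scalars
also serve as the strategy-specific cost and utility of a recurrent-stroke
cycle later on.

**Long run (Markov cohort model, 3-month cycles).** Ninety-day survivors
enter states mRS 0–5 plus an absorbing dead state and cycle until
extinction (or age 110). Each cycle applies, in order: background mortality
from an age- and sex-indexed life table adjusted by mRS-specific hazard
ratios on the rate scale, `p = 1 − exp(−hr · (−log(1 − q_x))/4)`; then
stroke recurrence (probability 0.013 per cycle, equal across states, at
most one per cycle), which is fatal with probability 0.0513 or moves the
patient to a strictly worse mRS state with equal risk. Costs (state-specific
long-term costs, or the recurrent-stroke cost for recurring patients) and
QALYs (`utility × 0.25` per cycle) accrue discounted at 3% per year.

**Comparative economics.** Strategies are compared by incremental cost
ΔC, incremental QALYs ΔE, the ICER ΔC/ΔE (with dominant/dominated
labels), and net monetary benefit `NMB = λ·ΔE − ΔC`. Parameter uncertainty
propagates through a probabilistic sensitivity analysis (beta, beta-PERT,
Dirichlet, log-normal and uniform distributions; 2000 draws by default)
summarised by percentile credibility intervals and cost-effectiveness
acceptability curves; one-way sensitivity produces tornado diagrams.

Because the per-arm trial outcome tables and national life tables cannot be
redistributed here, the package ships a synthetic-data generator
(`synth_efficacy()`, `synth_life_table()`, `fixture_base_case()`) that
emulates their statistical structure: Dirichlet-sampled arm-level mRS
proportions around a proportional-odds treatment effect, and a Gompertz
life table. Real efficacy CSVs and life tables drop in via
`read_efficacy()` / `read_life_table()`.

## Worked example

```r
library(strokecea)

cfg <- fixture_base_case(seed = 20260)   # synthetic 4-subgroup study
study <- run_study(cfg)                  # deterministic Table-style matrix
study
#> # A tibble: 4 × 8
#>   trial   subgroup     delta_cost delta_qaly   icer dominance     nmb    wtp
#>   <chr>   <chr>             <dbl>      <dbl>  <dbl> <chr>       <dbl>  <dbl>
#> 1 DAWN    synthetic_01     25887.       1.81 14321. <NA>      154878. 100000
#> 2 DEFUSE3 synthetic_02      3754.       1.62  2313. <NA>      158565. 100000
#> 3 DAWN    synthetic_03      7403.       1.83  4034. <NA>      176090. 100000
#> 4 DEFUSE3 synthetic_04     51357.       1.37 37561. <NA>       85373. 100000
```

Each row compares MT+SMC against SMC alone for one synthetic subgroup:
thrombectomy costs $3.8k–$51k more per patient over a lifetime, gains
1.4–1.8 discounted QALYs, and therefore buys a QALY for $2.3k–$38k — far
below the $100,000/QALY willingness-to-pay, so the net monetary benefit is
large and positive everywhere.

Per-strategy lifetime outcomes and uncertainty for one subgroup:

```r
sg <- cfg$subgroups[[1]]
det <- run_deterministic(sg, cfg$params, cfg$life_table, cfg$settings)
tidy(det)
#> # A tibble: 2 × 6
#>   strategy    cost  qaly cost_undisc qaly_undisc life_years
#>   <chr>      <dbl> <dbl>       <dbl>       <dbl>      <dbl>
#> 1 MT_SMC   360662.  4.49     451470.        5.61      12.0
#> 2 SMC      334775.  2.68     412878.        3.32       9.09

psa <- run_psa(sg, cfg$params, cfg$life_table,
               cea_settings(seed = 20260, psa_draws = 500))
glance(psa)
#> # A tibble: 1 × 11
#>   trial subgroup     n_draws n_rejected delta_cost delta_qaly   icer dominance
#>   <chr> <chr>          <int>      <int>      <dbl>      <dbl>  <dbl> <chr>
#> 1 DAWN  synthetic_01     500          0     27649.       1.81 15300. <NA>
#>       nmb    wtp prob_ce
#> 1 153059. 100000   0.998
```

So across 500 parameter draws thrombectomy is cost-effective at
$100,000/QALY in 99.8% of simulations for this subgroup. `plot_ceac(psa)`,
`autoplot(psa)` (incremental cost/QALY scatter) and
`plot_tornado(tornado_analysis(...))` give the standard figures.

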