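# sarcscreen

Cost-effectiveness evaluation of community sarcopenia screening strategies
with a decision-analytic Markov cohort model.

Sarcopenia — age-related loss of muscle mass, strength and physical
function — increases the risks of cardiovascular disease (CVD), falls,
fractures and death in older adults, and screening enables interventions
that reduce its incidence and speed recovery. This package compares **21
strategies** (ten screening tools × annual/biennial intervals, plus no
screening) for community-dwelling adults followed from age 60 over 25
one-year cycles, for health economists and screening-programme analysts.

## The model in brief

A cohort evolves over five states — no sarcopenia (NS), sarcopenia (S), CVD
(C), sarcopenia + CVD (SC), death — each living state stratified by an
intervention flag. Per cycle: screening (decision tree on the tool's
sensitivity/specificity; positives receive an immediate one-year
intervention episode: incidence ×0.45, recovery ×3.61), then fall/fracture
overlays and accrual, then the age-dependent state transition. Strategies
are compared on discounted (3%/yr) cost and quality-adjusted life-years
(QALYs):

* **CE ratio** = cost / QALYs per strategy;
* **ICER** = ΔC / ΔE versus no screening, classified against 1× and 3×
  per-capita GDP ($12,551.49 / $37,654.49, 2021 USD);
* **efficiency frontier** = the non-dominated convex hull on the (E, C)
  plane;
* **NMB** = E × λ − C, driving the tornado DSA and the PSA acceptability
  curves.

Age-specific CVD and fall schedules are supplied via configuration or
generated synthetically (`generate_schedules()`; calibrated so the
no-screening cohort's healthy life expectancy is ≈ 69 years). See the
methods vignette (`vignettes/model-methods.Rmd`) for the full model account.

## Worked example

```r
library(sarcscreen)

ps  <- default_parameters()          # published inputs + mid synthetic schedules
tab <- cea_table(ps)                 # all 21 strategies
head(tab[, c("strategy", "cost", "qaly", "icer", "threshold_class", "on_frontier")], 7)
#>                strategy   cost   qaly   icer       threshold_class on_frontier
#>            no screening 1802.1 5.4648     NA                  <NA>        TRUE
#>  SARC-F|MSRA-5 biennial 2149.0 5.5652 3455.8 highly cost-effective       FALSE
#>  SARC-F|MSRA-7 biennial 2190.1 5.6073 2724.2 highly cost-effective        TRUE
#>    SARC-F|MSRA-5 annual 2386.8 5.6263 3619.9 highly cost-effective       FALSE
#>    SARC-F|MSRA-7 annual 2392.7 5.6798 2746.7 highly cost-effective        TRUE
#>         SARC-F biennial 2407.1 5.5562 6618.3 highly cost-effective       FALSE
#>      AWGS 2019 biennial 2445.3 5.6707 3125.0 highly cost-effective        FALSE
```

Costs are discounted 2021 USD per person over 25 years; `qaly` the
discounted QALYs; `icer` dollars per QALY gained versus no screening.
Biennial SARC-F|MSRA-7 attains the lowest ICER ($2,724/QALY — "most
cost-effective"), annual MSRA-7 the highest QALYs, and the frontier runs

```r
frontier_table(tab)
#>                strategy   qaly   cost sequential_icer
#>            no screening 5.4648 1802.1              NA
#>  SARC-F|MSRA-7 biennial 5.6073 2190.1          2724.2
#>    SARC-F|MSRA-7 annual 5.6798 2392.7          2791.1
#>        AWGS 2019 annual 5.7501 2735.8          4885.2
#>           MSRA-7 annual 5.7991 6927.9         85500.8
```

so annual AWGS 2019 screening is optimal for any willingness to pay between
about $4,900 and $85,500 per QALY — the whole policy-relevant range. The
no-screening cohort's undiscounted healthy life expectancy is 68.9 years.

Sensitivity analyses:

```r
dsa <- one_way_dsa(ps)                      # tornado: incremental NMB, AWGS annual vs none
psa <- run_psa(ps, n_draws = 1000, seed = 1)
cc  <- ceac(psa)                            # acceptability curves on a 0-40k grid
```

`run_base_case()`, `run_dsa()` and `run_psa_report()` write the canonical
CSV outputs (`cea_table.csv`, `frontier.csv`, per-strategy traces,
`tornado.csv`, `psa_draws.csv`, `ceac.csv`) plus a hash manifest;
`write_default_config()` / `load_parameters()` round-trip the full
parameterisation through an editable YAML file.

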