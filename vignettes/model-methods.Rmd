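---
title: "Model and methods: cost-effectiveness of sarcopenia screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: cost-effectiveness of sarcopenia screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcscreen)
```

## The decision problem

Sarcopenia — age-related loss of muscle mass, strength and physical function —
raises the risks of cardiovascular disease (CVD), falls, fractures and death,
and community screening can trigger exercise/nutrition interventions that
reduce incidence and speed recovery. `sarcscreen` evaluates 21 strategies for
community-dwelling adults followed from age 60: ten screening tools (SARC-F,
MSRA-5, MSRA-7, calf circumference, finger-ring test, Ishii test, SARC-CALF,
the two-step AWGS 2019 pathway, and the two parallel combinations
SARC-F|MSRA-5 and SARC-F|MSRA-7), each at an annual or biennial interval, plus
a no-screening comparator.

## Model structure

The natural history is a Markov cohort over five health states — no
sarcopenia, sarcopenia, CVD, sarcopenia + CVD, and death — run for 25 one-year
cycles on a cohort entering at age 60 with sarcopenia prevalence 0.12 and no
CVD. Each living state is split by an intervention flag, giving nine strata.
Within a cycle the order is fixed:

1. **Screening** (cycle 0, then every 1 or 2 years). All living members are
   screened; the sarcopenic fraction tests positive with the tool's
   sensitivity, the non-sarcopenic with one minus its specificity. Positives
   (true and false) enter the intervened strata and incur one intervention
   episode cost. Screening participation is 100% by assumption.
2. **Event overlay and accrual.** Falls occur with the age-band fall rate,
   scaled by relative risks for sarcopenia (1.89) and CVD (2.17); a fraction
   0.26 of falls fracture, scaled by the sarcopenia fracture RR (1.71) — the
   fall RR acts on fall incidence and the fracture RR on the conditional
   fracture proportion so no margin is scaled twice. Fractures cost $3,599.05
   and substitute the with-fracture utility for that cycle only (fractures
   heal within the year; no tunnel state). Utilities and the continuing CVD
   cost ($1,904.77 per CVD-year) accrue on the start-of-cycle occupancy;
   there is no half-cycle correction.
3. **Transition.** Sarcopenia onset (age-banded incidence 0.04 / 0.12 / 0.17,
   multiplied by 0.45 under intervention) and recovery (0.16, multiplied by
   3.61 under intervention, clamped at 1) compose with CVD onset (age-band
   incidence, ×1.33 when sarcopenic) as mutually exclusive competing events:
   each is thinned by the other's complement and the joint event stays put,
   which keeps all moves inside the permitted transition diagram (CVD is
   irreversible; death absorbing). Death combines background mortality
   (0.09 per year, ×2.00 when sarcopenic), CVD case fatality
   (mortality/prevalence of the age band) and fall fatality applied to
   fallers, as independent components: `1 - prod(1 - p_i)`. New CVD entrants
   incur the initial CVD cost ($4,149.29) in the cycle of onset.

Costs and QALYs are discounted at a common 3% per year (range 0.01–0.05); the
willingness-to-pay thresholds are 1× and 3× per-capita GDP ($12,551.49 /
$37,654.49, 2021 USD).

### The intervention episode

The sources state only that screen-positives "receive immediate intervention
with a stable effect". Two readings were implemented:

* `effect_duration = "one_cycle"` (default): an episode protects for the year
  of the screen and expires; biennial strategies leave off-years unprotected.
* `effect_duration = "interval"`: the flag persists until the next due screen.

The one-cycle default was chosen because published base cases for this
problem show annual screening gaining 0.14–0.23 QALYs over biennial for
almost every tool — a pattern only the one-cycle episode reproduces; under
interval-long persistence biennial screening becomes nearly as effective as
annual (gaps ≈ 0.03 QALYs) and the strategy ranking collapses into ties.
Intervention cost ($1,119.05) is charged once per positive screen, so annual
strategies charge annually and biennial biennially.

### The AWGS 2019 two-step pathway

Handgrip strength ($1.31) and gait speed ($0.71) are applied to every
screened person; DXA ($42.86) confirms all sarcopenic members (step-1
sensitivity treated as perfect, preserving the pathway's 1.00/1.00 accuracy)
plus the "possible sarcopenia" fraction (0.40) of the non-sarcopenic. This is
the only reading of the possible-sarcopenia parameter consistent with the
stated pathway and its perfect overall accuracy.

### Parallel tests

`parallel_combine()` provides the textbook either-positive composition, but
the shipped SARC-F|MSRA-5 and SARC-F|MSRA-7 strategies use empirically
measured combined accuracies (0.42/0.98 and 0.64/1.00), which a validation
study found lower than the formula predicts; the printed values are used
as-is.

## Parameters and uncertainty

All inputs live in a `sarc_params` object (`default_parameters()`), are
editable through a YAML configuration (`write_default_config()`,
`load_parameters()`), and carry a distribution for probabilistic sensitivity
analysis (PSA) and a range rule for deterministic sensitivity analysis (DSA):

* probabilities/utilities with a 95% CI → beta, fitted with the mean held
  exact and the concentration refined so the fitted 2.5%/97.5% quantiles
  match the reported interval (standard interval-elicitation practice; a pure
  moment fit misses mildly asymmetric intervals). One reported interval —
  SARC-CALF sensitivity 0.59 (0.57–0.70) — is arithmetically inconsistent
  with its own mean (no beta with mean 0.59 has that 95% interval) and is
  carried verbatim; its fit minimises the endpoint error at ≈ 0.04.
* quantities with a reported SD → beta (utilities) or gamma (costs) by
  moments, reproducing mean and SD exactly.
* relative risks (values > 1) → lognormal with median equal to the point
  value and σ from the log-interval width. A beta cannot represent a ratio
  above 1, whatever the source table's distribution column says.
* rows printed without uncertainty (perfect sensitivities/specificities,
  age-banded incidence and fracture utilities, background mortality) are
  fixed in PSA.

DSA ranges: reported CIs where available, ±10% otherwise (clamped to [0, 1]
for probabilities and utilities), 0.01–0.05 for the discount rate. The
tornado (`one_way_dsa()`) tracks the incremental net monetary benefit of a
chosen strategy (default: annual AWGS 2019, the recommended strategy) versus
no screening at 3× GDP; influence shares are each parameter's NMB swing over
the sum of swings.

PSA (`run_psa()`) draws each uncertain parameter from its own
seed-and-name-derived substream, so draws are reproducible and adding a
parameter does not perturb the others. Cost-effectiveness acceptability
curves (`ceac()`) report, per willingness-to-pay on a 0–40,000 by 200 grid,
the fraction of draws in which each strategy attains the maximum net monetary
benefit, with exact ties split equally.

## Synthetic age-rate schedules

The engine needs age-specific CVD and fall incidence, prevalence and
cause-specific mortality. Real burden-of-disease tables can be supplied via
the `age_schedules` configuration section, which bypasses generation
entirely. `generate_schedules()` otherwise produces smooth log-linear-in-age
rates over 5-year bands from 60 (CVD incidence 1%/year rising to ~4%, CVD
case fatality 2–4%; injurious-faller rate 6% rising to ~13%, fall fatality
well below 1%), deterministic per seed up to a ±2% level jitter. The mid
level's constants were fixed once so the default no-screening cohort reaches
an undiscounted healthy life expectancy of ≈ 68.9 years (start age plus
summed living occupancy), matching the ~69-year anchor reported for this
population; `low`/`high` scale incidence and mortality by 0.7/1.3. The
generator emulates the *shape and order of magnitude* of real schedules, not
any published table's values — absolute costs and QALYs therefore differ
from analyses built on the real rates, while within-model comparisons
(ICER rankings, frontier membership, CEAC ordering) are the meaningful
outputs. Fall "incidence" uses the injurious-faller convention (fraction of
persons with ≥1 medically relevant fall per year).

## Validation

* **Independent worksheet oracle.** A three-cycle toy configuration
  (`toy_parameter_set()`) is reproduced to machine precision by a
  straight-line 9-state arithmetic oracle kept in the test helpers.
* **Microsimulation oracle.** `microsim_oracle()` re-implements the same
  rules at the individual level; cohort totals agree within 3 Monte Carlo
  standard errors at n = 200,000.
* **Structural properties.** Row-stochastic transition matrices and death
  absorption over 1,000 random PSA draws; occupancy conservation every cycle;
  a deathless unit-utility cohort accrues exactly 25 QALYs; a costless
  perfect test with a neutral intervention reproduces no screening to
  machine precision; CEAC probabilities sum to 1 at every threshold.

Problem sizes used in the shipped tests: 1,000 PSA draws × 21 strategies ×
25 cycles, 200,000 microsimulated individuals on the 3-cycle toy set.

## Known limitations

* Only CVD is modelled as a comorbidity; cognitive impairment, diabetes and
  other sarcopenia-associated outcomes are out of scope, as is a separate
  severe-sarcopenia state.
* Background mortality is a flat annual 0.09 as published; age enters only
  through the CVD/fall schedules and sarcopenia incidence bands.
* Screening participation and intervention adherence are 100%.
* The non-sarcopenic-CVD-with-fracture utility is not published; it is
  imputed multiplicatively as `u_cvd × (age-band fracture utility / 0.76)`.
* Parameter draws are independent; no correlation structure is modelled.
* With the published uncertainty for the intervention recovery effect
  (95% CI 1.05–13.66), roughly 9% of PSA draws carry a near-null
  intervention benefit, in which no screening is optimal — acceptability
  curves therefore plateau below 1 even where the base case is clear-cut.
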