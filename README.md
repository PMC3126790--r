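# oabcea

A decision-tree cohort model of the cost-effectiveness of antimuscarinic
therapy for overactive bladder (OAB) with urgency incontinence, comparing
fesoterodine (4 mg, titratable to 8 mg), extended-release tolterodine (4 mg)
and solifenacin (5 mg, titratable to 10 mg) over a 52-week horizon from the
societal or payer perspective, with all inputs in 2010 euros.

The package is aimed at health-economics and HTA analysts who want the
published deterministic model as tested, reusable code: every parameter is a
validated, perturbable input; every accrual convention is explicit; and the
cohort algebra is cross-checked against an individual-level
microsimulation.

## The model

A unit cohort starts therapy and is assessed at scheduled checkpoints:

- **Week 4 (titration):** week-8 trial data serve as the proxy for the
  week-4 assessment. For the two-dose arms, 50% of responders and 50% of
  non-responders titrate to the higher dose; tolterodine has a single dose.
- **Week 12 (responder gate):** each branch responds with the dose-specific
  conditional probability P(responder at W12 | W8 status). Responders
  (continent, <1 urge incontinence episode/24 h) continue therapy;
  non-responders discontinue and become untreated.
- **Weeks 12–52 (extrapolation):** response is carried forward (LOCF);
  responders leave therapy only through the shared persistence curve
  (90.64% at week 12, 79.32% at week 24, 59.27% at week 52).

Outcomes are accrued over the periods (0,12], (12,24] and (24,52] weeks,
each valued at the occupancy of its closing checkpoint:

- **QALY gain** versus the all-untreated baseline:
  `sum over periods of (weeks/52) * sum over states of occupancy * (u_state - u_untreated)`
  with utilities 0.9569 (continent on therapy), 0.9412 (incontinent on
  therapy) and 0.9332 (untreated baseline). Optional comorbidity utility
  decrements are supported and off by default.
- **Costs** per patient started: drug acquisition, incontinence pads,
  physician visits and laboratory tests, constipation management,
  status-conditional comorbidities (fractures, skin infections, urinary
  tract infections, depression, nursing-home admission) and, under the
  societal perspective, productivity effects relative to no treatment
  (avoided incontinence work-hour loss and avoided nocturia impairment —
  a gain, entering with negative sign).
- **CEA:** incremental cost over incremental QALYs (ICER) with dominance
  classification — "cost-saving" when the reference arm is cheaper and more
  effective — against a 30,000 euro/QALY willingness-to-pay threshold.
- **Sensitivity:** a one-way grid perturbing every parameter group by
  +/-25%, plus horizon (52 to 12 weeks) and perspective switches.

## Worked example

```r
library(oabcea)

params <- oab_basecase()          # the published input tables, validated
report <- run_report(params)      # 52 weeks, societal perspective
print(report)
```

```
<oab_report: 52 weeks, societal perspective>
  fesoterodine  continent w12  50.6%  w52  33.1%  QALY gain 0.01015  total     1142 EUR
  tolterodine   continent w12  40.6%  w52  26.5%  QALY gain 0.00847  total     1484 EUR
  solifenacin   continent w12  47.2%  w52  30.9%  QALY gain 0.00958  total     1220 EUR
  fesoterodine vs tolterodine: Cost-saving
  fesoterodine vs solifenacin: Cost-saving
```

Half the fesoterodine cohort is continent at week 12 (50.6%, vs 40.6% on
tolterodine and 47.2% on solifenacin); attrition leaves 33.1% continent on
therapy at week 52. Fesoterodine accrues the largest QALY gain over the
untreated baseline and the lowest societal cost, so it dominates
("cost-saving") both comparators — no ICER is reported. The per-component
breakdown (`report$arm_table`) shows why: its higher drug spend (382 EUR vs
269 EUR for tolterodine) is more than offset by lower pad, comorbidity and
productivity costs among the larger continent fraction.

The sensitivity grid and the microsimulation cross-check run the same way:

```r
grid <- tornado(params)               # the published +/-25% scenario grid
subset(grid, label != "cost-saving")  # empty: dominance is robust
sim <- microsim("fesoterodine", params, n = 1e5, seed = 1)
continent_fraction(sim, 12)           # ~0.506, within 3 binomial SE
```

The numbered scripts under `analysis/` (`01_basecase.R`, `02_sensitivity.R`,
`03_microsim_validation.R`) run these analyses end to end and write their
tables under `results/`.

## Package layout

- `R/` — parameter schema and validation, cohort engine, QALY and cost
  accrual, CEA, sensitivity grid, fixtures (base case, random parameter
  sets, microsimulation oracle), report assembly.
- `inst/extdata/oab_basecase.yaml` — the base-case parameter file (the
  schema is documented by example there).
- `analysis/` — the numbered analysis workflow.
- `vignettes/oab-cea-model.Rmd` — methods: model, conventions, design
  choices, limitations.
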