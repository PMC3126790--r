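---
title: "Methods: the OAB antimuscarinic cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the OAB antimuscarinic cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oabcea)
```

## The decision problem

Overactive bladder (OAB) with urgency urinary incontinence is treated with
antimuscarinics whose value depends jointly on efficacy (restoring
continence), tolerability, persistence and the downstream costs of
uncontrolled incontinence: pads, physician visits, and comorbidities
(falls with fracture, skin and urinary tract infections, depression,
nursing-home admission), plus lost productivity. This package implements a
deterministic decision-tree cohort model comparing fesoterodine
(4 mg, titratable to 8 mg), extended-release tolterodine (4 mg, single
dose) and solifenacin (5 mg, titratable to 10 mg) over 52 weeks in a
Spanish setting (2010 euros), from the societal perspective with a payer
variant.

## Model structure and assumptions

A unit cohort enters on the start dose. The tree has two decision points
and an extrapolation phase:

1. **Week 4, titration.** The trials assessed patients at weeks 2, 8 and
   12; week-8 efficacy and discontinuation serve as the proxy for the
   week-4 assessment, so the engine has no separate week-4 state. For the
   two-dose arms, 50% of week-8-proxy responders and 50% of non-responders
   move to the higher dose; tolterodine's whole cohort continues on 4 mg
   (which gives its patients the same two chances at response). This
   yields a `BranchSplit` of up to four branches, each carrying a dose.
2. **Week 12, responder gate.** Each branch responds with the
   dose-specific conditional probability of week-12 response given week-8
   status, taken directly from the printed conditional columns of the
   efficacy table. Non-responders discontinue at the gate (no further
   titration, no dose lowering); responders continue.
3. **Weeks 12–52, carried-forward response.** Responders remain responders
   (last observation carried forward) and leave therapy only through the
   persistence curve, which from week 12 onward is the placebo curve for
   every arm (published 12-week discontinuation does not differ from
   placebo). Attrition removes responders proportionally across doses;
   leavers become untreated.

Checkpoint occupancy at weeks 8, 12, 24 and 52 spans three states:
continent on therapy (by dose), incontinent on therapy (by dose; after
week 12 this state is empty because non-responders have left), and
untreated. Occupancy always sums to 1.

Two structural readings deserve note. First, the printed conditional
columns and the ratio of the printed marginals cannot both hold exactly
under the law of total probability; the engine treats the two conditional
columns as primary, which is the reading that reproduces the published
checkpoint continence. Second, surviving responders after week 12 are
*response-weighted* across doses (a surviving responder is more likely to
be on the dose with the higher conditional, e.g. 48.55%/51.45% across
fesoterodine 4/8 mg rather than the 50/50 split of the whole cohort); this
is the composition the individual-level microsimulation implies, and it is
what the engine uses for survivor drug and constipation pricing. The
effect versus the cohort-mix approximation is ~0.4% of drug cost.

Solifenacin was not an arm of the source trials; its efficacy row is the
placebo row scaled by published relative risks (1.50 for 5 mg, 1.53 for
10 mg), with the responder conditional taken equal to placebo. The
derivation (`scale_efficacy_by_rr()`) rounds to the two-decimal percent
convention of the input tables, half away from zero. Week-2 efficacy
values are loaded and validated but unused: no accrual rule needs them.

## Parameters

All inputs live in a YAML file mirroring the published tables section by
section (`inst/extdata/oab_basecase.yaml`); `load_parameter_set()` converts
percents to fractions and enforces the invariants — probabilities in
[0, 1], non-increasing persistence, zero titration for single-dose arms,
expected comorbidity events at least the probability of any event, and the
consistency of each dose's week-12 marginal with (week-8 marginal) x
(responder conditional) within ±0.005, the tolerance implied by
two-decimal percents. Violations are enumerated with their parameter
paths, never silently repaired.

Parameters that matter most, with defaults:

| Parameter | Default | Units / note |
|---|---|---|
| Titration fractions (responders / non-responders) | 0.5 / 0.5 | two-dose arms only |
| Persistence at weeks 12 / 24 / 52 | 0.9064 / 0.7932 / 0.5927 | shared placebo curve |
| State utilities (continent / incontinent-on-rx / untreated) | 0.9569 / 0.9412 / 0.9332 | untreated anchors the gain |
| Drug cost per day | 1.70–2.72 | euros, dose-specific |
| Horizon | 52 | weeks; 12 supported |
| Perspective | societal | payer excludes productivity |
| `annualize_six_month` | TRUE | x2 on 6-month comorbidity windows |
| `decrements_enabled` | FALSE | comorbidity utility decrements |
| Willingness to pay | 30,000 | euro/QALY |

The nursing-home utility decrement has no published value and defaults
to 0 (configurable). Depression uses the published "overall" annual
probabilities; the sex-specific rows and the trial's 80.87% female share
are stored for sensitivity use.

## Accrual conventions

Both QALYs and costs use a single **end-of-period convention**: periods
(0,12], (12,24] and (24,52] weeks (84/84/196 days; one 84-day period at
the 12-week horizon), each valued at the occupancy of its closing
checkpoint. During the first period, week-12 non-responders are still on
therapy in the incontinent-on-treatment state — incontinent-on-rx equals
persistence(12) minus continent(12). This convention reproduces the three
published QALY gains to ~1e-5, which is why it was adopted; QALYs are
undiscounted (one-year horizon).

Costs, per patient started:

- **Drug:** days 0–28 at the start dose, the rest of period 1 at the
  post-titration cohort mix, later periods at the survivors'
  response-weighted mix; weighted by closing on-treatment occupancy.
- **Pads / visits / labs:** status-conditional daily pad cost and monthly
  visit profiles (a month is 1/12 of the 364-day model year).
- **Comorbidities:** occupancy-weighted annual rates x unit costs x period
  year-fractions. The source table's header says "rate per year" while
  listing 6-month windows for fracture/skin/UTI; the package annualizes
  these x2 by default, as a flagged, configurable convention
  (`annualize_six_month`). Depression is an annual probability times a
  per-patient-year cost; nursing home is admissions per 1000 patient-years
  times a per-admitted-patient-year cost. Untreated patients accrue the
  untreated-column rates for the remainder of the horizon.
- **Productivity** (societal only, entering negatively as a gain relative
  to no treatment): continent occupancy avoids the 21.1% incontinence
  work-hours reduction; on-treatment occupancy, weighted by baseline
  nocturia prevalence (48.58%) and dose-specific week-12 nocturia
  resolution, avoids the 9.2% nocturia work impairment. Both channels are
  valued at hours/week x wage x employment fraction.

The payer total is the sum of direct components; the societal total adds
productivity. The identity `societal = payer + productivity` holds exactly
for every parameter set and is property-tested.

## Sensitivity analysis

`default_scenarios()` encodes the published one-way grid: base case,
perspective and horizon switches, and ±25% multipliers on comorbidity
costs and rates (continent and incontinent separately), utilities,
titration shares, week-12 and week-52 continence, medical service costs,
utilization rates, and the productivity inputs, each ± direction as its
own row. Three perturbations need care:

- **Utilities.** Multiplying the utilities themselves by 1.25 would clamp
  all three states at 1.0 and collapse the QALY gain to zero, leaving no
  comparison at all. Since the QALY gain is linear in the
  baseline-anchored increments (u_state − u_untreated), the utility
  scenario scales those increments, which is well-defined in both
  directions and leaves costs untouched.
- **Week-12 continence.** The scenario scales every arm's pre-attrition
  week-12 responder fraction by the factor, capped at each dose's
  occupancy. Scaling at the response-fraction level (rather than clamping
  each conditional at 1) perturbs all arms by exactly the same factor, so
  the between-arm comparison is not distorted by arm-specific clamping —
  fesoterodine's conditionals (up to 0.9065) would otherwise saturate
  first and artificially erase its advantage in the +25% direction.
- **Week-52 continence** scales the week-52 persistence value, kept below
  the week-24 value to preserve monotonicity.

Perturbed probabilities clamp to [0, 1] with a warning rather than being
rejected; counts and rates above 1 (e.g. admissions per 1000
patient-years) are never clamped. Scenario runs are pure: the base
parameter set is never modified, and re-running the base case after any
scenario is bit-identical.

Under the packaged base case, all 80 grid cells (40 scenarios x 2
comparators) keep fesoterodine cost-saving against both comparators —
including the 12-week-horizon and −25%-week-12-continence rows, where the
published analysis reported finite positive ICERs instead; see "Known
limitations".

## The synthetic-data generator and the microsimulation oracle

`random_parameter_set(seed)` draws every parameter family uniformly within
realistic ranges, constructing validity directly (persistence sorted
descending; week-12 marginals derived from the drawn week-8 marginals and
conditionals; utilities ordered untreated ≤ incontinent ≤ continent). One
root seed feeds an independent sub-stream per family, so adding a family
cannot shift existing draws; the same seed is bit-reproducible. The
generator emulates the *statistical structure* of the published inputs —
per-arm response probabilities at scheduled checkpoints, a non-increasing
persistence curve, status-conditional resource and comorbidity rates,
bounded utilities — not their empirical correlations (e.g. efficacy and
price are drawn independently), so property tests certify the engine's
algebra, not clinical realism.

`microsim()` is an independent individual-level implementation of the same
tree: Bernoulli week-8 response, Bernoulli titration, Bernoulli week-12
response with the branch's conditional, and nested persistence survival
via a single uniform per patient. The test suite requires the cohort
expectations to match the microsimulation within three binomial standard
errors at every checkpoint (n = 100,000), on the base case and under the
week-12 scaling scenario.

## Numerical choices

- Percent inputs are stored as fractions; the fixture keeps the printed
  two-decimal percent precision (decimal commas normalized at authoring
  time). Derivations round half away from zero with a 1e-7 epsilon on the
  scaled value so exact decimal halves (e.g. 20.99% x 1.5 = 31.485%) land
  on the upper side despite binary floating point.
- Dominance uses strict signs: "cost-saving" requires delta cost < 0 and
  delta QALY > 0; a zero QALY delta yields a labelled result
  (cheaper-equal / costlier-equal / equivalent), never a ratio; a
  cheaper-and-worse comparison reports the ICER with an explicit
  south-west flag.
- The model year is 364 days (52 weeks x 7); problem sizes in the test
  suite are 200 random parameter sets for the algebraic properties and
  100,000 simulated patients for the oracle comparison, which keeps the
  full suite under a minute of compute while making the 3-SE band ~0.5
  percentage points wide.

## Known limitations

- **Absolute cost totals.** The published analysis never itemizes its cost
  components, so its exact accrual conventions are unrecoverable. Under
  this package's documented conventions the societal totals are ~1,142 /
  1,484 / 1,220 euros (fesoterodine / tolterodine / solifenacin) versus
  the published 1,937 / 2,089 / 1,960 — the payer totals (~2,755 / 2,802 /
  2,787) bracket them from above, and the arm *orderings* and every
  dominance classification agree. Notably, payer total plus half the
  productivity gain reproduces all three published totals within ~3%,
  suggesting the original spreadsheet weighted the productivity channels
  about half as strongly as the printed 21.1%/9.2% inputs imply; lacking
  a published basis for that factor, the package keeps the printed inputs.
- **Non-dominant sensitivity cells.** For the same reason, the four
  published non-dominant cells (12-week payer ICERs of 574 and 14,568
  euro/QALY; −25% week-12-continence ICERs of 39,447 and 17,814) are not
  reproduced: at the 12-week horizon the untreated fractions are identical
  across arms, and under any status-based accrual the comparator's extra
  pad/comorbidity costs outweigh fesoterodine's extra drug cost, so the
  model yields cost-saving there. The implied incremental costs behind the
  published ICERs (0.2–50 euros) are smaller than the spread between
  plausible accrual conventions.
- **Conditional-column precision.** The printed week-12-given-week-8
  responder conditionals are not the two-decimal rounding of the printed
  marginals' ratio for three of five rows (differences of 0.007–0.015
  percentage points); they appear to derive from unrounded trial data. The
  engine therefore consumes the printed conditionals as given.
- The comorbidity utility decrements are off by default: the published
  QALY gains are reproduced almost exactly without them, so how (or
  whether) they entered the original base case is indeterminate. Both
  modes are supported.
- No probabilistic sensitivity analysis (the source model is explicitly
  deterministic), no discounting (one-year horizon), no out-of-pocket
  costs, and no estimation from patient-level trial data (the
  KHQ-to-utility regression is out of scope; utilities are consumed as
  parameters).
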