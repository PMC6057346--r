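---
title: "The CLABSI risk engine: model, simulator, and surveillance metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The CLABSI risk engine: model, simulator, and surveillance metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clabsitools)
library(dplyr)
```

## The problem

Central-line-associated bloodstream infections (CLABSI) are among the most
consequential healthcare-associated infections: a laboratory-confirmed
bloodstream infection in a patient who had a central venous catheter in place
at, or within 48 hours before, symptom onset, with no other attributable
source. Surveillance programmes keep a *line list* — one row per BSI event —
and need two things from it: a quick, reviewable stratification of each
patient's infection risk, and unit-level metrics (device utilization, and
infections observed relative to predicted) that track whether prevention is
working.

`clabsitools` implements that desk-scale workflow: a categorical rule engine
over a 24-predictor catalog, line-list validation and I/O, a constrained
record simulator for training and testing, and the device utilization ratio
(DUR) and standardized infection ratio (SIR) with period summaries.

## The classification model

The engine is deliberately not a learned model. Each of 24 predictors
(insertion site, rewire, procedure status, comorbidity, bundle compliance,
length of stay, parenteral nutrition, antimicrobial use, renal failure,
surgery, age band, sex, device duration, transfers, co-existing infection,
temperature, APACHE band, ventilation, and four neonatal items: birth weight,
nasal CPAP, blood transfusion, trauma) takes exactly one categorical value
label per record, and the catalog maps every label to one of four ordinal
risk levels:

> No Risk < Low Risk < Mild Risk < High Risk

Scoring a record is therefore 24 independent lookups followed by a tally
$(n_\text{high}, n_\text{mild}, n_\text{low}, n_\text{none})$ with
$n_\text{high}+n_\text{mild}+n_\text{low}+n_\text{none}=24$. The final
category applies a threshold rule with severity precedence:

| Category | Rule | Label | Color |
|---|---|---|---|
| A | $n_\text{high} \ge t$ | high risk | Red |
| B | else $n_\text{mild} \ge t$ | mild risk | Orange |
| C | else $n_\text{low} \ge t$ | low risk | Yellow |
| D | otherwise | no risk | Green |

with threshold $t = 5$ by default. Each level is also reported as a
percentage, $n_\ell / 24 \times 100$, rounded half-up to two decimals.

Three modelling decisions deserve a note, because the source material leaves
them open:

- **Weights.** The rule table speaks of "symptom weights", but the catalog
  assigns only categorical levels. Each predictor value therefore contributes
  weight 1 to its level's tally — the only reading consistent with the
  published x/24 percentage numerators.
- **Category D.** The published wording for the Green row conflicts with the
  prose (which re-states it as "normal count at least five"). D is implemented
  as the fall-through case — no at-risk level reaches the threshold — which
  reproduces every published final category.
- **One comorbidity slot.** The catalog lists twelve comorbidity labels, but a
  record carries exactly one comorbidity value (the highest-risk comorbidity
  present, chosen upstream), because the percentage denominator is always 24.

Two catalog irregularities are preserved rather than smoothed over. *Multiple
insertion* appears in the predictor list but has no published value mapping;
it is loaded with a single implicit No-Risk label (flagged `implicit`), so
every predictor contributes a level without inventing risk assignments.
*Bundle compliance* runs inverted: complying ("Yes") is its no-risk state,
so it is the one predictor without a literal "No Risk" label.

```{r}
catalog <- load_catalog()
catalog
lookup_risk(catalog, "Site of insertion", "femoral")
```

### Non-monotonicity near the threshold

The threshold rule is **not monotone**: escalating a single predictor from a
lower to a higher level can soften the final category. With counts
(4, 3, 5, 12) the record is category C; promoting one Low value to Mild gives
(4, 4, 4, 12), which is category D, because the Low tally drops below the
threshold without the Mild tally reaching it. This is a property of the
published rule set, not an implementation artefact; only escalating a no-risk
predictor to High Risk is guaranteed never to soften the category, and that is
the property the test suite asserts. Reviewers using the color codes should be
aware of this edge behaviour near the cutoff.

### Erratum handling

The published prediction report prints "2/24 = 8.44%" in three cells; under
the report's own formula, 2/24 × 100 = 8.33. The engine computes 8.33. All
eight published profiles nonetheless reproduce their final categories, and
every other printed percentage matches. Similarly, the worked device
utilization example prints 85/153 = 0.38, but 85/153 = 0.5556; the
implementation follows the formula (0.56), and no reported quantity depends on
the misprinted value.

### Rounding

All reported ratios and percentages round **half away from zero** (two
decimals for ratios and percentages, whole points for period reductions).
Base R's `round()` rounds half to even, which would disagree with the
published 16.67 / 20.83 / 54.17 pattern; `round_half_up()` implements the
reporting convention, with an ulp-scale guard against floating-point
representation of exact halves.

## Validation and follow-up

`validate_records()` enforces the BSI event form: patient ID, gender, date of
birth, event type (`"BSI"`) and event date are required; the event date
cannot precede birth; predictor entries must be admissible catalog labels
(matching is case-insensitive and whitespace-tolerant, since line lists are
hand-entered). Problems are reported as a tibble, never raised, and invalid
records land in a rejects section of the cohort summary rather than being
silently dropped. A missing predictor entry means "not assessed" and scores
at the No-Risk level, keeping the denominator at 24 for every patient —
including adults, for whom the four neonatal predictors simply stay at No
Risk. The Medicare number, required only for CMS reporting, is optional
unless `strict_medicare = TRUE`.

After a positive prediction the patient is re-measured until cleared:
`followup_status()` reduces a chronological category history to
`infected-monitor` (latest category A/B/C) or `cleared` (latest D).

```{r}
followup_status(c("A", "A", "D"))
```

## The simulator

`simulate_records()` generates synthetic line lists for training and for
testing the engine. What it emulates:

- every predictor value is drawn from that predictor's admissible catalog
  labels — uniformly by default, since no sampling distribution is published;
  `category_bias` re-weights draws by risk level to synthesise high-risk-rich
  training cohorts;
- clinical interdependencies are enforced as explicit, user-extensible rules.
  The default set constrains the four neonatal predictors to No Risk unless
  the age band is New Born or Premature, and forces a real procedure status
  (Elective/Emergency) whenever a multiple insertion is recorded. A rumoured
  link between parenteral nutrition and gender has no coherent clinical
  reading and is deliberately not encoded;
- demographics are made coherent with the drawn predictors: recorded gender
  follows the Sex predictor, and the date of birth falls in the age band
  implied by the Age predictor relative to the event date (events are placed
  in calendar year 2017, an arbitrary fixed year that keeps output
  deterministic);
- a single seeded RNG is threaded through all draws (and the session RNG
  state is restored afterwards), so identical seeds give byte-identical
  line lists. The default batch is 10 records.

What it does **not** emulate: longitudinal progression (each record is one
cross-sectional event), realistic marginal prevalences (uniform draws make
high-risk values far more common than in real cohorts — with ~50% of binary
predictors at High Risk, most simulated records classify as category A), or
correlations beyond the encoded rules. Passing tests on simulated data
therefore demonstrate *mechanical* correctness of the pipeline — the same
operations run on real and simulated records by construction — not clinical
calibration.

`check_validity()` is the simulator's acceptance gate and works on any line
list: catalog conformance, form validity, and dependency-rule compliance.
Generator output always passes, which the test suite asserts on a
1,000-record run. Contradictory rule configurations (no admissible label left
for a target) and cyclic rule graphs are rejected before any record is
emitted.

```{r}
rec <- simulate_records(n = 10, seed = 42)
check_validity(rec)
score_cohort(rec) |> glance()
```

## Surveillance metrics

Over a monthly census table (month, central-line days CLD, patient days PD,
observed and predicted CLABSI cases):

$$\mathrm{DUR} = \frac{\mathrm{CLD}}{\mathrm{PD}}, \qquad
  \mathrm{SIR} = \frac{\text{observed cases}}{\text{predicted cases}}$$

SIR benchmarks at 1; below 1 means fewer infections than predicted. A zero
denominator is an explicit error in both cases, never a silent `Inf`.
`period_average_sir()` takes the arithmetic mean of monthly SIRs over a
period, and `reduction_and_improvement()` converts two period averages into a
whole-point reduction and the companion "improvement value"
$100 - \text{reduction}$. That improvement figure is the published
convention, retained under an explicit name precisely because it is *not* a
conventional relative risk reduction; interpret it as such.

How `predicted_cases` is obtained is outside the model's scope — it is a
user-supplied column. As a convenience, `predicted_cases_by_month()` counts
category-A classifications of a scored cohort per event month, for programmes
that want the engine itself to supply the prediction feed. No national
risk-adjustment baseline is built in.

```{r}
reduction_and_improvement(0.86, 0.73)
```

## Numerical and design notes

- **Threshold** `t` is configurable per call (`classify_risk(threshold = )`)
  but defaults to 5, the published minimum number of symptom criteria that
  justifies an infected prediction; percentages always use the fixed
  denominator 24.
- **Precedence ties**: a record reaching the threshold at several levels
  (e.g. 6 High and 6 Mild) takes the most severe category — A before B
  before C.
- **Degenerate inputs**: empty line lists score to an empty summary with
  zero totals per category and exit cleanly; a zero-record simulation returns
  an empty (but fully typed) line list; empty month subsets and negative
  thresholds are argument errors.
- **Determinism**: all outputs are pure functions of (inputs, configuration,
  seed); re-running the pipeline writes byte-identical CSVs, with the
  timestamp confined to the run log.
- **Problem sizes** used by the test suite — an exhaustive scan of all 2,925
  level-count compositions, simulator batches up to 1,000 records, and
  25-record oracle comparisons — keep the whole suite in the tens of seconds
  on a laptop while still covering the rule space exhaustively where it is
  finite.

## Known limitations

- The classifier encodes the published rule table verbatim; it has no notion
  of laboratory confirmation (blood-culture positivity or time to
  positivity), which the source defines only narratively.
- The non-monotone threshold behaviour described above is inherited from the
  rule set.
- The simulator's uniform draws are a testing device, not an epidemiological
  model; do not interpret simulated category frequencies as incidence.
- DUR/SIR are computed from supplied census tables; the package ships no
  benchmark population data.
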