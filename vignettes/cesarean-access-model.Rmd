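---
title: "Methods: a microsimulation of CS rates and access to obstetric surgical care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a microsimulation of CS rates and access to obstetric surgical care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(cesim)
```

## The model and its assumptions

`cesim` simulates the reproductive lifetime of women aged 14–49 in India as
a Markov state-transition model with four states — pregnant (utility 0.99),
non-pregnant (1), history of hysterectomy (0.94) and dead (0, absorbing) —
on a one-year cycle over a 35-year horizon. The individual-level (first-order
Monte Carlo) engine tracks each woman's prior-CS count, because placenta
previa, placenta accreta and the choice between an elective repeat cesarean
and a trial of labor after cesarean (TOLAC) all depend on it.

Each cycle a non-pregnant woman becomes pregnant with probability 0.0654
(India's fertility-derived annual rate; assumed uniform nationally). A
pregnancy resolves to term within the same cycle through a delivery-episode
decision tree, dispatched by a single access draw against the strategy's
probability of reaching a CEmOC facility:

* **With access** — in order: antepartum absolute indication (accreta, then
  previa, then a general antepartum indication at 0.0362, treated as
  additive risks with the placental conditions drawn first); otherwise a
  non-indicated antepartum CS at the calibrated probability; otherwise
  labor. Laboring women with a prior CS split into elective repeat CS versus
  TOLAC (per the prior-CS table); TOLAC can end in uterine rupture (0.0169,
  with PPH 0.314 and hysterectomy 0.0819), conversion to intrapartum CS
  (0.739), a non-indicated intrapartum CS, or VBAC. Women without a prior CS
  face an intrapartum absolute indication (0.144), a non-indicated
  intrapartum CS, or a vaginal delivery (PPH 0.009 with mortality 0.006;
  hysterectomy 0.0003). Any cesarean without a condition-specific
  hysterectomy risk carries the emergency-hysterectomy-during-CS probability
  0.0027; any peripartum hysterectomy can lead to ICU admission (0.357) with
  ICU mortality 0.2165. Absolute indications carry their printed antepartum
  (0.00323) and intrapartum (0.0025) mortality probabilities.
* **Without access** — every delivery is vaginal and costs only the vaginal
  delivery; there is no transfusion, hysterectomy or ICU care. Absolute
  indications (antepartum as above; uterine rupture for women with a prior
  CS; the 0.144 intrapartum indication) are unmet: the neonate dies, the
  obstructed-labor sequelae (fistula 0.0001, incontinence 0.0011, stroke
  0.0015) are drawn, and the indication mortalities apply. PPH carries the
  without-access mortality 0.0006.

A cesarean increments the prior-CS count; a hysterectomy (if the woman
survives) moves her to the post-hysterectomy state, from which she cannot
become pregnant. With access the neonate always survives; neonatal death
occurs exactly when an absolute indication is unmet. Costs (2016 USD) are
additive along the path: delivery mode (153.70 vaginal / 745.66 CS, rupture
costed as a CS), PPH management incl. transfusion 79.89 (with access only),
hysterectomy 2241.42, ICU 1172.50.

Two printed near-duplicate parameters — PPH mortality during vaginal
delivery 0.006 (with access) and 0.0006 (without access) — are kept as
distinct inputs exactly as published, although they share one beta
distribution whose mean matches only the smaller value.

### Open points resolved at design time

* The general antepartum indication is additive to the previa/accreta risks
  (placental conditions drawn first), since the indications are declared
  mutually exclusive and the antepartum branch is evaluated before labor.
* ICU admission is reachable only through peripartum hysterectomy, the only
  ICU-entry probability published.
* TOLAC/VBAC are facility-management concepts and are tallied only in the
  with-access tree; a prior-CS woman laboring without access faces the
  rupture risk directly.
* Strategy access probabilities default to the canonical input-table values
  (0.502/0.472/0.557); the slightly different prose values
  (0.4958/0.4719/0.5574) are available via `strategies(access_source = "text")`.
* The single neonatal-death counter absorbs what discussions of such models
  sometimes split into stillbirths and early neonatal deaths; the model has
  no separate stillbirth state.

## Parameters

`param_registry()` holds every input with its baseline, units and sampling
distribution (beta for probabilities, gamma for costs, uniform for
utilities, point for definitional constants). Every decision node in the
trees is binary, so complement probabilities are implicit (`1 - p`), branch
probabilities sum to one identically, and the case of jointly-sampled
sibling probabilities overflowing one cannot arise — which is also why the
Dirichlet family, though supported, is unused by the default registry (a
two-component Dirichlet *is* a beta). Utility distributions are uniform
bands of ±0.01–0.05 centred on the baselines, chosen as modest ranges in the
absence of published ones.

The per-prior-CS-count table (`prior_cs_table()`) is a **synthetic
stand-in**: the source model's exact values are unpublished. Its defaults
were fixed once, before any acceptance measurement: previa/accreta risks
rise with CS count and are anchored so the cohort-weighted marginal event
rates match the published per-10,000-women scale (≈0.0007 and ≈0.0005 per
pregnancy); elective-repeat shares (0 / 0.54 / 0.90 / 0.95 for 0/1/2/3+
prior CS) reflect the documented decline of VBAC in India and near-universal
repeat CS at high counts. Counts above the top row reuse the top row, which
also caps the state space. Users with the exact table substitute it by file.

## Engine, randomness and the exact oracle

`run_cohort()` vectorises the cohort: all randomness is one uniform array
indexed (woman, cycle, slot) with a fixed slot per tree decision, generated
from the run seed. Results are therefore bitwise reproducible, and two
strategies evaluated under the same seed share random numbers — paired
(common-random-numbers) comparisons, since the draw array does not depend on
the strategy. Utilities use the half-cycle convention: each cycle credits
the mean of the within-cycle state utility (pregnant if a pregnancy
occurred) and the exit-state utility, so a woman dying in childbirth
collects half the pregnant-state utility that year and nothing afterwards.
Discounting is off by default (configurable), matching the source analysis,
which states none.

`expected_value()` computes exact expectations by enumerating every leaf of
the delivery tree (`episode_leaves()`, typically ~300 leaves per prior-CS
count) and running a cycle-by-cycle expectation recursion over
{non-pregnant × CS count 0–3+, post-hysterectomy, dead}. Because episode
dynamics depend on history only through the capped count, the recursion is
exact at any horizon — a strictly stronger oracle than short-horizon path
enumeration. The test suite holds the Monte Carlo engine to within 4
standard errors of this evaluator across randomized parameter tables at
horizons 1–3, and the two implementations are deliberately independent
codings of the same wiring.

## Calibration

The non-indicated antepartum/intrapartum CS probabilities are unobservable
and are estimated by grid search: both move together along their published
baseline ratio (0.0094 : 0.018) on a regular grid (default fine step 0.001,
tolerance 0.005), with the CS-per-full-term-pregnancy rate evaluated by the
exact recursion so selection is deterministic and idempotent. A coarse pass
at ten times the step brackets the optimum before the fine pass; because the
achieved rate is monotone in the sweep scale (property-tested), this selects
the same point as the full regular grid. A target at or below the
indicated-only **floor** (the rate with both probabilities zero) yields zero
non-indicated CS and a `floor_constrained` flag — the model's form of the
assumption that settings below the recommended CS rate perform no
unindicated cesareans.

Under the published indication probabilities this floor binds for two of the
three strategies: the 0.739 TOLAC-conversion probability and the 0.144
intrapartum indication alone push the indicated-only rate to ≈0.18 at
national access (≈0.154 rural), so the 17.2% and 12.8% targets are met only
approximately (at the floor), while the urban 28.2% target calibrates
exactly. This is a structural property of the printed inputs under this
tree wiring, not a search failure, and it is reported honestly by
`calibrate()` rather than absorbed by loosening the tolerance.

## Reporting conventions

`summarize_outcomes()` reports events per 10,000 women **per year** (the
published table's arithmetic convention: its per-10k pregnancy count equals
one annual cycle of the fertility rate, and its national totals are annual),
alongside lifetime per-10k counts and a national extrapolation using a
reference population of 3.25×10⁸ women of reproductive age, recovered from
the published (per-10k, national) reporting pair. MMR is maternal deaths per
100,000 live births and NMR neonatal deaths per 1,000 live births, both
undefined (NA, never zero) when there are no live births.

## Sensitivity analyses

One-way sweeps (±50% of baseline by default, clipped to units-legal bounds;
published ranges are not available) re-evaluate all strategies exactly, so
sweeps are smooth and the optimal-strategy label is free of Monte Carlo
jitter. The two-way analysis calibrates a custom strategy for every
(access, CS-rate) cell, flags infeasible cells, and labels each cell with
the NMB-optimal strategy among the bases plus the cell's own. The PSA
redraws every registry parameter (default 1,000 draws × 2,000 women, a
desk-scale compromise; the cohort size trades Monte Carlo error per draw
against draw count), holding the calibrated non-indicated probabilities
fixed as strategy attributes.

## What the synthetic fixtures do and do not show

`random_parameter_table()` generates registry-valid inputs (probabilities on
(0,1), log-uniform costs, utility bands) used to property-test leaf-sum
conservation, tally conservation, the QALY ceiling and Monte Carlo/oracle
agreement on inputs the implementation was never tuned to;
`degenerate_scenarios()` pins closed-form boundary cases (zero fertility,
certain uncomplicated pregnancy, unmet certain indication, certain
first-delivery death). Passing these shows the *arithmetic* of the model is
right under its stated wiring. It does not validate the wiring against real
Indian data: fertility is age-invariant, background mortality, sepsis,
abortion and late-postpartum events are out of scope, and neonatal outcomes
enter only as counted events.

## Known limitations

* **Maternal-only QALYs.** Neonatal deaths are tallied but carry no QALY
  weight by scope. Since access to CEmOC mostly saves neonates in this
  structure (the printed indication-mortality probabilities apply with and
  without access), between-strategy QALY differences are small and driven by
  hysterectomy/ICU harms of additional cesareans; at the default threshold
  the rural strategy is cost-effective, and the published frontier ordering
  (urban strategy optimal with an ICER of a few hundred USD/QALY) is not
  reproducible under this scope — it would require valuing neonatal
  survival, whose QALY weight is of the order of a full lifetime per death
  averted. The frontier machinery itself is validated against a brute-force
  convex-hull oracle.
* **Indicated-only floors above two calibration targets**, as discussed
  above.
* The simulated NMR (~100 per 1,000 live births at the national strategy) is
  the direct consequence of "unmet absolute indication ⇒ neonatal death"
  with an ~18% indication incidence and ~50% access; published NMR values an
  order of magnitude lower imply additional survival pathways not derivable
  from the printed inputs.
* Problem sizes: default cohorts of 10,000 women × 35 cycles; oracle
  comparisons in the test suite use 2,000–5,000 women at horizons 1–3 and
  the PSA examples run scaled down. These sizes are the package's chosen
  defaults for desk-scale reproducibility.

## A small worked run

```{r, eval = FALSE}
cal <- calibrate_strategies()
res <- lapply(1:3, function(i)
  run_cohort(cal$strategies[i, ], n_women = 10000, seed = 1))
build_frontier(res)
summarize_outcomes(res[[1]])
```
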