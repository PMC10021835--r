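# cesim

Obstetric surgical care in India sits between two failures: women who cannot
reach a facility capable of a cesarean section (CS) when one is medically
necessary, and women who receive a CS without indication and carry the
compounding risks — placenta previa, placenta accreta, hemorrhage, peripartum
hysterectomy, ICU admission — into every later pregnancy. `cesim` is a
first-order Monte Carlo state-transition microsimulation built to compare
health-policy strategies that couple a population's probability of access to
comprehensive emergency obstetric care (CEmOC) with an overall CS rate, from
a societal cost perspective in 2016 USD. It is written for health economists
and health-systems researchers who want the full pipeline — parameter
registry, individual-level simulation, calibration, cost-effectiveness
analysis, sensitivity analyses — as tested, reusable R functions.

## The model

Women enter at age 14 and cycle annually to age 49 (35 one-year cycles)
through four health states with utilities

* pregnant, u = 0.99
* non-pregnant, u = 1
* history of hysterectomy, u = 0.94
* dead, u = 0 (absorbing),

with a half-cycle correction (each cycle credits the mean of the within-cycle
and exit-state utilities). Non-pregnant women become pregnant with annual
probability 0.0654. A pregnancy resolves within the cycle through a
delivery-episode decision tree: an access draw (the strategy's CEmOC access
probability) dispatches to a with-access tree — antepartum absolute
indications (previa/accreta risk rising with prior-CS count, plus a general
indication), non-indicated antepartum CS, then labor with TOLAC/elective
repeat CS for women with a prior CS or intrapartum indication otherwise,
with PPH, hysterectomy, ICU and mortality sub-branches — or a no-access tree
in which every delivery is vaginal, no transfusion/hysterectomy/ICU care
exists, an unmet absolute indication is fatal to the neonate, and
obstructed-labor sequelae (fistula, incontinence, stroke) can follow. Every
branch probability, cost and utility is a registry parameter with a
beta/gamma/uniform sampling distribution for probabilistic sensitivity
analysis.

Three strategies extend observed Indian access/CS-rate pairs to the whole
population: **A** national average (50.2% access, 17.2% CS rate), **B**
rural (47.2%, 12.8%), **C** urban (55.7%, 28.2%). The unobservable
non-indicated CS probabilities are estimated by regular-interval grid
calibration until the simulated CS-per-pregnancy rate matches each
strategy's target; strategies are compared by incremental
cost-effectiveness ratio (ICER = Δcost/ΔQALY versus the next-least-expensive
non-dominated strategy) against a willingness-to-pay threshold of $1,939.61
per QALY (India's 2017 GDP per capita).

A distinctive engineering feature: alongside the Monte Carlo engine the
package ships an exact expected-value evaluator (`expected_value()`) that
enumerates every delivery-tree leaf and runs a per-cycle expectation
recursion over the capped state space. It is the verification oracle for the
simulator in the test suite and the jitter-free objective for calibration
and deterministic sweeps.

## Worked example

```r
library(cesim)

cal <- calibrate_strategies()            # grid-calibrate A, B, C
dplyr::bind_rows(lapply(cal$calibrations, glance))
#>   strategy_id target achieved floor floor_constrained converged
#> 1 A_national   0.172    0.180 0.180 TRUE              FALSE
#> 2 B_rural      0.128    0.154 0.154 TRUE              FALSE
#> 3 C_urban      0.282    0.282 0.245 FALSE             TRUE

res <- lapply(1:3, function(i)
  run_cohort(cal$strategies[i, ], n_women = 10000, seed = 1))
build_frontier(res)
#>   strategy_id    cost    qaly     icer   status
#> 1     B_rural 556.860 34.9132       NA frontier
#> 2  A_national 592.991 34.9152  18401.6 frontier
#> 3     C_urban 736.040 34.9157 286958.1 frontier

summarize_outcomes(res[[1]])   # events per 10,000 women, national scale-up
#>   pregnancies_to_term  per_10k_year 646.  national_annual 20,984,786
#>   cesarean_sections    per_10k_year 116.  national_annual  3,781,143
#>   Maternal mortality: 82.9 per 100,000 live births
```

Reading the numbers: the national and rural targets lie *below* the CS rate
already implied by medical indication alone under the published indication
probabilities (the calibration `floor`), so both strategies run with zero
non-indicated CS — the model's restatement of the assumption that rural
settings below the recommended CS rate perform no unindicated cesareans. The
urban strategy calibrates exactly to 28.2%. On the cost side the urban
strategy buys its extra access with many more cesareans and their sequelae;
because this implementation accrues QALYs to mothers only (neonatal survival
is tallied as an event, not valued in QALYs — see the methods vignette),
between-strategy QALY differences are small and the rural strategy is
cost-effective at the default threshold. Event tallies per 10,000 women per
year, national annual extrapolations to the 3.25×10⁸ women of reproductive
age, and MMR/NMR are produced by `summarize_outcomes()`;
`one_way_sensitivity()`, `two_way_sensitivity()` and `run_psa()` cover the
sensitivity analyses, and `run_full_analysis()` writes the whole bundle with
a reproducibility manifest.

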