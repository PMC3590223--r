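---
title: "Methods: a decision-analytic cost-effectiveness model of TOLAC versus ERCD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a decision-analytic cost-effectiveness model of TOLAC versus ERCD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tolaccea)
```

## The decision problem

For a low-risk woman with one previous caesarean delivery, the clinical
choice is between a trial of labour after caesarean (TOLAC) and an elective
repeat caesarean delivery (ERCD). `tolaccea` implements a two-arm decision
tree over a six-week postpartum horizon. In the TOLAC arm a woman either
succeeds — delivering vaginally, unassisted or by ventouse — or fails the
trial and undergoes an emergency caesarean section. Each of the four
terminal delivery pathways (unassisted vaginal, ventouse, emergency
caesarean, elective repeat caesarean) then resolves to one of three health
states: complication-free (*healthy*), a composite maternal *morbidity*
state, or maternal *death*. Payoffs are per-woman cost in euro (2010 health
system perspective, no discounting over the short horizon) and
quality-adjusted life years (QALYs).

The five maternal complications in the model — uterine rupture,
hysterectomy, operative injury, blood transfusion and postpartum
endometritis — are pooled into one composite morbidity state per pathway.
The pooling weight of each complication is its conditional share of all
morbidities in that pathway, so the composite payoff is the
conditional-weight average of the five complication-specific payoffs; this
is the `morbidity_weights` field of the configuration.

## Parameters and their defaults

All inputs live in a validated `cea_config` object, round-trippable through
YAML (`save_config()` / `load_config()`; the bundled base case is at
`system.file("extdata", "paper_base_case.yaml", package = "tolaccea")`).
The base case, `default_paper_config()`, encodes the published tables:

* **Branch probabilities.** TOLAC success 0.666; ventouse given success
  0.13; per-pathway morbidity probabilities stored at full precision from
  the 10,000-woman cohort table (124/5797, 19/867, 465/3336, 290/10000);
  maternal mortality 1/10,000 in the ERCD arm and 0 elsewhere, reflecting
  that death was essentially absent after a trial of labour in the source
  data. The published success rate is quoted both as "66.6%" and, via the
  cohort table, as 66.64%; we store 0.666, which makes the projected cohort
  show 6,660 successful trials rather than the printed 6,664 — a
  presentational difference with no effect at the reported precision.
* **Disutility profiles** (per-day decrement from full health, with a
  duration in days): unassisted vaginal 0.41 for 7 days; caesarean
  (emergency or elective) 0.58 for 21 days; uterine rupture and
  hysterectomy 0.58/21; operative injury 0.53/21; blood transfusion
  0.41/7; endometritis 0.38/14. Each total is the sum of its four
  Quality of Well-Being components within a 0.005 rounding tolerance, and
  the validator enforces exactly that.
* **Delivery costs** (consumables + staff + DRG bed-days beyond the two
  days shared by both arms): unassisted vaginal EUR 627.94; ventouse
  1,637.09 (one excess day at 883/day); emergency caesarean 4,423.39 and
  elective repeat caesarean 4,095.01 (three excess days at 1,161/day).
* **Complication costs**: add-on costs excluding mode of delivery
  (1,235.33 / 905.94 / 355.25 / 596.63 / 49.50), with complication lengths
  of stay of 5, 11, 6 and 5 days for rupture, hysterectomy, operative
  injury and transfusion.
* **Frame**: 42-day horizon, cohort of 10,000 women per arm,
  willingness-to-pay threshold EUR 45,000 per QALY.

## QALY integration

Utilities sit on a linear 0 (death) to 1 (full health) scale, constant
within days. A profile with per-day disutility $d$ and duration $k$ gives
the trajectory $u_t = 1 - d$ for $t \le \min(k, H)$ and $u_t = 1$
afterwards, with $H = 42$ days. On the headline *horizon* basis the QALY
value is $\frac{1}{H}\sum_t u_t$; on the *annual* basis full health is
assumed from day $H+1$ to day 365 and the sum is divided by 365. The
successful-vaginal-delivery profile yields
$(7 \times 0.59 + 35)/42 = 0.93$ over six weeks and
$(7 \times 0.59 + 358)/365 = 0.99$ over one year, reproducing the published
worked example, and this is the package's standing check that the
integration scale is right.

## Design choices where the source was silent

These were genuinely open points; each is a package decision, configurable
where sensible:

* **Ventouse disutility.** The published disutility table has no ventouse
  row. The default assigns the caesarean profile (0.58 for 21 days) to the
  ventouse pathway; with the milder vaginal profile instead, the TOLAC arm
  expectation rises to about 0.86 and no published figure supports it. The
  profile is an ordinary config field, so the alternative is one edit away.
* **Combining concurrent disutilities.** How a delivery decrement and a
  complication decrement interact was not stated. The default
  `max_disutility` rule takes the per-day worst state (minimum utility),
  because additive stacking of QWB components can exceed total health; an
  `additive_capped` rule (sum of decrements, utility floored at 0) is
  selectable. The max rule also reproduces the published TOLAC expectation
  of 0.84 QALYs; the additive rule gives 0.83.
* **Endometritis length of stay.** Stated for the other four complications
  only. Endometritis is costed as a pure add-on (EUR 49.50) with no stay
  extension (`los_days = NA`), consistent with its placement among the
  add-on costs.
* **Extended-stay billing for complications.** The source gives
  complication stays but not the billing rule. We bill days beyond the
  delivery pathway's own baseline stay at that pathway's DRG bed-day rate,
  the natural extension of the "days beyond shared" rule; the unassisted
  vaginal pathway, which has no printed rate, uses the ventouse rate of
  EUR 883 (`complication_bed_day_rate`).
* **Cost of maternal death.** Not priced; a death terminal carries its
  pathway's delivery cost and zero QALYs.
* **Durations and weights under uncertainty.** The probabilistic analysis
  samples per-day disutilities but holds durations and the conditional
  morbidity weights fixed: durations are integer day counts with no
  published spread, and the weights are compositional (they must stay on
  the simplex), so jittering them independently would manufacture
  structure the source never quantified.

## Known irreproducibility of the expected arm costs

The published expected costs per woman (EUR 1,830.73 TOLAC, 4,039.87 ERCD
deterministic) cannot be reconstructed from the printed cost and cohort
tables under any weighting: the ERCD expectation sits *below* the ERCD
delivery cost of 4,095.01 that every woman in that arm incurs, before any
complication is added. This package therefore reproduces the component
arithmetic exactly (all four per-woman delivery costs) and asserts the
qualitative cost claim — the TOLAC arm is substantially cheaper in
expectation (about EUR 2,037 versus 4,115, a saving of roughly 2,078) —
rather than the unprintable expectations. Similarly, the published ERCD
expectation of 0.70 QALYs is unreachable from the published disutility
table: the ERCD healthy state alone evaluates to exactly
$(21 \times 0.42 + 21)/42 = 0.71$, and the morbidity state equals 0.71
under the default rule, so the arm expectation is 0.7099 and rounds to
0.71 under every combination rule we examined (additive: 0.706; a
sequential variant: 0.705). The dominance conclusion — TOLAC cheaper *and*
more effective — is insensitive to all of this.

## Probabilistic sensitivity analysis

The supplementary distribution tables of the source are not available, so
the bundled spreads are package defaults chosen to keep parameter
uncertainty realistic rather than vestigial: normal distributions with a
10% coefficient of variation on every monetary parameter (resampled, not
clipped, if a draw is negative — up to 100 rounds); normals with an
absolute standard error of 0.02 on every per-day disutility (clipped to
[0, 1], and the QWB components rescaled proportionally so the profile
invariant survives the draw); and beta distributions on branch
probabilities, parameterised by the method of moments
($\nu = m(1-m)/se^2 - 1$, $\alpha = m\nu$, $\beta = (1-m)\nu$) with
binomial standard errors $\sqrt{p(1-p)/n}$ at the cohort denominators
(10,000; 6,664; 5,797; 867; 3,336; 10,000). Structural zeros (death after
a trial of labour) stay fixed.

Sampling uses one master seed; parameters are drawn in a fixed registry
order as vectorised per-parameter streams of `n_iter` values, so iteration
$i$ is row $i$ of the draw matrix, runs are bit-reproducible, and a
zero-spread analysis collapses to the deterministic result exactly (a
tested identity, not an approximation). Each iteration re-evaluates the
tree; increments are TOLAC minus ERCD. Quadrants of the
cost-effectiveness plane put effects east–west and costs north–south;
exact zeros are resolved against the intervention (zero effect counts
west, zero cost north), a convention that only matters on a set of
measure zero. Cost-effectiveness at threshold $\lambda$ is positive net
monetary benefit $\lambda \Delta E - \Delta C > 0$, and the acceptability
curve sweeps $\lambda$. With the defaults, all 10,000 iterations fall in
the south-east quadrant — TOLAC cheaper and more effective — and the
probability of cost-effectiveness at EUR 45,000/QALY is 100%, matching
the published probabilistic result.

## The microsimulation oracle

`simulate_cohort()` is the model's independent check on itself: women are
allocated to the expanded terminals (pathway × healthy/complication/death)
by a single multinomial draw over the chain-rule probabilities —
equivalent to sequential sampling at each chance node, but exact about the
conditional structure — and each woman carries her terminal's cost and
QALY payoff. Empirical means converge to `evaluate_tree()`'s expectations
at the usual $1/\sqrt{n}$ rate; the test suite checks agreement within 3
Monte Carlo standard errors at $n = 200{,}000$ and complication
frequencies against the conditional weights by a chi-square test.
`random_config()` supplies internally consistent perturbed parameter sets
(lognormal on money, logit-jitter on probabilities and disutilities,
renormalised weights) for property-style tests, and
`parameter_recovery_report()` closes the loop by re-estimating branch
probabilities from simulated cohorts.

### What the synthetic layers do and do not show

They validate the *internal* consistency of the arithmetic: tree
expectations, cohort projections and simulated individuals all agree. They
cannot validate the epidemiology — morbidity incidence imported from a
North American systematic review, Irish costing aggregates, off-the-shelf
community utility weights — so a green test suite says the model computes
its stated inputs correctly, not that those inputs transfer to any
particular population.

## Problem sizes and numerical conventions

The packaged analyses use 10,000 PSA iterations (the published simulation
size; about 20 seconds on one core), a 10,000-woman cohort projection with
largest-remainder rounding so counts conserve the cohort exactly, and a
200,000-woman microsimulation for the convergence check. Money is held at
full precision internally and rounded to 2 decimals only in reports, as
are QALYs. Chance-node closure is enforced at $10^{-12}$; the composite
weights tolerate the 0.02 slack that printed percentage columns
accumulate. Degenerate inputs are defined, not special-cased: zero
morbidity probabilities drop the composite state, a zero-spread PSA is the
deterministic model, and `n = 0` cohorts project to all-zero counts.

## Limitations

Neonatal and long-term maternal outcomes, thromboembolism, incontinence,
placenta accreta and comorbidity interactions are outside the model, as in
the source analysis; the six-week horizon excludes any later consequence
of either delivery mode. The expected-cost discrepancy described above
means headline *cost levels* should be read as this package's
reconstruction from the printed components, not as the published point
estimates; increments and the dominance conclusion are the robust
quantities.
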