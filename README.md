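# tolaccea

A decision-analytic cost-effectiveness model comparing a **trial of labour
after caesarean (TOLAC)** with an **elective repeat caesarean delivery
(ERCD)** for low-risk women with one previous caesarean, over a six-week
postpartum horizon, from the perspective of the Irish health system
(2010 euro). It is written for health economists and perinatal
epidemiologists who want the published analysis as tested, configurable
code rather than a spreadsheet.

## The model

A two-arm decision tree: a TOLAC either succeeds (unassisted vaginal or
ventouse delivery) or fails, ending in an emergency caesarean; the ERCD arm
has a single pathway. Every terminal pathway resolves to *healthy*, a
composite *morbidity* state (uterine rupture, hysterectomy, operative
injury, blood transfusion, endometritis — pooled by their conditional
shares), or *death*. Payoffs per woman:

* **Cost** — bottom-up components (consumables, staff) plus a top-down DRG
  bed-day rate for each day of stay beyond the two days common to both
  arms; complications add their printed add-on cost and any stay beyond
  the pathway baseline.
* **QALYs** — each health state carries a per-day disutility *d* lasting
  *k* days; utility is *u<sub>t</sub>* = 1 − *d* while the decrement lasts
  and 1 afterwards, and QALYs over the horizon *H* = 42 days are
  (Σ *u<sub>t</sub>*)/*H*.

Strategies are compared by the incremental cost-effectiveness ratio
ΔC/ΔE with dominance classification, and by net monetary benefit
λΔE − ΔC at a willingness-to-pay threshold λ = EUR 45,000/QALY.
Parameter uncertainty is propagated by Monte Carlo probabilistic
sensitivity analysis (normal costs and disutilities, beta branch
probabilities via method-of-moments) onto the cost-effectiveness plane and
acceptability curve. An individual-level microsimulation
(`simulate_cohort()`) provides an independent convergence check on the
tree's expectations. See `vignettes/model-methods.Rmd` for the full
methods account.

## Worked example

```r
library(tolaccea)

config <- default_paper_config()   # the published base case, validated
ev <- evaluate_tree(config)
ev
#> <cea_evaluation>
#>   TOLAC expected cost EUR    2036.75 | expected QALYs 0.8373
#>   ERCD  expected cost EUR    4114.74 | expected QALYs 0.7099

icer(ev$tolac, ev$ercd, config$wtp_threshold)
#> <cea_icer> dCost EUR -2077.99 | dQALY 0.1274 | TOLAC dominates | cost-effective at EUR 45,000/QALY: TRUE

psa <- run_psa(config, n_iter = 10000, seed = 1)
psa
#> <cea_psa> 10000 iterations (seed 1)
#>   mean TOLAC: EUR 2036.08, 0.8372 QALYs | mean ERCD: EUR 4122.01, 0.7097 QALYs
#>   quadrants: NE 0.0%, SE 100.0%, SW 0.0%, NW 0.0%
#>   P(cost-effective at EUR 45,000/QALY) = 1.000
```

A woman attempting a TOLAC is expected to accrue 0.84 QALYs of the 1.0
available in the six-week window versus 0.71 for an ERCD, at roughly half
the cost (EUR 2,037 versus 4,115), so TOLAC *dominates*: it is cheaper and
more effective, and no trade-off ratio is needed. Every one of the 10,000
probabilistic iterations lands in the south-east quadrant of the
cost-effectiveness plane, so the probability that TOLAC is cost-effective
at EUR 45,000/QALY is 100%. `cohort_counts(config)` projects the
10,000-woman cohort onto the terminals (e.g. 6,660 successful trials, 21
uterine ruptures among unassisted vaginal deliveries), `run_all(config,
out_dir, seed, n_iter)` writes the full table/plane/CEAC report bundle,
and `plot_ce_plane(psa)` / `plot_ceac(ceac(psa))` draw the figures. A thin
command-line wrapper with `evaluate`, `psa`, `simulate`, `report` and
`validate-config` subcommands is installed at `inst/cli/tolaccea.R`.

### A note on reproducing the published cost levels

The published *component* costs reproduce exactly (unassisted vaginal
EUR 627.94; ventouse 1,637.09; emergency caesarean 4,423.39; elective
repeat caesarean 4,095.01), as does the QALY worked example (0.93 over six
weeks, 0.99 over one year). The published *expected arm costs*
(EUR 1,830.73 TOLAC / 4,039.87 ERCD) are, however, not reconstructible
from those printed inputs — the ERCD expectation lies below the ERCD
delivery cost that every woman in that arm incurs — so this package
targets the qualitative cost claim (TOLAC strictly cheaper in expectation)
together with the exact component arithmetic, and documents the
discrepancy rather than calibrating to it. The published ERCD expectation
of 0.70 QALYs likewise evaluates to 0.71 from the printed disutility
table. The dominance conclusion is unaffected.

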