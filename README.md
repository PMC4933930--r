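# niptscreen

Cost-consequence modelling of contingent non-invasive prenatal testing
(NIPT) in a national Down's syndrome screening programme.

## What it is for

Screening committees deciding whether to insert NIPT — a highly accurate
cell-free-DNA screening test — between first-line risk assessment
(combined/quadruple test) and invasive prenatal diagnosis (IPD) need to
know what the change does to costs, case detection, invasive-test volumes
and procedure-related miscarriages. `niptscreen` answers that with a
decision-tree model of **seven testing strategies**: the current pathway
(IPD offered at risk ≥ 1/150) and contingent NIPT at risk thresholds
1/150, 1/500 and 1/1000, each with or without a direct-to-IPD option for
high-risk women.

For a screening population *N* with uptake *u*, high-risk proportion
*π_h* and threshold-dependent intermediate proportion *π_m*, the tree
computes expected test volumes, e.g. under contingent NIPT

> n_NIPT = N·u·(π_h·u_nipt + π_m·u_int),  detections = direct-IPD
> positives + NIPT positives,  miscarriages = (all invasive tests) × 0.5%,

with costs for the screening pathway only, in 2012/13 GBP (screening
test mix, NIPT at laboratory + counselling + phlebotomy with
repeat-rate-weighted laboratory cost, invasive tests at £650). On top of
the deterministic model sit a probabilistic sensitivity analysis
(beta/gamma/Dirichlet input distributions, percentile intervals), cost-
neutral NIPT price solving, one-way threshold analysis with uptake
coupling, uptake scenario tables, and an individual-level synthetic
cohort generator with exact (Clopper-Pearson) re-estimation of every
input proportion.

Two parameter presets ship: `"national"` (national statistics, 698 500
pregnancies/year) and `"rapid"` (an eight-unit prospective cohort).

## Worked example

```r
library(niptscreen)
national <- screening_params("national")

format_results_table(pathway_table(national))[
  , c("strategy", "n_nipt", "cost_nipt_k", "total_cost_k",
      "n_ds_detected", "n_miscarriage")]
#>                        strategy n_nipt cost_nipt_k total_cost_k n_ds_detected n_miscarriage
#> 1                       Current      0           0        17045           580          28.7
#> 2                 NIPT >=1/1000  32160        8939        23827           835          12.1
#> 3                  NIPT >=1/500  18795        5224        20102           816          12.0
#> 4                  NIPT >=1/150   7711        2143        16999           774          11.9
#> 5 NIPT >=1/1000 - no direct IPD  34128        9486        23230           826           3.3
#> 6  NIPT >=1/500 - no direct IPD  20762        5771        19504           807           3.2
#> 7  NIPT >=1/150 - no direct IPD   9678        2690        16402           765           3.1
```

Reading the 1/150 row against the current pathway: 7 711 NIPT tests
(£2 143k) replace most invasive testing — invasive tests fall from
5 743 to 2 375, procedure-related miscarriages from 28.7 to 11.9 — while
detecting ~194 more cases, at essentially unchanged total cost
(£16 999k vs £17 045k). The incremental view:

```r
format_results_table(incremental_table(national))[, c(1, 2, 4, 5, 6)]
#>                        strategy d_ds_detected ipd_avoided miscarriage_avoided d_total_cost_k
#> 1                 NIPT >=1/1000           255        3319                16.6           6782
#> 2                  NIPT >=1/500           236        3334                16.7           3057
#> 3                  NIPT >=1/150           194        3368                16.8            -46
#> 4 NIPT >=1/1000 - no direct IPD           246        5079                25.4           6185
#> 5  NIPT >=1/500 - no direct IPD           227        5095                25.5           2460
#> 6  NIPT >=1/150 - no direct IPD           185        5128                25.6           -643
```

At the current 1/150 threshold NIPT is (just) cost saving; lowering the
threshold buys little extra detection at sharply higher cost. How robust
is the saving?

```r
# price at which the 1/150 strategy stops saving money
solve_cost_neutral_price(national, strategy("contingent", 150, TRUE))
#> [1] 255.8994     # i.e. cost neutral at an NIPT laboratory price of ~£256
solve_cost_neutral_price(national, strategy("contingent", 150, FALSE))
#> [1] 315.6757     # ~£316 without the direct-IPD option

# NIPT uptake below which it stops saving money, with total high-risk
# further-testing uptake held at 92.5%
q <- threshold_query(strategy("contingent", 150, TRUE), "u_nipt_high",
                     coupling = "complement_within_further_testing")
one_way_threshold(national, q)
#> [1] 0.7126871    # ~71.3%

# uncertainty intervals by probabilistic sensitivity analysis
psa <- run_psa(national, psa_config(n_sims = 1000, seed = 42),
               strategies = list("1/150"))
subset(psa$summary, field %in% c("ipd_avoided", "d_total_cost"))
#>       strategy        field        point          lo         hi
#> 3 NIPT >=1/150  ipd_avoided   3368.04866     2864.90    3875.28
#> 5 NIPT >=1/150 d_total_cost -45983.04682 -1165092.76 1129744.07
```

Synthetic cohorts close the loop between the individual level and the
tree:

```r
co <- simulate_cohort(national, n_booked = 40527,
                      scenario = strategy("contingent", 150, TRUE),
                      seed = 1)
est <- estimate_params(co)
subset(est$estimates, field == "u_nipt_high")
#>         field   x   n  estimate     lower     upper estimable
#> 7 u_nipt_high 473 638 0.7413793 0.7055502 0.7749574      TRUE
```

A command-line interface wraps the same operations
(`run_cli(c("table3", "--preset", "national"))`; subcommands `evaluate`,
`table3`, `table4`, `psa`, `threshold`, `price-sweep`, `scenarios`,
`simulate`, `estimate`).

## Layout

- `R/params.R` — parameter sets, presets, flat key-value config I/O
- `R/strategies.R` — the seven testing strategies
- `R/decision_model.R` — the decision tree, pathway and incremental tables
- `R/psa.R` — probabilistic sensitivity analysis
- `R/sensitivity.R` — cost-neutral price, one-way thresholds, price sweep,
  uptake scenarios
- `R/cohort.R` — synthetic cohorts, parameter re-estimation, exact
  diagnostic accuracy
- `R/cli.R` — command-line interface and presentation rounding
- `vignettes/cost-consequence-methods.Rmd` — model assumptions, PSA
  distribution choices, generator design, numerical conventions
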