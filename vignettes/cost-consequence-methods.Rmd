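---
title: "Methods: cost-consequence modelling of contingent NIPT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-consequence modelling of contingent NIPT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(niptscreen)
```

## The problem

A national Down's syndrome screening programme offers every pregnant woman
a first-line risk assessment (the first-trimester combined test or, for
later bookers, the second-trimester quadruple test). Women whose risk
exceeds 1/150 are offered invasive prenatal diagnosis (IPD: chorionic
villus sampling or amniocentesis), which is diagnostic but carries a
procedure-related miscarriage risk. Non-invasive prenatal testing (NIPT)
of cell-free DNA in maternal plasma is a far more accurate *screening*
test that can be inserted between the two: offered contingently to women
above a chosen risk threshold, with invasive testing reserved for
confirmation of a positive NIPT result.

`niptscreen` evaluates that insertion as a **cost-consequence analysis**:
rather than collapsing everything into a cost-effectiveness ratio or
QALYs, it reports costs alongside the disaggregated outcomes a screening
committee actually weighs — Down's syndrome cases detected, invasive
tests performed, and iatrogenic miscarriages — for seven testing
strategies: the current pathway, and contingent NIPT at risk thresholds
1/150, 1/500 and 1/1000, each with or without the option for high-risk
women to go directly to invasive testing.

## The decision model

The model is a decision tree evaluated with expected-value (cohort-mean)
arithmetic. For a screening population $N$ with screening uptake
$u_s$, high-risk proportion $\pi_h$ (risk $\ge 1/150$) and
intermediate-band proportion $\pi_m$ (set by the threshold: none at
1/150, the 1/151–1/500 band at 1/500, the 1/151–1/1000 band at 1/1000):

* current pathway: $n_{IPD} = N u_s \pi_h u_{IPD}$, detections
  $n_{IPD} \cdot p^{+}_{IPD}$;
* contingent pathway: NIPT tests
  $n_{NIPT} = N u_s(\pi_h u_n + \pi_m u_m)$, direct invasive tests
  $N u_s \pi_h u_d$, NIPT positives from band-specific positivity rates,
  confirmatory invasive tests = positives $\times$ confirmation uptake;
  detections = direct-IPD positives + NIPT positives.

Miscarriages are (invasive tests) $\times$ 0.5%. Costs cover the
screening pathway only — first-line test, NIPT (laboratory + midwife
counselling + phlebotomy, with repeats incurring the laboratory
component only), and invasive tests at £650 — in 2012/13 GBP with no
discounting (the horizon is one pregnancy). Decisions after diagnosis
(termination/continuation) are deliberately outside the cost scope.

Fractional women are carried exactly throughout and only rounded for
presentation (`format_results_table()`: £000 half-away-from-zero,
integer counts, one decimal for miscarriages). This is why incremental
miscarriages can legitimately print as "16.8".

Two parameter presets ship (`screening_params()`): `"national"`
(national uptake 66.2%, test mix 86.9/13.1, band frequencies 2.3/3.4/7.5%,
population 698 500) and `"rapid"` (the eight-unit cohort: uptake 78.7%,
mix 88.5/11.5, bands 2.7/3.2/7.1%). NIPT/invasive behaviour
(uptakes 72.5/70.5/91/20/54/80.4%, positivity 4/0.38/0.25/7.9%,
confirmation positivity 90.1%, direct-test positivity 21.9%, repeat rate
1.2%) and unit costs are common to both, since only the study measured
them. The NIPT-pathway screening uptake equals the current-pathway
uptake — a single field — because the programme's own uptake is assumed
unchanged by introducing NIPT.

```{r table3}
national <- screening_params("national")
format_results_table(pathway_table(national))[, c(1, 5, 6, 10:13)]
```

### A worked identity: the NIPT unit cost

The repeat rate enters the unit cost as laboratory-only:
$c_{NIPT} = c_{lab} + c_{mid} + c_{phl} + p_{rep} c_{lab} = 250 + 15.96
+ 9 + 0.012 \times 250 = £277.96$. This is the unique reading consistent
with the published pathway costs (7 711 tests $\times$ £277.96 = £2 143k).

## Sensitivity analyses

**Cost-neutral price** (`solve_cost_neutral_price()`): incremental cost
is affine in $c_{lab}$ with slope $n_{NIPT}(1 + p_{rep})$, so the
cost-neutral laboratory price has a closed form; the primary path is
nonetheless bisection on the incremental-cost function (robust to
non-linear extensions), with the closed form kept as a cross-check.
Both agree to £0.01 by test.

**One-way thresholds** (`one_way_threshold()`): any parameter can be
varied with a bracketing bisection to the value where incremental cost
crosses zero. Two subtleties:

* *Coupling.* High-risk NIPT uptake and direct-invasive uptake are not
  independent — they compete for the same women. The
  `complement_within_further_testing` rule holds their sum at the base
  92.5% while `u_nipt_high` varies; this is the only coupling under
  which lowering NIPT uptake raises costs (direct invasive testing at
  £650 absorbs the difference), reproducing the 71.3% cost-neutrality
  point. Varying `u_nipt_high` alone moves costs the other way.
* *Arms.* Screening uptake appears in both arms of the comparison, so
  varying it "in both" can never produce a crossing. The query's `arm`
  field varies it in the contingent arm only (cost neutral at 66.4%,
  current arm fixed at 66.2%) or the current arm only (66.0%).
  A parameter with no effect on incremental cost (e.g. the miscarriage
  risk, which has no cost attached) reports "not cost-neutral anywhere
  in range" as a typed condition rather than a root.

**Uptake scenarios** (`uptake_scenarios()`): unit-level uptake splits
are substituted into the 1/150 strategies; the no-direct column uses the
scenario's *combined* further-testing uptake as the NIPT uptake, on the
assumption that direct-IPD choosers switch to NIPT when that is the only
option. The published main-analysis row is the base case itself (91%
no-direct uptake), not a substitution — the package tests treat it so.

## Probabilistic sensitivity analysis

The published analysis drew 1000 simulations from distributions over all
inputs but did not publish the distributions. `psa_config()` therefore
adopts the conventional choices for this model class, fully swappable
per parameter:

* **beta** for every proportion, with hyperparameters
  $\alpha = p\,n_{\mathrm{eff}}$, $\beta = (1-p)\,n_{\mathrm{eff}}$
  built from the study's actual group sizes (934 high-risk women, 2 241
  intermediate, 59 NIPT positives, 47 confirmatory tests, 166 direct
  invasive tests, 30 790 screened, 40 527 booked);
* **gamma** with 20% coefficient of variation for the two genuinely
  uncertain unit costs (`c_nipt_lab`, `c_ipd`); other costs, the test
  mix and the population are fixed;
* a **Dirichlet** over the high-risk choice simplex {NIPT, direct IPD,
  decline} (effective denominator 934) coupling `u_nipt_high` and
  `u_direct_ipd`, mirroring the one-way coupling above.

Intervals are equal-tailed 2.5/97.5 percentile intervals
(linear-interpolation quantiles) over the draws; the draw matrix is
retained for export. Because the true distributions are unpublished, the
package never asserts the published interval endpoints; the tests
assert *properties*: degenerate all-fixed configurations collapse onto
the deterministic point estimates, intervals bracket them with positive
width, bit-identical reproduction under a fixed seed, interval width
shrinking in $n_{\mathrm{eff}}$, and Monte-Carlo means converging to the
deterministic values (every sampled parameter enters the tree linearly
or as products of independent draws, so the means must agree). The
convergence check runs at 20 000 draws rather than 50 000 to stay inside
the test-time budget; the incremental cost of the 1/150 strategy has a
near-zero point value (≈ −£46k) against a ≈ £1.1M draw standard
deviation, so it is checked within 3 Monte-Carlo standard errors — a 1%
*relative* check on that output is unattainable at any feasible
simulation size.

## The synthetic cohort generator

`simulate_cohort()` draws one trajectory per booked woman: screening
uptake → test type → risk band (with the 1/151–1/500 sub-band nested
inside 1/151–1/1000) → the scenario-dependent testing choice → NIPT
result → confirmatory invasive testing → procedure miscarriage →
pregnancy outcome. It emulates the structure of the underlying
prospective cohort; it does **not** model maternal age, gestational age,
unit-level heterogeneity, or risk as a continuous variable — bands are
drawn directly at their marginal frequencies. A green test therefore
establishes internal consistency between the generator, the estimator
and the decision tree, not fidelity to any real population beyond the
marginal rates it was given.

Design choices:

* **NIPT error model.** Sensitivity is fixed at 1 (the study observed
  100%); positives are drawn at the band-specific positivity rates, and
  the *true* status behind a positive is resolved by the confirmatory
  test when one occurs (positive at rate 90.1%) or, for unconfirmed
  positives, by a configurable discordant-positive rate (default 5/55 ≈
  9.1%, the study's discordance among positives). The decision model
  consumes positive-predictive-style quantities, so a per-positive
  discordance rate, not a population false-positive rate, is the
  faithful primitive.
* **Repeat tests** are a boolean column (`nipt_repeated`) alongside the
  final result rather than a value of the result enum, so the repeat
  rate and the positivity rate are independently estimable from the
  same cohort.
* **Loss to follow-up** (default 6%) applies once, after the testing
  choice; cohorts meant as a Monte-Carlo oracle for the deterministic
  tree (which has no follow-up concept) are generated with it set to 0.
* **Outcome stage** uses the observed continuation probabilities after
  a confirmed diagnosis (13/42 after NIPT, 2/29 after direct invasive
  testing) and is excluded from all cost computations.

`estimate_params()` inverts the generator: every proportion whose
numerator and denominator are observable under the cohort's scenario is
re-estimated as successes/denominator with an exact Clopper-Pearson
interval (equal-tailed beta quantiles — the interval method of record
for all exact intervals in this package); zero denominators flag the
field not-estimable rather than failing. Costs are not observable in a
cohort and pass through.

### Calibration, stated precisely

The closed-loop property "estimates from simulated cohorts cover the
generating values" is tested over 100 seeds at 200 000 women per seed.
The exact coverage of a Clopper-Pearson interval at the denominators
involved is ≈ 95–96%, so the number of covering seeds per field is
Binomial(100, ≈0.957): a strict per-field "≥ 93 of 100" cutoff rejects
an *exactly calibrated* estimator with roughly 40% probability once ~14
fields are checked, and requiring all fields inside simultaneously per
seed would pass only ≈ 54% of seeds. The suite therefore asserts
aggregate coverage ≥ 93% across all field × seed checks plus a
per-field floor of 88/100 (≈ 4 SD below exact coverage) that only a
genuinely biased estimator would breach.

## Numerical conventions and edge cases

* Root-finding: bisection, tolerance £0.01 on prices and 10⁻⁶ on
  proportions; solutions are invariant to the bracketing interval for
  monotone objectives (tested).
* A strategy with no NIPT tests has no cost-neutral price and says so;
  a contingent strategy parameterised to mimic the current pathway
  yields exactly zero incrementals (tested).
* Reading parameter files accepts `units: percent|proportion`
  declarations to prevent silent 100× errors; unknown keys are
  rejected outright.
* Published-value tests use ±1% relative (±1 unit on small integers),
  absorbing the source tables' printed rounding: the inputs are printed
  to 2–3 significant figures, which propagates to ~0.5% discrepancies
  in derived outputs (e.g. detected cases 835.4 computed vs 833
  printed at threshold 1/1000). The incremental confirmed-by-IPD
  column is not reproducible from the printed inputs at that tolerance
  and is computed but not asserted against print.

## Known limitations

* Economic scope is the screening pathway only: no QALYs, no lifetime
  costs, no trisomy 13/18 economics, no currency adjustment.
* The PSA distributions are this package's (documented, configurable)
  choices, not the original analysis's unpublished ones; its intervals
  are comparable in kind, not in digits.
* The cohort generator reproduces marginal flow rates, not individual
  risk heterogeneity; positive predictive value emerges from the
  discordance rate rather than from disease prevalence by risk band.
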