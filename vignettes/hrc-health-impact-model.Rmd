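---
title: "Modelling the health impact of regulating health-related food claims"
author: "hrcimpact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the health impact of regulating health-related food claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrcimpact)
```

## The problem

Health-related claims (HRCs) — nutrition claims ("high in fibre") and
health claims ("calcium contributes to normal bones") — appear on roughly a
quarter of pre-packaged foods and measurably boost purchases of the
products that carry them.  Regulators have proposed gating claim
eligibility on a *nutrient profile* (NP) model, so that only foods judged
healthy enough may carry a claim.  The intuition is that this protects
consumers; the complication is that claim-carrying foods are, on average,
*already* healthier than claim-free foods in the same food group.  If
claims steer purchases towards those healthier products, restricting
claims can steer purchases back towards less healthy ones.  Whether
regulation helps or harms is therefore an empirical, quantitative question.

`hrcimpact` implements a full desk-scale pipeline for that question:

1. **Disaggregation** — split each food group's purchases and nutrient
   intake into claim and non-claim streams, consistent with observed
   totals.
2. **Nutrient profiling** — score products against the FSANZ Nutrient
   Profiling Scoring Criterion (NPSC) or a configurable EU-style threshold
   model.
3. **Scenarios** — rebuild the diet under claim *restriction* (models
   1a/2a) or restriction with *reformulation* (models 1b/2b).
4. **Mortality impact** — convert intake changes into deaths averted or
   delayed through population impact fractions (PIFs) across age/sex
   strata, with direct and mediated exposure–outcome links.
5. **Uncertainty** — Monte Carlo 95% uncertainty intervals and a tornado
   decomposition.

A synthetic-data module generates every input the pipeline needs (a
product-label survey, purchase/intake tables, population and mortality
tables), so the whole analysis is reproducible without access to the
underlying commercial and national surveys.

## The baseline model

### Splitting purchases into claim and non-claim streams

For a food group with claim prevalence $q$ (the proportion of *available*
products carrying a claim) and a choice odds ratio $\mathrm{OR}$ (the odds
of choosing a product when a claim is present relative to when it is not),
the claim-food share of *purchases* is taken on the odds scale:

$$ s = \frac{q\,\mathrm{OR}}{q\,\mathrm{OR} + (1-q)} . $$

This is the only reading of a choice odds ratio that reduces to $s=q$ at
$\mathrm{OR}=1$, stays within $[0,1]$, and conserves total sales.  It is
isolated in `hrc_sales_share()` so an alternative reading (e.g. a
probability-scale multiplier) is a one-function swap; a discrete-choice
simulation over a synthetic shelf is used as an independent oracle in the
test suite.

### Nutrient quality ratios

The composition link between the streams is the *nutrient quality ratio*
(NQR): per group and nutrient, the mean content per 100 g of
claim-carrying foods divided by that of claim-free foods.  Given the group
totals $S$ (grams/day) and $T_n$ (nutrient intake/day), the non-claim
concentration solves

$$ c^{non}_n = \frac{T_n}{\left(s S\,\mathrm{NQR}_n + (1-s) S\right)/100},
   \qquad c^{hrc}_n = \mathrm{NQR}_n\, c^{non}_n , $$

so the two streams reconstruct the observed totals *exactly* (closed form;
the conservation suite checks $10^{-9}$ relative error over random
configurations).  Fruit and vegetables are carried as grams of the
fruit-and-vegetables group's sales split — food quantities, not chemical
concentrations — so their NQR is identically 1.

### Scenario construction

* **Restriction (models a).**  Claim foods failing the NP model lose the
  claim and its sales boost: the group is re-split at the pass prevalence
  $q^{pass} \le q$ with pass-variant NQRs, while the non-claim
  concentration stays at its baseline value (foods losing claims are
  assumed to take on average non-claim composition — a conservative
  simplification that, if anything, understates non-claim quality).
* **Reformulation (models b).**  Prevalence and the sales split stay at
  baseline; failing claim foods reformulate to pass, so the claim stream's
  concentration becomes the pass-variant NQR times the baseline non-claim
  concentration.
* Group sales totals never change (substitution stays within food
  category); the change in total nutrient intake *is* the measured
  outcome.  Both builders reproduce the baseline exactly under null
  parameters, which the suite asserts bit-for-bit.

The central mechanism follows directly: with claim foods less energy-dense
than non-claim foods ($\mathrm{NQR}_{energy} < 1$), restriction moves
purchases into denser products and energy intake *rises*, while
reformulation lowers it.  The acceptance suite demonstrates both signs on
the fully synthetic end-to-end path (survey → scoring → derived parameters
→ scenarios → mortality).

## The mortality engine

For each exposure–outcome link, the baseline intake distribution is a
normal with the population mean and SD, truncated at zero and discretised
on a 1,000-point grid over mean ± 6 SD (the suite checks agreement with a
10,000-point reference).  The counterfactual shifts the mean by the
scenario's intake delta and keeps the SD.  With
$RR(x) = rr^{(x - x_{ref})/u}$ (per unit $u$, reference at the baseline
mean — the PIF is invariant to that choice),

$$ \mathrm{PIF} = \frac{\sum_x P(x)RR(x) - \sum_x P'(x)RR(x)}
                        {\sum_x P(x)RR(x)} . $$

Links are *direct* (fruit, vegetables, fibre) or *mediated* by body
weight, systolic blood pressure, or blood cholesterol: each exposure unit
moves the mediator by a configured slope and the RR applies per mediator
unit.  Energy is routed solely through the body-weight mediator and
reported separately ("with energy" totals), since weight change is the
only plausible channel for an energy-intake effect at fixed diet
composition.  Multiple links on one cause combine multiplicatively on
survival fractions, $1 - \prod_\ell (1 - \mathrm{PIF}_\ell)$; per-factor
rows are computed with each factor's links alone, which is why factor rows
do not sum to the combined total.  Deaths averted in a stratum–cause cell
are baseline deaths times the combined PIF; negative values are additional
deaths.

The RR catalogue of the published comparative-risk-assessment model is not
reproduced here: the packaged links are **illustrative** defaults with the
conventional pathway structure (saturated fat → cholesterol → coronary
disease strong; salt → blood pressure → cardiovascular disease moderate;
fruit/vegetables/fibre direct and protective), intended to be replaced by
a user-supplied catalogue for substantive work.

## Uncertainty propagation

Four parameter groups are sampled per iteration (10,000 iterations is the
reference setting; examples below use fewer):

* claim prevalences — logit-normal matched to their 95% CIs;
* stream nutrient means behind the NQRs — normal with survey standard
  errors, the ratio recomputed per draw;
* choice odds ratios and epidemiological RRs — lognormal with
  $\sigma = \log(U/L)/(2 \times 1.96)$, median at the point estimate.

Sampling families are not dictated by the source material; these are the
standard choices for proportions, means and ratio parameters, and each is
isolated in one function (`sample_proportion()`, `sample_ratio()`) for
swapping.  Parameters are drawn independently (no correlation information
is available) and **shared between baseline and counterfactual within an
iteration** — common random numbers — otherwise scenario deltas would be
dominated by sampling noise rather than the regulation effect.  Iteration
$i$ reseeds deterministically from `(seed, i)`, so results are
reproducible bit-for-bit and single iterations can be replayed.

The tornado analysis reruns the Monte Carlo varying one parameter group at
a time, all others fixed at central values (the source setting leaves this
unstated; fixing at central values is the standard one-at-a-time
convention), and ranks groups by the width of the 95% UI of total deaths
averted.  Under the packaged defaults the nutrient-mean (NQR) group ranks
first by a wide margin, reproducing the qualitative finding that the
underpowered food-composition survey dominates the model's uncertainty.

## The synthetic data generator

`gen_product_survey()` emulates a product-label survey: products are
allocated to the eight food groups (six Eatwell Guide groups plus
composite and miscellaneous), carry a claim with the group's prevalence
(Bernoulli), and draw each nutrient independently from a truncated normal
whose mean depends on claim status (claim mean = NQR × non-claim mean,
SD = CV × mean).  Truncation at zero (and at 900 kcal/100 g for energy)
uses rejection resampling rather than clipping, so realised means follow
the closed-form truncated-normal mean (`tnorm0_mean()`), which is also the
reference for the parameter-recovery tests.  Nutrients are drawn
independently because only marginal means and SDs are available;
correlation structure is out of scope.  The claim/non-claim mean shifts
default to the survey-aggregate values (energy −43.7 kcal/100 g, fibre
+0.7 g, sodium −354 mg, etc.) applied as uniform ratios across groups,
with per-group overrides supported.

`gen_sales_and_mortality()` is deterministic: per-group intakes are fixed
shares of the configured population totals (so totals like
1906.8 kcal/person/day reproduce exactly), and deaths follow a smooth
exponential age-rate model per cause, scaled to UK-like annual totals
(about 66,000 coronary, 38,000 stroke, 16,000 colorectal and 4,300 stomach
cancer deaths), rounded to integer counts.

What the generator does *not* emulate: household sampling design, diary
measurement error, nutrient correlations, within-group product
sub-categories, or claim-type heterogeneity.  Passing tests therefore
show internal consistency of the method under the stated statistical
structure, not validity on real survey data.

## Calibration and parameter-table ambiguities

Several aspects of the printed parameter table are ambiguous or internally
inconsistent, and the package makes its choices explicit and overridable:

* **Prevalence column mapping.**  The printed table has three prevalence
  columns per group whose scenario roles cannot be recovered from the
  garbled layout.  `default_config()` reads them as (baseline, FSANZ-pass,
  EU-pass) — `prevalence_mapping = "baseline_first"` — matching the
  column order as printed.  But under that reading almost every "pass"
  prevalence *exceeds* baseline, which is structurally impossible
  (`q_pass =` claims *and* passing `/ group count` ≤ `q_baseline`) and
  contradicts the described fall in restricted prevalence.  The
  alternative reading, `"pass_last"` (FSANZ-pass, EU-pass, baseline),
  satisfies `q_pass ≤ q_baseline` for every group and is the only reading
  under which the published baseline claim-food shares (37% of purchase
  grams, 29% of energy) are attainable.  `study_config()` uses it;
  restricted builders reject `q_pass > q_baseline` unless explicitly
  overridden.
* **Starchy-carbohydrates OR.**  Printed as 1.17 with CI (1.60–1.91) — the
  CI excludes the point and equals the pooled OR's CI.  The packaged
  default keeps the point 1.17 and imputes a CI with the pooled estimate's
  relative width (1.07, 1.28).
* **Oils and spreads** are absent from the printed table; they receive the
  pooled OR 1.75 (1.60, 1.91) and the overall prevalence 26% (24–28%).
* **Baseline diet calibration.**  Per-group purchase weights and intake
  shares are free parameters of the synthetic world.  They were chosen
  once to be UK-plausible (milk-heavy dairy purchases, starchy foods the
  largest energy source, fruit+vegetable grams fixed at the printed
  151.2 + 131.1 g/day) and so that the baseline disaggregation under
  `study_config()` reproduces the published claim-food shares: 37.1% of
  purchase grams and 29.3% of energy (559 of 1906.8 kcal/person/day).
* **NQR uncertainty.**  Standard errors are derived from the survey design
  (delta method on stream means, about 2,000 products split 8 ways and
  then by claim status) times a design-effect multiplier
  (`survey$se_inflation = 2.5`) representing heterogeneity beyond simple
  random sampling — five countries, broad food groups, skewed label
  distributions.  This reproduces the magnitude relationship in which
  food-composition uncertainty dominates all other parameter groups.
* **EU threshold table.**  The draft EU model's structure is unpublished;
  the packaged per-group caps on energy, saturated fat, sugars and sodium
  are labelled illustrative and are strictly a configuration.

## Numerical choices and degenerate inputs

* NPSC points use strict `>` band comparisons on kJ (kcal × 4.184), per
  the published schedule; protein modifying points are withheld at
  baseline ≥ 13 unless FVNL points reach 5; pass thresholds are < 1 / < 4
  / < 28 for categories 1/2/3.  Category-3 extended bands and
  claim-type-specific requisites (e.g. the 90%-fruit rule) are out of
  scope, matching the uniform application used in the source analysis.
* A group with zero sales but positive intake is an inconsistency error;
  zero sales with zero intake yields empty streams.
* NQR estimates are missing when a stream is empty or the non-claim mean
  is zero; stream SEs are missing below two products; derived scenario
  parameters fall back to configured tables when a stream has fewer than
  `min_stream = 10` products (a ratio of means over a handful of products
  is noise).
* PIF grids share a common support between baseline and counterfactual;
  distributions are renormalised after truncation and validated to 1e-6.
* Monte Carlo sub-seeds are `(48271 * seed + 104729 * i) mod (2^31 - 1)`,
  keeping every derived seed within R's 32-bit integer range.

## Worked example

```{r example, eval = FALSE}
cfg <- study_config()
inputs <- gen_sales_and_mortality(cfg)

baseline <- baseline_disaggregate(inputs$sales, cfg$hrc_params,
                                  cfg$nqr$baseline)
hrc_share(baseline, "grams")        # ~0.371
hrc_share(baseline, "energy_kcal")  # ~0.293

# end-to-end synthetic route: survey -> scoring -> scenarios -> deaths
products <- gen_product_survey(cfg, n_products = 4000, seed = 11)
dp <- derive_scenario_params(products, cfg)
restricted <- run_scenario(cfg, "1a", derived = dp)
reformulated <- run_scenario(cfg, "1b", derived = dp)

deaths_averted(restricted$delta, cfg$intake_total, cfg$intake_sd,
               cfg$links, inputs$population, inputs$mortality)

# uncertainty (reference setting: n_iter = 10000)
mc <- monte_carlo(cfg, "1b", mc_spec(n_iter = 1000, seed = 4), derived = dp)
tornado(cfg, "1a", mc_spec(n_iter = 500, seed = 15))
```

Problem sizes used by the shipped checks: 4,000-product surveys for the
scenario mechanism, a 100,000-product survey for parameter recovery,
100,000 draws for sampler calibration, 100 random configurations for the
conservation suite, and Monte Carlo runs of 120–400 iterations (tornado
250 per group) — large enough for stable signs and percentile positions
at the tolerances tested.

## Known limitations

* The epidemiological RR catalogue is illustrative; absolute deaths
  averted under the packaged links are not substantive estimates.
* Fruit and vegetable intake is invariant across scenarios by
  construction (fixed group sales, quantities not concentrations), so the
  fruit-and-vegetables factor contributes zero here, unlike in the source
  analysis where it carried wide uncertainty.
* No cross-category substitution, compensatory consumption,
  price/socio-economic effects, or age/sex-specific choice behaviour.
* Nutrient profile models are applied uniformly to all foods and claim
  types.
* The truncation-at-zero bias of the generator is negligible at the
  default CVs except for extreme cells (oils energy), where the
  closed-form truncated means are used as the recovery reference.
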