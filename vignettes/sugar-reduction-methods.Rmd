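---
title: "Methods: simulating a population sugar reduction programme"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating a population sugar reduction programme}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sugarsim)
```

## The modelled intervention

`sugarsim` simulates a reformulation-style public-health programme that
reduces the sugar content of ten targeted food categories (breakfast
cereals, yogurts, biscuits, cakes, morning goods, puddings, ice cream,
chocolate and sweet confectionery, sweet spreads and sauces) by 20%
through three mechanisms:

* **reformulation** — less sugar in the same product;
* **portion size reduction** — the whole product shrinks, removing sugar
  and non-sugar calories alike;
* **sales weighting** — sales shift from high- to low-sugar variants,
  modelled as an average sugar reduction across the category.

When a category uses several mechanisms, each delivers an equal share of
the 20% so that the total remains 20% (`equal_split`). Categories with
dairy or dried-fruit content keep a small *natural-sugar allowance*: the
exempt grams are subtracted before the percentage cut and added back
afterwards. Consumers are assumed not to compensate and industry not to
replace sugar with other calories; those assumptions are the scenario's
definition, not a claim about behaviour.

Disabling a mechanism (the "one mechanism fails" sensitivity) removes its
share of the reduction without redistributing it to the surviving
mechanisms — the reduction is lost.

## From calories to weight and BMI

Two deliberately different models convert the daily calorie reduction to
a weight change.

**Children (4–18):** a linear coefficient from randomised-trial evidence,
0.041 kg per gram of daily sugar (a two-year weight difference). Sugar
calories are converted to grams at 3.75 kcal/g (the
carbohydrate-as-monosaccharide convention), so the slope is
$0.041/3.75 \approx 0.0109$ kg per kcal/day. Non-sugar calories are
excluded for children because the underlying trials manipulated sugar
only.

**Adults (19–80, and 18-year-olds for health modelling):** the
Christiansen–Garby energy-conservation argument. A sustained intake
reduction $\Delta I$ is balanced at the new equilibrium by the fall in
expenditure from the lost tissue:

$$\Delta I = PAL \times \big(f\,c_{fat} + (1-f)\,c_{lean}\big) \times \Delta W$$

where $PAL$ is the physical activity level, $f$ the fat fraction of the
weight change, and $c_{fat}, c_{lean}$ the resting energy costs of fat
and lean tissue. We solve the closed form at equilibrium rather than
integrating a trajectory, because the quantity of interest is a single
steady-state weight difference. Defaults are $c_{fat} = 4.5$,
$c_{lean} = 19.7$ kcal/kg/day, $f = 0.60$ (men) and $0.75$ (women) —
external physiological constants, all configurable via
`adult_weight_params()`. Both sugar and non-sugar calorie reductions
enter the adult model.

BMI change is $\Delta W / h^2$. Children are classified against
age/sex-specific cut-offs at −2, +1 and +2 SD of a reference median
(obesity requires *strictly more* than +2 SD; 4-year-olds use the
5-year-old cut-offs); adults use the fixed half-open bands
18.5 / 25 / 30 / 35. The bundled cut-off table is a synthetic,
smooth-in-age approximation anchored so the +1 SD and +2 SD curves reach
25 and 30 at age 19; real analyses should supply the official WHO values
through `load_bmi_reference(path)`.

## Imputation

Height, weight and PAL are imputed separately by age band (4–18, 19–80)
and sex with linear regressions on age and daily calorie intake.
Candidate nested models (intercept; +age; +age+kcal) are compared by
sequential likelihood-ratio tests at $\alpha = 0.05$; the level and the
search order (age before kcal) are package choices, since a "best fit by
likelihood-ratio test" prescription pins down neither.
Each missing value gets the linear prediction plus a
Normal(0, residual SD) draw; draws implying impossible values are redrawn
up to 10 times, then floored. Observed values, including self-reported
ones, are never altered; provenance flags allow the verified-only
sensitivity to drop imputed and self-reported records. Strata with fewer
than 30 complete cases fall back to the stratum mean. Single stochastic
completion, not multiple imputation: the downstream model consumes one
completed dataset per run, and run-to-run variation is carried by the
master seed.

Imputation runs before scenario arithmetic because anthropometrics are
baseline traits; the kcal predictor is baseline diary energy.

## The proportional multistate lifetable

Adult BMI changes act on chronic disease through population impact
fractions (PIFs). With relative risk $RR(x) = rr^{\,x - x_{ref}}$ per BMI
unit ($x_{ref} = 22$ by default; the PIF is invariant to this anchor),

$$PIF = \frac{\sum_i w_i RR(x_i) - \sum_i w_i RR(x_i')}{\sum_i w_i RR(x_i)}$$

computed per sex from the individual baseline and scenario BMI values,
pooled over adult ages — 1508 survey records are too sparse to support
single-age exposure distributions.

The lifetable follows eleven diseases (cardiovascular disease, stroke,
diabetes, breast, colorectal, lung, stomach, pancreatic, kidney and
liver cancer, cirrhosis) in closed single-year birth cohorts by sex.
Each disease is an illness–death process with constant within-year
rates: incidence $i$, case fatality $f$, remission (default 0). The
one-year update uses the analytic matrix exponential of the two-state
system, so prevalence at annual steps equals the continuous-time closed
form exactly — no Euler error. The Markov assumption holds throughout:
rates do not depend on time already spent in a state.

Comorbidity combines multiplicatively (one disease's prevalence does not
alter another's), with one exception: diabetes is both an endpoint and a
risk factor. Scenario-arm incidence of diabetes-sensitive diseases is
scaled by $\frac{1+(RR_{dia}-1)p^{scen}_{dia}}{1+(RR_{dia}-1)p^{base}_{dia}}$,
the relative change in diabetes prevalence between arms; the baseline arm
runs first and supplies the reference trajectory.

All-cause mortality each year is background mortality plus
prevalence-weighted case fatality; survival is exponential within the
year, so alive + cumulative deaths reproduces the initial cohort exactly.
Life years accrue as mid-year person-years. QALYs weight person-years by
$\prod_d (1 - p_d u_d)$ over the disease utility decrements; costs
combine prevalence-weighted annual disease costs with an
unrelated-future-cost schedule applied to all person-years, so added
longevity carries the healthcare cost of conditions outside the model.
Lung and stomach cancer carry RR = 1: they respond only through
longevity, which is why their incident cases *rise* slightly under an
effective intervention.

Numerical and structural choices worth knowing:

* Both arms run the same code path; a null intervention yields bitwise
  zero deltas.
* Cohorts start disease-free in both arms. Early-year absolute
  prevalence is therefore understated, but this cancels in the
  scenario − baseline differences the package reports.
* Beyond the oldest tabulated age, rates are held at the last value.
* No lag between exposure change and rate change (the scenario is a
  sustained, already-achieved reduction); QALY/cost discounting defaults
  to 0% with a `discount_rate` option.

## Monte Carlo uncertainty

`mc_config()` controls the probabilistic analysis (default 2000 runs).
Per draw, relative risks per BMI unit are lognormal around their central
values (sdlog 0.015), annual costs gamma (CV 0.10), utility decrements
beta (concentration 80); diseases with RR exactly 1 never acquire a BMI
link. PIFs are re-derived per draw from the drawn RRs and both arms are
re-run. Point estimates are means of draws; 95% uncertainty intervals
are the empirical 2.5th–97.5th centiles. The spread parameters are
package defaults chosen to give interval widths of the order seen in
comparable health-impact models; they are inputs, not estimates.

## What the synthetic data emulate — and what they do not

The generator (`synthetic_config()`, `generate_population()`,
`generate_diaries()`, `generate_disease_tables()`) reproduces the
*statistical structure* the pipeline assumes:

* 1508 respondents aged 4–80 with every single-year age present;
* in-scope sugars near 7% of energy in children and 5% in adults
  (person-level lognormal variation, mean on target), spread over the
  ten categories plus an out-of-scope filler that carries the remaining
  ~15% of energy as non-targeted sugars — so reductions can be expressed
  against total baseline sugar intake as diet surveys do;
* targeted items are sugar-dense (45–95% of item energy), keeping the
  portion mechanism's non-sugar losses small relative to sugar losses;
* age/sex-conditional anthropometrics: child BMI spread wider and
  shifted above the reference median (modern prevalence vs reference
  population), adult BMI lognormal with mean ≈ 26 and ~26% obese;
* missingness in height (5%), weight (7%) and PAL (20%), 15%
  self-reported flags, gamma survey weights with CV 0.3;
* disease parameter tables with plausible—but synthetic—magnitudes:
  Gompertz-like incidence, constant case fatality, RRs per BMI unit
  between 1.02 and 1.10 (1.0 for lung and stomach cancer), female-only
  breast cancer.

They do **not** reproduce real survey microdata, real food composition
codes, GBD-calibrated epidemiology or NHS programme budgeting costs.
Passing tests therefore demonstrate the *mechanics* — calibration,
conservation, direction, proportionality, uncertainty propagation — not
the published absolute case counts or cost totals, which require the
restricted inputs. On the synthetic defaults the pipeline lands close to
the published per-person magnitudes (mean adult weight change ≈ 1.7 kg,
child sugar reductions ≈ 23–28 kcal/day) while population-level QALY and
cost totals differ from the published ones, as expected with synthetic
disease inputs.

## Problem sizes

The study-scale configuration (1508 people, 2000 Monte Carlo draws,
10-year horizon, 63 single-year adult cohorts per sex) runs in well
under a minute on one core because the cohort arithmetic is vectorised
over cohorts × diseases and the age-indexed rate arrays are precomputed
once per configuration. Property tests use 100–400 synthetic people,
which is ample for the structural checks they make; the calibration test
uses 1200 people so the realised sugar-energy shares are within 20%
relative error of target with comfortable margin.

## Known limitations

* PIFs pooled over adult ages flatten any age gradient in the BMI shift.
* Starting cohorts disease-free understates early absolute burden.
* The children's model ignores non-sugar calories by construction; the
  adult model is an equilibrium, not a trajectory (no time constant).
* The Hall dynamic weight model is acknowledged as the gold standard for
  adults but is not implemented; `adult_weight_change()` is the single
  adult method, and its parameters object is the natural extension point.
* Sales weighting is mechanically identical to reformulation (an average
  sugar reduction); it is tracked separately only for attribution and
  sensitivity toggling.
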