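---
title: "Measuring and modelling dietary health in rural household surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modelling dietary health in rural household surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ruraldiet)
```

## The problem

Rural Chinese households are aging quickly while incomes keep rising, and
the two forces pull dietary quality in opposite directions. ruraldiet
implements a complete analysis pipeline for the question "how do family
age composition and per-capita income shape the healthiness of a
household's diet?", built around 3-day household food-consumption records
of the kind collected by stratified village surveys: every gram of edible
food eaten at home, by food group and day, together with a ledger of how
many family and guest meals were actually eaten at home.

Because survey microdata of this kind are rarely shareable, the package
ships a calibrated synthetic-data generator with the same nested sampling
frame (provinces, counties, townships, villages, households). All
estimation and projection machinery is exercised and validated against
data from this generator; nothing in the package requires the original
survey.

## The three indices

All indices are computed from per-capita daily intakes over twelve food
groups (cereals, tubers, dried legumes, vegetables, fungi/algae, fruits,
nuts/seeds, meat, poultry, dairy, eggs, aquatic products). Sugar, sweets
and soft drinks are excluded on purpose: they inflate apparent variety
without improving quality.

**Standardization.** Household totals are divided by at-home
person-days, computed from the meal ledger as (family + guest
person-meals) / meals-per-day. This corrects simultaneously for household
size, meals eaten away from home, and guests. A household with zero
recorded person-meals has undefined intake and is excluded with a reason
code — never scored zero. The same applies to a household with zero total
intake; this is why a regression sample can be one household short of the
generated frame.

**Entropy index (EI).** Shannon entropy of the edible-weight shares
$w_i$: $EI = -\sum_{i=1}^{12} w_i \ln w_i$, with $0\ln 0 = 0$. It ranges
from 0 (single-group diet) to $\ln 12 = 2.48$ (perfectly even intake),
and is invariant to the overall quantity eaten. Natural logs are used
throughout; the printed maximum 2.48 only makes sense in nats.

**Pagoda score (CFPS).** The twelve groups are aggregated into the eight
categories of the 2016 Chinese Dietary Pagoda (the package maps
fungi/algae with vegetables; cereals, tubers and dried legumes into one
grains category; meat with poultry — the mapping is a plain named vector
and fully configurable). Each category intake is scored by a three-tier
rule against the recommended band $[L_j, U_j]$: 1 in band, 0.5 when
outside but within 50% relative distance of either bound, 0 otherwise.
The full-credit band takes precedence where the clauses overlap (an
intake just inside $L_j$ also satisfies the near-band inequality; it
scores 1). CFPS is the sum, 0–8 in half-point steps.

**Healthy-eating index (CHEI).** Twelve 5-point components, one per food
group, summing to 0–60. Adequacy components score
$\min(\text{intake}/R_k, 1)\times 5$; limitation components score 5 up to
the ideal limit $L_k$, decline linearly, and reach 0 at the cut-off
$U_k$. We score intake exactly at $U_k$ as 0: the linear ramp evaluates
to 0 there, so the piecewise rule stays continuous. Note this 0–60
equal-weight variant differs from the published 0–100 CHEI with unequal
weights; the package implements the equal-weight variant deliberately.

The guideline numbers themselves ($L_j, U_j, R_k, L_k, U_k$) are shipped
as editable CSVs seeded from the 2016 Pagoda ranges, because the source
analysis cites the guideline without printing its numbers. Every test of
the scoring rules depends only on their structure (bounds, tiers,
continuity, maxima), not on the particular defaults. The default
component table classifies all twelve groups as adequacy components —
the twelve groups were chosen to exclude the classic "foods to curb", and
no authoritative limitation designation exists for them; limitation
components are fully supported through the table's `kind` column.

```{r indices}
even <- setNames(rep(100, 12), food_groups())
entropy_index(even)          # ln 12 = 2.48
comp <- default_chei_components()
chei(setNames(comp$R[match(food_groups(), comp$component)],
              food_groups()))  # every target met -> 60
```

## The synthetic survey generator

`generate_survey()` emulates the study conditions: 3 provinces x 4
counties x 3 townships x 3 villages x 10 households (1,080 households,
108 villages) observed over 3 days, with covariate marginals calibrated
to the published descriptive statistics — e.g. member-age mixture with
expected shares 9.17 / 63.46 / 26.61 percent (under 18 / 18–65 / 65+),
log-normal per-capita income with mean 2.53 and SD 2.51 (10⁴ Yuan),
78% female food decision-makers, a Binomial(9, 7.11/9) knowledge index.
Right-skewed non-negative quantities (income, land, property, village
aggregates) are log-normal with the target mean and SD matched exactly;
zero-heavy pension income is a 60/40 zero/log-normal mixture. Household
age profiles get a Dirichlet layer (concentration 1.3) on top of the
mixture so that all-elderly and no-child households are common, matching
the large published SDs of the composition shares.

Effects are planted backwards from the indices. For each household the
generator draws latent EI and CHEI targets from linear models with the
published coefficient pattern (aging harms, income helps; i.i.d. normal
county effects stand in for county fixed effects), then constructs
consumption consistent with the targets: a 12-group weight vector
interpolating between a dominant-staple spike and the uniform
distribution, with the interpolation parameter solved by bisection so
the entropy equals the EI target exactly, and a total-quantity scale
solved by bisection so the adequacy score equals the CHEI target
exactly. The Pagoda score is *emergent*: one consumption vector cannot
pin three indices independently, so CFPS inherits the planted structure
through the induced adherence rather than being separately controlled.
Planted-effect recovery is therefore validated on EI and CHEI.

Default noise SDs (0.25 EI, 0.9 CFPS-model, 5.5 CHEI index units) were
chosen once so that simulated index dispersion is of the same order as
the published descriptive SDs; latent targets are clipped to the
admissible index ranges (clipping is a sub-percent event under the
defaults). What the generator does **not** emulate: the true joint
dependence of covariates (they are drawn independently given the village),
within-day meal composition, spatial structure, or away-from-home
consumption (only at-home intake exists, as in the source records). A
green test suite therefore shows the estimators are correct and well
calibrated, not that any particular real-world coefficient is true.

## Estimation

`fit_main_model()` runs OLS of an index on the composition shares
(18–65 omitted as reference), income, sixteen controls and county
fixed-effect dummies. Standard errors use the clustered sandwich
estimator with the `G/(G-1) * (n-1)/(n-k)` small-sample factor. The
published design clusters at the household level with one observation
per household — operationally exactly HC1 heteroskedasticity-robust
errors — so the cluster factor is configurable (household, village,
county) with household as the documented default. t statistics use
`G - 1` degrees of freedom. Missing fields cause listwise deletion with
a logged count. Log transforms use `log(1 + x)` for variables with
legitimate zeros (pension, market distance, land) and plain `log` for
strictly positive village aggregates; this is a package convention, as
descriptive tables of such surveys list the transformed moments without
stating the formula.

`run_heterogeneity()` refits per stratum of income (terciles by default,
with custom thresholds for unequal published splits), labor count,
pension, market density or land. When the sample is split on income
terciles, income is dropped from the stratum regressions — its variation
defines the strata and published stratified tables omit the row. The
derived `labor_number` is `round(household_size * ratio_18_65 / 100)`
because the covariates table carries shares, not a member roster.

`fit_sur()` estimates the eight Pagoda-category intake equations by
one-step feasible GLS (OLS residual covariance with divisor `n - k`,
then GLS on the stacked system — deterministic, no iteration). With a
shared regressor matrix the FGLS point estimates coincide with
per-equation OLS (the textbook result), but the joint Wald test that a
regressor is zero in *all eight* equations uses the cross-equation
covariance and is referred to chi-square with 8 degrees of freedom. A
near-singular residual covariance (relative condition below 1e-12) falls
back to its diagonal — equation-by-equation OLS — with a warning.

`fit_lasso_cv()` is the robustness check: L1-penalized least squares via
glmnet over a 100-point log-spaced penalty grid (down to 1e-4 of the
all-zero penalty), 10-fold cross-validation with folds assigned by a
seeded permutation, and penalty selection by CV minimum (a
one-standard-error option is provided). Predictors are standardized
internally.

## Projection

With fitted constant $\alpha$, aging coefficient $\beta_3$ and income
coefficient $\gamma$, the index in year $t$ is the exact linear plug-in
$y_t = \alpha + \beta_3\,\text{ratio}_t + \gamma\,\text{income}_t$ with
geometric drivers $\text{ratio}_t = \text{ratio}_{t-1}(1+m)$,
$\text{income}_t = \text{income}_{t-1}(1+n)$. Defaults cover 2023–2050
with aging rate m = 0.0103 and income growth n in {0, 2.5, 5, 7.5}%.
Because "annual growth of 1.03%" can also be read as +1.03 percentage
points per year (which more than doubles a 20% elderly share by 2050,
versus ~26% under proportional growth from the same start),
a `linear_increment` mode implements that reading; the multiplicative
mode is the default, matching the printed recursion, and neither reading
is endorsed. The controls drop out of the projection equation by
construction (the constant absorbs them at their estimation-sample
levels); projections are unconstrained linear extrapolations unless an
explicit `clip_range` is supplied, and no uncertainty bands are produced
because the projection model itself states none.

```{r projection}
g <- scenario_grid(c(alpha = 0.693, beta = -0.001, gamma = 0.017),
                   scenario(ratio0 = 26.61, income0 = 2.53),
                   n_values = c(0, 0.025, 0.05, 0.075))
subset(g, year == 2050)[, c("scenario", "ratio", "income", "y")]
```

## Numerical choices and validation design

* Bisection solvers (evenness and quantity scale) run 60 fixed
  iterations, vectorized over households; they are deterministic and
  accurate to ~1e-15 on the unit interval. The quantity solve requires
  an adequacy-only component table — the score is then monotone in the
  scale — and errors otherwise rather than silently mis-inverting.
* The whole generator consumes a single integer seed through base R's
  RNG stream; identical configuration and seed give byte-identical CSVs.
* Estimator correctness is tested against independent oracles: a
  hand-coded clustered sandwich formula, per-equation `lm()` for the
  SUR equivalence, and the soft-threshold closed form for the LASSO on
  a standardized single predictor.
* Statistical calibration is tested by simulation: the focal t-test
  holds its 5% size under a null data-generating process (1,000
  replicates, n = 240), the SUR joint Wald statistic matches
  chi-square(8) tail frequencies (1,000 replicates), and planted aging
  and income effects at the full design size n = 1,080 are recovered
  with correct sign and significance and with nominal 95% CI coverage
  over 200 replicates. These problem sizes are the package's validation
  conditions and are fixed in the test suite.

## Known limitations

* Covariates are mutually independent given the village, so the
  generator cannot exhibit confounding between income and composition;
  estimator robustness to such dependence is untested here.
* CFPS is not separately plantable (see above); its regression recovers
  effects induced through adherence, attenuated relative to the CHEI
  model that drives the quantity scale.
* The cross-sectional design supports association only; no causal
  identification machinery (instruments, panels) is provided.
* Eating away from home is neither simulated nor imputed; the
  standardization removes it from the denominator, as the meal ledger
  was designed to allow.
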