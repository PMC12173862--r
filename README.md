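# ruraldiet

Dietary diversity and diet-quality analysis for rural household
food-consumption surveys.

## What it is for

Surveys of rural Chinese households record every gram of edible food
eaten at home over three consecutive days, a ledger of at-home
person-meals (family and guests), and a rich set of household and
village covariates. ruraldiet turns such records into three
dietary-health indices, estimates how family age composition and income
shape them, and projects the indices decades ahead under joint aging and
income-growth scenarios. It is aimed at nutrition economists and
epidemiologists who need the full pipeline — scoring, inference,
projection — reproducible from a single seed, including a calibrated
synthetic-survey generator so everything runs without access to survey
microdata.

## The indices and models

For per-capita daily intakes over twelve food groups (weight shares
$w_i$):

* **Entropy index** $EI = -\sum_{i=1}^{12} w_i \ln w_i \in [0, \ln 12 = 2.48]$
  — evenness of the diet.
* **Chinese Food Pagoda Score** $CFPS = \sum_{j=1}^{8} s_j \in [0, 8]$,
  where each of the eight guideline categories scores
  $s_j = 1$ inside its recommended band $[L_j, U_j]$, $0.5$ within 50%
  relative distance of a bound, else $0$.
* **Chinese Healthy Eating Index (0–60 variant)**
  $CHEI = \sum_{k=1}^{12} c_k$, with adequacy components
  $c_k = \min(\text{intake}_k / R_k, 1)\times 5$ and limitation
  components ramping linearly from 5 (at the ideal limit $L_k$) to 0
  (at the cut-off $U_k$).

Intakes are standardized by at-home person-days from the meal ledger,
so household size, meals away from home, and guests are all corrected
for. The main model is OLS of each index on the household's under-18 and
over-65 member shares, per-capita income and sixteen controls, with
county fixed effects and cluster-robust (sandwich) standard errors:

```
y_i = alpha + beta_1 ratio_under18_i + beta_3 ratio_over65_i
      + gamma income_i + theta' Z_i + county FE + e_i
```

Heterogeneity splits, an eight-equation SUR over Pagoda-category intakes
with joint Wald tests, and a cross-validated LASSO robustness check
complete the inference layer. Projection extrapolates
`y_t = alpha + beta_3 ratio_t + gamma income_t` with geometric drivers
`ratio_t = ratio_{t-1}(1+m)`, `income_t = income_{t-1}(1+n)`.

## Worked example

```r
library(ruraldiet)

svy    <- generate_survey(seed = 2026)          # 1,080-household design
scores <- score_dataset(svy$consumption, svy$meals)
head(scores, 3)
#>   household_id person_days    EI  CFPS  CHEI
#> 1 h00001             10.7  1.63    2    25.1
#> 2 h00002              8.67 1.20    1    21.4
#> 3 h00003              5.67 0.951   0.5  23.5

fit <- fit_main_model(analysis_frame(scores, svy$covariates),
                      regression_spec("EI"))
fit
#> OLS fit of EI (cluster-robust SEs on household_id)
#>   term                     estimate         se
#>   (Intercept)                 0.601      0.098 ***
#>   ratio_under18               0.001      0.000 ***
#>   ratio_over65               -0.001      0.000 ***
#>   income                      0.019      0.003 ***
#>   ...
#>   County FE Yes   N 1080 (dropped 0)
```

Every extra percentage point of over-65 members lowers dietary diversity
by about 0.001 nats, while each additional 10⁴ Yuan of per-capita income
raises it by about 0.019 — the planted aging-harms / income-helps
pattern, recovered with the correct signs and significance. Feeding the
fitted coefficients into the scenario engine:

```r
g <- scenario_grid(projection_coefs(fit),
                   scenario(ratio0 = 26.61, income0 = 2.53),
                   n_values = c(0, 0.05))
subset(g, year %in% c(2023, 2050))
#>   year ratio income     y scenario
#>   2023  26.6   2.53 0.612 n=0%
#>   2050  35.1   2.53 0.600 n=0%
#>   2023  26.6   2.53 0.612 n=5%
#>   2050  35.1   9.45 0.732 n=5%
```

Without income growth, aging alone erodes the index through 2050; 5%
annual income growth more than offsets it. `run_pipeline()` chains all
stages (simulate → score → fit → project) and persists every
intermediate table as CSV.

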