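# greyrel

Grey relational analysis and intervention regression for short annual
health panels.

## What problem this solves

Evaluating a population-level intervention — say, a phased smoking ban —
often has to work from a handful of short aggregate series: two decades
of annual circulatory-disease mortality per 100,000, stratified by sex,
plus candidate drivers such as smoking rate, physician density and
income per capita. Twenty observations per stratum are too few for a
covariate-rich regression, and no distributional assumption is easy to
defend. Grey relational analysis (GRA) ranks the candidate factors by
the *geometric similarity* of their trajectories to the outcome's
trajectory; a small companion regression then sizes the intervention
effect with bootstrap standard errors. `greyrel` implements both stages
for epidemiologists and policy analysts working with exactly this kind
of data, plus a synthetic panel generator so the whole pipeline runs and
can be validated without any external data.

## The models

For a reference sequence $x_0(k)$ (outcome) and comparison sequences
$x_i(k)$, $k = 1,\dots,m$ years, on mean images
$x'(k) = x(k)/\bar{x}$ with deviations
$\Delta_i(k) = |x_0'(k) - x_i'(k)|$:

- **Deng's degree** — mean of the grey relational coefficients
  $\gamma_i(k) = \dfrac{\min_i\min_k \Delta + \varepsilon\,\max_i\max_k \Delta}
  {\Delta_i(k) + \varepsilon\,\max_i\max_k \Delta}$, resolution
  coefficient $\varepsilon = 0.5$ by default.
- **Absolute degree** — area-based: on zero-start images, with
  $s = \sum_{k=2}^{m-1} X^0(k) + \tfrac12 X^0(m)$,
  degree $= \dfrac{1+|s_0|+|s_i|}{1+|s_0|+|s_i|+|s_i-s_0|}$.
- **Relative degree** — the same construction on initial-value images
  (scale-free, rate-of-change geometry).
- **SDGRA** $= \theta\rho_{abs} + (1-\theta)\rho_{rel}$ and
  **SSGRA** $= (\beta_{deng} + \rho_{abs})/2$ — composite scores.

Factors are ranked per model (descending degree, ties shared after
rounding, `"3(4)"` notation), optionally with factors lagged one year.
The regression stage stacks the sex strata (40 rows), adds a
group-after-intervention dummy, and reports case-resampling bootstrap
standard errors and a Ramsey RESET specification diagnostic. See the
methods vignette (`vignettes/grey-incidence-methods.Rmd`) for the full
account.

## Worked example

```r
library(greyrel)

panel <- simulate_panel(synthetic_spec(seed = 1))
sq <- panel_sequences(panel, "female",
                      factors = c("income", "physician", "smoking"))
gra_table(sq$reference, sq$comparisons)
#> Degrees of grey incidence (epsilon = 0.5, theta = 0.5)
#>
#>     factor  deng rank sdgra rank ssgra rank absolute rank relative rank
#>     income 0.587    3 0.546    3 0.574    3    0.561    2    0.530    3
#>  physician 0.803    1 0.754    1 0.782    1    0.762    1    0.746    1
#>    smoking 0.773    2 0.547    2 0.658    2    0.544    3    0.551    2
```

Each cell is a degree of grey incidence in (0, 1]: closer to 1 means the
factor's trajectory tracks female mortality more closely under that
model's geometry. In this draw physician density ranks first under every
model — as it should, since the generator drives mortality through
physician density plus the post-ban shift.

```r
regress_panel(panel, regression_spec(bootstrap_reps = 1000, seed = 1))
#> OLS with case-resampling bootstrap SEs (1000 reps)
#>
#>             estimate  boot_se sig
#> (Intercept)   52.916 (14.746) ***
#> smoking        0.099  (0.069)
#> physician     -3.902  (6.285)
#> after_ban     -6.030  (2.819)  **
#>
#> Observations: 40
#> R-squared: 0.363
#> Ramsey RESET: F(3, 33) = 0.81, Prob > F = 0.4987
#> Sig.: *** p<0.01, ** p<0.05, * p<0.1
```

The `after_ban` coefficient estimates the excess annual change in female
mortality after the intervention: −6.0 deaths per 100k here, against a
planted truth of −5 in a world calibrated to R² ≈ 0.28 — single draws
are noisy by design; averaged over many panels the estimator is
unbiased (the test suite measures this). The RESET F-test finds no
evidence of misspecification.

The complete workflow (simulate → describe → rank → robustness →
regress) is scripted under `analysis/01_simulate.R` …
`analysis/05_regress.R`; each stage writes its tables under `results/`.

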