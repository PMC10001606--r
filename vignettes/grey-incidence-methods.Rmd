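---
title: "Ranking risk factors of an annual mortality series by degree of grey incidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking risk factors of an annual mortality series by degree of grey incidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greyrel)
```

## The problem

Public-health surveillance often leaves an analyst with a handful of very
short annual series: two decades of circulatory-disease mortality per
100,000, and a few candidate drivers — smoking rate, physician density,
income per capita. With 20 observations per stratum, a regression with
several covariates is fragile, and distributional assumptions are hard to
defend. Grey relational analysis (GRA), from grey system theory, takes a
different route: it scores the *geometric similarity* of each factor's
trajectory to the outcome's trajectory and uses the scores to rank the
factors. It needs no distributional assumptions and works at exactly this
sample size; its output is an ordering, not an effect size. `greyrel`
pairs the ranking stage with a small regression stage that does estimate
an effect size — an intervention dummy with bootstrap standard errors —
so the two stages answer complementary questions.

## The five degrees of grey incidence

All models compare a reference sequence $x_0(k)$ (the outcome) with
comparison sequences $x_i(k)$, $k = 1, \dots, m$ years, after a
normalisation ("image"):

* **mean image** $x'(k) = x(k)/\bar{x}$ — removes units, output has mean 1;
* **initial image** $x(k)/x(1)$ — output starts at 1;
* **zero-start image** $X^0(k) = x(k) - x(1)$ — output starts at 0.

**Deng's degree** is pointwise. On mean images, with deviations
$\Delta_i(k) = |x_0'(k) - x_i'(k)|$,

$$\gamma_i(k) = \frac{\min_i \min_k \Delta_i(k) +
\varepsilon \max_i \max_k \Delta_i(k)}{\Delta_i(k) +
\varepsilon \max_i \max_k \Delta_i(k)}, \qquad
\beta_i = \frac{1}{m}\sum_{k=1}^m \gamma_i(k).$$

The min/max run over all observations *and* all factors in the run (the
classical two-level scope; with one factor the scopes coincide). The
resolution coefficient $\varepsilon \in (0, 1]$ damps the influence of the
largest deviation; the conventional middle value $0.5$ is the default.
$\beta_i$ is invariant under positive rescaling of either series, because
the mean image absorbs scale.

**Absolute degree.** On zero-start images, accumulate the signed area
$s = \sum_{k=2}^{m-1} X^0(k) + \tfrac{1}{2} X^0(m)$ for the reference
($s_0$) and the factor ($s_i$); then

$$\rho_{\mathrm{abs}} = \frac{1 + |s_0| + |s_i|}{1 + |s_0| + |s_i| + |s_i - s_0|}.$$

This is sensitive to the *magnitude* of change (deliberately not
scale-invariant) and equals 1 when the two series differ only by a
constant shift. The construction needs $m \ge 3$, which is why the
sequence type enforces that minimum.

**Relative degree** is the same construction applied to initial images of
the raw data: scale-free, sensitive to *rates* of change, equal to 1 for
proportional series.

**SDGRA** $= \theta\,\rho_{\mathrm{abs}} + (1-\theta)\,\rho_{\mathrm{rel}}$
(default $\theta = 0.5$) and **SSGRA** $= (\beta + \rho_{\mathrm{abs}})/2$
are composite scores mixing the perspectives. Both identities hold
*exactly* on unrounded degrees in `gra_table()`; rounding happens only at
the reporting layer.

Within a run, `gra_table()` applies the mean image uniformly before
Deng's and the absolute degree (the single unit-removing standardisation
the method prescribes), and the initial image — of the raw data — for the
relative degree, which is initial-value based by definition. No z-scoring
is performed anywhere.

### Ranking and ties

Factors are ranked per model by descending degree, on unrounded values.
Two factors whose degrees coincide *after* rounding to the reporting
precision (3 decimals by default) share a rank, printed in the
`"3(4)"` notation: the pair occupies sorted positions 3 and 4 and both
carry the same label. Detecting ties after rounding mirrors how such
tables are read: at 3 printed decimals, 0.6431 and 0.6428 are the same
number.

### Lagged variants

A factor may act with delay: `gra_table(..., lag = 1)` relates the
outcome at year $t$ to factor levels at $t - 1$ via `lag_align()`, which
trims the reference to years where every factor has an observation at
$t - \mathrm{lag}$. With complete years this is pure index bookkeeping
(20 years give 19 aligned pairs); with gaps permitted at load time,
pairing is by year value. The lag must leave at least three pairs.

## The regression stage

The ranking stage says *which* factors matter; the regression stage
estimates *how much* the intervention changed the outcome. The male and
female strata are stacked into $n = 2 \times 20 = 40$ rows and

$$\mathrm{mortality}_{gt} = \alpha + \beta_1\,\mathrm{smoking}_{gt} +
\beta_2\,\mathrm{physician}_t + \delta\,D_{gt} + u_{gt}, \qquad
D_{gt} = \mathbf{1}[g = \mathrm{female},\ t \ge 2012],$$

is fit by OLS. $\delta$ captures the excess post-ban change in female
mortality. Aggregate "total" rows are never stacked alongside the strata
(they would double-count), and the dummy uses the inclusive convention
$t \ge$ ban year.

Because 40 observations are too few for comfortable asymptotics,
standard errors come from a **case-resampling bootstrap**: rows are
resampled with replacement (size $n$), the model is refit, and the SE of
a coefficient is the standard deviation of its estimates across
replications (default 1000, seeded and bit-reproducible). Case
resampling — not residual resampling — is the choice because it samples
from the empirical distribution without assuming the model's error
structure. Rank-deficient resamples are redrawn, with a bounded redraw
budget; the redraw count is retained as an attribute. No autocorrelation
(HAC) correction is applied to these time-indexed rows — a known
limitation worth remembering when interpreting the SEs.

The **Ramsey RESET** diagnostic augments the design with the 2nd–4th
powers of the fitted values and F-tests their joint nullity: numerator
df 3, denominator df $n - p - 3$. At $n = 40$ that gives $F(3, 34)$ for
the 3-parameter specification and $F(3, 33)$ for the 4-parameter one —
a structural identity the test suite checks directly.

## The synthetic panel generator

No individual-level or raw administrative data ship with the package.
`simulate_panel()` draws a fully synthetic stand-in with the statistical
structure the analysis assumes, so every stage runs end to end and
parameter recovery can be measured against known truth:

* 20 years (2001–2020), strata male and female plus a derived total;
* physician density: linear trend, mean ≈ 2.4 per 1,000, small jitter;
* income per capita: multiplicative growth with lognormal rate jitter —
  strictly increasing by construction;
* smoking: male flat near 33%, female near 2.5% with a piecewise-linear
  decline after the 2012 ban year that roughly halves the rate by 2020;
  rates clipped to $[0, 100]$;
* mortality (per 100k of total population, per stratum):
  $\alpha + \beta_{\mathrm{phys}}\,\mathrm{physician} + \beta_{\mathrm{ban}} D + N(0, \sigma)$
  with defaults $\alpha = 66$, $\beta_{\mathrm{phys}} = -9$,
  $\beta_{\mathrm{ban}} = -5$;
* total mortality is the *sum* of the strata — the descriptive tables
  this generator is calibrated against book-keep sex-specific deaths per
  100k of the total population, so strata sum to the total;
* optional alcohol-use and overweight/obesity series feed the five-factor
  robustness table.

Noise enters mortality only; covariates carry deterministic trends plus
small jitter. That is the simplest structure that satisfies the
regression's assumptions while still exercising the curve-similarity
geometry of the ranking stage. The default $\sigma = 5.6$ was calibrated
once, by simulating the default panel over many seeds, so that the full
regression's mean $R^2$ lands near 0.28 — a deliberately noisy world in
which single-draw coefficient estimates wobble but averages recover the
truth.

What the generator does **not** emulate: autocorrelated mortality
shocks, measurement-error spikes in survey-based smoking rates,
demographic composition shifts, and any feedback from mortality to the
covariates. Tests passing on these panels therefore certify the
*machinery* — alignment, degrees, ranking, bootstrap, recovery under the
assumed model — not the correctness of conclusions drawn from any real
panel.

`planted_rank_scenario()` is the ranking test-bed: mortality is built as
a positive multiple of one chosen factor's trajectory plus noise, while
the other factors follow independent trends with deliberately distinct
mean-image signatures (steep growth / gentle growth / decline). The
planted factor should — and in the suite's 200-replicate check does, in
well over 95% of draws — top Deng's ranking; with zero noise and exact
proportionality its Deng and relative degrees are exactly 1.

## Numerical choices and degenerate inputs

* Degrees are computed at full precision; rounding (default 3 decimals)
  applies only to reports and tie detection.
* Perfect-incidence guard: if the maximum mean-image deviation is at or
  below $10^{-12}$ (mean images are $O(1)$ by construction), all
  coefficients are defined as 1 — the 0/0 limit. Without the tolerance,
  exactly proportional series would hit rounding noise of order
  $10^{-16}$ and the coefficients would collapse.
* RESET powers use *standardised* fitted values. The augmented column
  space is identical (the design contains the intercept and the fitted
  values), so the F statistic is unchanged in exact arithmetic, but raw
  powers of a narrow-range fitted series (e.g. 40–46) are numerically
  collinear and would spuriously degenerate the test.
* Degenerate RESET cases — zero residual variance or genuinely collinear
  augmented terms — report statistic 0 with p-value 1 and a `degenerate`
  flag: an exact linear fit is no evidence of misspecification.
* Sequences with zero mean (mean image) or zero first value (initial
  image) raise degenerate-sequence errors rather than propagating
  infinities; missing years are rejected at load time unless explicitly
  allowed, and are never interpolated.
* The intercept-only bootstrap SE is validated against the closed form
  $\sigma/\sqrt{n}$, and the 1000-rep SEs against 10,000-rep SEs (within
  10%) on a fixed panel.

## Problem sizes in the test suite

The simulation-backed checks use 500 synthetic panels ($n = 40$ each)
for coefficient recovery, 200 planted-rank scenarios for ordering
recovery, 1000 random small sequences (length ≤ 6) for brute-force
oracle equivalence at $10^{-12}$, and 2000 bootstrap replications for
the SE calibration check. These sizes keep each property estimate's
Monte-Carlo error comfortably below the margin it is tested against.

## Limitations

The ranking output is an ordering without uncertainty quantification;
different degree models can legitimately disagree, which is why all five
are reported side by side. The regression stage is an ecological,
aggregate-level association — it cannot separate the intervention from
contemporaneous trends beyond what the included covariates absorb, and
its bootstrap SEs ignore serial correlation. The synthetic generator's
simplifications are listed above; none of the package's tests should be
read as validation of substantive claims about any real population.
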