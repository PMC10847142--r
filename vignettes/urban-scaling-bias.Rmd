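---
title: "Modelling city-level implicit bias with urban scaling and learning curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling city-level implicit bias with urban scaling and learning curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbanbias)
```

## The model and its assumptions

Urban scaling theory treats a city as a social network whose average
per-capita interaction count grows as a power of population,
$k \sim N^{\delta}$ with a reference exponent $\delta = 1/6$. `urbanbias`
extends this with heterogeneous mixing between $G$ demographic groups:
group $g$ interacts with its own members at relative rate $1 + h^{in}_g$
and with other groups at $1 - h^{bet}_g$, one avoidance value per group
(no pairwise avoidance matrix). `per_capita_interactions()` evaluates the
resulting decomposition into within- and between-group interactions.

The behavioural assumption is a power-law learning curve: average implicit
bias declines with inter-group exposure as $b \sim k_{inter}^{-\alpha}$,
$0 < \alpha < 1$. For two groups this yields

$$b \;=\; A \, N^{-\delta\alpha} \, (f_1 - f_1^2)^{-\alpha} \,
  (2 - h_1 - h_2)^{-\alpha},$$

three multiplicative terms: a scaling relationship, a diversity
adjustment (maximal mixing at a 50/50 composition), and a segregation
adjustment. The avoidance values are not observable; they are proxied
linearly by residential segregation, $h_g = h^{bet}_0 + b^{bet} s_g$,
with $s_g$ one of four aspatial tract-level indices (mean deviance,
dissimilarity, Gini, correlation ratio). All proportionalities carry an
explicit prefactor (default 1 in the interaction model) so that forward
simulations are deterministic.

Key assumptions to keep in mind: every group avoids all other groups
equally; interaction quality is not modelled, only quantity; segregation
here is aspatial (no tract adjacency); and the bias pipeline is strictly
two-group, matching attitude measures that contrast two groups.

## Two-stage inference and the learning rate

`fit_scaling()` regresses $\ln b$ on $\ln N$ by unweighted OLS (cities are
the units of analysis; a respondent-count weighting option exists but is
off by default). Its residuals $\epsilon_i$ are the scaling deviations.
`fit_adjustments()` then regresses $\epsilon_i$ on the diversity
adjustment $\ln(f_1 - f_1^2)$ and the segregation sum $s_1 + s_2$. The
sum arises from the linearization $\ln(2 - x) \approx \ln 2 - x/2$, which
is accurate to better than 0.01 for $x \le 0.26$ — comfortably covering
realistic avoidance levels; the proxy constants are absorbed into the
intercept and the fitted coefficient.

The model implies $\beta_1 = -\delta\alpha$ and $\beta_2 = -\alpha$.
`estimate_learning_rates()` therefore reports
$\hat\alpha_{scaling} = -\beta_1/\delta$ and
$\hat\alpha_{diversity} = -\beta_2$; the signs are chosen so that a
positive learning rate means bias falls with exposure (quoting the ratio
$\beta_1/\delta$ without the sign flip would make the estimate negative
whenever bias declines with city size). $\delta$ is fixed at $1/6$ rather
than estimated jointly — deviations of the empirical exponent from the
reference value are exactly what the learning rate is read from — and is
exposed as a parameter. Confidence intervals are linear transforms of the
OLS coefficient intervals, exact for a scalar multiple. Agreement of the
two estimates is a substantive check: they are computed from different
regressors and need not coincide unless the learning-curve mechanism
links them.

A caution that the package deliberately preserves rather than hides: the
two-stage procedure attributes to $\ln N$ any component of diversity or
segregation that is correlated with it in-sample. On balanced designs
(see `generate_city_grid()`) the two stages equal the joint regression;
on observational data they can differ. `variance_inflation()` provides
the usual collinearity diagnostic.

### Variance decomposition

How much of the between-city variance in $\ln b$ each factor explains is
not uniquely defined when regressors correlate. `variance_decomposition()`
uses the first-stage $R^2$ as the scaling share, and converts the
second-stage nested-model $R^2$ increments of the diversity and
segregation terms — averaged over the two orders in which the terms can be
added — to the $\ln b$ scale by multiplying by $1 - R^2_{scaling}$. The
three shares then sum to at most 1. Because the mean-deviance values of a
city scale with $p(1-p)$, segregation regressors retain some correlation
with composition, and the order-averaged split assigns half of that shared
variance to each side; a truly null segregation effect therefore shows a
small positive share, not an exact zero.

## The synthetic-city generator

The generator is first-class, tested code: it defines the study
conditions under which the pipeline is validated.

* **Tracts.** A city of population $N$ is divided into
  $M = \mathrm{round}(N/4000)$ tracts (the census-tract scale). Tract
  group-1 shares are drawn from a Beta distribution with mean equal to
  the city share $p$ and concentration $\kappa = (1-s)/s$, where the
  unevenness knob $s$ equals the between-tract share variance as a
  fraction of $p(1-p)$ — so $s$ is approximately the correlation ratio of
  the generated city. $s = 0$ is the exact even distribution; above
  $0.999$ the generator switches to filling whole tracts with one group
  (the complete-segregation limit, where at most one boundary tract is
  mixed). Integer counts are apportioned by capped largest-remainder
  rounding, so tract, group, and city totals are conserved exactly.
* **Defaults as study conditions.** Populations are log-uniform on
  $[5\times10^4, 2\times10^7]$ (the span of U.S. metro areas, without
  assuming an empirical size distribution); majority fractions uniform on
  $[0.55, 0.85]$; unevenness uniform on $[0.05, 0.4]$ (city-level
  segregation values are empirically small). The forward model uses
  $\delta = 1/6$, $\alpha = 0.2$ (compatible with observed scaling and
  diversity slopes), $h^{bet}_0 = 0.1$, $b^{bet} = 0.5$ (implying a
  segregation coefficient $\alpha b^{bet}/2 = 0.05$ on $s_1+s_2$, the
  scale seen empirically), prefactor 0.5 (city means near 0.4, the scale
  of IAT D-score averages), city-level noise $\sigma = 0.1$ on $\ln b$
  (total model $R^2$ near one third), and respondent-level noise 0.4
  (typical D-score spread). Noise enters additively on $\ln b$ —
  multiplicatively on $b$ — because all inference is on logs.
* **Degenerate cities.** Single-group cities are generated-then-flagged:
  `generate_bias()` excludes them with a warning and lists them in an
  attribute, since a zero diversity term is a real hazard in observational
  tables and silent dropping would corrupt joins downstream.
* **What it does not emulate.** No spatial adjacency of tracts, no
  migration dynamics, no respondent-level covariate effects on bias (the
  demographic covariates are drawn independently of the score), and no
  heavy-tailed city-size distribution. Passing tests therefore establish
  that the estimators recover the data-generating process they assume —
  not that real cities obey that process.

### The balanced recovery design

`generate_city_grid()` produces a full-factorial design (population
levels log-spaced and snapped to multiples of 1000, compositions to
multiples of 1/1000, unevenness levels equally spaced) so group counts are
integer-exact and the realized diversity regressor is orthogonal
in-sample to $\ln N$. Exact parameter recovery — learning rates back to
within $10^{-6}$ on noise-free data — is only a well-posed demand on such
a design, and with composition-independent avoidance ($b^{bet} = 0$): with
a random design the first stage absorbs whatever composition variance
happens to correlate with $\ln N$, and with $b^{bet} \ne 0$ the fitted
linear regressor $s_1 + s_2$ only approximates the model's
$\ln(2 - h_1 - h_2)$. The stochastic validation (noise $\sigma = 0.1$,
500 noise replicates on 150 grid cities) checks unbiasedness, near-nominal
95% CI coverage, and agreement of the two learning-rate estimates.

## Segregation indices

Writing $p_m$ for the tract share and $p$ for the city share of a group:
mean deviance $\frac{1}{M}\sum_m |p_m - p|$; dissimilarity
$\sum_m |p_m - p| N_m / (2 N p(1-p))$; Gini
$\sum_{m,l} |p_m - p_l| N_m N_l / (2 N^2 p(1-p))$ over ordered tract
pairs; and the correlation ratio $(I - p)/(1-p)$ with isolation
$I = \sum_m N_{g,m}^2/(N_m N_g)$. All four are 0 for an even distribution;
the last three are 1 under complete segregation. A variant of the
correlation ratio that omits the per-tract total from each summand
circulates in print; evaluated literally it violates both boundary
conditions, so the standard form is the default and the literal variant is
available behind `literal = TRUE` for comparison. Tracts with zero total
population are rejected, not skipped — silently skipping would change $M$
in the mean-deviance denominator. The Gini is computed by an
$O(M \log M)$ sorted form; the test suite checks all four indices against
naive double-loop oracles to $10^{-12}$ on a thousand random cities.

## Noise ceilings

`noise_ceiling()` repeats, for each of `n_splits` permutations (default
500), a random within-city split of respondents into halves; the lower
bound is the between-half correlation of city means, the upper bound the
mean correlation of each half with the full-sample means. With
between-city sd $\tau$, within-city sd $\sigma$, and $n$ respondents per
city, the lower bound converges to $\tau^2/(\tau^2 + 2\sigma^2/n)$. Note
that the upper bound correlates each half with a quantity containing that
half, so under a pure-noise null it converges to $\sqrt{1/2}$ rather than
0 — only the lower bound is a valid null diagnostic. Pearson correlation
is the default (the framing is variance-based), Spearman is available by
flag; an odd respondent joins a half uniformly at random; cities
contribute unweighted. The noise-corrected $R^2$ is reported as
$R^2 / \mathrm{lower}^2$.

## Temporal precedence on short panels

`granger_test()` compares a restricted autoregression of $y_t$ on its own
lags with the unrestricted model adding lags of $x$, and returns both the
small-sample F statistic and the asymptotic $\chi^2$ variant
$n(SSR_r - SSR_u)/SSR_u$. On 10-point series the $\chi^2$ variant rejects
a true null at roughly three times the nominal rate, while the F test
holds its size, so `precedence_summary()` uses the F p-value for its
significance decisions by default and exposes the $\chi^2$ decision via
`test = "ssr_chi2"`. At lag 3 on a 10-year panel the unrestricted model
is saturated (seven observations, seven parameters): its SSR is zero,
the $\chi^2$ statistic is infinite, and every city appears "significant"
in both directions. The package returns `NA` for the undefined F variant
there and falls back to the $\chi^2$ p-value, so lag-3 percentages from
10-year panels should be read as an artifact of the test, not as
evidence. Series are tested on the transformed scales used in fitting
($\ln N$, the diversity adjustment, the segregation sum, $\ln b$), with
no differencing or stationarity pre-processing (the panels are 10
points). Percentages of significant cities are bootstrapped over cities
(default 1000 resamples) for standard errors; `combine_measures()` pools
four per-measure standard errors as the root mean square.

The panel generator gives each city a latent city-growth factor: a
fraction `common_frac` (default 0.7) of each structural series' innovation
variance is shared. Under structural-to-bias coupling the bias series
responds to this common factor lagged by `lag`; this is what makes each
individual structural variable informative about bias in the pairwise
tests, as a common-cause structure would in real cities. No multiple
testing correction is applied across lags, directions, or measures —
each combination addresses the same hypothesis on a different slice, not
competing hypotheses on one dataset.

## Individual-level controls

`fit_individual()` turns respondent scores into the indicator
$D_{biep} > 0$ and fits a logistic regression on the city-level structural
variables joined by city plus respondent race, education, and birth sex.
The 14-level education code collapses to three categories (defaults: 1–6,
7–11, 12–14; the cut table is configurable since conventions vary), race
to White / Black / Multiracial with everything else, unknown included, as
the base category (a user-supplied code map accommodates raw code lists).
Covariate categories with no respondents are dropped with a warning; a
constant outcome stops with an explicit separation error instead of
returning a silent estimate.

## Numerical and design choices

* Respondent filter: cities are retained with at least 500 respondents
  (`min_responses`), with 250 and 1000 as conventional robustness
  alternates; the filter applies at fit or read time.
* Integer apportionment uses water-filling to a capped proportional
  allocation followed by largest-remainder rounding; totals are conserved
  exactly, which the tests treat as an invariant, and per-tract capacities
  are never exceeded.
* All generators and resampling routines are pure functions of their
  arguments and a `seed`; they restore the caller's RNG state.
  `run_pipeline()` is byte-identical across runs with the same seed.
* Reals are serialized to CSV at 17 significant digits, so write-read
  round-trips are lossless.
* Problem sizes used in the validation suite: 150 grid cities for
  recovery (500 noise replicates), 200 cities for ceiling calibration,
  2000 replicates for Granger null size, and 43-city, 10-year panels for
  precedence — comfortably larger than needed for the effects involved
  while keeping the full suite fast on a laptop.

## Known limitations

The two-stage estimator is exactly unbiased only on composition-balanced
designs; the linear segregation proxy is an approximation whose quality
degrades for highly avoidant cities; the noise-ceiling upper bound is not
a null-calibrated statistic; lag-3 precedence on 10-year panels is
degenerate by construction; and synthetic validation certifies estimator
correctness under the stated generative model, not the model's truth in
any real city system.
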