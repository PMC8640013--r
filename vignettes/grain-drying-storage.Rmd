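---
title: "Modelling grain drying kinetics, shrinkage, diffusivity and storage quality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling grain drying kinetics, shrinkage, diffusivity and storage quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`graindry` implements the quantitative workflow used in post-harvest grain
process studies, with soybean as the motivating crop: thin-layer drying
kinetics, unit volumetric shrinkage, effective moisture diffusivity from
Fick's second law for a sphere, Arrhenius analysis of diffusivity against
drying air temperature, and a multivariate analysis of factorial
storage-quality experiments. Every stage is paired with a seeded synthetic
generator so that each estimator can be exercised against data with known
ground truth.

## Moisture ratio and the thin-layer models

Drying records are dry-basis moisture $X$ (kg water per kg dry matter,
decimal) against time $t$ in hours. The dimensionless moisture ratio

$$MR(t) = \frac{X(t) - X_e}{X_0 - X_e}$$

normalizes a curve to start at 1 and decay towards 0 as the grain
approaches the equilibrium moisture $X_e$ with the drying air. Eleven
classical semi-empirical models for $MR(t)$ are registered (Newton, Page,
modified Page, Henderson & Pabis and its modified three-term form,
logarithmic, two-term, two-exponential-term, Wang & Singh, Midilli,
diffusion approximation); `drying_models()` lists them and
`drying_model(name)` returns the closed form, parameter names, bounds and
a data-driven initialization rule.

Choices that matter:

* **Time unit.** Hours throughout the drying-model layer, because drying
  constants $k$ are conventionally reported in h$^{-1}$; seconds appear
  only at the diffusivity boundary, where transport coefficients are in
  m$^2$ s$^{-1}$.
* **$X_e$ policy.** $X_e$ is ideally measured or taken from a sorption
  isotherm and is supplied by the user. When absent, `moisture_ratio()`
  falls back to $0.9 \cdot \min(X)$ with a warning. The fallback keeps MR
  strictly positive and well-defined without smuggling in an isotherm
  model; it is a pragmatic default, not a recommendation.
* **Noisy tails.** Observations at or below $X_e$ (possible in noisy
  tails) clip to $MR = 0$ with a warning rather than erroring or going
  negative: real curves end in instrument noise around equilibrium.
* **Bounds.** Box bounds $k, k_0, k_1 \in (10^{-6}, 10^3)$ h$^{-1}$,
  $n \in (10^{-6}, 10)$ and coefficients $a, b, c \in (-100, 100)$
  bracket published estimates for cereal and oilseed drying with wide
  margin (published soybean sets reach $b = 55$ for the diffusion
  approximation at 120&nbsp;°C, which is why the coefficient box is
  wider than a first guess would make it).

## Shrinkage

Grain volume is the triaxial ellipsoid $V_g = \pi a b c / 6$ from caliper
axes in mm, and the unit volumetric shrinkage $\psi_g$ is the volume at a
given moisture divided by the initial volume. Six models are registered
(`shrinkage_models()`): Bala & Woods, Lang & Sokhansanj, Rahman, Corrêa,
a plain line and an exponential. Lang & Sokhansanj's slope
$\beta_1 = a + b\,UR + c\,T$ is fitted as a single free scalar per
condition - per-condition coefficient tables report exactly one slope, so
the decomposition into humidity and temperature terms is not identifiable
from a single curve and is not attempted. Rahman's and the line's forms
are exact re-parameterizations of one another
($a_{line} = a_R - \beta_2 X_0$, $b_{line} = \beta_2$); the test suite
asserts their fitted SSE agrees to $10^{-10}$, a useful internal
consistency check on the optimizer.

Some published shrinkage coefficient sets evaluate outside the physical
$\psi_g \in (0, 1.2]$ band (a Rahman intercept near 0.27 implies
$\psi_g(X_0) \approx 0.27$, not 1, suggesting a moisture-scale
inconsistency in the source tables). The package therefore validates
ranges in `shrinkage_series()` but lets `gen_shrinkage_series(...,
validate = FALSE)` produce such series verbatim: parameter-recovery
exercises only need internal consistency, and silently "fixing" published
numbers would be worse than carrying them as printed.

## Fitting engine

`fit_model()` minimizes the residual sum of squares over the bounded
parameter box with Levenberg-Marquardt least squares (`minpack.lm`),
started from the model's data-driven initialization plus seven
multiplicatively jittered copies ($\times U(0.5, 2)$ per parameter,
seeded). The contract is "global SSE minimum within bounds", not a named
algorithm: on these smooth low-dimensional problems a bounded
trust-region/LM search from multiple starts finds the same minimum a
Quasi-Newton search would, and the test suite pins this with an
exhaustive grid-search oracle (step $10^{-3}$) on all one- and
two-parameter models.

Reported statistics follow drying-literature conventions:
$R^2$ (percent), the mean relative error
$P = \frac{100}{n}\sum |Y - \hat Y| / Y$, the average estimated error
$SE = \sqrt{\sum (Y - \hat Y)^2 / GLR}$ with $GLR$ the residual degrees
of freedom, and a classification of the residual distribution. Coefficient
t-tests from the Jacobian-based covariance are reported but deliberately
play no role in ranking.

**Residual classification.** "Tendentious" residuals - a systematic trend
the model fails to capture - produce few sign runs. The classifier is an
exact Wald-Wolfowitz runs test, one-sided on the lower tail of the
run-count distribution at $\alpha = 0.05$: too few runs means tendentious,
while long alternating patterns (many runs, negative serial correlation)
are not evidence of lack of fit and stay "random". The exact combinatorial
distribution is used up to $n = 60$, the normal approximation with
continuity correction beyond. Zero residuals inherit the preceding sign;
an all-zero (perfect-fit) residual vector is random by convention.

**Ranking.** `rank_models()` orders fits lexicographically: random
residuals first, then $P < 10\%$ (the conventional acceptability
threshold, configurable), then lowest SE, then highest $R^2$. A fit is
"acceptable" when it clears the first two rules.

**Identifiability.** Parameter recovery from noiseless self-generated
data (12 points, 8 starts) is the package's core recovery property and
holds to $10^{-3}$ relative error for the nine identifiable drying models
and all six shrinkage models across 50 random draws each. The two
exponential-sum models (`two_terms`, `henderson_pabis_modified`) are
identified only up to permutation and near-degeneracy of their
components - many parameter vectors produce numerically identical curves -
so their recovery is asserted in function space (fitted curve within
$10^{-4}$ of the generating curve), which is the scientifically meaningful
statement for those models.

## Diffusivity and Arrhenius analysis

For a sphere of radius $R$ with uniform initial moisture and surface at
$X_e$, Fick's second law gives

$$MR(t) = \frac{6}{\pi^2} \sum_{n=1}^{\infty} \frac{1}{n^2}
  \exp\!\left(-\frac{D n^2 \pi^2 t}{R^2}\right).$$

Two estimators of the effective diffusivity $D$ are provided:

* `estimate_d_slopes()` - the method of slopes: regress $\ln MR$ on time
  over the window $MR < 0.6$, where the first series term dominates, and
  convert the slope via $D = -\text{slope} \cdot R^2 / \pi^2$. The 0.6
  window is standard practice and configurable.
* `estimate_d_series()` - one-parameter bounded least squares of the
  truncated series against the observations, searched over $\log_{10} D$
  for conditioning, $D \in [10^{-13}, 10^{-7}]$ m$^2$ s$^{-1}$.

Truncation: 50 terms are ample for fitting at $t > 0$ (the $n$-th term
decays like $e^{-n^2}$ in the exponent), while generation near $t = 0$
uses 1000 terms; the truncation error at $t = 0$ is bounded by
$6/(\pi^2 N)$ and the test suite asserts that bound. Note the truncated
series at $t = 0$ is structurally independent of $D$, so a residual there
cannot bias the series fit.

The equivalent sphere radius is not usually reported;
`equivalent_radius_m()` supplies the volume-equivalent
$(abc)^{1/3}/2$ from caliper axes, and all estimators take the radius
explicitly. `arrhenius_fit()` recovers $D = A\exp(-E/RT)$ by ordinary
regression of $\ln D$ on $1/T$, with $R = 8314$ J kmol$^{-1}$ K$^{-1}$
and $E$ reported in kJ kmol$^{-1}$ (sources sometimes print the gas
constant with kJ units; dimensionally it must be J kmol$^{-1}$ K$^{-1}$).

## Storage-quality multivariate analysis

Factorial storage experiments cross harvest moisture (18, 23% d.b.),
drying temperature (80, 100, 120 °C and a mixed lot), storage temperature
(15, 23, 30 °C), package (paper `P`, polyethylene `PL`) and storage time
(0, 4, 8 months), with replicated measurements of moisture, electrical
conductivity (EC), oil, lipid acidity and crude protein.
`run_storage_pipeline()` chains:

1. treatment means over replicates (dendrogram leaves are treatments,
   which implies means, not replicates, are clustered);
2. column standardization (mean 0, sample SD 1) - mandatory before
   Euclidean distances across variables on scales as different as
   percent oil and µS cm$^{-1}$ g$^{-1}$ EC;
3. Ward minimum-variance clustering on Euclidean distances. The Ward
   dialect is fixed to the squared-Euclidean update (`hclust`
   `"ward.D2"`) because Ward implementations differ and silent dialect
   drift is a classic reproducibility trap. `k` is user-chosen
   (default 4); no automatic cut criterion is invented;
4. per-cluster Pearson correlations over the *raw* variables (clusters
   under 3 members, or within-cluster constant variables, yield `NA`
   entries, never fabricated zeros);
5. compact-letter Tukey displays per quality variable, in the two
   directions storage tables conventionally report: across times within
   each storage-condition cell, and across conditions within each time.
   Letters come from one-way ANOVA + `TukeyHSD` (studentized range) with
   an insert-and-absorb letter assignment, 'a' for the highest mean.
   At fixed data, $\alpha = 0.01$ can only merge letters relative to
   $\alpha = 0.05$.

All five quality variables enter the clustering by default; the variable
set is an argument for sensitivity analysis.

## The synthetic storage generator

`gen_storage_table()` emulates the factorial above (432 records at 3
replicates). Each variable responds linearly to a latent *damage* score,
the sum of:

* a drying/harvest component (0 at 80 °C/23% harvest, rising to 0.65 at
  120 °C, plus 0.15 for the 18% harvest) - so even time-0 lots differ in
  a correlated way, as real time-0 quality tables do; and
* a storage-severity component determined by (time, storage temperature,
  package). Time 0 is exactly zero everywhere - a lot's quality at the
  start of storage cannot depend on where it will later be stored. The
  twelve stressed cells take values in three deliberately separated bands
  (3.0-3.6, 7.0-7.6, 11.0-11.6), ordered within each band so severity
  grows with time, temperature and package permeability (paper bags
  breathe, polyethylene protects).

Oil and protein carry negative damage coefficients, EC and acidity
positive ones. This single-latent-variable construction is what makes the
generator's statistical structure match the analysis assumptions: EC is
anti-correlated with oil and protein *within* every group (the
within-group variation comes from the drying/harvest component plus the
within-band severity spread, both of which exceed the noise), oil and
protein move together, and the four severity bands plant a four-group
structure that Ward clustering at $k = 4$ recovers with adjusted Rand
index 1 across seeds.

Why a severity *table* rather than per-month slopes: a pure
slope-times-months parameterization cannot produce well-separated groups
while keeping every cell's degradation monotone in time - eight-month
mild cells inevitably collide with four-month moderate cells. The table
keeps both properties and remains fully user-configurable.

Baselines default to a fresh, gently dried lot (moisture 10.31% d.b., EC
191 µS cm$^{-1}$ g$^{-1}$, oil 25.89%, acidity 5.54 mL, protein 35.69%),
and coefficients are scaled so severe cells lose roughly 5 points of oil
and 10 of protein and gain roughly 160 µS cm$^{-1}$ g$^{-1}$ of EC over 8
months - the order of magnitude of published stored-soybean tables. The
generator is a *structural* emulation: it reproduces design, trend
directions, correlation structure and separation, not any particular
measured dataset. Real storage data add features the generator omits -
non-monotone moisture (re-humidification at high ambient RH),
heteroscedastic noise, occasional outlying replicates - so passing the
recovery suite shows the estimators work when their assumptions hold, not
that those assumptions hold in any given warehouse.

Noise is additive Gaussian, independent across samples, on each measured
scale (SDs: moisture 0.08, EC 3, oil 0.15, acidity 0.06, protein 0.2 in
the variables' own units); drying/shrinkage/Fick generators likewise add
Gaussian noise but keep the initial reference observation noiseless,
since the normalization anchor ($X_0$, $\psi = 1$) is a definition rather
than a measurement.

## Problem sizes and numerical choices

The recovery and property suites use 12-point curves, 50 parameter draws
per model, 8 optimizer starts, 20-seed cluster-recovery sweeps and
200-replicate noise studies - sizes at which every property is stable and
the whole suite runs in under a minute on a laptop. Grid oracles use
fixed a-priori boxes over the physically plausible parameter region with
step $10^{-3}$; along strongly correlated parameter ridges (e.g. the
$a e^{bX}$ models) grid quantization inflates to a few steps, which the
oracle comparisons account for by comparing SSE primarily and parameters
secondarily.

Degenerate inputs are contract errors, not silent results: constant
predictors, constant observed vectors (undefined $R^2$), zero
observations (undefined $P$), $GLR < 1$, $X_0 \le X_e$, non-positive
axes, empty series, single replicates in Tukey cells, constant columns in
standardization. Where published parameter tables are internally
inconsistent, the package carries them verbatim and leaves validation to
explicit validators rather than guessing corrections.

## Known limitations

* No sorption-isotherm modelling: $X_e$ must come from the user (or the
  documented fallback).
* Constant effective diffusivity; no moisture-dependent $D$, no
  finite-difference PDE solver - the analytical sphere series is the
  implemented solution.
* Unweighted least squares only; no autocorrelation-robust errors for
  the drying fits.
* The compact-letter Tukey display assumes a balanced one-way layout per
  call; factorial structure is handled by calling it per cell, as
  storage tables conventionally do, not by a joint mixed model.
* The storage generator's linear single-latent-damage construction is a
  deliberate simplification; it is not a deterioration-kinetics model.
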