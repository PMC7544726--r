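---
title: "Methods: assigned share of radiation with Monte Carlo uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assigned share of radiation with Monte Carlo uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radshare)
```

## The quantity being computed

The assigned share (probability of causation) for a cancer diagnosed at
attained age $a$ is

$$Z = \frac{h}{\lambda_0 + h},$$

with $\lambda_0$ the baseline incidence rate of the matching unexposed
population (PY$^{-1}$) and $h$ the radiation-attributed excess rate. $Z$
lies in $[0, 1)$ for non-negative excess; a negative sampled excess
(possible under Gaussian parameter uncertainty of a non-significant risk)
is retained in intermediate sums — preserving the sampled correlation
structure across exposures — and $Z$ is floored at zero only at the end.

Risks are estimated from cohort models of two kinds,

$$\lambda = \lambda_0 (1 + \mathrm{ERR}) = \lambda_0 + \mathrm{EAR},
\qquad
\mathrm{ERR}\ \text{or}\ \mathrm{EAR} = p(\boldsymbol\rho\,|\,d, s)\,
r(\boldsymbol\rho\,|\,s, a, e),$$

where $p$ is the dose response and $r$ the effect-modifier product. EAR
coefficients follow the cohort-table convention of $10^{-4}$ PY$^{-1}$
Gy$^{-1}$ and are converted internally. Supported dose-response forms:
linear $\beta d$, quadratic $\alpha d^2$, linear-quadratic, power
$\beta d^\gamma$ ($\gamma > 0$), quadratic-exponential
$(\beta d + \alpha d^2)e^{\delta d}$, and a continuous two-slope
threshold-linear spline with a configurable knot (default 0.7 Gy, matching
the dose region where non-linear leukaemia responses change slope). Every
form vanishes at zero dose.

### Modifier parameterisation

The modifiers use the field's standard centring: sex enters as
$e^{\sigma s}$ with $s = -1$ (male) and $+1$ (female) — a $(1 + \sigma s)$
convention is accepted via configuration, since published sex-averaged
coefficients do not always identify which convention produced the
sex-specific values; attained age as $(a/70)^\phi$; age at exposure as
$e^{\psi (e - 30)/10}$ (per decade). With all modifiers inactive $r \equiv 1$.
An optional log-linear smoking-intensity modifier $e^{\theta\,\mathrm{cpd}}$
supports smoking-interaction lung models; its coefficients are user
configuration, as are the radon models (linear in working-level months for
miners, linear in concentration × duration for indoor exposure).

### Baseline and risk transfer

The cohort baseline is
$\lambda_{0m} = f(s,a,b)\, \bar g\, \cdot \text{screening}(y)$ with
log-linear $f$ in sex, $\log(a/70)$ and birth-year decade; the cohort factor
$g(c, \mathrm{IC})$ over city and in-city strata is meaningless for a target
population, so it enters as a pre-averaged multiplier $\bar g$ (weighted by
cases or person-years, the user's choice at fit time). Calendar time in the
cohort is anchored at 1945: a diagnosis $t$ years after exposure maps to
cohort year $1945 + t$.

Transfer to the target population mixes additive and multiplicative modes,

$$h = h_m (1 - f + f B), \qquad B = \lambda_0 / \lambda_{0m},$$

with one $f \sim U(0,1)$ per iteration shared across exposures (maximum
entropy in the absence of mechanistic knowledge; a fixed $f = 0.5$ override
supports best-estimate comparisons, and non-uniform $f$ distributions can be
configured). $B$ is evaluated per exposure at the actual attained age, the
target diagnosis year and the mapped cohort year. Models without a usable
baseline parametrisation (pooled-cohort breast, smoking-adjusted lung)
instead sample $B$ log-uniformly on $[1/3, 3]$; for an ERR model the implied
cohort baseline is then $\lambda_0 / B$.

### Multiple exposures, caps and twins

Excess rates add across exposures (organ-specific rates are small enough
that interactions are negligible), giving

$$Z = \frac{(1-f)\sum_i h_{m,i} + f \sum_i h_{m,i} B_i}
          {\lambda_0 + (1-f)\sum_i h_{m,i} + f \sum_i h_{m,i} B_i}.$$

Cohort follow-up supports solid-cancer risk only up to 53 years since
exposure, and hematopoietic risk between 5 and 56 years. The engine clamps
the *evaluation* time accordingly and shifts the model evaluation ages with
it ($a_\text{eff} = e_i + t_\text{eff}$, cohort year $1945 + t_\text{eff}$),
while the latency factor and the target baseline always use the raw times —
so the assigned share is frozen at the boundary rather than extrapolated.

Non-linear dose responses would make fractionated or protracted exposures
vanish (a pure quadratic response under $k$ fractions scales as $1/k$ — the
package reproduces the 10-fold and 100-fold reductions exactly). Each
non-linear leukaemia model therefore carries a linear *twin* sharing its
baseline and modifiers; within each iteration the assigned share is computed
for both with identical samples and the maximum is kept, which hands control
to the linear twin at low doses. For smoking-interaction lung models the
analogous conservative device is the pointwise maximum ERR across the model
group, flattening the implausible ERR collapse at high smoking intensities.

## Adjustment factors

**Latency.** $F_L(t) = [1 + e^{-\eta \ln(t/t_0)}]^{-1}$ multiplies the
excess: zero at $t = 0$, one half at $t = t_0$. Solid cancers sample
$t_0 \sim U(3, 4)$ y with $\eta = 6.25$; hematopoietic malignancies
$t_0 \sim U(1.25, 1.75)$ y with $\eta = 7.66$ — in practice only the first
~6 y (solid) or ~2 y (hematopoietic) after exposure are affected.

**DREF.** The dose-rate effectiveness factor is lognormal with geometric
mean 1 and $\mathrm{GSD}(dr) = \max(1.0,\, 1.1803 - 0.2317 \log_{10} dr)$
below the 6 mGy/h threshold (GSD 1.5 at 1 mGy/day); above it GSD $= 1$.
One percentile $u$ is drawn per iteration and shared across exposures, each
exposure applying its own GSD from its dose rate (sampled dose / duration).
The DREF divides the excess, so with GM $= 1$ the median assigned share is
unchanged while the uncertainty bounds widen at low dose rates — a property
checked by a common-random-numbers test. Missing duration means the dose
rate is unknown and the DREF is fixed at 1 (no adjustment, documented
convention); radon exposures never receive a DREF.

**Cohort factors.** For models fitted to the atomic-bomb survivor cohort, a
dosimetry factor (lognormal, GM 1, GSD 1.1) divides the excess (a bias in
cohort doses scales risk coefficients inversely — a stated convention, since
the direction is not defined by the source material), and a neutron
weighting factor (triangular on $[5, 30]$, mode 10) perturbs it through a
configurable linear sensitivity per organ class, defaulting to zero because
the published response functions live in an external report.

## Multi-model inference

Model weights derive from AIC, $w_i \propto e^{-\Delta \mathrm{AIC}_i / 2}$
(`AIC = dev + 2·n_params`), optionally arranged in a weight tree whose fixed
branch weights express decisions such as the 50/50 split between
sex-specific and joint attained-age model sets. Two assignment modes exist:
*stratified* (default) converts the flattened branch × AIC product weights
into exact per-iteration counts by largest-remainder rounding — two models
weighted 60/40 at 10,000 iterations receive exactly 6000 and 4000
realizations — and *random* draws a model per iteration. Stratified
allocation over product weights is equivalent in expectation to per-branch
stratification and keeps the realization split exactly reproducible, which
is why it is the default.

## The Monte Carlo protocol

Per iteration: assign the model; draw its parameters from the multivariate
normal defined by the fitted covariance (a covariance whose smallest
eigenvalue is negative but within $-10^{-10}$ of the trace is clipped to
PSD — tolerating serialisation round-trips without hiding genuinely broken
configurations); draw latency parameters, $f$, the DREF percentile and the
target baseline (Poisson around the registered case count — a zero count is
floored at 0.5 cases so the baseline cannot degenerate and force
$Z \to 1$); draw per-exposure doses independently from their stated
uncertainty distributions (normal doses truncated at zero by rejection;
doses in mSv are converted to Gy); evaluate the combined $Z$; apply the
twin rule. All other sampled factors are iteration-level and shared across
exposures (fully correlated, as the exposures belong to one individual).
Everything is reproducible under a single seed.

Summaries report the mean, median, requested percentiles and the 68%
(16–84) and 95% (2.5–97.5) intervals, with linear interpolation between
order statistics (quantile type 7; the choice is a documented convention).

## Fitting grouped cohort tables

The fitter minimises the grouped Poisson deviance

$$\mathrm{dev} = 2 \sum_{i: n_i \ne 0}
  \left[ n_i \ln \frac{n_i}{\mu_i} - (n_i - \mu_i) \right]
  + 2 \sum_{i: n_i = 0} \mu_i,
\qquad \mu_i = \lambda(\boldsymbol\beta, X_i)\, PY_i$$

over cells $X_i = (s, a, e, d, c, \mathrm{IC}, n, PY)$, by BFGS quasi-Newton
iteration with numerically differenced gradients, three starts (an analytic
intercept start, $b_0 = \log(\sum n / \sum PY)$, plus jittered copies) to
guard against local minima, and relative convergence tolerance $10^{-12}$.
The covariance is the inverse of half the deviance Hessian at the optimum
(observed information); a singular Hessian flags the fit as non-converged.
Model reduction uses likelihood-ratio tests: non-significant
($p > 0.05$) modifiers and baseline terms are dropped iteratively, but the
primary dose-response coefficient is never removed even when its confidence
interval includes zero — weak risks must surface as wide $Z$ distributions,
not silently disappear. The dedicated deviance and rate forms are the point
of this module; a `glm()` fit with a person-year offset serves as an
independent oracle for the log-linear baseline special case in the test
suite.

## What the synthetic data emulate — and what they do not

`generate_population_table()` produces a registry-like table (5-year age
bands, log-linear rate surface in age and calendar year, Poisson counts);
`generate_cohort_cells()` produces grouped cohort tables from a known true
model over a dose grid of 0–4 Gy; `generate_smoking_prevalence()` a
plausible national smoking table; `example_model_sets()` ready-to-run model
sets built from published grouped-model constants with **illustrative
diagonal covariances** back-computed from printed Wald p-values and
**synthetic baselines**. Passing tests on these fixtures demonstrates that
the machinery is correct (estimators recover known truths, invariants hold,
formats round-trip); it does not validate the example parameter values
against any real cohort, reproduce restricted cohort analyses, or certify
the packaged sets for claims adjudication.

Problem sizes in the test suite were chosen as the smallest that make the
statistical assertions sharp: Monte Carlo checks at $10^4$–$10^5$ draws with
3-standard-error bands, engine runs of a few hundred to $10^4$ iterations,
and the parameter-recovery study at 200 replicates of a 48-cell table with
$10^5$ person-years per cell, asserting 95% Wald coverage within its
binomial 3-sigma band.

## Known limitations

* The packaged example model sets are structural stand-ins: real
  applications must supply fitted model sets (the YAML schema is the
  contract).
* Smoking-interaction and radon coefficients are configuration, not
  shipped values.
* The neutron-weighting sensitivity defaults to a no-op.
* Competing risks, non-cancer endpoints, benign tumours and mechanistic
  carcinogenesis models are out of scope.
* Whether negative sampled excess should be clipped before or after summing
  across exposures is not externally defined; the after-sum convention is
  the default and documented above.
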