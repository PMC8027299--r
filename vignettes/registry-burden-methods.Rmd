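---
title: "Estimating cancer burden from incomplete registries: models and design"
author: "RegistryBurden maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cancer burden from incomplete registries: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

National cancer registries in middle-income countries under-ascertain
cases, lose demographic fields, accumulate duplicate entries, and change
administrative geographies mid-stream. RegistryBurden implements a complete,
testable pipeline from such record-level registry data to subnational burden
estimates: age-standardized incidence (ASIR), death (ASDR) and
years-of-life-lost (ASYR) rates with 95% uncertainty intervals, annual
percent changes (APC), mortality-to-incidence ratios (MIR), a decomposition
of the change in annual case counts, and an age-period-cohort analysis with
the intrinsic estimator. The motivating application is female breast cancer
across 31 provinces over 1990–2016, estimated from a cancer registration
system (CRS), a death registration system (DRS) and a partially overlapping
insurance-based cancer registry used as a reference capture source.

Because real registry microdata of this kind are confidential, the package
ships a synthetic-registry generator with known ground truth. Every
downstream stage is tested against that truth; the published national and
subnational endpoint estimates bundled in `referenceEstimates()` are used to
verify the trend arithmetic (APC, fold changes, case-count increases)
reproduces the published figures.

# Pipeline overview

1. **Synthetic registries** (`makeGeography()`, `simulateTruth()`,
   `simulateRegistry()`): Poisson events from a log-linear rate surface;
   per-source registration probabilities; field missingness; duplicates.
2. **Preparation** (`deduplicate()`, `imputeMissing()`,
   `estimateCompleteness()`, `correctCounts()`, `remapProvinces()`,
   `aggregateCounts()`): record-level cleaning to corrected panel counts.
3. **Two-stage rate model** (`fitStage1()`, `buildWeights()`,
   `smoothResiduals()`, `sampleDraws()`, `uncertaintyInterval()`,
   `estimateRates()`): a Poisson mixed model, then empirical-Bayes
   smoothing of its residuals across neighbouring provinces, adjacent age
   groups and nearby years, with Monte-Carlo uncertainty.
4. **Cause fractions** (`fitCauseFractions()`, `applyToEnvelope()`):
   multinomial allocation of all-cause envelopes, conserving totals.
5. **Burden metrics** (`ageStandardize()`, `computeAPC()`, `computeYLL()`,
   `computeMIR()`, `standardizedSeries()`).
6. **Decomposition** (`decomposeChange()`) and **age-period-cohort
   analysis** (`lexisTable()`, `fitIE()`).
7. **Orchestration** (`runPipeline()`), writing per-location summary
   tables, full rate surfaces, a decomposition JSON, APC effects and a run
   manifest. The package's interface is its functions; `runPipeline()` is
   the single entry point for an end-to-end run.

# The synthetic registry generator

The generator's defaults are the study conditions for every test. Log
incidence for province $p$, age group $a$ (5-year groups 15–19 … 85+,
$A = 15$) and year $t$ is

$$\log \lambda_{pat} = \log \beta_a + u_p + g_p\,(t - t_0) + \delta_{pa},$$

where $\beta_a$ is a baseline age profile rising steeply after age 40
(about 1.2 per 100,000 at 15–19 to near 100 at the oldest groups in the
first year), $u_p$ is a province effect (iid sd 0.25 plus a spatially
correlated component of scale 0.15 built from the row-normalised smoothed
adjacency kernel), $g_p \approx \log(1 + s_p)$ with province annual changes
$s_p \sim N(0.048, 0.015^2)$, and $\delta_{pa}$ is a smooth, time-constant
province-specific age-profile deviation (log sd 0.1). The mean annual
change of 4.8% matches the national incidence trend of the motivating
application; the between-province spread reflects the published provincial
APC range (0.8%–6.8%). The age-profile deviations exist because a two-stage
model is pointless on data whose truth is exactly the stage-one functional
form: real provinces differ in where their burden concentrates, and the
second stage exists to capture precisely such structure. Mortality is
incidence times a mortality fraction starting at 0.44 and declining 5% per
year, emulating improving case fatality; mortality never exceeds incidence.

Observation noise: each true case enters the CRS with probability 0.8 and
the reference source with probability 0.9, independently; deaths enter the
DRS with probability 0.85; ages, sexes and provinces go missing with
probabilities 0.05/0.03/0.04; each registered row is duplicated with
probability 0.05, the duplicate carrying a distinct record id that
normalises (case/whitespace) onto the original. CRS and reference rows of
the same case share a person identifier, as insurance-linked registries do.

What the generator does **not** emulate: migration, male cases, diagnostic
drift or registry-improvement artefacts, ICD coding errors, correlated
(block) missingness, and non-Poisson overdispersion. Passing tests
therefore show the machinery is correct and calibrated under clean
Poisson sampling with the stated noise processes — not that real Iranian
registry data meet those assumptions.

# Registry preparation

**Deduplication.** Two rules: rows whose record ids are equal after
whitespace/case normalisation, and rows identical on the full demographic
key (source, cause, age, sex, province, year). The key rule is the
documented default, but at national densities distinct persons collide on
so coarse a key (we measured over 80% spurious removals at realistic
densities), so the pipeline's capture–recapture path links and deduplicates
by normalised id only (`by = "id"`), which already catches every planted
duplicate.

**Imputation.** Hot-deck: a missing field is copied from a donor drawn
uniformly among complete records of the same source and year, falling back
to the same source across all years. `m = 5` completed tables are analysed
and their panel counts averaged (Rubin's rule for means; variance pooling
is deliberately out of scope for the headline metrics). Hot-deck preserves
the empirical joint distribution of the categorical fields, which is all
the downstream aggregation needs.

**Completeness.** Two-source capture–recapture per province × year with the
reference source treated as the enumeration standard: completeness
$= m/n_2$, where $n_2$ counts reference captures and $m$ those also found
in the primary source. Under independent capture this is unbiased; the
symmetric Chandra Sekar–Deming variant yields algebraically the same
primary-source completeness (the implied total $\hat N = n_1 n_2 / m$ is
reported behind a flag). Primary records that lost their province are
assigned the stratum of their linked reference record; the reference side
is never back-filled, because that would retain matched rows
preferentially and bias the estimate upward. Strata never seen in the
reference source are flagged rather than silently treated as complete.
Observed counts are inflated by 1/completeness; the stratum level
(province × year) is a default, since finer levels leave too few reference
captures per cell.

# The two-stage rate model

**Stage one** is a Poisson log-linear mixed model of events with offset
$\log(\text{person-years}/10^5)$: age-group indicators, province-level
covariates (wealth, schooling, urbanization) and a province random
intercept, fitted with `lme4::glmer`. Completeness-corrected counts are
fractional; the likelihood uses rounded counts while residuals keep the
fractional values. A calendar-year fixed effect is deliberately absent by
default: the secular trend is carried by the trending covariates and by the
residual field, which is the second stage's job (set `includeYear = TRUE`
to change this). If the mixed solver fails on degenerate (e.g. noise-free)
inputs, a fixed-effects GLM with zero intercepts is used, with a message.

**Stage two** smooths what stage one missed. The kernel factorises over
the three axes, $w = w_{\text{space}} \cdot w_{\text{age}} \cdot
w_{\text{time}}$, with $w_{\text{space}} = 1$ on the own province and
$\lambda/\deg(p)$ on adjacent provinces, $w_{\text{age}} =
e^{-\omega|a-a'|}$ and $w_{\text{time}} = \zeta^{|t-t'|}$; defaults
$\lambda = 0.3$, $\omega = 0.7$, $\zeta = 0.8$ keep all three axes active.
`smoothResiduals()` is the literal normalised linear kernel operator (rows
sum to one; optional precision weights) and is tested against brute-force
triple loops.

The estimator itself, however, does not average log residuals directly:
the log of a sparse Poisson count is biased low (by Jensen's inequality,
about $-1/2\mu$), and averaging such residuals pushes whole neighbourhoods
of the surface down. Instead, for each cell two estimates of the log
deviation $\delta_s$ from the stage-one prediction are combined by
precision:

* the cell's own ratio $d_s = \log\{(y_s + 0.5)/(\hat\mu_s + 0.5)\}$,
  variance $\approx 1/(\hat\mu_s + 0.5)$;
* the kernel-aggregated ratio $a_s = \log\{(K y)_s + 0.5\} -
  \log\{(K\hat\mu)_s + 0.5\}$ — the log taken *after* aggregation, where
  counts are large and the Jensen bias negligible — with variance from
  squared-kernel Poisson propagation.

The structure variance $\tau^2$ is estimated globally by method of moments
from the smoothed field, truncated at zero. The posterior mean
$(d/\sigma_d^2 + a/v)/(1/\sigma_d^2 + 1/v + 1/\tau^2)$ shrinks to zero when
the residuals show nothing beyond Poisson noise, so smoothing cannot make
the estimates worse than stage one; when structure exists, data-rich cells
follow their own data and sparse cells borrow strength.

**Uncertainty.** 1,000 Monte-Carlo draws perturb the fixed effects by a
multivariate normal with the fitted covariance (a non-positive-definite
covariance is projected with a warning), recompute predictions, and draw
the residual deviation from its empirical-Bayes posterior. The posterior
variance carries a variance inflation factor of 4, calibrated by
simulation, because the nominal posterior understates the uncertainty of
the kernel field (its attenuation of structure is not modelled); the
factor widens intervals only and never moves a point estimate. Random
intercepts are held at their estimates. The 95% interval is the empirical
2.5th–97.5th percentile (linear-interpolation quantiles) per stratum,
clamped to bracket the point estimate. On synthetic registries at default
conditions this yields smoothed-vs-stage-one mean-squared-error ratios
below one and empirical 95% coverage of the true stratum rates between
0.89 and 0.98 across simulation seeds.

# Cause fractions, metrics, decomposition

**Cause fractions** are a maximum-likelihood multinomial logit
(`nnet::multinom`) of cause counts on age-group indicators, a centred
linear year term and province indicators, with the last cause as the
reference. Apparent separation triggers a ridge (weight-decay) refit with
a warning. Applying the model to an all-cause envelope multiplies predicted
fractions by envelope counts, so cause sums reproduce the envelope exactly
(softmax fractions sum to one by construction).

**Direct standardization** uses the population of the final study year as
the standard (configurable). **APC** is $100(e^\beta - 1)$ from the
least-squares regression of log rate on year; it is exact on geometric
series, which is what makes the published endpoint rates sufficient to
verify the published APCs. By default the pipeline computes incidence APCs
over the full span and death/YLL APCs excluding the final year, matching
the reporting convention of the motivating tables. **YLL** multiplies
deaths by remaining life expectancy at the age group, with no discounting
or age weighting. **MIR** is ASDR/ASIR on the same standard population
(crude variant behind a flag). Uncertainty intervals for standardized rates
standardize every draw, then take percentiles.

**Decomposition** of the change in annual cases between a base and final
year forms two hypothetical counts: $H_1$ applies base rates and base age
structure to the final population total; $H_2$ applies base rates to the
final population. Growth $= H_1 - \text{cases}_{\text{base}}$, ageing
$= H_2 - H_1$, rate change $= \text{cases}_{\text{final}} - H_2$; the
three sum to the total change as an algebraic identity, verified on a
thousand randomized inputs. The observed final-year count is an input, not
recomputed from final rates. Sex is collapsed because the analysis is
female-only.

# Age-period-cohort analysis

On an equal-width Lexis grid, cohort $=$ period $-$ age makes the
effect-coded design rank-deficient with a one-dimensional null space. The
intrinsic estimator is the minimum-norm solution: we solve the Poisson
IRLS normal equations with a Moore–Penrose pseudoinverse, so every iterate
(hence the solution) is orthogonal to the null vector $B_0$, computed as
the unit-norm kernel of the normal matrix with its sign fixed by the first
non-zero element. Fitted cell means coincide with any other
minimal-constraint identification (verified against a drop-one-cohort GLM
to $10^{-6}$ relative), and only effect contrasts orthogonal to $B_0$ are
interpretable: a linear trend cannot be attributed among age, period and
cohort, which is why recovery tests generate effects orthogonal to $B_0$.
With $A$ age groups and $P$ periods the grid has $A + P - 1$ cohorts —
with 15 age groups and 4 periods, 18 cohorts; the implementation always
derives the count from the grid. The open-ended 85+ group is treated as a
regular 5-year block for cohort assignment. Percentile bootstrap intervals
(parametric resampling of events around fitted means, 200 resamples by
default) are available via `bootstrapIE()`; an OLS-on-log-rates variant
sits behind `family = "gaussian"`.

# Numerical choices

* 0.5-event stabilisation is applied symmetrically to observed and fitted
  counts wherever a log of counts is taken.
* Kernel degeneracies: $\omega = \infty$ and $\zeta \to 0$ reduce to
  self-weights; $\zeta = 1$, $\omega = 0$, $\lambda = 0$ pools uniformly
  within a province. A disconnected adjacency warns rather than errors.
* IRLS converges on the max coefficient change at $10^{-12}$ (cap 100
  iterations); pseudoinverse cutoffs are relative to the largest singular
  value; the null-space test uses a $10^{-10}$ relative eigenvalue
  threshold.
* Quantiles are R's type-7 (linear interpolation) everywhere.
* Zero-exposure strata are excluded from likelihoods with a message, carry
  zero residual, and zero-exposure Lexis cells are dropped with a warning.
* All generators and Monte-Carlo paths take explicit integer seeds;
  equal seeds give byte-identical outputs.

# Problem sizes used by the tests

The bundled tests and the acceptance script run the full machinery on
scaled-down worlds chosen as the package's own test design: 8 provinces,
10 age groups and 14 years (1,120 strata) for model-recovery and
calibration checks with 1,000 draws; 3-4 provinces and 4-6 age groups for
record-level preparation checks; 100 small two-province replicates for
capture-recapture recovery; and a 3-province, 10-year demonstration
pipeline. The defaults of the generator itself (31 provinces, 1990–2016,
15 age groups) remain the documented study conditions.

# Known limitations

* Completeness correction ignores its own estimation uncertainty; the
  binomial error of $m/n_2$ is not propagated into the intervals.
* Imputation variance is not pooled into the headline metrics (means
  only).
* The second-stage structure variance is a single global scalar; strongly
  heterogeneous structure (e.g. one aberrant province) is smoothed with
  the same strength as everything else.
* The interval calibration factor was tuned on the generator's study
  conditions; materially different sparsity or structure regimes may
  need re-calibration.
* The APC-IE effect split, as with any minimal-constraint identification,
  attributes the inestimable linear drift by convention (minimum norm);
  only deviations from linearity are data-driven.
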