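# RegistryBurden

Estimating national and subnational cancer burden — incidence, mortality,
years of life lost (YLL) and mortality-to-incidence ratio (MIR) — from
noisy, incomplete registry records, with uncertainty intervals,
decomposition of case-count change, and age-period-cohort analysis.

The package is written for epidemiologists and biostatisticians who work
with cancer or death registries that under-ascertain events, lose
demographic fields, and accumulate duplicates. It implements, end to end:

* a **synthetic registry generator** with known ground truth (Poisson
  events from a log-linear province × age × year rate surface;
  per-source registration probabilities; field missingness; duplicate
  rows; a partially overlapping reference capture source), so every
  estimation stage is testable without confidential data;
* **registry preparation**: deduplication, hot-deck multiple imputation,
  two-source capture–recapture completeness (`completeness = m / n2`,
  the reference source treated as the enumeration standard) and
  multiplicative count correction, province remapping, aggregation to
  panel counts;
* the **two-stage rate model**: a Poisson mixed model
  (`events ~ age + covariates + (1 | province)`, offset
  `log(person-years/1e5)`), then empirical-Bayes smoothing of its
  residuals with a factorised kernel over neighbouring provinces
  (`lambda/deg(p)`), age distance (`exp(-omega |Δa|)`) and time distance
  (`zeta^|Δt|`), with 1,000 Monte-Carlo draws and 2.5th/97.5th-percentile
  95% uncertainty intervals;
* **cause fractions** by multinomial logit, conserving all-cause
  envelopes exactly;
* **burden metrics**: direct age standardization
  (`ASR = Σ_a w_a r_a`), annual percent change
  (`APC = 100 (e^β − 1)` with `β` from regressing ln rate on year), YLL
  (`deaths × remaining life expectancy`), MIR (`ASDR / ASIR`);
* **decomposition** of the 26-year change in annual cases into population
  growth, population ageing and age-specific rate change via sequential
  hypothetical populations (the three parts sum to the total change
  exactly);
* **age-period-cohort analysis with the intrinsic estimator**: the
  minimum-norm, null-space-orthogonal solution of the rank-deficient
  Poisson APC model, solved by pseudoinverse IRLS and verified against a
  constrained GLM.

See the methods vignette (`vignettes/registry-burden-methods.Rmd`) for the
models, assumptions, parameter defaults and design decisions.

## Worked example

Reproducing a published trend figure from its endpoint age-standardized
rates: a series rising geometrically from 13 to 44 cases per 100,000 over
1990–2016 has, by the ln-regression definition,

```r
library(RegistryBurden)
s <- geometricInterpolation(1990, 2016, 13, 44)
cat(sprintf("APC: %.1f%%\n", computeAPC(s$year, s$value)))
#> APC: 4.8%
```

Decomposing a change in annual case counts (two age groups, base rates 10
and 100 per 100,000, the older population tripling, 600 cases observed in
the final year):

```r
decomposeChange(c(10, 100), c(1000, 1000), c(1000, 3000), casesFinal = 600)
#> Decomposition of change in annual cases
#>   cases: 1.1 -> 600.0 (+54445.5%)
#>   population growth: +1.1 (+100.0%)
#>   population ageing: +0.9 (+81.8%)
#>   age-specific rates: +596.9 (+54263.6%)
```

An end-to-end run on a small synthetic world — three provinces, ten years,
200 draws — generates registries, cleans and corrects them, fits both
stages, and summarises per location:

```r
bundle <- runPipeline(list(seed = 5, nProvinces = 3, years = 2000:2009,
                           prep = list(m = 2), draws = list(n = 200)))
round(bundle$summaryTable[1:3, c("asir_start", "asir_end",
                                 "apc_incidence", "mir_end")], 2)
#>   asir_start asir_end apc_incidence mir_end
#> 1      23.01    35.36          4.89    0.23
#> 2      24.37    37.53          4.92    0.23
#> 3      15.58    23.97          4.90    0.22
```

The estimated incidence APCs (4.9% nationally) recover the generator's
configured mean annual increase of 4.8%, and the end-of-period MIR of 0.23
reflects the configured decline in the mortality fraction. Setting
`outdir` additionally writes the summary table, full rate surfaces with
uncertainty bounds, completeness estimates, the decomposition JSON, APC
effects and a reproducibility manifest.

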