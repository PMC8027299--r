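Package: RegistryBurden
Title: Cancer Burden Estimation from Incomplete Registry Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates national and subnational cancer incidence, mortality,
    years of life lost and mortality-to-incidence ratios from noisy,
    incomplete registry records. Provides a synthetic registry generator
    with known ground truth; record deduplication, hot-deck multiple
    imputation and two-source capture-recapture completeness correction; a
    two-stage spatio-temporal rate model (covariate mixed model followed by
    neighbour/age/time kernel smoothing of residuals) with draw-based 95
    percent uncertainty intervals; multinomial cause-fraction allocation of
    all-cause envelopes; direct age standardization, annual percent change,
    YLL and MIR metrics; decomposition of case-count change into population
    growth, ageing and rate change; and age-period-cohort analysis with the
    intrinsic estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, lme4, nnet, MASS,
    jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Epidemiology, Regression, Spatial, TimeCourse
RoxygenNote: 7.3.3
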