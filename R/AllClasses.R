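#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
NULL

## ---------------------------------------------------------------------------
## Panel containers: province x age-group strata in rows, calendar years in
## columns.  Row order is province-major (all age groups of province 1, then
## province 2, ...); helpers below convert between the matrix layout and the
## [province, age, year] array layout used by the smoother.
## ---------------------------------------------------------------------------

#' Panel of event counts and person-years on a province x age x year grid
#'
#' A \linkS4class{SummarizedExperiment} with assays \code{events} (event
#' counts; fractional values are permitted after completeness correction) and
#' \code{personYears}.  Rows are province x age-group strata (row order is
#' province-major), columns are calendar years.
#'
#' @export
setClass("PanelCounts", contains = "SummarizedExperiment")

#' Latent true rate surface used by the synthetic registry generator
#'
#' Assays \code{incidence} and \code{mortality} hold rates per 100,000
#' person-years; \code{metadata(x)$params} records the generating parameters.
#'
#' @export
setClass("TruthSurface", contains = "SummarizedExperiment")

#' Estimated rate surface with uncertainty bounds
#'
#' Assays \code{rate}, \code{lower} and \code{upper}, all per 100,000
#' person-years, with \code{lower <= rate <= upper} in every stratum.
#'
#' @export
setClass("RateSurface", contains = "SummarizedExperiment")

.validPanelDims <- function(object, assayNames) {
  msg <- NULL
  for (nm in assayNames) {
    if (!nm %in% SummarizedExperiment::assayNames(object))
      msg <- c(msg, sprintf("assay '%s' is required", nm))
  }
  rd <- rowData(object)
  for (col in c("province", "ageIndex"))
    if (!col %in% colnames(rd))
      msg <- c(msg, sprintf("rowData column '%s' is required", col))
  if (!"year" %in% colnames(colData(object)))
    msg <- c(msg, "colData column 'year' is required")
  msg
}

setValidity("PanelCounts", function(object) {
  msg <- .validPanelDims(object, c("events", "personYears"))
  if (is.null(msg)) {
    ev <- assay(object, "events"); py <- assay(object, "personYears")
    if (any(!is.finite(ev)) || any(ev < 0))
      msg <- c(msg, "events must be finite and non-negative")
    if (any(!is.finite(py)) || any(py < 0))
      msg <- c(msg, "personYears must be finite and non-negative")
  }
  if (is.null(msg)) TRUE else msg
})

setValidity("TruthSurface", function(object) {
  msg <- .validPanelDims(object, c("incidence", "mortality"))
  if (is.null(msg)) {
    inc <- assay(object, "incidence"); mort <- assay(object, "mortality")
    if (any(!is.finite(inc)) || any(inc < 0))
      msg <- c(msg, "incidence rates must be finite and non-negative")
    if (any(!is.finite(mort)) || any(mort < 0))
      msg <- c(msg, "mortality rates must be finite and non-negative")
    else if (any(mort > inc + 1e-9))
      msg <- c(msg, "mortality rate must not exceed incidence rate")
  }
  if (is.null(msg)) TRUE else msg
})

setValidity("RateSurface", function(object) {
  msg <- .validPanelDims(object, c("rate", "lower", "upper"))
  if (is.null(msg)) {
    r <- assay(object, "rate"); lo <- assay(object, "lower")
    up <- assay(object, "upper")
    if (any(r < 0) || any(lo < 0)) msg <- c(msg, "rates must be non-negative")
    if (any(lo > r + 1e-9) || any(r > up + 1e-9))
      msg <- c(msg, "bounds must satisfy lower <= rate <= upper")
  }
  if (is.null(msg)) TRUE else msg
})

.panelSE <- function(class, assays, provinces, ageGroups, years) {
  P <- length(provinces); A <- length(ageGroups); Y <- length(years)
  rd <- DataFrame(
    province = rep(provinces, each = A),
    ageIndex = rep(seq_len(A), times = P),
    ageGroup = rep(ageGroups, times = P))
  rownames(rd) <- paste0("p", rd$province, "_a", rd$ageIndex)
  cd <- DataFrame(year = years)
  rownames(cd) <- as.character(years)
  assays <- lapply(assays, function(m) {
    m <- as.matrix(m)
    stopifnot(nrow(m) == P * A, ncol(m) == Y)
    dimnames(m) <- list(rownames(rd), rownames(cd))
    m
  })
  new(class, SummarizedExperiment(assays = assays, rowData = rd, colData = cd))
}

#' Construct a PanelCounts object
#'
#' @param events,personYears numeric matrices with one row per province x
#'   age-group stratum (province-major order) and one column per year.
#' @param provinces integer vector of province ids.
#' @param ageGroups character vector of age-group labels (see
#'   [ageGroupLabels()]).
#' @param years integer vector of calendar years.
#' @return A \linkS4class{PanelCounts} object.
#' @examples
#' pc <- PanelCounts(matrix(0, 4, 2), matrix(1e5, 4, 2),
#'                   provinces = 1:2, ageGroups = c("15-19", "20-24"),
#'                   years = 2000:2001)
#' @export
PanelCounts <- function(events, personYears, provinces, ageGroups, years) {
  .panelSE("PanelCounts", list(events = events, personYears = personYears),
           provinces, ageGroups, years)
}

#' Construct a TruthSurface object
#'
#' @param incidence,mortality rate matrices per 100,000 (strata x years).
#' @inheritParams PanelCounts
#' @param params list of generating parameters, kept in `metadata()`.
#' @return A \linkS4class{TruthSurface} object.
#' @export
TruthSurface <- function(incidence, mortality, provinces, ageGroups, years,
                         params = list()) {
  x <- .panelSE("TruthSurface",
                list(incidence = incidence, mortality = mortality),
                provinces, ageGroups, years)
  metadata(x)$params <- params
  x
}

#' Construct a RateSurface object
#'
#' @param rate,lower,upper rate matrices per 100,000 (strata x years).
#' @inheritParams PanelCounts
#' @return A \linkS4class{RateSurface} object.
#' @export
RateSurface <- function(rate, lower, upper, provinces, ageGroups, years) {
  .panelSE("RateSurface", list(rate = rate, lower = lower, upper = upper),
           provinces, ageGroups, years)
}

## array <-> assay layout helpers -------------------------------------------

#' Extract an assay of a panel object as a [province, age, year] array
#'
#' @param x a panel-shaped SummarizedExperiment (PanelCounts, TruthSurface,
#'   RateSurface).
#' @param assay name of the assay to extract.
#' @return 3-dimensional numeric array indexed province x age-group x year.
#' @export
panelArray <- function(x, assay = SummarizedExperiment::assayNames(x)[1]) {
  provinces <- unique(rowData(x)$province)
  A <- length(unique(rowData(x)$ageIndex))
  m <- SummarizedExperiment::assay(x, assay)
  arr <- array(0, dim = c(length(provinces), A, ncol(m)),
               dimnames = list(as.character(provinces),
                               unique(rowData(x)$ageGroup),
                               colnames(m)))
  for (i in seq_along(provinces)) {
    idx <- which(rowData(x)$province == provinces[i])
    arr[i, , ] <- m[idx, , drop = FALSE][order(rowData(x)$ageIndex[idx]), ,
                                         drop = FALSE]
  }
  arr
}

## flatten a [P, A, Y] array back to the (P*A) x Y province-major matrix
.arrayToMatrix <- function(arr) {
  d <- dim(arr)
  matrix(aperm(arr, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
}

## ---------------------------------------------------------------------------
## Result classes
## ---------------------------------------------------------------------------

#' First-stage mixed-model fit for log rates
#'
#' Holds the fixed-effect estimates, their covariance, the per-province
#' random intercepts and the log-scale residual array of the stage-one
#' Poisson mixed model; the pieces the residual smoother and the draw
#' machinery need to reconstruct predictions under perturbed coefficients.
#'
#' @slot coef named numeric vector of fixed effects.
#' @slot vcov covariance matrix of the fixed effects.
#' @slot ranef named numeric vector of province random intercepts.
#' @slot design fixed-effect model matrix, one row per stratum-year cell in
#'   province-major row, year-major column order.
#' @slot ranefIndex integer vector mapping each design row to a province.
#' @slot fitted log-rate predictions as a [province, age, year] array.
#' @slot logObserved log observed rates (0.5-event stabilisation), same
#'   layout.
#' @slot residuals `log((events + 0.5) / (fitted events + 0.5))`, same
#'   layout.
#' @slot events,personYears observed events and person-years, same layout.
#' @slot provinces,ageGroups,years grid labels.
#' @export
setClass("Stage1Fit", representation(
  coef = "numeric", vcov = "matrix", ranef = "numeric",
  design = "matrix", ranefIndex = "integer",
  fitted = "array", logObserved = "array", residuals = "array",
  events = "array", personYears = "array",
  provinces = "integer", ageGroups = "character", years = "integer"))

setValidity("Stage1Fit", function(object) {
  msg <- NULL
  if (any(!is.finite(object@residuals)))
    msg <- c(msg, "residuals must be finite")
  if (nrow(object@vcov) != length(object@coef))
    msg <- c(msg, "vcov dimension must match coef")
  if (is.null(msg)) TRUE else msg
})

#' Kernel weights for the age-spatio-temporal residual smoother
#'
#' The smoothing weight between strata factorises over the three axes:
#' \code{w = w_space * w_age * w_time}, with \code{w_space = 1} on the own
#' province and \code{lambda/deg(p)} on adjacent provinces,
#' \code{w_age = exp(-omega * |a - a'|)} and \code{w_time = zeta^|y - y'|}.
#' Weights over all donor strata are normalised to sum to one per target
#' stratum; the factorisation makes that a product of per-axis row sums.
#'
#' @slot space,age,time per-axis (unnormalised) kernel matrices.
#' @slot lambda,omega,zeta the hyperparameters.
#' @export
setClass("SmoothingWeights", representation(
  space = "matrix", age = "matrix", time = "matrix",
  lambda = "numeric", omega = "numeric", zeta = "numeric"))

#' Monte-Carlo rate draws for uncertainty intervals
#'
#' @slot draws matrix of rate draws (per 100,000), draws in rows, strata in
#'   columns (province-major, year-major as in the flattened panel layout).
#' @slot point point-estimate rates, [province, age, year] array.
#' @slot seed integer seed used.
#' @slot provinces,ageGroups,years grid labels.
#' @export
setClass("DrawsCube", representation(
  draws = "matrix", point = "array", seed = "integer",
  provinces = "integer", ageGroups = "character", years = "integer"))

setValidity("DrawsCube", function(object) {
  if (any(object@draws < 0)) "draws must be non-negative" else TRUE
})

#' Decomposition of a change in case counts
#'
#' Splits the change in annual new cases between a base and a final year into
#' population growth, population ageing and age-specific rate change, via two
#' hypothetical populations: H1 applies base-year rates and base-year age
#' structure to the final-year population total; H2 applies base-year rates
#' to the final-year population.
#'
#' @slot casesBase,casesFinal observed annual cases in the two years.
#' @slot H1,H2 the hypothetical case counts.
#' @slot deltaGrowth,deltaAging,deltaRate absolute contributions; they sum
#'   exactly to \code{casesFinal - casesBase}.
#' @slot pctGrowth,pctAging,pctRate the same as percent of \code{casesBase}.
#' @export
setClass("DecompositionResult", representation(
  casesBase = "numeric", casesFinal = "numeric", H1 = "numeric",
  H2 = "numeric", deltaGrowth = "numeric", deltaAging = "numeric",
  deltaRate = "numeric", pctGrowth = "numeric", pctAging = "numeric",
  pctRate = "numeric"))

#' Events and exposure on an age-group x period Lexis grid
#'
#' @slot events,exposure A x P matrices (equal 5-year age and period widths).
#' @slot ageWidth,periodWidth interval widths in years.
#' @slot ageLabels,periodLabels dimension labels.
#' @export
setClass("LexisTable", representation(
  events = "matrix", exposure = "matrix",
  ageWidth = "numeric", periodWidth = "numeric",
  ageLabels = "character", periodLabels = "character"))

setValidity("LexisTable", function(object) {
  msg <- NULL
  if (!all(dim(object@events) == dim(object@exposure)))
    msg <- c(msg, "events and exposure must have equal dimensions")
  if (any(object@events > 0 & object@exposure <= 0))
    msg <- c(msg, "exposure must be positive wherever events are positive")
  if (object@ageWidth != object@periodWidth)
    msg <- c(msg, "age and period interval widths must be equal")
  if (is.null(msg)) TRUE else msg
})

#' Construct a LexisTable
#'
#' Cohort index for age row i (1-based) and period column j is
#' \code{k = (A - i) + j}, giving \code{A + P - 1} birth cohorts along the
#' anti-diagonals.
#'
#' @param events,exposure numeric A x P matrices of event counts and
#'   person-years.
#' @param ageWidth,periodWidth interval widths in years (must be equal).
#' @param ageLabels,periodLabels optional labels.
#' @return A \linkS4class{LexisTable}.
#' @export
lexisTable <- function(events, exposure, ageWidth = 5, periodWidth = 5,
                       ageLabels = NULL, periodLabels = NULL) {
  events <- as.matrix(events); exposure <- as.matrix(exposure)
  if (is.null(ageLabels))
    ageLabels <- rownames(events) %||% paste0("age", seq_len(nrow(events)))
  if (is.null(periodLabels))
    periodLabels <- colnames(events) %||% paste0("period", seq_len(ncol(events)))
  new("LexisTable", events = events, exposure = exposure,
      ageWidth = ageWidth, periodWidth = periodWidth,
      ageLabels = as.character(ageLabels),
      periodLabels = as.character(periodLabels))
}

#' Age-period-cohort effects from the intrinsic estimator
#'
#' @slot intercept model intercept (log rate scale).
#' @slot age,period,cohort named effect vectors under sum-to-zero coding.
#' @slot coef full coefficient vector in design (contrast) coordinates.
#' @slot b0 the unit-norm null vector of the rank-deficient design.
#' @slot deviance residual deviance of the Poisson fit.
#' @slot fitted fitted cell means (events scale), A x P.
#' @export
setClass("APCEffects", representation(
  intercept = "numeric", age = "numeric", period = "numeric",
  cohort = "numeric", coef = "numeric", b0 = "numeric",
  deviance = "numeric", fitted = "matrix"))

setValidity("APCEffects", function(object) {
  msg <- NULL
  for (nm in c("age", "period", "cohort")) {
    v <- slot(object, nm)
    if (abs(sum(v)) > 1e-9)
      msg <- c(msg, sprintf("%s effects must sum to zero", nm))
  }
  if (abs(sum(object@coef * object@b0)) > 1e-8)
    msg <- c(msg, "coefficient vector must be orthogonal to the null vector")
  if (is.null(msg)) TRUE else msg
})

#' Multinomial cause-fraction model
#'
#' @slot fit the underlying multinomial logistic fit.
#' @slot causes cause labels in fitting order; the last one is the reference.
#' @slot predictors character vector of predictor terms used.
#' @slot converged logical.
#' @export
setClass("CauseFractionModel", representation(
  fit = "ANY", causes = "character", predictors = "character",
  converged = "logical"))

`%||%` <- function(a, b) if (is.null(a)) b else a
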