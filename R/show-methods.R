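#' @describeIn Stage1Fit-class compact display
#' @param object a Stage1Fit
#' @exportMethod show
setMethod("show", "Stage1Fit", function(object) {
  cat("Stage1Fit: Poisson mixed model on log rates\n")
  cat(sprintf("  grid: %d provinces x %d age groups x %d years\n",
              length(object@provinces), length(object@ageGroups),
              length(object@years)))
  cat(sprintf("  fixed effects: %d; residual SD (log scale): %.3f\n",
              length(object@coef), stats::sd(object@residuals)))
})

#' @describeIn SmoothingWeights-class compact display
#' @param object a SmoothingWeights
#' @export
setMethod("show", "SmoothingWeights", function(object) {
  cat(sprintf(
    "SmoothingWeights: lambda = %.3g (space), omega = %.3g (age), zeta = %.3g (time)\n",
    object@lambda, object@omega, object@zeta))
  cat(sprintf("  axes: %d provinces, %d age groups, %d years\n",
              nrow(object@space), nrow(object@age), nrow(object@time)))
})

#' @describeIn DrawsCube-class compact display
#' @param object a DrawsCube
#' @export
setMethod("show", "DrawsCube", function(object) {
  cat(sprintf("DrawsCube: %d draws x %d strata (seed %d)\n",
              nrow(object@draws), ncol(object@draws), object@seed))
})

#' @describeIn DecompositionResult-class compact display
#' @param object a DecompositionResult
#' @export
setMethod("show", "DecompositionResult", function(object) {
  cat("Decomposition of change in annual cases\n")
  cat(sprintf("  cases: %.1f -> %.1f (%+.1f%%)\n", object@casesBase,
              object@casesFinal,
              100 * (object@casesFinal - object@casesBase) / object@casesBase))
  cat(sprintf("  population growth: %+.1f (%+.1f%%)\n",
              object@deltaGrowth, object@pctGrowth))
  cat(sprintf("  population ageing: %+.1f (%+.1f%%)\n",
              object@deltaAging, object@pctAging))
  cat(sprintf("  age-specific rates: %+.1f (%+.1f%%)\n",
              object@deltaRate, object@pctRate))
})

#' @describeIn LexisTable-class compact display
#' @param object a LexisTable
#' @export
setMethod("show", "LexisTable", function(object) {
  cat(sprintf("LexisTable: %d age groups x %d periods (%g-year intervals), %d cohorts\n",
              nrow(object@events), ncol(object@events), object@ageWidth,
              nrow(object@events) + ncol(object@events) - 1L))
  cat(sprintf("  total events: %g\n", sum(object@events)))
})

#' @describeIn APCEffects-class compact display
#' @param object an APCEffects
#' @export
setMethod("show", "APCEffects", function(object) {
  cat("APCEffects (intrinsic estimator)\n")
  cat(sprintf("  intercept: %.4f; deviance: %.2f\n", object@intercept,
              object@deviance))
  cat(sprintf("  effects: %d age, %d period, %d cohort (sum-to-zero)\n",
              length(object@age), length(object@period),
              length(object@cohort)))
})

#' @describeIn CauseFractionModel-class compact display
#' @param object a CauseFractionModel
#' @export
setMethod("show", "CauseFractionModel", function(object) {
  cat(sprintf("CauseFractionModel: %d causes (reference: %s)%s\n",
              length(object@causes), object@causes[length(object@causes)],
              if (object@converged) "" else " [not converged]"))
})

## ---------------------------------------------------------------------------
## Accessors
## ---------------------------------------------------------------------------

#' Relative risks from an APC fit
#' @param object an \linkS4class{APCEffects}.
#' @return list with components `age`, `period`, `cohort` of exp(effects).
#' @export
relativeRisks <- function(object) {
  stopifnot(is(object, "APCEffects"))
  list(age = exp(object@age), period = exp(object@period),
       cohort = exp(object@cohort))
}

#' Effect vectors from an APC fit
#' @param object an \linkS4class{APCEffects}.
#' @return list with `intercept`, `age`, `period`, `cohort`, `deviance`.
#' @export
apcEffects <- function(object) {
  stopifnot(is(object, "APCEffects"))
  list(intercept = object@intercept, age = object@age,
       period = object@period, cohort = object@cohort,
       deviance = object@deviance)
}

#' Rate draws matrix
#' @param object a \linkS4class{DrawsCube}.
#' @return numeric matrix, draws in rows, strata in columns.
#' @export
rateDraws <- function(object) {
  stopifnot(is(object, "DrawsCube"))
  object@draws
}

#' Stage-one fixed effects
#' @param object a \linkS4class{Stage1Fit}.
#' @return named numeric vector.
#' @export
stage1Coef <- function(object) {
  stopifnot(is(object, "Stage1Fit"))
  object@coef
}

#' Stage-one fixed-effect covariance
#' @param object a \linkS4class{Stage1Fit}.
#' @return covariance matrix.
#' @export
stage1Vcov <- function(object) {
  stopifnot(is(object, "Stage1Fit"))
  object@vcov
}

#' Stage-one province random intercepts
#' @param object a \linkS4class{Stage1Fit}.
#' @return named numeric vector, one entry per province.
#' @export
stage1Ranef <- function(object) {
  stopifnot(is(object, "Stage1Fit"))
  object@ranef
}

#' Stage-one residuals on the log-rate scale
#' @param object a \linkS4class{Stage1Fit}.
#' @return [province, age, year] array.
#' @export
stage1Residuals <- function(object) {
  stopifnot(is(object, "Stage1Fit"))
  object@residuals
}

#' Decomposition result as a named list
#' @param object a \linkS4class{DecompositionResult}.
#' @return named list with all seven components and the hypothetical counts.
#' @export
decompositionTable <- function(object) {
  stopifnot(is(object, "DecompositionResult"))
  list(cases_base = object@casesBase, cases_final = object@casesFinal,
       H1 = object@H1, H2 = object@H2,
       delta_growth = object@deltaGrowth, delta_aging = object@deltaAging,
       delta_rate = object@deltaRate,
       pct_growth = object@pctGrowth, pct_aging = object@pctAging,
       pct_rate = object@pctRate)
}
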