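## Cause-fraction modelling: multinomial logistic regression of cause
## shares over age, year and province, applied to all-cause envelopes so
## cause-specific counts always sum back to the envelope.

#' Fit a multinomial cause-fraction model
#'
#' Maximum-likelihood multinomial logit of cause counts per stratum, with
#' the last cause as the reference category.  Default predictors are
#' age-group indicators, a linear year term and province indicators;
#' predictors with a single observed level are dropped.  Apparent
#' separation (non-convergence or runaway coefficients) triggers a ridge
#' (weight-decay) refit with a warning.
#'
#' @param causeCounts data.frame with columns `province`, `age_group` (or
#'   `age_index`), `year`, `cause`, `count`.
#' @param predictors subset of `c("age", "year", "province")`.
#' @param maxit maximum optimiser iterations.
#' @return A \linkS4class{CauseFractionModel}.
#' @export
fitCauseFractions <- function(causeCounts,
                              predictors = c("age", "year", "province"),
                              maxit = 500) {
  stopifnot(all(c("province", "year", "cause", "count") %in%
                  names(causeCounts)))
  ageCol <- if ("age_index" %in% names(causeCounts)) "age_index" else
    "age_group"
  causes <- sort(unique(as.character(causeCounts$cause)))
  if (length(causes) < 2) stop("at least two causes are required")

  key <- paste(causeCounts$province, causeCounts[[ageCol]], causeCounts$year)
  strata <- !duplicated(key)
  wide <- data.frame(province = causeCounts$province[strata],
                     age = causeCounts[[ageCol]][strata],
                     year = causeCounts$year[strata])
  Ymat <- matrix(0, nrow(wide), length(causes),
                 dimnames = list(NULL, causes))
  idx <- cbind(match(key, key[strata]),
               match(as.character(causeCounts$cause), causes))
  for (i in seq_len(nrow(causeCounts)))
    Ymat[idx[i, 1], idx[i, 2]] <- Ymat[idx[i, 1], idx[i, 2]] +
      causeCounts$count[i]
  if (any(colSums(Ymat) == 0)) stop("every cause must be observed somewhere")

  ## multinom's reference is the FIRST response column; put the last cause
  ## there so the final cause acts as the reference category
  Yfit <- Ymat[, c(length(causes), seq_len(length(causes) - 1)), drop = FALSE]

  terms <- character(0)
  wide$ageF <- factor(wide$age)
  wide$provinceF <- factor(wide$province)
  if ("age" %in% predictors && nlevels(wide$ageF) > 1)
    terms <- c(terms, "ageF")
  if ("year" %in% predictors && length(unique(wide$year)) > 1) {
    wide$yearC <- wide$year - mean(range(wide$year))
    terms <- c(terms, "yearC")
  }
  if ("province" %in% predictors && nlevels(wide$provinceF) > 1)
    terms <- c(terms, "provinceF")
  form <- stats::reformulate(if (length(terms)) terms else "1",
                             response = "Yfit")

  fit <- nnet::multinom(form, data = wide, maxit = maxit, trace = FALSE)
  converged <- fit$convergence == 0
  if (!converged || max(abs(stats::coef(fit))) > 30) {
    warning("possible separation in cause-fraction model; ridge refit")
    fit <- nnet::multinom(form, data = wide, maxit = maxit, trace = FALSE,
                          decay = 1e-3)
    converged <- fit$convergence == 0
  }
  attr(fit, "yearShift") <- if ("yearC" %in% terms) mean(range(wide$year))
                            else 0
  new("CauseFractionModel", fit = fit, causes = causes,
      predictors = if (length(terms)) terms else "1", converged = converged)
}

#' Predicted cause fractions per stratum
#'
#' @param model a \linkS4class{CauseFractionModel}.
#' @param newdata data.frame with columns `province`, `age` (group index or
#'   label, as fitted) and `year`.
#' @return matrix of fractions (rows = strata, columns = causes, original
#'   cause order); rows sum to one.
#' @export
predictFractions <- function(model, newdata) {
  mf <- model@fit
  xl <- mf$xlevels
  nd <- data.frame(row.names = seq_len(nrow(newdata)))
  if (!is.null(xl$ageF)) nd$ageF <- factor(newdata$age, levels = xl$ageF)
  if (!is.null(xl$provinceF))
    nd$provinceF <- factor(newdata$province, levels = xl$provinceF)
  nd$yearC <- newdata$year - attr(mf, "yearShift")
  pr <- stats::predict(mf, newdata = nd, type = "probs")
  classes <- colnames(stats::fitted(mf)) %||% model@causes
  if (is.null(dim(pr)))
    pr <- matrix(pr, nrow = nrow(nd), ncol = length(classes), byrow = TRUE,
                 dimnames = list(NULL, classes))
  pr[, model@causes, drop = FALSE]   # restore original cause order
}

#' Allocate an all-cause envelope to causes
#'
#' Cause-specific count is the predicted fraction times the envelope count,
#' so cause sums reproduce the envelope exactly in every stratum.
#'
#' @param model a \linkS4class{CauseFractionModel}.
#' @param envelope a \linkS4class{PanelCounts} of all-cause events.
#' @return data.frame `province, age_group, year, cause, count` in long
#'   form.
#' @export
applyToEnvelope <- function(model, envelope) {
  stopifnot(is(envelope, "PanelCounts"))
  rd <- rowData(envelope)
  years <- colData(envelope)$year
  ev <- assay(envelope, "events")
  grid <- expand.grid(stratum = seq_len(nrow(ev)), yearIdx = seq_along(years),
                      KEEP.OUT.ATTRS = FALSE)
  nd <- data.frame(province = rd$province[grid$stratum],
                   age = rd$ageIndex[grid$stratum],
                   year = years[grid$yearIdx])
  fr <- predictFractions(model, nd)
  env <- ev[cbind(grid$stratum, grid$yearIdx)]
  out <- data.frame(
    province = rep(nd$province, times = ncol(fr)),
    age_group = rep(rd$ageGroup[grid$stratum], times = ncol(fr)),
    year = rep(nd$year, times = ncol(fr)),
    cause = rep(colnames(fr), each = nrow(fr)),
    count = as.vector(fr * env))
  out
}
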