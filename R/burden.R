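## Headline burden metrics: direct age standardization, annual percent
## change from the log-linear trend, years of life lost, and the
## mortality-to-incidence ratio.

#' Standard population age weights
#'
#' Builds normalised age weights from a population table, by default using
#' the final year covered (direct standardization against the population of
#' the last study year).
#'
#' @param population data.frame as from [simulatePopulation()].
#' @param year reference year; default the last year present.
#' @return data.frame `age_index, weight` with weights summing to one;
#'   attribute `provenance` records the year used.
#' @export
standardPopulation <- function(population, year = max(population$year)) {
  sub <- population[population$year == year, , drop = FALSE]
  if (!nrow(sub)) stop("no population rows for year ", year)
  w <- tapply(sub$population, sub$age_index, sum)
  w <- w / sum(w)
  out <- data.frame(age_index = as.integer(names(w)), weight = as.numeric(w))
  attr(out, "provenance") <- year
  out
}

#' Direct age standardization
#'
#' `ASR = sum_a weight_a * rate_a` with the weights of a fixed standard
#' population.
#'
#' @param ageRates numeric vector of age-specific rates (per 100,000).
#' @param std data.frame from [standardPopulation()], or a bare numeric
#'   weight vector summing to one.
#' @return the age-standardized rate (same scale as the input rates).
#' @examples
#' ageStandardize(c(10, 30), c(0.5, 0.5))
#' @export
ageStandardize <- function(ageRates, std) {
  w <- if (is.data.frame(std)) std$weight else as.numeric(std)
  if (length(w) != length(ageRates))
    stop("rate vector and weight vector must align on age groups")
  if (abs(sum(w) - 1) > 1e-8)
    stop("standard population weights must sum to one")
  sum(w * ageRates)
}

#' Annual percent change of a positive trend series
#'
#' Least-squares fit of `ln(value) = alpha + beta * year`;
#' `APC = 100 * (exp(beta) - 1)`.
#'
#' @param years strictly increasing numeric vector (>= 3 points).
#' @param values positive values, one per year.
#' @return APC in percent.
#' @examples
#' s <- geometricInterpolation(1990, 2016, 13, 44)
#' computeAPC(s$year, s$value)   # 4.80...
#' @export
computeAPC <- function(years, values) {
  if (length(years) < 3) stop("at least 3 points are required")
  if (any(diff(years) <= 0)) stop("years must be strictly increasing")
  bad <- which(values <= 0)
  if (length(bad))
    stop("non-positive value in year ", paste(years[bad], collapse = ", "))
  beta <- stats::coef(stats::lm(log(values) ~ years))[["years"]]
  100 * (exp(beta) - 1)
}

#' Years of life lost
#'
#' `YLL_a = deaths_a * LE_a` with the remaining life expectancy at each age
#' group; no discounting or age weighting.
#'
#' @param deaths numeric vector of deaths by age group.
#' @param lifeTable data.frame with columns `age_index` and
#'   `life_expectancy` covering every age group with deaths.
#' @param ageIndex age-group indices of `deaths` (default `seq_along`).
#' @return numeric vector of YLL by age group.
#' @export
computeYLL <- function(deaths, lifeTable, ageIndex = seq_along(deaths)) {
  le <- lifeTable$life_expectancy[match(ageIndex, lifeTable$age_index)]
  if (any(is.na(le) & deaths > 0))
    stop("life table does not cover all age groups with deaths")
  le[is.na(le)] <- 0
  deaths * le
}

#' Mortality-to-incidence ratio
#'
#' `MIR = ASDR / ASIR`, both age-standardized with the same standard
#' population (set `crude = TRUE` if passing crude rates or counts).
#'
#' @param asdr age-standardized death rate.
#' @param asir age-standardized incidence rate (> 0).
#' @param crude informational flag recorded as an attribute.
#' @return the ratio, or flagged `NA` (with a warning) if `asir <= 0`.
#' @export
computeMIR <- function(asdr, asir, crude = FALSE) {
  if (is.na(asir) || asir <= 0) {
    warning("MIR undefined for non-positive incidence")
    out <- NA_real_
  } else out <- asdr / asir
  attr(out, "crude") <- crude
  out
}

#' Age-standardized rate series with uncertainty from draws
#'
#' Standardizes every Monte-Carlo rate draw, then takes the 2.5th/97.5th
#' percentiles, so the uncertainty interval of the ASR reflects the full
#' draw distribution.
#'
#' @param cube a \linkS4class{DrawsCube}.
#' @param std standard population (see [ageStandardize()]).
#' @param province province id, or `NULL` for the population-weighted
#'   national rate.
#' @param population data.frame of population counts; required for
#'   `province = NULL`.
#' @return data.frame `year, rate, lower, upper`.
#' @export
standardizedSeries <- function(cube, std, province = NULL,
                               population = NULL) {
  P <- length(cube@provinces); A <- length(cube@ageGroups)
  years <- cube@years
  w <- if (is.data.frame(std)) std$weight else as.numeric(std)
  stopifnot(length(w) == A)

  ## weights over the (stratum, year) columns of the draws matrix
  asrWeights <- function(yIdx) {
    wt <- matrix(0, P * A, length(years))
    if (is.null(province)) {
      stopifnot(!is.null(population))
      py <- .populationMatrix(population, cube@provinces, A, years)
      ## national age-specific rate = population-weighted mean over
      ## provinces, then standardized: one linear functional of the draws
      for (a in seq_len(A)) {
        rows <- (seq_len(P) - 1L) * A + a
        pa <- py[rows, yIdx]
        wt[rows, yIdx] <- w[a] * pa / sum(pa)
      }
    } else {
      p <- match(province, cube@provinces)
      wt[(p - 1L) * A + seq_len(A), yIdx] <- w
    }
    as.vector(wt)
  }

  res <- lapply(seq_along(years), function(yIdx) {
    v <- asrWeights(yIdx)
    draws <- as.numeric(cube@draws %*% v)
    point <- sum(as.vector(.arrayToMatrix(cube@point)) * v)
    qs <- stats::quantile(draws, c(0.025, 0.975), names = FALSE)
    data.frame(year = years[yIdx], rate = point,
               lower = min(qs[1], point), upper = max(qs[2], point))
  })
  do.call(rbind, res)
}
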