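## Synthetic registry generator: latent rate surfaces with known ground
## truth, populations, life tables, covariates, and noisy multi-source
## registry tables (cancer registry, death registry and a partially
## overlapping reference capture source for completeness estimation).

#' Generate a connected province adjacency graph
#'
#' Builds a random connected, symmetric, binary adjacency matrix with zero
#' diagonal: a random spanning tree plus extra edges.
#'
#' @param nProvinces number of provinces (>= 2).
#' @param seed integer seed; the result is deterministic given the seed.
#' @param extraEdgeProb probability of each additional (non-tree) edge.
#' @return symmetric binary `nProvinces` x `nProvinces` matrix.
#' @examples
#' adj <- makeGeography(5, seed = 1)
#' @export
makeGeography <- function(nProvinces, seed = 1, extraEdgeProb = 0.15) {
  if (!is.numeric(nProvinces) || nProvinces < 2)
    stop("nProvinces must be at least 2")
  nProvinces <- as.integer(nProvinces)
  adj <- matrix(0L, nProvinces, nProvinces)
  if (nProvinces == 2L) {
    adj[1, 2] <- adj[2, 1] <- 1L
    return(adj)
  }
  set.seed(seed)
  for (i in 2:nProvinces) {
    j <- sample.int(i - 1L, 1L)
    adj[i, j] <- adj[j, i] <- 1L
  }
  pairs <- which(upper.tri(adj) & adj == 0L, arr.ind = TRUE)
  if (nrow(pairs)) {
    add <- stats::runif(nrow(pairs)) < extraEdgeProb
    for (k in which(add)) {
      adj[pairs[k, 1], pairs[k, 2]] <- 1L
      adj[pairs[k, 2], pairs[k, 1]] <- 1L
    }
  }
  adj
}

#' Default configuration for the latent truth surface
#'
#' The defaults emulate female breast cancer in a middle-income country over
#' 1990-2016: an age profile rising steeply after age 40, a national secular
#' increase of about 4.8 percent per year in age-specific incidence, province
#' heterogeneity on the log scale, spatially correlated province effects, and
#' a mortality-to-incidence fraction that starts around 0.44 and declines as
#' care improves.
#'
#' @param nProvinces number of provinces.
#' @param years calendar years covered.
#' @param A number of 5-year age groups starting at age 15 (default 15,
#'   i.e. 15-19 ... 85+).
#' @return list of generating parameters accepted by [simulateTruth()].
#' @export
defaultTruthConfig <- function(nProvinces = 31, years = 1990:2016, A = 15) {
  ages <- seq_len(A)
  ## baseline (first-year) incidence per 100,000 by age group
  ageProfile <- 1.2 * exp(0.32 * (ages - 1))
  hi <- ageProfile > 95
  if (any(hi))   # flatten the oldest groups to a linear rise
    ageProfile[hi] <- 95 + 6 * (ages[hi] - min(ages[hi]))
  list(
    nProvinces = nProvinces,
    years = years,
    ageProfile = ageProfile,
    slope = 0.048,            # mean annual proportional change in incidence
    slopeSd = 0.015,          # between-province spread of the annual change
    provinceSd = 0.25,        # iid province effect, log scale
    spatialScale = 0.15,      # spatially correlated province effect
    ageDeviationSd = 0.1,     # province-specific age-profile wobble
                              # (smooth in age, stable over time)
    mortalityFraction = 0.44, # baseline mortality/incidence ratio
    mortalityDecline = 0.95,  # annual multiplier on that fraction
    covariates = NULL,        # optional data.frame(province, year, ...)
    covariateCoefs = NULL)    # named log-scale coefficients
}

#' Simulate the latent true rate surface
#'
#' Log incidence is `log(ageProfile[a]) + u_p + log(1 + slope) * (year - y0)`
#' plus an optional covariate term; the province effect `u_p` is the sum of
#' an iid Gaussian term and a spatially correlated term built from the
#' row-normalised smoothed adjacency kernel, each drawn once per province.
#' Mortality is incidence times a declining mortality fraction, so mortality
#' never exceeds incidence.
#'
#' @param config list as returned by [defaultTruthConfig()].
#' @param adjacency province adjacency matrix from [makeGeography()].
#' @param seed integer seed.
#' @return A \linkS4class{TruthSurface}.
#' @examples
#' cfg <- defaultTruthConfig(nProvinces = 4, years = 2000:2005)
#' truth <- simulateTruth(cfg, makeGeography(4, 1), seed = 1)
#' @export
simulateTruth <- function(config, adjacency, seed = 1) {
  P <- config$nProvinces
  stopifnot(nrow(adjacency) == P, ncol(adjacency) == P)
  num <- unlist(config[c("ageProfile", "slope", "provinceSd", "spatialScale",
                         "mortalityFraction", "mortalityDecline")])
  if (any(!is.finite(num)))
    stop("truth configuration contains non-finite values")
  A <- length(config$ageProfile)
  years <- config$years
  Y <- length(years)

  set.seed(seed)
  slope <- rep_len(config$slope, P)
  slopeSd <- config$slopeSd %||% 0
  if (slopeSd > 0)   # provinces trend at different speeds
    slope <- pmax(slope + slopeSd * stats::rnorm(P), -0.5)
  u <- config$provinceSd * stats::rnorm(P)

  ## province-specific age-profile deviations: smooth in age, centred per
  ## province, constant over time -- provinces differ in which ages their
  ## burden concentrates at, which is what the second-stage smoother of
  ## the estimation model is there to pick up
  devSd <- config$ageDeviationSd %||% 0
  ageDev <- matrix(0, P, A)
  if (devSd > 0) {
    kern <- stats::dnorm(-3:3 / 1.5)
    for (p in seq_len(P)) {
      z <- stats::rnorm(A + 6)
      s <- vapply(seq_len(A), function(a) sum(z[a:(a + 6)] * kern),
                  numeric(1))
      s <- s - mean(s)
      ageDev[p, ] <- devSd * s / max(stats::sd(s), 1e-9)
    }
  }

  if (config$spatialScale > 0) {
    K <- diag(P) + adjacency
    K <- K / rowSums(K)                  # smoothed adjacency kernel
    u <- u + config$spatialScale * as.numeric(K %*% stats::rnorm(P))
  }

  covTerm <- matrix(0, P, Y)
  if (!is.null(config$covariateCoefs) && length(config$covariateCoefs)) {
    cv <- config$covariates
    stopifnot(!is.null(cv))
    for (nm in names(config$covariateCoefs)) {
      x <- matrix(NA_real_, P, Y)
      idx <- cbind(match(cv$province, seq_len(P)), match(cv$year, years))
      x[idx] <- cv[[nm]]
      if (any(is.na(x))) stop("covariate table does not cover the grid: ", nm)
      covTerm <- covTerm + config$covariateCoefs[[nm]] * x
    }
  }

  inc <- array(0, dim = c(P, A, Y))
  for (y in seq_len(Y)) {
    t <- years[y] - years[1]
    for (p in seq_len(P)) {
      inc[p, , y] <- exp(log(config$ageProfile) + u[p] + ageDev[p, ] +
                           log(1 + slope[p]) * t + covTerm[p, y])
    }
  }
  mf <- pmin(config$mortalityFraction *
               config$mortalityDecline^(seq_len(Y) - 1), 1)
  mort <- inc
  for (y in seq_len(Y)) mort[, , y] <- inc[, , y] * mf[y]

  TruthSurface(.arrayToMatrix(inc), .arrayToMatrix(mort),
               provinces = seq_len(P), ageGroups = ageGroupLabels(A),
               years = years,
               params = c(config[setdiff(names(config), "covariates")],
                          list(provinceEffect = u, provinceSlope = slope,
                               ageDeviation = ageDev, seed = seed)))
}

#' Simulate female population counts by province, age group and year
#'
#' Province sizes are lognormal; the age pyramid declines with age; the
#' population grows over time with older groups growing faster, so both
#' growth and ageing are present for the decomposition analysis.
#'
#' @param nProvinces number of provinces.
#' @param years calendar years.
#' @param A number of age groups.
#' @param seed integer seed.
#' @param baseSize median province population in the first age group.
#' @return data.frame with columns `province`, `age_index`, `age_group`,
#'   `year`, `population`.
#' @export
simulatePopulation <- function(nProvinces, years, A = 15, seed = 1,
                               baseSize = 8e4) {
  set.seed(seed)
  sizes <- baseSize * exp(stats::rnorm(nProvinces, 0, 0.7))
  grid <- expand.grid(age_index = seq_len(A), province = seq_len(nProvinces),
                      year = years)
  t <- grid$year - years[1]
  growth <- 0.012 + 0.0035 * (grid$age_index - 1) / (A - 1) * 4
  pyramid <- exp(-0.11 * (grid$age_index - 1))
  pop <- sizes[grid$province] * pyramid * (1 + growth)^t
  data.frame(province = grid$province, age_index = grid$age_index,
             age_group = ageGroupLabels(A)[grid$age_index],
             year = grid$year, population = round(pop))
}

#' Synthetic remaining life expectancy by age group
#'
#' Strictly decreasing in age and positive, roughly matching remaining life
#' expectancy of women in a middle-income country (about 64 years at 15-19
#' down to about 5 years at 85+).
#'
#' @param A number of age groups.
#' @param e15 remaining life expectancy in the first (15-19) group.
#' @return data.frame with columns `age_index`, `age_group`,
#'   `life_expectancy`.
#' @export
simulateLifeTable <- function(A = 15, e15 = 64) {
  le <- e15 - (e15 - 5) * (seq_len(A) - 1) / (A - 1)
  data.frame(age_index = seq_len(A), age_group = ageGroupLabels(A),
             life_expectancy = le)
}

#' Simulate province-level covariates
#'
#' Wealth index (standardised), average successful schooling years and
#' urbanization proportion by province and year, each with a province level
#' and a smooth secular trend.
#'
#' @param nProvinces number of provinces.
#' @param years calendar years.
#' @param seed integer seed.
#' @return data.frame with columns `province`, `year`, `wealth`,
#'   `schooling`, `urbanization`.
#' @export
simulateCovariates <- function(nProvinces, years, seed = 1) {
  set.seed(seed)
  wealth0 <- stats::rnorm(nProvinces)
  school0 <- pmax(stats::rnorm(nProvinces, 4.5, 1.2), 1)
  urban0 <- stats::rnorm(nProvinces, 0.2, 0.5)
  grid <- expand.grid(province = seq_len(nProvinces), year = years)
  t <- grid$year - years[1]
  data.frame(
    province = grid$province, year = grid$year,
    wealth = wealth0[grid$province] + 0.02 * t,
    schooling = school0[grid$province] + 0.12 * t,
    urbanization = stats::plogis(urban0[grid$province] + 0.015 * t))
}

#' Default observation (noise) configuration for the registry generator
#'
#' Registration probabilities, per-field missingness, and the duplicate
#' probability applied when converting true events into registry rows.
#'
#' @return list with elements `piCRS`, `piSSOCR`, `piDRS`, `missingAge`,
#'   `missingSex`, `missingProvince`, `dupProb`, `otherCauses`.
#' @export
defaultObsConfig <- function() {
  list(piCRS = 0.8, piSSOCR = 0.9, piDRS = 0.85,
       missingAge = 0.05, missingSex = 0.03, missingProvince = 0.04,
       dupProb = 0.05,
       ## optional extra causes: flat incidence rates per 100,000 used to
       ## exercise the cause-fraction machinery (NULL = breast only)
       otherCauses = NULL)
}

.expandEvents <- function(counts, provinces, years, A, prefix) {
  ## counts: [P, A, Y] integer array of true events
  idx <- which(counts > 0, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(truth_link = character(), province = integer(),
                      age_index = integer(), year = integer()))
  n <- counts[idx]
  data.frame(
    truth_link = paste0(prefix, seq_len(sum(n))),
    province = rep(provinces[idx[, 1]], n),
    age_index = rep(idx[, 2], n),
    year = rep(years[idx[, 3]], n))
}

.maskFields <- function(df, obs) {
  n <- nrow(df)
  df$age[stats::runif(n) < obs$missingAge] <- NA_integer_
  df$sex[stats::runif(n) < obs$missingSex] <- NA_character_
  df$province[stats::runif(n) < obs$missingProvince] <- NA_integer_
  df
}

.addDuplicates <- function(df, dupProb) {
  if (!nrow(df) || dupProb <= 0) return(df)
  dup <- which(stats::runif(nrow(df)) < dupProb)
  if (!length(dup)) return(df)
  extra <- df[dup, , drop = FALSE]
  ## duplicates carry a distinct record_id string that normalises to the
  ## original (case flip + trailing whitespace)
  extra$record_id <- paste0(tolower(extra$record_id), " ")
  rbind(df, extra)
}

#' Simulate registry tables from a truth surface
#'
#' True case and death counts per stratum are Poisson with mean
#' `rate * population / 100,000`.  Each true case is registered in the
#' cancer registry (CRS) with probability `piCRS` and in the reference
#' capture source (SSOCR analogue) with probability `piSSOCR`, independently;
#' deaths are registered in the death registry (DRS) with probability
#' `piDRS`.  Field missingness is applied after registration, then duplicate
#' rows (distinct record ids, equal `truth_link`) are appended.  CRS and
#' SSOCR rows of the same true case share a person identifier, so the two
#' sources can be linked by normalised `record_id`.
#'
#' @param truth a \linkS4class{TruthSurface}.
#' @param population data.frame from [simulatePopulation()].
#' @param obsConfig list from [defaultObsConfig()].
#' @param seed integer seed.
#' @return list with registry data.frames `crs`, `drs`, `ssocr` and
#'   \linkS4class{PanelCounts} ground truth `trueCases`, `trueDeaths`.
#' @export
simulateRegistry <- function(truth, population, obsConfig = defaultObsConfig(),
                             seed = 1) {
  probs <- unlist(obsConfig[c("piCRS", "piSSOCR", "piDRS")])
  if (any(probs <= 0) || any(probs > 1))
    stop("registration probabilities must lie in (0, 1]")
  miss <- unlist(obsConfig[c("missingAge", "missingSex", "missingProvince",
                             "dupProb")])
  if (any(miss < 0) || any(miss >= 1))
    stop("missingness and duplicate probabilities must lie in [0, 1)")

  provinces <- unique(rowData(truth)$province)
  years <- colData(truth)$year
  A <- length(unique(rowData(truth)$ageIndex))
  startAge <- as.integer(sub("[-+].*", "", ageGroupLabels(A)[1]))

  inc <- panelArray(truth, "incidence")
  mort <- panelArray(truth, "mortality")
  popM <- .populationMatrix(population, provinces, A, years)
  popArr <- aperm(array(popM, dim = c(A, length(provinces), length(years))),
                  c(2, 1, 3))

  set.seed(seed)
  nCases <- array(stats::rpois(length(inc), inc * popArr / 1e5), dim = dim(inc))
  nDeaths <- array(stats::rpois(length(mort), mort * popArr / 1e5),
                   dim = dim(mort))

  cases <- .expandEvents(nCases, provinces, years, A, "C")
  deaths <- .expandEvents(nDeaths, provinces, years, A, "D")

  drawAge <- function(ageIndex) {
    lo <- startAge + 5L * (ageIndex - 1L)
    width <- ifelse(ageIndex == A, 10L, 5L)   # 85+ sampled over 85-94
    lo + as.integer(floor(stats::runif(length(ageIndex)) * width))
  }

  mkRows <- function(ev, cause) {
    data.frame(record_id = paste0("P", ev$truth_link), source = "",
               cause = cause, age = drawAge(ev$age_index), sex = "female",
               province = ev$province, year = ev$year,
               truth_link = ev$truth_link, stringsAsFactors = FALSE)
  }

  caseRows <- mkRows(cases, "breast")
  deathRows <- mkRows(deaths, "breast")

  ## optional extra causes (flat rates) to exercise cause-fraction models
  if (!is.null(obsConfig$otherCauses)) {
    for (nm in names(obsConfig$otherCauses)) {
      rate <- obsConfig$otherCauses[[nm]]
      nOther <- array(stats::rpois(length(popArr), rate * popArr / 1e5),
                      dim = dim(popArr))
      ev <- .expandEvents(nOther, provinces, years, A,
                          paste0("C", toupper(substr(nm, 1, 2))))
      caseRows <- rbind(caseRows, mkRows(ev, nm))
      nOtherD <- array(stats::rpois(length(popArr), 0.4 * rate * popArr / 1e5),
                       dim = dim(popArr))
      evd <- .expandEvents(nOtherD, provinces, years, A,
                           paste0("D", toupper(substr(nm, 1, 2))))
      deathRows <- rbind(deathRows, mkRows(evd, nm))
    }
  }

  capture <- function(rows, pi, source) {
    keep <- rows[stats::runif(nrow(rows)) < pi, , drop = FALSE]
    keep$source <- source
    keep <- .maskFields(keep, obsConfig)
    keep <- .addDuplicates(keep, obsConfig$dupProb)
    rownames(keep) <- NULL
    keep
  }

  crs <- capture(caseRows, obsConfig$piCRS, "CRS")
  ssocr <- capture(caseRows, obsConfig$piSSOCR, "SSOCR")
  drs <- capture(deathRows, obsConfig$piDRS, "DRS")

  ageGroups <- ageGroupLabels(A)
  trueCases <- PanelCounts(.arrayToMatrix(nCases), popM,
                           provinces, ageGroups, years)
  trueDeaths <- PanelCounts(.arrayToMatrix(nDeaths), popM,
                            provinces, ageGroups, years)
  list(crs = crs, drs = drs, ssocr = ssocr,
       trueCases = trueCases, trueDeaths = trueDeaths)
}

## population data.frame -> (P*A) x Y province-major matrix
.populationMatrix <- function(population, provinces, A, years) {
  m <- matrix(NA_real_, length(provinces) * A, length(years))
  row <- (match(population$province, provinces) - 1L) * A +
    population$age_index
  col <- match(population$year, years)
  ok <- !is.na(row) & !is.na(col)
  m[cbind(row[ok], col[ok])] <- population$population[ok]
  if (any(is.na(m)))
    stop("population table does not cover the full province x age x year grid")
  m
}
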