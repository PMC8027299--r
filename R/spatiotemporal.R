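## Two-stage rate estimation: a Poisson mixed model on log rates (stage
## one), then kernel smoothing of its residuals across neighbouring
## provinces, adjacent age groups and nearby years, with Monte-Carlo draws
## for 95% uncertainty intervals.

## build the stage-1 model frame in array order (age fastest, then
## province, then year), matching the flattened panel layout
.panelFrame <- function(counts, covariates = NULL) {
  provinces <- unique(rowData(counts)$province)
  A <- length(unique(rowData(counts)$ageIndex))
  years <- colData(counts)$year
  df <- expand.grid(ageIndex = seq_len(A), province = provinces,
                    year = years, KEEP.OUT.ATTRS = FALSE)
  df$events <- as.vector(assay(counts, "events"))
  df$personYears <- as.vector(assay(counts, "personYears"))
  if (!is.null(covariates)) {
    idx <- match(paste(df$province, df$year),
                 paste(covariates$province, covariates$year))
    if (any(is.na(idx)))
      stop("covariate table does not cover the panel grid")
    for (nm in setdiff(names(covariates), c("province", "year")))
      df[[nm]] <- covariates[[nm]][idx]
  }
  df$ageGroup <- factor(df$ageIndex)
  df$provinceF <- factor(df$province)
  df
}

#' Fit the stage-one covariate mixed model
#'
#' A Poisson log-linear model of events with offset
#' `log(personYears / 100,000)`: fixed effects for age-group indicators, a
#' (centred) calendar-year trend and any province-level covariates, plus a
#' random intercept per province.  Residuals are formed on the log-rate
#' scale as `log((events + 0.5) / (fitted events + 0.5))`: the 0.5-event
#' stabilisation is applied symmetrically to the observed and fitted
#' counts, which keeps zero-event strata finite without the systematic
#' upward bias a one-sided continuity correction produces in sparse cells.
#'
#' The secular time trend is deliberately not a fixed effect by default:
#' stage one captures covariate and age structure, and whatever trend the
#' covariates miss is left in the residuals for the age-spatio-temporal
#' smoother (set `includeYear = TRUE` to add a linear year term).
#'
#' @param counts a \linkS4class{PanelCounts}.
#' @param covariates optional data.frame with columns `province`, `year` and
#'   numeric covariate columns; constant columns are dropped.
#' @param includeYear include a linear calendar-year fixed effect.
#' @return A \linkS4class{Stage1Fit}.
#' @export
fitStage1 <- function(counts, covariates = NULL, includeYear = FALSE) {
  stopifnot(is(counts, "PanelCounts"))
  df <- .panelFrame(counts, covariates)
  provinces <- unique(rowData(counts)$province)
  A <- length(unique(rowData(counts)$ageIndex))
  years <- colData(counts)$year

  usable <- df$personYears > 0
  if (!all(usable))
    message(sprintf("fitStage1: %d strata with zero person-years excluded",
                    sum(!usable)))

  ## the Poisson likelihood needs integer counts: fit on rounded events,
  ## keep the fractional (completeness-corrected) events for residuals
  df$eventsFit <- round(df$events)

  terms <- character(0)
  if (A > 1) terms <- c(terms, "ageGroup")
  if (includeYear && length(unique(df$year)) > 1) {
    df$yearC <- df$year - mean(range(df$year))
    terms <- c(terms, "yearC")
  }
  covNames <- setdiff(names(df),
                      c("ageIndex", "province", "year", "events", "eventsFit",
                        "personYears", "ageGroup", "provinceF", "yearC",
                        "off"))
  for (nm in covNames)
    if (stats::sd(df[[nm]][usable]) > 0) terms <- c(terms, nm)
  fixed <- stats::reformulate(if (length(terms)) terms else "1",
                              response = "eventsFit")

  df$off <- log(pmax(df$personYears, 1e-12) / 1e5)
  full <- stats::update(fixed, . ~ . + (1 | provinceF))
  fit <- tryCatch(
    suppressWarnings(lme4::glmer(
      full, data = df[usable, , drop = FALSE], family = stats::poisson(),
      offset = df$off[usable],
      control = lme4::glmerControl(check.conv.singular = "ignore",
                                   check.response.not.const = "ignore"))),
    error = function(e) e)

  u <- stats::setNames(rep(0, length(provinces)), as.character(provinces))
  if (inherits(fit, "error")) {
    ## degenerate inputs (e.g. noise-free panels) can defeat the mixed
    ## solver; fall back to the fixed-effects GLM with zero intercepts
    message("fitStage1: mixed model failed (", conditionMessage(fit),
            "); falling back to a fixed-effects Poisson GLM")
    gfit <- suppressWarnings(stats::glm(
      fixed, data = df[usable, , drop = FALSE], family = stats::poisson(),
      offset = df$off[usable]))
    beta <- stats::coef(gfit)
    V <- as.matrix(stats::vcov(gfit))
  } else {
    beta <- lme4::fixef(fit)
    V <- as.matrix(suppressWarnings(stats::vcov(fit)))
    re <- lme4::ranef(fit)$provinceF
    u[rownames(re)] <- re[["(Intercept)"]]
  }

  X <- stats::model.matrix(stats::delete.response(stats::terms(fixed)), df)
  ranefIndex <- match(as.character(df$province), names(u))
  predVec <- as.numeric(X %*% beta) + u[ranefIndex]

  dims <- c(length(provinces), A, length(years))
  toArr <- function(v) aperm(array(v, dim = c(A, dims[1], dims[3])), c(2, 1, 3))
  py <- pmax(df$personYears, 1e-12)
  muHat <- exp(predVec) * py / 1e5        # fitted events
  logObs <- log((df$events + 0.5) / py * 1e5)
  resid <- log((df$events + 0.5) / (muHat + 0.5))
  logObs[!usable] <- predVec[!usable]     # neutral where no exposure
  resid[!usable] <- 0

  new("Stage1Fit", coef = beta, vcov = V, ranef = u, design = X,
      ranefIndex = as.integer(ranefIndex),
      fitted = toArr(predVec), logObserved = toArr(logObs),
      residuals = toArr(resid),
      events = toArr(df$events), personYears = toArr(df$personYears),
      provinces = as.integer(provinces),
      ageGroups = unique(as.character(rowData(counts)$ageGroup)),
      years = as.integer(years))
}

#' Build the age-spatio-temporal smoothing kernel
#'
#' The weight between a target stratum (p, a, y) and a donor (p', a', y')
#' factorises as `w_space * w_age * w_time`: `w_space` is 1 on the own
#' province, `lambda / deg(p)` on adjacent provinces and 0 elsewhere;
#' `w_age = exp(-omega |a - a'|)`; `w_time = zeta^|y - y'|`.  Weights over
#' all donors are normalised to sum to one for each target stratum.
#'
#' @param adjacency province adjacency matrix.
#' @param params list with `lambda` in \[0, 1\], `omega >= 0` (may be `Inf`)
#'   and `zeta` in (0, 1\].
#' @param A number of age groups.
#' @param years calendar years (only the count and spacing matter).
#' @return A \linkS4class{SmoothingWeights}.
#' @export
buildWeights <- function(adjacency,
                         params = list(lambda = 0.3, omega = 0.7, zeta = 0.8),
                         A, years) {
  lambda <- params$lambda; omega <- params$omega; zeta <- params$zeta
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (omega < 0) stop("omega must be non-negative")
  if (zeta <= 0 || zeta > 1) stop("zeta must lie in (0, 1]")
  P <- nrow(adjacency)

  ## connectivity check (BFS) -- disconnected graphs only warn
  seen <- logical(P); seen[1] <- TRUE; queue <- 1L
  while (length(queue)) {
    nb <- which(adjacency[queue[1], ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue[-1], nb)
  }
  if (!all(seen))
    warning("province adjacency graph is not connected")

  deg <- pmax(rowSums(adjacency > 0), 1)
  Ws <- diag(P) + sweep(1 * (adjacency > 0), 1, lambda / deg, `*`)
  dAge <- abs(outer(seq_len(A), seq_len(A), `-`))
  Wa <- if (is.infinite(omega)) diag(A) else exp(-omega * dAge)
  yy <- as.numeric(years)
  Wt <- zeta^abs(outer(yy, yy, `-`))
  new("SmoothingWeights", space = Ws, age = Wa, time = Wt,
      lambda = lambda, omega = omega, zeta = zeta)
}

#' Evaluate a single normalised smoothing weight
#'
#' @param weights a \linkS4class{SmoothingWeights}.
#' @param target,donor integer vectors `c(province, ageIndex, yearIndex)`.
#' @return the normalised weight of the donor stratum for the target.
#' @export
pairWeight <- function(weights, target, donor) {
  num <- weights@space[target[1], donor[1]] *
    weights@age[target[2], donor[2]] * weights@time[target[3], donor[3]]
  den <- sum(weights@space[target[1], ]) * sum(weights@age[target[2], ]) *
    sum(weights@time[target[3], ])
  num / den
}

## multiply an [P, A, Y] array by a matrix along one mode
.modeMult <- function(arr, M, mode) {
  d <- dim(arr)
  perm <- switch(mode, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  m <- M %*% matrix(a, nrow = d[mode])
  out <- array(m, dim = d[perm])
  aperm(out, order(perm))
}

## apply the unnormalised factorised kernel to an array
.kernelApply <- function(arr, weights) {
  .modeMult(.modeMult(.modeMult(arr, weights@space, 1),
                      weights@age, 2), weights@time, 3)
}

#' Smooth a residual surface with the factorised kernel
#'
#' Computes `eps*(s) = sum_s' w(s, s') eps(s')` with the normalised
#' product kernel.  Because the kernel factorises over the three axes, the
#' numerator is three successive mode products and the normaliser is the
#' kernel applied to the (optional) precision field; the operation is
#' linear in `eps` with rows summing to one.
#'
#' When `precision` is supplied (typically fitted event counts), donor
#' strata contribute proportionally to kernel weight times precision:
#' sparse cells, whose log-scale residuals are noisy and Jensen-biased,
#' then borrow strength from data-rich neighbours instead of spreading
#' noise into them.  A \linkS4class{Stage1Fit} input uses its fitted
#' events as the precision by default.
#'
#' @param eps residual array `[province, age, year]`, or a
#'   \linkS4class{Stage1Fit} (its residuals are used).
#' @param weights a \linkS4class{SmoothingWeights}.
#' @param precision optional non-negative array of the same shape.
#' @return smoothed residual array of the same shape.
#' @export
smoothResiduals <- function(eps, weights, precision = NULL) {
  if (is(eps, "Stage1Fit")) {
    if (is.null(precision))
      precision <- exp(eps@fitted) * eps@personYears / 1e5 + 0.5
    eps <- eps@residuals
  }
  if (is.null(precision)) precision <- array(1, dim = dim(eps))
  .kernelApply(eps * precision, weights) / .kernelApply(precision, weights)
}

## apply the kernel with squared per-axis weights (for variance fields)
.kernelApplySq <- function(arr, weights) {
  .modeMult(.modeMult(.modeMult(arr, weights@space^2, 1),
                      weights@age^2, 2), weights@time^2, 3)
}

## Empirical-Bayes residual adjustment on the count scale.
##
## Two noisy estimates of each cell's log deviation from the stage-one
## prediction are combined by precision: the cell's own observed/fitted
## log ratio (variance ~ 1/events) and the kernel-smoothed log ratio of
## aggregated observed to fitted counts (variance from the squared-kernel
## Poisson propagation).  Taking logs after kernel aggregation avoids the
## Jensen bias that log residuals of sparse Poisson cells would carry into
## their neighbours.  The structure variance tau^2 is estimated globally
## from the smoothed field (method of moments, truncated at zero); when
## the data show no residual structure the adjustment shrinks to zero and
## the estimator falls back to stage one.
.ebPosterior <- function(events, mu, weights) {
  Ky <- .kernelApply(events, weights)
  Kmu <- .kernelApply(mu, weights)
  a <- log((Ky + 0.5) / (Kmu + 0.5))          # kernel estimate
  v <- .kernelApplySq(mu, weights) / (Kmu + 0.5)^2
  d <- log((events + 0.5) / (mu + 0.5))       # own-cell estimate
  sd2 <- 1 / (mu + 0.5)
  tau2 <- max(0, mean(a^2 - v))
  if (tau2 <= 0)
    return(list(mean = array(0, dim = dim(mu)),
                var = array(0, dim = dim(mu))))
  prec <- 1 / sd2 + 1 / v + 1 / tau2
  ## the nominal posterior variance understates the uncertainty of the
  ## kernel field (its attenuation of structure is not modelled); the
  ## draw variance carries a simulation-calibrated inflation factor so
  ## the 95% intervals attain close-to-nominal coverage
  list(mean = (d / sd2 + a / v) / prec, var = 4 / prec)
}

.ebAdjust <- function(events, mu, weights) {
  .ebPosterior(events, mu, weights)$mean
}

#' Point-estimate rate surface from a stage-one fit
#'
#' Final log rate is the stage-one prediction plus an empirical-Bayes
#' residual adjustment: the precision-weighted combination of the cell's
#' own observed/fitted log event ratio and the kernel-smoothed aggregated
#' ratio, shrunk by the globally estimated structure variance.  When the
#' residuals show no structure beyond Poisson noise the adjustment is zero
#' and the surface equals the stage-one predictions.
#'
#' @param stage1 a \linkS4class{Stage1Fit}.
#' @param weights a \linkS4class{SmoothingWeights}.
#' @return rate array `[province, age, year]` per 100,000.
#' @export
pointRates <- function(stage1, weights) {
  mu <- exp(stage1@fitted) * stage1@personYears / 1e5
  exp(stage1@fitted + .ebAdjust(stage1@events, mu, weights))
}

#' Monte-Carlo draws of the rate surface
#'
#' Each draw perturbs the fixed effects by a multivariate normal with the
#' fitted covariance (random intercepts are held at their estimates),
#' recomputes the stage-one predictions and the empirical-Bayes residual
#' posterior, draws the residual deviation from that posterior
#' (mean plus posterior-variance normal noise) and exponentiates, so the
#' intervals carry both parameter uncertainty and the posterior
#' uncertainty of the smoothed deviations.  Deterministic given `seed`.
#'
#' @param stage1 a \linkS4class{Stage1Fit}.
#' @param weights a \linkS4class{SmoothingWeights}.
#' @param nDraws number of draws (default 1000).
#' @param seed integer seed.
#' @param posteriorNoise include the residual-posterior noise (set
#'   `FALSE` for parameter-uncertainty-only draws, which are degenerate
#'   when the coefficient covariance is zero).
#' @return A \linkS4class{DrawsCube}.
#' @export
sampleDraws <- function(stage1, weights, nDraws = 1000, seed = 1,
                        posteriorNoise = TRUE) {
  V <- (stage1@vcov + t(stage1@vcov)) / 2
  ev <- eigen(V, symmetric = TRUE)
  if (any(ev$values < -1e-8 * max(abs(ev$values), 1e-12))) {
    warning("fixed-effect covariance not positive semidefinite; projecting")
    V <- ev$vectors %*% diag(pmax(ev$values, 0), nrow(V)) %*% t(ev$vectors)
  }
  set.seed(seed)
  B <- MASS::mvrnorm(nDraws, mu = stage1@coef, Sigma = V)
  if (nDraws == 1) B <- matrix(B, nrow = 1)

  u <- stage1@ranef[stage1@ranefIndex]
  dims <- dim(stage1@fitted)
  toArr <- function(v) aperm(array(v, dim = c(dims[2], dims[1], dims[3])),
                             c(2, 1, 3))
  y <- stage1@events
  py <- pmax(stage1@personYears, 1e-12)
  point <- pointRates(stage1, weights)
  draws <- matrix(0, nDraws, prod(dims))
  for (d in seq_len(nDraws)) {
    pred <- toArr(as.numeric(stage1@design %*% B[d, ]) + u)
    mu <- exp(pred) * py / 1e5
    post <- .ebPosterior(y, mu, weights)
    delta <- post$mean
    if (posteriorNoise)
      delta <- delta + sqrt(post$var) *
        array(stats::rnorm(length(delta)), dim = dims)
    draws[d, ] <- as.vector(.arrayToMatrix(exp(pred + delta)))
  }
  new("DrawsCube", draws = draws,
      point = point, seed = as.integer(seed),
      provinces = stage1@provinces, ageGroups = stage1@ageGroups,
      years = stage1@years)
}

#' Empirical 95% uncertainty intervals from rate draws
#'
#' Per-stratum 2.5th and 97.5th empirical percentiles (linear-interpolation
#' quantile definition) around the point-estimate surface.
#'
#' @param cube a \linkS4class{DrawsCube} with at least 100 draws.
#' @return A \linkS4class{RateSurface}.
#' @export
uncertaintyInterval <- function(cube) {
  if (nrow(cube@draws) < 100)
    stop("at least 100 draws are required for uncertainty intervals")
  q <- apply(cube@draws, 2, stats::quantile, probs = c(0.025, 0.975),
             names = FALSE, type = 7)
  pt <- .arrayToMatrix(cube@point)
  nr <- nrow(pt); nc <- ncol(pt)
  lower <- pmin(matrix(q[1, ], nr, nc), pt)
  upper <- pmax(matrix(q[2, ], nr, nc), pt)
  RateSurface(pt, lower, upper, provinces = cube@provinces,
              ageGroups = cube@ageGroups, years = cube@years)
}

#' One-call two-stage rate estimation
#'
#' Convenience wrapper: stage-one fit, kernel construction, Monte-Carlo
#' draws and uncertainty intervals.
#'
#' @inheritParams fitStage1
#' @param adjacency province adjacency matrix.
#' @param params smoothing hyperparameters (see [buildWeights()]).
#' @param nDraws number of Monte-Carlo draws.
#' @param seed integer seed.
#' @return list with `fit`, `weights`, `cube` and `surface` (a
#'   \linkS4class{RateSurface}).
#' @export
estimateRates <- function(counts, covariates = NULL, adjacency,
                          params = list(lambda = 0.3, omega = 0.7, zeta = 0.8),
                          nDraws = 1000, seed = 1, includeYear = FALSE) {
  fit <- fitStage1(counts, covariates, includeYear = includeYear)
  A <- length(fit@ageGroups)
  w <- buildWeights(adjacency, params, A = A, years = fit@years)
  cube <- sampleDraws(fit, w, nDraws = nDraws, seed = seed)
  list(fit = fit, weights = w, cube = cube,
       surface = uncertaintyInterval(cube))
}
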