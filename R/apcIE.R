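## Age-period-cohort analysis with the intrinsic estimator: the
## minimum-norm (null-space-orthogonal) solution of the rank-deficient
## Poisson log-linear APC model, solved by iteratively reweighted least
## squares with a pseudoinverse.

#' Build the effect-coded APC design matrix
#'
#' Rows are the A x P Lexis cells (age fastest); columns are an intercept
#' plus sum-to-zero contrasts for age (A-1), period (P-1) and cohort
#' (A+P-2).  Because cohort = period - age on equal-width grids, the matrix
#' has a one-dimensional null space: rank = columns - 1.
#'
#' @param lexis a \linkS4class{LexisTable}.
#' @return list with `X` (design matrix), `cohort` (1-based cohort index
#'   per cell), `A`, `P`, `C`.
#' @export
buildDesign <- function(lexis) {
  A <- nrow(lexis@events); P <- ncol(lexis@events)
  if (A < 2 || P < 2) stop("at least 2 age groups and 2 periods required")
  grid <- expand.grid(age = seq_len(A), period = seq_len(P))
  cohort <- (A - grid$age) + grid$period      # 1 .. A + P - 1
  C <- A + P - 1L
  Ca <- stats::contr.sum(A); Cp <- stats::contr.sum(P)
  Cc <- stats::contr.sum(C)
  X <- cbind(`(Intercept)` = 1,
             Ca[grid$age, , drop = FALSE],
             Cp[grid$period, , drop = FALSE],
             Cc[cohort, , drop = FALSE])
  colnames(X) <- c("(Intercept)",
                   paste0("age", seq_len(A - 1)),
                   paste0("period", seq_len(P - 1)),
                   paste0("cohort", seq_len(C - 1)))
  list(X = X, cohort = cohort, A = A, P = P, C = C)
}

#' Null vector of the APC design
#'
#' The unit-norm basis of the kernel of the design (equivalently of its
#' normal matrix), with sign fixed so the first non-zero element is
#' positive.  Errors if the numerical kernel is not one-dimensional.
#'
#' @param design list from [buildDesign()], or a design matrix.
#' @return unit-norm numeric vector `B0` with `X %*% B0 = 0`.
#' @export
nullVector <- function(design) {
  X <- if (is.list(design)) design$X else design
  ev <- eigen(crossprod(X), symmetric = TRUE)
  tol <- max(ev$values) * 1e-10
  nKernel <- sum(ev$values < tol)
  if (nKernel != 1)
    stop("numeric kernel dimension is ", nKernel, ", expected 1")
  b0 <- ev$vectors[, ncol(X)]
  nz <- which(abs(b0) > 1e-12)[1]
  if (b0[nz] < 0) b0 <- -b0
  b0 / sqrt(sum(b0^2))
}

## Moore-Penrose pseudoinverse solve of the weighted normal equations
.pinvSolve <- function(X, w, z) {
  Xw <- X * sqrt(w)
  sv <- svd(Xw)
  tol <- max(dim(Xw)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol * 1e3
  as.numeric(sv$v[, pos] %*% ((t(sv$u[, pos]) %*% (sqrt(w) * z)) / sv$d[pos]))
}

#' Fit the age-period-cohort model with the intrinsic estimator
#'
#' Poisson log-linear model of events with offset `log(exposure)`, solved
#' by IRLS where each step uses the Moore-Penrose pseudoinverse of the
#' weighted normal equations.  Every iterate — hence the solution — is
#' orthogonal to the design's null vector, which is the intrinsic
#' estimator; fitted cell means coincide with any other
#' minimal-constraint identification.  `family = "gaussian"` instead
#' regresses log observed rates (0.5-event continuity correction) by
#' ordinary least squares.
#'
#' @param lexis a \linkS4class{LexisTable}.
#' @param family `"poisson"` (default) or `"gaussian"`.
#' @param maxit,tol IRLS iteration cap and convergence tolerance on the
#'   coefficient change.
#' @return An \linkS4class{APCEffects}.
#' @export
fitIE <- function(lexis, family = c("poisson", "gaussian"),
                  maxit = 100, tol = 1e-12) {
  family <- match.arg(family)
  des <- buildDesign(lexis)
  X <- des$X
  y <- as.vector(lexis@events)
  ex <- as.vector(lexis@exposure)
  keep <- ex > 0
  if (!all(keep)) {
    warning(sprintf("fitIE: %d zero-exposure cell(s) dropped", sum(!keep)))
    X <- X[keep, , drop = FALSE]; y <- y[keep]; ex <- ex[keep]
  }
  off <- log(ex)
  b0 <- nullVector(des)

  if (family == "gaussian") {
    z <- log((y + 0.5 * (y == 0)) / ex)
    b <- .pinvSolve(X, rep(1, length(z)), z)
    mu <- exp(as.numeric(X %*% b) + off)
    dev <- sum((z - as.numeric(X %*% b))^2)
  } else {
    b <- rep(0, ncol(X))
    b[1] <- log(sum(y) / sum(ex))
    for (it in seq_len(maxit)) {
      eta <- as.numeric(X %*% b) + off
      mu <- exp(eta)
      z <- eta - off + (y - mu) / mu
      bNew <- .pinvSolve(X, mu, z)
      delta <- max(abs(bNew - b))
      b <- bNew
      if (delta < tol) break
    }
    if (delta >= max(tol, 1e-8))
      stop("IRLS did not converge after ", maxit, " iterations")
    mu <- exp(as.numeric(X %*% b) + off)
    dev <- 2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  }

  ## project out any numerical drift along the null direction
  b <- b - sum(b * b0) * b0

  A <- des$A; P <- des$P; C <- des$C
  splitIdx <- function(n0, k) seq.int(n0, length.out = k)
  bAge <- b[splitIdx(2, A - 1)]
  bPer <- b[splitIdx(A + 1, P - 1)]
  bCoh <- b[splitIdx(A + P, C - 1)]
  ageEff <- as.numeric(stats::contr.sum(A) %*% bAge)
  perEff <- as.numeric(stats::contr.sum(P) %*% bPer)
  cohEff <- as.numeric(stats::contr.sum(C) %*% bCoh)

  fitted <- matrix(NA_real_, A, P,
                   dimnames = list(lexis@ageLabels, lexis@periodLabels))
  fitted[keep] <- mu

  new("APCEffects", intercept = b[1],
      age = stats::setNames(ageEff, lexis@ageLabels),
      period = stats::setNames(perEff, lexis@periodLabels),
      cohort = stats::setNames(cohEff, paste0("cohort", seq_len(C))),
      coef = stats::setNames(b, colnames(X)), b0 = b0,
      deviance = dev, fitted = fitted)
}

#' Percentile bootstrap intervals for APC relative risks
#'
#' Parametric bootstrap: events are redrawn Poisson around the fitted cell
#' means and the intrinsic estimator refitted; percentile intervals are
#' taken per effect level.
#'
#' @param lexis a \linkS4class{LexisTable}.
#' @param nBoot number of resamples (default 200).
#' @param seed integer seed.
#' @param level confidence level.
#' @return list with data.frames `age`, `period`, `cohort`, each with
#'   columns `level`, `rr`, `lower`, `upper`.
#' @export
bootstrapIE <- function(lexis, nBoot = 200, seed = 1, level = 0.95) {
  fit0 <- fitIE(lexis)
  mu <- fit0@fitted
  mu[is.na(mu)] <- 0
  set.seed(seed)
  res <- replicate(nBoot, {
    ystar <- matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu))
    f <- fitIE(lexisTable(ystar, lexis@exposure, lexis@ageWidth,
                          lexis@periodWidth, lexis@ageLabels,
                          lexis@periodLabels))
    c(f@age, f@period, f@cohort)
  })
  alpha <- (1 - level) / 2
  qs <- apply(res, 1, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  eff <- list(age = fit0@age, period = fit0@period, cohort = fit0@cohort)
  off <- 0
  out <- lapply(eff, function(e) {
    idx <- off + seq_along(e)
    off <<- off + length(e)
    data.frame(level = names(e), rr = exp(e),
               lower = exp(qs[1, idx]), upper = exp(qs[2, idx]),
               row.names = NULL)
  })
  out
}

#' Collapse a panel to a national Lexis table
#'
#' Sums events and person-years over provinces and groups calendar years
#' into consecutive equal-width periods starting at the first year; a
#' trailing incomplete period is dropped with a message.
#'
#' @param counts a \linkS4class{PanelCounts}.
#' @param width period width in years (default 5, matching the age groups).
#' @return A \linkS4class{LexisTable}.
#' @export
lexisFromPanel <- function(counts, width = 5) {
  years <- colData(counts)$year
  block <- (years - years[1]) %/% width
  full <- table(block) == width
  keep <- block %in% as.integer(names(full)[full])
  if (!all(keep))
    message(sprintf("lexisFromPanel: dropping %d year(s) in a trailing incomplete period",
                    sum(!keep)))
  A <- length(unique(rowData(counts)$ageIndex))
  ev <- assay(counts, "events"); py <- assay(counts, "personYears")
  blocks <- sort(unique(block[keep]))
  agg <- function(m) vapply(blocks, function(b) {
    cols <- which(block == b & keep)
    rowSums(matrix(rowsum(m[, cols, drop = FALSE],
                          rowData(counts)$ageIndex), nrow = A))
  }, numeric(A))
  labs <- vapply(blocks, function(b) {
    yr <- years[block == b & keep]
    paste0(min(yr), "-", max(yr))
  }, character(1))
  lexisTable(agg(ev), agg(py), ageWidth = width, periodWidth = width,
             ageLabels = unique(as.character(rowData(counts)$ageGroup)),
             periodLabels = labs)
}
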