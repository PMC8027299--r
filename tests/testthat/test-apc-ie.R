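## events from a pure age profile whose coefficient vector is orthogonal
## to the design's null direction: the inestimable linear drift is then
## genuinely zero and the intrinsic estimator recovers the effects
curvatureLexis <- function(A = 6, P = 4, exposure = 2e6, seed = 1,
                           noise = TRUE) {
  des <- buildDesign(lexisTable(matrix(1, A, P), matrix(1, A, P)))
  b0 <- nullVector(des)
  Ca <- stats::contr.sum(A)
  quad <- scale(stats::poly(seq_len(A), 2)[, 2])[, 1]
  quad <- quad - mean(quad)
  bAge <- solve(crossprod(Ca), crossprod(Ca, quad))[, 1]
  b0Age <- b0[2:A]
  bAge <- bAge - sum(bAge * b0Age) / sum(b0Age^2) * b0Age
  ageEff <- as.numeric(Ca %*% bAge)
  mu <- exp(log(40 / 1e5) + matrix(ageEff, A, P)) * exposure
  set.seed(seed)
  y <- if (noise) matrix(stats::rpois(A * P, mu), A, P) else mu
  list(lexis = lexisTable(y, matrix(exposure, A, P)), ageEff = ageEff,
       mu = mu)
}

test_that("the APC design has the documented shape and a rank-one deficiency", {
  lex <- lexisTable(matrix(1, 2, 2), matrix(10, 2, 2))
  des <- buildDesign(lex)
  expect_equal(dim(des$X), c(4, 5))   # intercept + 1 age + 1 period + 2 cohort
  expect_equal(qr(des$X)$rank, 4)
  expect_equal(des$C, 3)

  lex15 <- lexisTable(matrix(1, 15, 4), matrix(10, 15, 4))
  des15 <- buildDesign(lex15)
  expect_equal(des15$C, 18)           # A + P - 1 cohorts
  expect_equal(ncol(des15$X), 1 + 14 + 3 + 17)
  expect_equal(qr(des15$X)$rank, ncol(des15$X) - 1)
})

test_that("the null space is one-dimensional across random grid sizes", {
  set.seed(4)
  for (i in 1:6) {
    A <- sample(2:10, 1); P <- sample(2:10, 1)
    des <- buildDesign(lexisTable(matrix(1, A, P), matrix(10, A, P)))
    d <- svd(des$X)$d                 # SVD oracle
    tol <- max(dim(des$X)) * .Machine$double.eps * d[1]
    expect_equal(sum(d < tol * 100), min(1, ncol(des$X) - length(d) + 1))
    expect_lt(max(abs(des$X %*% nullVector(des))), 1e-10)
  }
})

test_that("the null vector matches an independent kernel computation", {
  des <- buildDesign(lexisTable(matrix(1, 2, 2), matrix(10, 2, 2)))
  b0 <- nullVector(des)
  oracle <- MASS::Null(t(des$X))      # kernel basis from QR, independent path
  expect_equal(ncol(oracle), 1)
  o <- oracle[, 1] / sqrt(sum(oracle[, 1]^2))
  if (sum(o * b0) < 0) o <- -o
  expect_equal(b0, o, tolerance = 1e-10)
  expect_identical(b0, nullVector(des))          # deterministic
  expect_equal(sqrt(sum(b0^2)), 1, tolerance = 1e-12)
})

test_that("identical rates in all cells give unit relative risks", {
  lex <- lexisTable(matrix(80, 5, 4), matrix(2e5, 5, 4))
  fit <- fitIE(lex)
  rr <- relativeRisks(fit)
  expect_equal(unname(rr$age), rep(1, 5), tolerance = 1e-8)
  expect_equal(unname(rr$period), rep(1, 4), tolerance = 1e-8)
  expect_equal(unname(rr$cohort), rep(1, 8), tolerance = 1e-8)
})

test_that("pure age curvature is recovered with null period and cohort effects", {
  sim <- curvatureLexis(seed = 2)
  fit <- fitIE(sim$lexis)
  ## rough per-row SE on the log scale: 1 / sqrt(events per age row)
  se <- 1 / sqrt(rowSums(sim$mu))
  expect_true(all(abs(fit@age - sim$ageEff) < 3 * se + 0.01))
  ## corner cohorts rest on a single cell: bound by its Poisson noise
  cellSe <- 1 / sqrt(min(sim$mu))
  expect_true(all(abs(fit@period) < 3 * cellSe))
  expect_true(all(abs(fit@cohort) < 3.5 * cellSe))
  expect_true(all(abs(exp(fit@period) - 1) < 0.15))
  expect_true(all(abs(exp(fit@cohort) - 1) < 0.15))
})

test_that("IE fitted means coincide with a drop-one-level constrained GLM", {
  sim <- curvatureLexis(A = 7, P = 5, seed = 3)
  fit <- fitIE(sim$lexis)
  des <- buildDesign(sim$lexis)
  Xc <- des$X[, -ncol(des$X)]         # drop one cohort contrast
  y <- as.vector(sim$lexis@events)
  off <- log(as.vector(sim$lexis@exposure))
  oracle <- stats::glm(y ~ Xc - 1 + offset(off), family = stats::poisson())
  expect_lt(max(abs(stats::fitted(oracle) - as.vector(fit@fitted)) /
                  stats::fitted(oracle)), 1e-6)
  expect_lt(abs(fit@deviance - stats::deviance(oracle)), 1e-6)
})

test_that("the IE coefficient vector is orthogonal to the null vector", {
  sim <- curvatureLexis(A = 5, P = 6, seed = 5)
  fit <- fitIE(sim$lexis)
  expect_lt(abs(sum(fit@coef * fit@b0)), 1e-8)
  for (v in list(fit@age, fit@period, fit@cohort))
    expect_lt(abs(sum(v)), 1e-9)
})

test_that("zero-exposure cells are dropped with a warning", {
  ex <- matrix(2e5, 4, 3); ex[1, 1] <- 0
  y <- matrix(50, 4, 3); y[1, 1] <- 0
  lex <- lexisTable(y, ex)
  expect_warning(fit <- fitIE(lex), "dropped")
  expect_true(is.na(fit@fitted[1, 1]))
})

test_that("the OLS-on-log-rates variant behaves like the Poisson fit", {
  sim <- curvatureLexis(A = 5, P = 4, exposure = 1e6, seed = 6)
  fp <- fitIE(sim$lexis, family = "poisson")
  fg <- fitIE(sim$lexis, family = "gaussian")
  expect_equal(unname(fg@age), unname(fp@age), tolerance = 0.05)
  expect_lt(abs(sum(fg@coef * fg@b0)), 1e-8)
})

test_that("panels collapse to national Lexis tables on complete periods", {
  ev <- matrix(2, 3 * 2, 12)          # 2 provinces x 3 ages x 12 years
  py <- matrix(5e4, 6, 12)
  pc <- PanelCounts(ev, py, provinces = 1:2, ageGroups = ageGroupLabels(3),
                    years = 2000:2011)
  lex <- lexisFromPanel(pc, width = 5)
  expect_equal(dim(lex@events), c(3, 2))          # 10 full years -> 2 periods
  expect_equal(lex@periodLabels, c("2000-2004", "2005-2009"))
  expect_equal(unname(lex@events[1, 1]), 2 * 2 * 5)  # provinces x years
  expect_equal(unname(lex@exposure[1, 1]), 2 * 5e4 * 5)
})

test_that("bootstrap intervals bracket the point relative risks", {
  sim <- curvatureLexis(A = 4, P = 3, seed = 8)
  ci <- bootstrapIE(sim$lexis, nBoot = 30, seed = 2)
  fit <- fitIE(sim$lexis)
  expect_true(all(ci$age$lower <= exp(fit@age) + 1e-9))
  expect_true(all(ci$age$upper >= exp(fit@age) - 1e-9))
  expect_named(ci, c("age", "period", "cohort"))
})
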