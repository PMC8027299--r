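## a tiny PanelCounts built directly from a rate, with Poisson noise off
constantPanel <- function(rate = 30, P = 3, A = 1, Y = 4, py = 2e5) {
  ev <- matrix(rate * py / 1e5, P * A, Y)
  PanelCounts(ev, matrix(py, P * A, Y), provinces = seq_len(P),
              ageGroups = ageGroupLabels(A), years = 2000 + seq_len(Y) - 1)
}

test_that("stage one recovers the pooled log rate in the homogeneous case", {
  pc <- constantPanel(rate = 30)
  fit <- fitStage1(pc)
  pooled <- log(sum(assay(pc, "events")) / sum(assay(pc, "personYears")) * 1e5)
  expect_equal(unname(stage1Coef(fit)[["(Intercept)"]]), pooled,
               tolerance = 1e-6)
  expect_lt(max(abs(stage1Residuals(fit))), 0.1)
})

test_that("stage one recovers covariate slopes on model-generated data", {
  P <- 6; yrs <- 2000:2009; A <- 5
  adj <- makeGeography(P, seed = 1)
  covs <- simulateCovariates(P, yrs, seed = 2)
  cfg <- flatTruthConfig(P, yrs, ageProfile = c(10, 25, 45, 80, 120))
  cfg$provinceSd <- 0.15
  cfg$covariates <- covs
  cfg$covariateCoefs <- c(wealth = 0.3)
  truth <- simulateTruth(cfg, adj, seed = 3)
  pop <- simulatePopulation(P, yrs, A = A, seed = 4)
  obs <- defaultObsConfig()
  obs$piCRS <- 1; obs$missingAge <- obs$missingSex <- 0
  obs$missingProvince <- 0; obs$dupProb <- 0
  reg <- simulateRegistry(truth, pop, obs, seed = 5)
  agg <- quietly(aggregateCounts(reg$crs, pop, A = A))
  fit <- fitStage1(agg, covs)
  est <- stage1Coef(fit)[["wealth"]]
  se <- sqrt(stage1Vcov(fit)["wealth", "wealth"])
  expect_lt(abs(est - 0.3), 3 * se)
})

test_that("random intercepts follow a relabelling of the provinces", {
  w <- smallWorld(seed = 21, P = 4, years = 2000:2004)
  agg <- quietly(aggregateCounts(deduplicate(w$reg$crs, by = "id"),
                                 w$pop, A = w$A))
  fit <- fitStage1(agg)
  ## relabel provinces 1..4 -> 4,3,2,1 by permuting panel rows
  perm <- 4:1
  ev <- assay(agg, "events"); py <- assay(agg, "personYears")
  rd <- rowData(agg)
  ord <- order(match(rd$province, perm), rd$ageIndex)
  agg2 <- PanelCounts(ev[ord, ], py[ord, ], provinces = 1:4,
                      ageGroups = ageGroupLabels(w$A),
                      years = w$years)
  fit2 <- fitStage1(agg2)
  expect_equal(unname(stage1Ranef(fit2)), unname(stage1Ranef(fit)[perm]),
               tolerance = 1e-4)
})

test_that("degenerate kernels reduce to self-weights or province pooling", {
  adj <- makeGeography(3, seed = 1)
  wSelf <- buildWeights(adj, list(lambda = 0, omega = Inf, zeta = 1e-9),
                        A = 3, years = 2000:2002)
  expect_equal(pairWeight(wSelf, c(1, 1, 1), c(1, 1, 1)), 1)
  expect_equal(pairWeight(wSelf, c(1, 1, 1), c(2, 1, 1)), 0)
  eps <- array(rnorm(27), dim = c(3, 3, 3))
  expect_equal(smoothResiduals(eps, wSelf), eps, tolerance = 1e-8)

  wPool <- buildWeights(adj, list(lambda = 0, omega = 0, zeta = 1),
                        A = 4, years = 2000:2004)
  expect_equal(pairWeight(wPool, c(2, 1, 1), c(2, 3, 4)), 1 / (4 * 5))
  expect_equal(pairWeight(wPool, c(2, 1, 1), c(1, 3, 4)), 0)
})

test_that("kernel weights on a 3-province chain match brute-force evaluation", {
  adj <- matrix(0, 3, 3)
  adj[1, 2] <- adj[2, 1] <- adj[2, 3] <- adj[3, 2] <- 1
  lambda <- 0.5; omega <- 0.3; zeta <- 0.6
  A <- 2; years <- 2000:2001
  w <- buildWeights(adj, list(lambda = lambda, omega = omega, zeta = zeta),
                    A = A, years = years)
  deg <- c(1, 2, 1)
  ws <- function(p, q) {
    if (p == q) 1 else if (adj[p, q] == 1) lambda / deg[p] else 0
  }
  for (target in list(c(1, 1, 1), c(2, 2, 2), c(3, 1, 2))) {
    total <- 0
    for (p in 1:3) for (a in 1:2) for (y in 1:2) {
      hand <- ws(target[1], p) * exp(-omega * abs(target[2] - a)) *
        zeta^abs(target[3] - y)
      total <- total + hand
    }
    for (p in 1:3) for (a in 1:2) for (y in 1:2) {
      hand <- ws(target[1], p) * exp(-omega * abs(target[2] - a)) *
        zeta^abs(target[3] - y)
      expect_equal(pairWeight(w, target, c(p, a, y)), hand / total,
                   tolerance = 1e-12)
    }
  }
})

test_that("smoothing preserves constants and matches a triple-loop oracle", {
  adj <- makeGeography(2, seed = 1)
  w <- buildWeights(adj, A = 3, years = 2000:2002)

  const <- array(2.5, dim = c(2, 3, 3))
  expect_equal(smoothResiduals(const, w), const, tolerance = 1e-10)

  set.seed(1)
  eps <- array(rnorm(18), dim = c(2, 3, 3))
  prec <- array(runif(18, 0.5, 4), dim = c(2, 3, 3))
  oracle <- array(0, dim = dim(eps))
  for (p in 1:2) for (a in 1:3) for (y in 1:3) {
    num <- 0; den <- 0
    for (pp in 1:2) for (aa in 1:3) for (yy in 1:3) {
      kern <- w@space[p, pp] * w@age[a, aa] * w@time[y, yy]
      num <- num + kern * prec[pp, aa, yy] * eps[pp, aa, yy]
      den <- den + kern * prec[pp, aa, yy]
    }
    oracle[p, a, y] <- num / den
  }
  expect_equal(smoothResiduals(eps, w, precision = prec), oracle,
               tolerance = 1e-12)

  uniform <- array(0, dim = dim(eps))
  for (p in 1:2) for (a in 1:3) for (y in 1:3) {
    num <- 0; den <- 0
    for (pp in 1:2) for (aa in 1:3) for (yy in 1:3) {
      kern <- w@space[p, pp] * w@age[a, aa] * w@time[y, yy]
      num <- num + kern * eps[pp, aa, yy]
      den <- den + kern
    }
    uniform[p, a, y] <- num / den
  }
  expect_equal(smoothResiduals(eps, w), uniform, tolerance = 1e-12)
})

test_that("smoothing rows sum to one as a linear operator", {
  adj <- makeGeography(4, seed = 2)
  w <- buildWeights(adj, A = 5, years = 2000:2006)
  ones <- array(1, dim = c(4, 5, 7))
  expect_equal(smoothResiduals(ones, w), ones, tolerance = 1e-10)
  ## linearity
  set.seed(2)
  e1 <- array(rnorm(140), dim = c(4, 5, 7))
  e2 <- array(rnorm(140), dim = c(4, 5, 7))
  expect_equal(smoothResiduals(e1 + 2 * e2, w),
               smoothResiduals(e1, w) + 2 * smoothResiduals(e2, w),
               tolerance = 1e-10)
})

test_that("invalid smoothing parameters are rejected and disconnection warns", {
  adj <- makeGeography(3, seed = 1)
  expect_error(buildWeights(adj, list(lambda = 1.2, omega = 1, zeta = 0.5),
                            A = 2, years = 2000:2001), "lambda")
  expect_error(buildWeights(adj, list(lambda = 0.2, omega = -1, zeta = 0.5),
                            A = 2, years = 2000:2001), "omega")
  expect_error(buildWeights(adj, list(lambda = 0.2, omega = 1, zeta = 0),
                            A = 2, years = 2000:2001), "zeta")
  disc <- matrix(0, 3, 3)
  expect_warning(buildWeights(disc, A = 2, years = 2000:2001),
                 "not connected")
})

test_that("zero fixed-effect covariance yields degenerate draws", {
  pc <- constantPanel(rate = 40, P = 2, A = 2, Y = 3)
  fit <- fitStage1(pc)
  fit@vcov[] <- 0
  w <- buildWeights(makeGeography(2, 1), A = 2, years = 2000:2002)
  cube <- sampleDraws(fit, w, nDraws = 150, seed = 4,
                      posteriorNoise = FALSE)
  pt <- as.vector(RegistryBurden:::.arrayToMatrix(cube@point))
  for (d in c(1, 75, 150))
    expect_equal(unname(rateDraws(cube)[d, ]), pt, tolerance = 1e-12)
})

test_that("draws are reproducible under a fixed seed", {
  pc <- constantPanel(rate = 40, P = 2, A = 2, Y = 3)
  fit <- fitStage1(pc)
  w <- buildWeights(makeGeography(2, 1), A = 2, years = 2000:2002)
  c1 <- sampleDraws(fit, w, nDraws = 120, seed = 9)
  c2 <- sampleDraws(fit, w, nDraws = 120, seed = 9)
  expect_identical(rateDraws(c1), rateDraws(c2))
})

test_that("scalar draws centre on the stratum's own data and damp parameter noise", {
  ## single province / age / year with a deliberately wrong stage-one
  ## coefficient: the empirical-Bayes smoothing adjustment must pull every
  ## draw back towards the observed rate, so the draw distribution is far
  ## tighter than the parameter draws and centred near the data
  mk1 <- function(v) array(v, dim = c(1, 1, 1))
  sigma <- 0.3
  fit <- new("Stage1Fit",
             coef = c(`(Intercept)` = log(20)),
             vcov = matrix(sigma^2, 1, 1),
             ranef = c(`1` = 0),
             design = matrix(1, 1, 1), ranefIndex = 1L,
             fitted = mk1(log(20)), logObserved = mk1(log(30.5)),
             residuals = mk1(log(30.5 / 20.5)),
             events = mk1(30), personYears = mk1(1e5),
             provinces = 1L, ageGroups = "15-19", years = 2000L)
  w <- buildWeights(matrix(0, 1, 1), A = 1, years = 2000)
  n <- 1000
  cube <- suppressWarnings(sampleDraws(fit, w, nDraws = n, seed = 7,
                                       posteriorNoise = FALSE))
  lr <- log(rateDraws(cube)[, 1])
  expect_lt(abs(mean(lr) - log(30)), 0.15)   # near the observed rate, not 20
  expect_lt(sd(lr), sigma / 2)               # data-anchoring damps the noise
  expect_gt(sd(lr), 0)
})

test_that("uncertainty intervals follow the draw percentiles", {
  pc <- constantPanel(rate = 25, P = 2, A = 1, Y = 2)
  fit <- fitStage1(pc)
  w <- buildWeights(makeGeography(2, 1), A = 1, years = 2000:2001)

  cube <- sampleDraws(fit, w, nDraws = 200, seed = 1,
                      posteriorNoise = FALSE)
  cube@draws <- matrix(7, 200, ncol(cube@draws))
  cube@point <- array(7, dim = dim(cube@point))
  ui <- uncertaintyInterval(cube)
  expect_equal(unique(as.vector(assay(ui, "lower"))), 7)
  expect_equal(unique(as.vector(assay(ui, "upper"))), 7)

  set.seed(3)
  z <- rnorm(20000)   # the tail quantile needs many draws for a 5% check
  cube@draws <- matrix(exp(z), 20000, ncol(cube@draws))
  cube@point <- array(1, dim = dim(cube@point))
  ui <- uncertaintyInterval(cube)
  expect_equal(as.vector(assay(ui, "lower"))[1], exp(-1.96), tolerance = 0.05)
  expect_equal(as.vector(assay(ui, "upper"))[1], exp(1.96), tolerance = 0.05)

  cube@draws <- cube@draws[1:50, , drop = FALSE]
  expect_error(uncertaintyInterval(cube), "100 draws")
})

test_that("uncertainty bounds always bracket the point estimate", {
  w0 <- smallWorld(seed = 22, P = 3, years = 2000:2005)
  agg <- quietly(aggregateCounts(deduplicate(w0$reg$crs, by = "id"),
                                 w0$pop, A = w0$A))
  est <- estimateRates(agg, adjacency = w0$adj, nDraws = 150, seed = 2)
  expect_true(all(assay(est$surface, "lower") <=
                    assay(est$surface, "rate") + 1e-9))
  expect_true(all(assay(est$surface, "rate") <=
                    assay(est$surface, "upper") + 1e-9))
})
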