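## shared fixtures: small synthetic worlds built in code

quietly <- function(expr) suppressWarnings(suppressMessages(expr))

## a truth configuration with all heterogeneity switched off
flatTruthConfig <- function(P, years, ageProfile = c(5, 10, 20, 40)) {
  cfg <- defaultTruthConfig(P, years, A = length(ageProfile))
  cfg$ageProfile <- ageProfile
  cfg$slope <- 0
  cfg$slopeSd <- 0
  cfg$provinceSd <- 0
  cfg$spatialScale <- 0
  cfg$ageDeviationSd <- 0
  cfg
}

## small registry world used across prep tests
smallWorld <- function(seed = 1, P = 3, years = 2000:2004, A = 4,
                       obs = defaultObsConfig()) {
  adj <- makeGeography(P, seed = seed)
  cfg <- defaultTruthConfig(P, years, A = A)
  cfg$ageProfile <- c(8, 20, 45, 90)[seq_len(A)]
  truth <- simulateTruth(cfg, adj, seed = seed)
  pop <- simulatePopulation(P, years, A = A, seed = seed)
  reg <- simulateRegistry(truth, pop, obs, seed = seed + 100)
  list(adj = adj, truth = truth, pop = pop, reg = reg, P = P,
       years = years, A = A)
}

## registry data.frame built by hand
handRegistry <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(record_id = r[[1]], source = r[[2]], cause = r[[3]],
               age = r[[4]], sex = r[[5]], province = r[[6]], year = r[[7]],
               stringsAsFactors = FALSE)))
}
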