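## End-to-end orchestration: synthetic data -> registry preparation ->
## two-stage rate model -> cause fractions -> burden metrics ->
## decomposition -> age-period-cohort analysis, with tabular outputs and a
## reproducibility manifest.

.pipelineDefaults <- function() {
  list(
    seed = 1,
    nProvinces = 6,
    years = 2000:2011,
    truth = list(),        # overrides for defaultTruthConfig()
    obs = list(),          # overrides for defaultObsConfig()
    prep = list(m = 5),
    smoothing = list(lambda = 0.3, omega = 0.7, zeta = 0.8),
    draws = list(n = 1000),
    drsCompleteness = 1,   # external completeness applied to death counts
    standardYear = NULL,   # default: last year
    outdir = NULL)
}

#' Validate a pipeline configuration
#'
#' Fills defaults and rejects unknown keys before any stage runs.
#'
#' @param config named list (or path to a YAML file) of settings; see
#'   Details in [runPipeline()].
#' @return validated configuration list.
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- .pipelineDefaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(defaults, config)
  if (length(out$years) < 3) stop("need at least 3 years")
  if (out$nProvinces < 2) stop("need at least 2 provinces")
  out
}

.stageLog <- function(manifest, stage, t0) {
  elapsed <- as.numeric(proc.time()["elapsed"]) - t0
  message(sprintf("[%s] done in %.1fs", stage, elapsed))
  manifest$stages[[stage]] <- round(elapsed, 2)
  manifest
}

#' Run the full estimation pipeline on synthetic registry data
#'
#' Generates registry data with known ground truth, prepares it
#' (deduplication, multiple imputation, completeness correction), fits the
#' two-stage spatio-temporal model for incidence and mortality, allocates
#' cause fractions when extra causes are configured, computes
#' age-standardized burden metrics with uncertainty intervals, decomposes
#' the change in case counts and fits the age-period-cohort intrinsic
#' estimator.  When `config$outdir` is set, writes a per-location summary
#' table, the full rate surfaces, the decomposition JSON, the APC effects
#' CSV and a run manifest.
#'
#' @param config list or YAML path accepted by [validateConfig()].
#' @return (invisibly) list with all intermediate and final objects.
#' @export
runPipeline <- function(config = list()) {
  cfg <- validateConfig(config)
  seed <- cfg$seed
  years <- cfg$years
  P <- cfg$nProvinces
  manifest <- list(seed = seed, config = cfg[setdiff(names(cfg), "outdir")],
                   package = as.character(utils::packageVersion("RegistryBurden")),
                   stages = list(), warnings = character())
  noteWarning <- function(w) {
    manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  ## --- simulate -----------------------------------------------------------
  t0 <- as.numeric(proc.time()["elapsed"])
  adj <- makeGeography(P, seed = seed)
  tcfg <- utils::modifyList(defaultTruthConfig(P, years), cfg$truth)
  truth <- simulateTruth(tcfg, adj, seed = seed + 1)
  A <- length(tcfg$ageProfile)
  population <- simulatePopulation(P, years, A = A, seed = seed + 2)
  covariates <- simulateCovariates(P, years, seed = seed + 3)
  lifeTable <- simulateLifeTable(A)
  obs <- utils::modifyList(defaultObsConfig(), cfg$obs)
  reg <- simulateRegistry(truth, population, obs, seed = seed + 4)
  manifest <- .stageLog(manifest, "simulate", t0)

  ## --- prep ---------------------------------------------------------------
  t0 <- as.numeric(proc.time()["elapsed"])
  ## id-based dedup only: the coarse demographic key merges distinct
  ## coincident cases at national densities and would bias the
  ## capture-recapture counts downward
  crs <- deduplicate(reg$crs, by = "id")
  ssocr <- deduplicate(reg$ssocr, by = "id")
  drs <- deduplicate(reg$drs, by = "id")
  completeness <- withCallingHandlers(
    estimateCompleteness(crs[crs$cause == "breast", ],
                         ssocr[ssocr$cause == "breast", ]),
    warning = noteWarning)
  m <- cfg$prep$m
  crsImp <- imputeMissing(crs, m = m, seed = seed + 5)
  drsImp <- imputeMissing(drs, m = m, seed = seed + 6)

  aggCause <- function(tables, cause) {
    panels <- lapply(tables, function(tb)
      suppressWarnings(aggregateCounts(tb[tb$cause %in% cause, ],
                                       population, A = A)))
    poolPanels(panels)
  }
  causes <- c("breast", names(obs$otherCauses))
  incAll <- aggCause(crsImp, causes)
  mortAll <- aggCause(drsImp, causes)

  ## cause fractions: allocate the all-cause envelope when extra causes
  ## are present, otherwise the envelope is already cause-specific
  if (length(causes) > 1) {
    longCounts <- function(tables) {
      do.call(rbind, lapply(causes, function(cs) {
        p <- aggCause(tables, cs)
        rd <- rowData(p)
        data.frame(province = rep(rd$province, ncol(p)),
                   age_index = rep(rd$ageIndex, ncol(p)),
                   year = rep(colData(p)$year, each = nrow(p)),
                   cause = cs, count = as.vector(assay(p, "events")))
      }))
    }
    cfModelInc <- fitCauseFractions(longCounts(crsImp))
    allocInc <- applyToEnvelope(cfModelInc, incAll)
    inc <- incAll
    assay(inc, "events", withDimnames = FALSE) <- matrix(
      allocInc$count[allocInc$cause == "breast"], nrow(incAll), ncol(incAll))
    cfModelMort <- fitCauseFractions(longCounts(drsImp))
    allocMort <- applyToEnvelope(cfModelMort, mortAll)
    mort <- mortAll
    assay(mort, "events", withDimnames = FALSE) <- matrix(
      allocMort$count[allocMort$cause == "breast"], nrow(mortAll),
      ncol(mortAll))
  } else {
    cfModelInc <- NULL
    inc <- incAll
    mort <- mortAll
  }

  inc <- withCallingHandlers(correctCounts(inc, completeness),
                             warning = noteWarning)
  mort <- correctCounts(mort, cfg$drsCompleteness)
  manifest <- .stageLog(manifest, "prep", t0)

  ## --- two-stage model ----------------------------------------------------
  t0 <- as.numeric(proc.time()["elapsed"])
  estInc <- estimateRates(inc, covariates, adj, params = cfg$smoothing,
                          nDraws = cfg$draws$n, seed = seed + 7)
  estMort <- estimateRates(mort, covariates, adj, params = cfg$smoothing,
                           nDraws = cfg$draws$n, seed = seed + 8)
  manifest <- .stageLog(manifest, "fit", t0)

  ## --- metrics ------------------------------------------------------------
  t0 <- as.numeric(proc.time()["elapsed"])
  stdYear <- cfg$standardYear %||% max(years)
  std <- standardPopulation(population, stdYear)
  popM <- .populationMatrix(population, seq_len(P), A, years)

  locSeries <- function(cube, province) {
    standardizedSeries(cube, std, province = province,
                       population = population)
  }
  locations <- c(list(National = NULL), stats::setNames(as.list(seq_len(P)),
                                                        paste0("Province", seq_len(P))))
  asir <- lapply(locations, locSeries, cube = estInc$cube)
  asdr <- lapply(locations, locSeries, cube = estMort$cube)

  ## estimated counts: rate x person-years / 1e5
  countsFrom <- function(est) {
    .arrayToMatrix(est$cube@point) * popM / 1e5
  }
  incCounts <- countsFrom(estInc)
  mortCounts <- countsFrom(estMort)

  ## YLL per stratum, then rates per 100,000 and their standardization
  le <- lifeTable$life_expectancy[rowData(inc)$ageIndex]
  yllCounts <- mortCounts * le
  yllRates <- yllCounts / popM * 1e5
  asyr <- lapply(locations, function(pv) {
    cube <- estMort$cube
    ## reuse the mortality draws scaled by life expectancy: linear in rate
    scaled <- cube
    scaled@draws <- cube@draws *
      rep(rep(le[seq_len(A)], P), length(years))[col(cube@draws)]
    scaled@point <- cube@point * array(rep(le[seq_len(A)], each = P),
                                       dim = dim(cube@point))
    standardizedSeries(scaled, std, province = pv, population = population)
  })

  apcSafe <- function(yrs, vals) {
    if (length(yrs) >= 3 && all(vals > 0)) computeAPC(yrs, vals) else NA_real_
  }
  deathYears <- years[seq_len(max(length(years) - 1, 3))]
  summaryRows <- lapply(names(locations), function(nm) {
    ai <- asir[[nm]]; ad <- asdr[[nm]]; ay <- asyr[[nm]]
    adU <- ad[ad$year %in% deathYears, ]; ayU <- ay[ay$year %in% deathYears, ]
    rows <- if (is.null(locations[[nm]])) seq_len(nrow(incCounts)) else
      which(rowData(inc)$province == locations[[nm]])
    data.frame(
      location = nm,
      cases_start = sum(incCounts[rows, 1]),
      cases_end = sum(incCounts[rows, length(years)]),
      deaths_end = sum(mortCounts[rows, length(deathYears)]),
      asir_start = ai$rate[1], asir_end = ai$rate[nrow(ai)],
      asir_lower_end = ai$lower[nrow(ai)], asir_upper_end = ai$upper[nrow(ai)],
      apc_incidence = apcSafe(ai$year, ai$rate),
      asdr_start = ad$rate[1], asdr_end = adU$rate[nrow(adU)],
      apc_death = apcSafe(adU$year, adU$rate),
      asyr_start = ay$rate[1], asyr_end = ayU$rate[nrow(ayU)],
      apc_yll = apcSafe(ayU$year, ayU$rate),
      mir_end = computeMIR(adU$rate[nrow(adU)], ai$rate[nrow(ai)]))
  })
  summaryTable <- do.call(rbind, summaryRows)
  manifest <- .stageLog(manifest, "metrics", t0)

  ## --- decomposition ------------------------------------------------------
  t0 <- as.numeric(proc.time()["elapsed"])
  natRate <- function(yIdx) {
    ev <- rowsum(incCounts[, yIdx], rowData(inc)$ageIndex)
    py <- rowsum(popM[, yIdx], rowData(inc)$ageIndex)
    as.numeric(ev / py * 1e5)
  }
  popByAge <- function(yIdx)
    as.numeric(rowsum(popM[, yIdx], rowData(inc)$ageIndex))
  decomp <- decomposeChange(natRate(1), popByAge(1),
                            popByAge(length(years)),
                            casesFinal = sum(incCounts[, length(years)]))
  manifest <- .stageLog(manifest, "decompose", t0)

  ## --- age-period-cohort --------------------------------------------------
  t0 <- as.numeric(proc.time()["elapsed"])
  lex <- suppressMessages(lexisFromPanel(inc))
  apc <- if (ncol(lex@events) >= 2) {
    fitIE(lexisTable(round(lex@events), lex@exposure, lex@ageWidth,
                     lex@periodWidth, lex@ageLabels, lex@periodLabels))
  } else NULL
  manifest <- .stageLog(manifest, "apc", t0)

  bundle <- list(config = cfg, adjacency = adj, truth = truth,
                 population = population, covariates = covariates,
                 lifeTable = lifeTable, registries = reg,
                 completeness = completeness,
                 incidenceCounts = inc, mortalityCounts = mort,
                 causeFractionModel = cfModelInc,
                 incidence = estInc, mortality = estMort,
                 asir = asir, asdr = asdr, asyr = asyr,
                 summaryTable = summaryTable, decomposition = decomp,
                 apc = apc, manifest = manifest)

  if (!is.null(cfg$outdir)) .writeBundle(bundle, cfg$outdir)
  invisible(bundle)
}

.surfaceFrame <- function(surface) {
  rd <- rowData(surface)
  years <- colData(surface)$year
  data.frame(
    province = rep(rd$province, length(years)),
    age_group = rep(rd$ageGroup, length(years)),
    year = rep(years, each = nrow(surface)),
    rate = as.vector(assay(surface, "rate")),
    lower = as.vector(assay(surface, "lower")),
    upper = as.vector(assay(surface, "upper")))
}

.writeBundle <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  num <- function(df) {
    isNum <- vapply(df, is.numeric, logical(1))
    df[isNum] <- lapply(df[isNum], function(x) signif(x, 10))
    df
  }
  utils::write.csv(num(bundle$summaryTable),
                   file.path(outdir, "summary_table.csv"), row.names = FALSE)
  utils::write.csv(num(.surfaceFrame(bundle$incidence$surface)),
                   file.path(outdir, "incidence_surface.csv"),
                   row.names = FALSE)
  utils::write.csv(num(.surfaceFrame(bundle$mortality$surface)),
                   file.path(outdir, "mortality_surface.csv"),
                   row.names = FALSE)
  utils::write.csv(num(bundle$completeness),
                   file.path(outdir, "completeness.csv"), row.names = FALSE)
  jsonlite::write_json(decompositionTable(bundle$decomposition),
                       file.path(outdir, "decomposition.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$apc)) {
    eff <- bundle$apc
    apcDf <- rbind(
      data.frame(dimension = "age", level = names(eff@age),
                 effect = as.numeric(eff@age), rr = exp(as.numeric(eff@age))),
      data.frame(dimension = "period", level = names(eff@period),
                 effect = as.numeric(eff@period),
                 rr = exp(as.numeric(eff@period))),
      data.frame(dimension = "cohort", level = names(eff@cohort),
                 effect = as.numeric(eff@cohort),
                 rr = exp(as.numeric(eff@cohort))))
    utils::write.csv(num(apcDf), file.path(outdir, "apc_effects.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(bundle$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
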