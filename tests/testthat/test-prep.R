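test_that("deduplication drops id-normalised and key-identical rows only", {
  clean <- handRegistry(
    list("A1", "CRS", "breast", 40, "female", 1, 2000),
    list("A2", "CRS", "breast", 51, "female", 2, 2001))
  expect_equal(nrow(deduplicate(clean)), 2)
  expect_equal(attr(deduplicate(clean), "removed"), 0)

  withDups <- rbind(clean,
    handRegistry(list(" a1 ", "CRS", "breast", 40, "female", 1, 2000),  # id variant
                 list("B9", "CRS", "breast", 51, "female", 2, 2001)))   # key clone
  out <- quietly(deduplicate(withDups))
  expect_equal(nrow(out), 2)
  expect_equal(out$record_id, c("A1", "A2"))
})

test_that("deduplication is idempotent", {
  w <- smallWorld(seed = 5)
  once <- quietly(deduplicate(w$reg$crs))
  twice <- quietly(deduplicate(once))
  expect_identical(once$record_id, twice$record_id)
  expect_equal(attr(twice, "removed"), 0)
})

test_that("planted generator duplicates are recalled almost completely", {
  obs <- defaultObsConfig()
  obs$dupProb <- 0.2
  w <- smallWorld(seed = 7, P = 4, years = 2000:2005, obs = obs)
  crs <- w$reg$crs
  planted <- sum(duplicated(crs$truth_link))
  out <- quietly(deduplicate(crs))
  surviving <- sum(duplicated(out$truth_link))
  expect_gte((planted - surviving) / planted, 0.95)
})

test_that("imputation reproduces complete tables and degenerate donor pools", {
  complete <- handRegistry(
    list("A1", "CRS", "breast", 40, "female", 3, 2000),
    list("A2", "CRS", "breast", 50, "female", 3, 2000))
  out <- imputeMissing(complete, m = 3, seed = 1)
  expect_length(out, 3)
  for (tb in out) expect_identical(tb, complete)

  withMiss <- rbind(complete,
    handRegistry(list("A3", "CRS", "breast", 60, "female", NA, 2000)))
  out <- imputeMissing(withMiss, m = 4, seed = 2)
  for (tb in out) expect_equal(tb$province[3], 3)
})

test_that("imputed age distribution tracks the donor distribution", {
  set.seed(10)
  n <- 1500
  ages <- sample(c(20, 30, 40, 50, 60), n, replace = TRUE,
                 prob = c(0.1, 0.2, 0.4, 0.2, 0.1))
  tb <- data.frame(record_id = paste0("R", seq_len(n)), source = "CRS",
                   cause = "breast", age = ages, sex = "female",
                   province = 1, year = 2000)
  tb$age[seq_len(0.2 * n)] <- NA
  donors <- table(factor(tb$age[!is.na(tb$age)], levels = c(20, 30, 40, 50, 60)))
  donorP <- donors / sum(donors)
  out <- imputeMissing(tb, m = 20, seed = 3)
  imputed <- unlist(lapply(out, function(x) x$age[seq_len(0.2 * n)]))
  impP <- table(factor(imputed, levels = c(20, 30, 40, 50, 60))) /
    length(imputed)
  tv <- 0.5 * sum(abs(as.numeric(impP) - as.numeric(donorP)))
  expect_lt(tv, 0.1)
})

test_that("imputation fails loudly without donors and is seed-deterministic", {
  allMiss <- handRegistry(list("A1", "CRS", "breast", NA, "female", NA, 2000))
  expect_error(imputeMissing(allMiss, m = 1, seed = 1), "donor")
  w <- smallWorld(seed = 9)
  a <- imputeMissing(w$reg$crs, m = 2, seed = 42)
  b <- imputeMissing(w$reg$crs, m = 2, seed = 42)
  expect_identical(a, b)
})

test_that("capture-recapture completeness matches hand-computed fractions", {
  mk <- function(ids, province = 1, year = 2000, source = "CRS")
    data.frame(record_id = ids, source = source, cause = "breast", age = 50,
               sex = "female", province = province, year = year)
  primary <- mk(paste0("P", 1:80))
  reference <- mk(c(paste0("P", 1:72), paste0("X", 1:18)), source = "SSOCR")
  ct <- estimateCompleteness(primary, reference)
  expect_equal(ct$completeness, 0.8)            # 72 / 90
  expect_equal(ct$n1, 80); expect_equal(ct$n2, 90); expect_equal(ct$m, 72)

  subsetRef <- mk(paste0("P", 1:30), source = "SSOCR")
  expect_equal(estimateCompleteness(primary, subsetRef)$completeness, 1)
})

test_that("strata absent from the reference source are flagged, not one", {
  mk <- function(ids, province, source)
    data.frame(record_id = ids, source = source, cause = "breast", age = 50,
               sex = "female", province = province, year = 2000)
  primary <- rbind(mk(paste0("A", 1:10), 1, "CRS"), mk(paste0("B", 1:5), 2, "CRS"))
  reference <- mk(paste0("A", 1:8), 1, "SSOCR")
  ct <- estimateCompleteness(primary, reference)
  expect_true(ct$flagged[ct$province == 2])
  expect_true(is.na(ct$completeness[ct$province == 2]))
})

test_that("impossible match counts raise a data-integrity error", {
  mk <- function(ids, source)
    data.frame(record_id = ids, source = source, cause = "breast", age = 50,
               sex = "female", province = 1, year = 2000)
  primary <- mk("A1", "CRS")
  reference <- mk(c("A1", "a1 "), "SSOCR")   # both normalise onto A1
  expect_error(estimateCompleteness(primary, reference), "integrity")
})

test_that("completeness estimates recover the registration probability", {
  obs <- defaultObsConfig()
  obs$piCRS <- 0.7
  w <- smallWorld(seed = 11, P = 4, years = 2000:2005, obs = obs)
  crs <- quietly(deduplicate(w$reg$crs, by = "id"))
  ssocr <- quietly(deduplicate(w$reg$ssocr, by = "id"))
  ct <- estimateCompleteness(crs, ssocr)
  ok <- !ct$flagged & ct$n2 >= 30
  z <- (ct$completeness[ok] - 0.7) / sqrt(0.7 * 0.3 / ct$n2[ok])
  expect_true(all(abs(z) < 3.5))
  pooled <- sum(ct$m) / sum(ct$n2)
  expect_lt(abs(pooled - 0.7), 3 * sqrt(0.7 * 0.3 / sum(ct$n2)))
})

test_that("count correction inverts completeness and validates inputs", {
  pc <- PanelCounts(matrix(50, 4, 2), matrix(1e5, 4, 2), provinces = 1:2,
                    ageGroups = ageGroupLabels(2), years = 2000:2001)
  expect_equal(assay(correctCounts(pc, 1), "events"), assay(pc, "events"))
  half <- correctCounts(pc, 0.5)
  expect_equal(unname(assay(half, "events")), matrix(100, 4, 2))
  expect_error(correctCounts(pc, 0), "positive")
  ct <- data.frame(province = c(1, 2), year = 2000,
                   completeness = c(0.5, -0.1), n1 = 1, n2 = 1, m = 1,
                   flagged = FALSE)
  expect_error(correctCounts(pc, ct), "positive")
})

test_that("correcting aggregated counts with completeness one is the identity", {
  w <- smallWorld(seed = 12)
  agg <- quietly(aggregateCounts(w$reg$crs, w$pop, A = w$A))
  expect_equal(assay(correctCounts(agg, 1), "events"), assay(agg, "events"))
})

test_that("corrected totals recover the true totals end to end", {
  obs <- defaultObsConfig()
  obs$piCRS <- 0.7
  obs$missingAge <- obs$missingSex <- obs$missingProvince <- 0
  obs$dupProb <- 0
  w <- smallWorld(seed = 13, P = 4, years = 2000:2006, obs = obs)
  crs <- quietly(deduplicate(w$reg$crs, by = "id"))
  ssocr <- quietly(deduplicate(w$reg$ssocr, by = "id"))
  ct <- estimateCompleteness(crs, ssocr)
  agg <- quietly(aggregateCounts(crs, w$pop, A = w$A))
  corrected <- quietly(correctCounts(agg, ct))
  trueTotal <- sum(assay(w$reg$trueCases, "events"))
  estTotal <- sum(assay(corrected, "events"))
  expect_lt(abs(estTotal - trueTotal), 3 * sqrt(trueTotal))
})

test_that("province remapping conserves rows and composes with its inverse", {
  w <- smallWorld(seed = 14)
  tb <- w$reg$crs
  idMap <- data.frame(legacy = 1:3, target = 1:3)
  expect_identical(remapProvinces(tb, idMap)$province, tb$province)

  mergeMap <- data.frame(legacy = 1:3, target = c(1, 1, 2))
  merged <- remapProvinces(tb, mergeMap)
  expect_equal(nrow(merged), nrow(tb))
  expect_equal(sum(merged$province == 1, na.rm = TRUE),
               sum(tb$province %in% 1:2, na.rm = TRUE))

  perm <- data.frame(legacy = 1:3, target = c(3, 1, 2))
  inv <- data.frame(legacy = c(3, 1, 2), target = 1:3)
  roundTrip <- remapProvinces(remapProvinces(tb, perm), inv)
  expect_identical(roundTrip$province, tb$province)

  expect_error(remapProvinces(tb, data.frame(legacy = 1, target = 1)),
               "unmapped")
})

test_that("aggregation bins ages, conserves rows and rejects impossible ages", {
  pop <- simulatePopulation(2, 2000:2001, A = 15, seed = 1)
  empty <- handRegistry(list("Z", "CRS", "breast", 40, "female", 1, 2000))[0, ]
  agg0 <- aggregateCounts(empty, pop)
  expect_equal(sum(assay(agg0, "events")), 0)

  one <- handRegistry(list("A1", "CRS", "breast", 40, "female", 1, 2000))
  agg1 <- aggregateCounts(one, pop)
  rd <- rowData(agg1)
  hit <- which(assay(agg1, "events")[, "2000"] == 1)
  expect_length(hit, 1)
  expect_equal(as.character(rd$ageGroup[hit]), "40-44")

  bad <- rbind(one, handRegistry(list("A2", "CRS", "breast", 130, "female",
                                      1, 2000)))
  expect_warning(agg2 <- aggregateCounts(bad, pop), "rejected")
  expect_equal(attr(agg2, "rejected"), 1)
  expect_equal(sum(assay(agg2, "events")), 1)
})

test_that("aggregation conserves record totals on generator output", {
  obs <- defaultObsConfig()
  obs$missingAge <- obs$missingSex <- obs$missingProvince <- 0
  w <- smallWorld(seed = 15, obs = obs)
  agg <- quietly(aggregateCounts(w$reg$crs, w$pop, A = w$A))
  expect_equal(sum(assay(agg, "events")), nrow(w$reg$crs))
})

test_that("pooling multiply-imputed panels averages events cell-wise", {
  w <- smallWorld(seed = 16)
  imp <- imputeMissing(quietly(deduplicate(w$reg$crs, by = "id")), m = 3,
                       seed = 1)
  panels <- lapply(imp, function(tb)
    quietly(aggregateCounts(tb, w$pop, A = w$A)))
  pooled <- poolPanels(panels)
  manual <- (assay(panels[[1]], "events") + assay(panels[[2]], "events") +
               assay(panels[[3]], "events")) / 3
  expect_equal(assay(pooled, "events"), manual)
})
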