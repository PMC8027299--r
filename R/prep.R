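## Registry preparation: deduplication, hot-deck multiple imputation,
## two-source capture-recapture completeness, province remapping and
## aggregation to panel counts.

.normalizeId <- function(id) {
  tolower(gsub("[[:space:]]+", "", as.character(id)))
}

#' Remove duplicate registry rows
#'
#' Drops (keeping the first occurrence) rows whose record ids are equal
#' after whitespace/case normalisation, and rows identical on the match key
#' (source, cause, age, sex, province, year).  `NA` fields compare equal, so
#' a duplicate that lost a field the same way as its original is still
#' caught.
#'
#' At realistic registry densities the demographic key is coarse enough
#' that distinct persons collide on it; `by = "id"` restricts removal to
#' normalised-id duplicates, which is what the capture-recapture linkage
#' uses so that coincident true cases are not merged away.
#'
#' @param table a registry data.frame (see [readRegistry()]).
#' @param by `"both"` (default: id rule and key rule), `"id"` or `"key"`.
#' @return the deduplicated table; the number of removed rows is attached as
#'   attribute `removed`.
#' @export
deduplicate <- function(table, by = c("both", "id", "key")) {
  .checkRegistry(table)
  by <- match.arg(by)
  n0 <- nrow(table)
  if (by %in% c("both", "id")) {
    keep <- !duplicated(.normalizeId(table$record_id))
    table <- table[keep, , drop = FALSE]
  }
  if (by %in% c("both", "key")) {
    key <- table[, c("source", "cause", "age", "sex", "province", "year")]
    table <- table[!duplicated(key), , drop = FALSE]
  }
  rownames(table) <- NULL
  removed <- n0 - nrow(table)
  if (removed > 0)
    message(sprintf("deduplicate: removed %d duplicate row(s)", removed))
  attr(table, "removed") <- removed
  table
}

#' Hot-deck multiple imputation of missing registry fields
#'
#' Missing `age`, `sex` or `province` fields are filled by drawing a donor
#' record uniformly from the complete records of the same source and year;
#' if that pool is empty, from complete records of the same source across
#' all years.  Each of the `m` completed tables uses independent draws; the
#' whole procedure is deterministic given `seed`.
#'
#' @param table a registry data.frame.
#' @param m number of completed tables (>= 1).
#' @param seed integer seed.
#' @return list of `m` completed registry data.frames.
#' @export
imputeMissing <- function(table, m = 5, seed = 1) {
  .checkRegistry(table)
  stopifnot(m >= 1)
  fields <- c("age", "sex", "province")
  missRow <- which(rowSums(is.na(table[, fields])) > 0)
  if (!length(missRow)) return(replicate(m, table, simplify = FALSE))

  complete <- rowSums(is.na(table[, fields])) == 0
  if (!any(complete))
    stop("no complete donor records available in source ",
         paste(unique(table$source), collapse = ","))
  donorsBySY <- split(which(complete),
                      paste(table$source, table$year)[complete])
  donorsByS <- split(which(complete), table$source[complete])

  set.seed(seed)
  out <- vector("list", m)
  for (k in seq_len(m)) {
    tk <- table
    for (i in missRow) {
      pool <- donorsBySY[[paste(tk$source[i], tk$year[i])]]
      if (is.null(pool) || !length(pool))
        pool <- donorsByS[[tk$source[i]]]
      if (is.null(pool) || !length(pool))
        stop(sprintf("no complete donor records for source %s (year %s)",
                     tk$source[i], tk$year[i]))
      donor <- pool[sample.int(length(pool), 1L)]
      for (f in fields)
        if (is.na(tk[[f]][i])) tk[[f]][i] <- table[[f]][donor]
    }
    out[[k]] <- tk
  }
  out
}

#' Two-source capture-recapture completeness of a registry
#'
#' Treats the reference source as the enumeration standard: within each
#' province x year stratum, completeness of the primary source is
#' `m / n2`, where `n2` is the number of reference captures and `m` the
#' number of reference records also found in the primary source (linked by
#' normalised record id, or by `truth_link` for synthetic data inside
#' tests).  With `symmetric = TRUE` the symmetric Chandra Sekar-Deming
#' total `Nhat = n1 * n2 / m` is reported alongside; the primary source's
#' capture probability `n1 / Nhat` algebraically equals `m / n2`, so the
#' completeness column is the same — the variants differ in the implied
#' true total (reference count versus `Nhat`).
#'
#' @param primary,reference deduplicated registry data.frames.
#' @param key linkage key column, `"record_id"` (normalised) or
#'   `"truth_link"`.
#' @param symmetric use the symmetric Chandra Sekar-Deming variant.
#' @return data.frame `province, year, completeness, n1, n2, m, flagged`;
#'   strata never seen in the reference source have `NA` completeness and
#'   `flagged = TRUE`.
#' @export
estimateCompleteness <- function(primary, reference, key = "record_id",
                                 symmetric = FALSE) {
  .checkRegistry(primary); .checkRegistry(reference)
  key <- match.arg(key, c("record_id", "truth_link"))
  getKey <- function(df)
    if (key == "record_id") .normalizeId(df$record_id) else df[[key]]

  pKeys <- getKey(primary)
  rKeys <- getKey(reference)

  ## borrow the stratum of the linked reference record when the primary
  ## record lost its province: the pair refers to one true case.  The
  ## reference side is NOT back-filled from the primary: that would keep
  ## matched reference records while dropping unmatched ones with missing
  ## fields, biasing m/n2 upward.
  idx <- match(pKeys, rKeys)
  use <- is.na(primary$province) & !is.na(idx) &
    !is.na(reference$province[idx])
  primary$province[use] <- reference$province[idx[use]]

  pOK <- !is.na(primary$province)
  rOK <- !is.na(reference$province)

  strata <- unique(rbind(
    data.frame(province = primary$province[pOK], year = primary$year[pOK]),
    data.frame(province = reference$province[rOK], year = reference$year[rOK])))
  strata <- strata[order(strata$province, strata$year), , drop = FALSE]

  matched <- rKeys %in% pKeys
  res <- lapply(seq_len(nrow(strata)), function(i) {
    p <- strata$province[i]; y <- strata$year[i]
    inP <- pOK & primary$province == p & primary$year == y
    inR <- rOK & reference$province == p & reference$year == y
    n1 <- sum(inP); n2 <- sum(inR); mm <- sum(matched & inR)
    if (mm > min(n1, n2) + 0L)
      stop(sprintf("data integrity: matches (%d) exceed source counts in province %s year %s",
                   mm, p, y))
    comp <- if (n2 > 0) mm / n2 else NA_real_
    out <- data.frame(province = p, year = y, completeness = comp,
                      n1 = n1, n2 = n2, m = mm, flagged = n2 == 0)
    if (symmetric)
      out$Nhat <- if (mm > 0) n1 * n2 / mm else NA_real_
    out
  })
  do.call(rbind, res)
}

#' Inflate observed counts by estimated completeness
#'
#' Corrected events are `observed / completeness` per province x year;
#' fractional counts are permitted downstream.  Flagged strata (no
#' reference-source information) are left uncorrected with a warning.
#'
#' @param counts a \linkS4class{PanelCounts}.
#' @param completeness data.frame from [estimateCompleteness()], or a single
#'   number applied everywhere.
#' @return corrected \linkS4class{PanelCounts}.
#' @export
correctCounts <- function(counts, completeness) {
  stopifnot(is(counts, "PanelCounts"))
  ev <- assay(counts, "events")
  if (is.numeric(completeness) && length(completeness) == 1) {
    if (completeness <= 0) stop("completeness must be positive")
    factor <- matrix(completeness, nrow(ev), ncol(ev))
  } else {
    if (any(!is.na(completeness$completeness) &
              completeness$completeness <= 0))
      stop("completeness must be positive in every used stratum")
    factor <- matrix(NA_real_, nrow(ev), ncol(ev))
    for (i in seq_len(nrow(completeness))) {
      ridx <- which(rowData(counts)$province == completeness$province[i])
      cidx <- which(colData(counts)$year == completeness$year[i])
      if (length(ridx) && length(cidx))
        factor[ridx, cidx] <- completeness$completeness[i]
    }
    if (any(is.na(factor))) {
      warning("strata without completeness information left uncorrected")
      factor[is.na(factor)] <- 1
    }
  }
  assay(counts, "events") <- ev / factor
  validObject(counts)
  counts
}

#' Remap legacy province codes to the current scheme
#'
#' @param table a registry data.frame.
#' @param map data.frame with columns `legacy` and `target`; every non-`NA`
#'   province code in `table` must appear in `legacy`.
#' @return the table with `province` rewritten; row count is conserved.
#' @export
remapProvinces <- function(table, map) {
  .checkRegistry(table)
  stopifnot(all(c("legacy", "target") %in% names(map)))
  if (anyDuplicated(map$legacy))
    stop("province map assigns a legacy code to more than one target")
  idx <- match(table$province, map$legacy)
  bad <- !is.na(table$province) & is.na(idx)
  if (any(bad))
    stop("unmapped province codes: ",
         paste(sort(unique(table$province[bad])), collapse = ", "))
  table$province <- map$target[idx]
  table
}

#' Aggregate registry records to panel counts
#'
#' Bins record ages into the 5-year age-group grid (open-ended last group)
#' and counts events per province x age-group x year; person-years are taken
#' from the population table.  Rows with age outside
#' `[startAge, 120]` are rejected with a warning and counted in attribute
#' `rejected`.
#'
#' @param table a fully imputed, remapped registry data.frame.
#' @param population data.frame as from [simulatePopulation()].
#' @param A number of age groups.
#' @param startAge lower bound of the first age group.
#' @return A \linkS4class{PanelCounts}; attribute `rejected` holds the
#'   number of dropped rows.
#' @export
aggregateCounts <- function(table, population, A = 15, startAge = 15) {
  .checkRegistry(table)
  provinces <- sort(unique(population$province))
  years <- sort(unique(population$year))
  grp <- .ageToGroup(table$age, A = A, startAge = startAge)
  bad <- is.na(grp) | is.na(table$province) | !(table$year %in% years)
  nRej <- sum(bad)
  if (nRej > 0)
    warning(sprintf("aggregateCounts: rejected %d row(s) outside the grid",
                    nRej))
  tab <- table[!bad, , drop = FALSE]
  grp <- grp[!bad]
  ev <- matrix(0, length(provinces) * A, length(years))
  row <- (match(tab$province, provinces) - 1L) * A + grp
  col <- match(tab$year, years)
  for (i in seq_along(row)) ev[row[i], col[i]] <- ev[row[i], col[i]] + 1
  pc <- PanelCounts(ev, .populationMatrix(population, provinces, A, years),
                    provinces, ageGroupLabels(A, startAge), years)
  attr(pc, "rejected") <- nRej
  pc
}

#' Average event counts across multiply-imputed panels
#'
#' Pools the `m` completed-data analyses by averaging event counts cell-wise
#' (Rubin's rule for means); person-years are identical across imputations.
#'
#' @param panels list of \linkS4class{PanelCounts} on the same grid.
#' @return pooled \linkS4class{PanelCounts}.
#' @export
poolPanels <- function(panels) {
  stopifnot(length(panels) >= 1)
  ev <- Reduce(`+`, lapply(panels, assay, "events")) / length(panels)
  out <- panels[[1]]
  assay(out, "events") <- ev
  out
}
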