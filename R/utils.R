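#' Age-group labels for the analysis grid
#'
#' The analysis uses 5-year age groups from `startAge` with an open-ended
#' last group (the default grid is 15-19 ... 80-84, 85+; A = 15).
#'
#' @param A number of age groups.
#' @param startAge lower bound of the first group, in years.
#' @param width group width in years.
#' @return character vector of labels.
#' @examples
#' ageGroupLabels(15)
#' @export
ageGroupLabels <- function(A = 15, startAge = 15, width = 5) {
  lo <- startAge + width * (seq_len(A) - 1)
  if (A == 1) return(paste0(lo, "+"))
  c(paste0(lo[-A], "-", lo[-A] + width - 1), paste0(lo[A], "+"))
}

## map integer ages to 1-based age-group index; NA outside [startAge, maxAge]
.ageToGroup <- function(age, A = 15, startAge = 15, width = 5,
                        maxAge = 120) {
  idx <- floor((age - startAge) / width) + 1L
  idx[idx > A] <- A
  idx[age < startAge | age > maxAge | !is.finite(age)] <- NA_integer_
  as.integer(idx)
}

.registryCols <- c("record_id", "source", "cause", "age", "sex", "province",
                   "year")

.checkRegistry <- function(table) {
  miss <- setdiff(.registryCols, names(table))
  if (length(miss))
    stop("registry table is missing columns: ", paste(miss, collapse = ", "))
  invisible(table)
}

#' Read / write registry tables
#'
#' Registry tables are delimited text with header
#' `record_id,source,cause,age,sex,province,year` (a `truth_link` column is
#' carried through when present); missing fields are encoded as empty
#' strings.
#'
#' @param path file path.
#' @return `readRegistry()` returns a data.frame with `NA` for missing
#'   fields.
#' @export
readRegistry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  .checkRegistry(df)
}

#' @rdname readRegistry
#' @param table a registry data.frame.
#' @export
writeRegistry <- function(table, path) {
  .checkRegistry(table)
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Geometric interpolation between two endpoint values
#'
#' Builds the exact geometric (constant-growth) series through two endpoint
#' values: the trend whose log is linear in the year.  Useful for
#' reconstructing an annual series consistent with published endpoint
#' age-standardized rates.
#'
#' @param startYear,endYear endpoint years.
#' @param startValue,endValue positive endpoint values.
#' @return data.frame with columns `year` and `value` covering every year in
#'   `startYear:endYear`.
#' @examples
#' geometricInterpolation(1990, 2016, 13, 44)
#' @export
geometricInterpolation <- function(startYear, endYear, startValue, endValue) {
  stopifnot(endYear > startYear, startValue > 0, endValue > 0)
  years <- startYear:endYear
  g <- (endValue / startValue)^(1 / (endYear - startYear))
  data.frame(year = years, value = startValue * g^(years - startYear))
}

#' Published reference estimates bundled for reproduction checks
#'
#' Endpoint age-standardized rates, case counts and published annual percent
#' changes for Iranian female breast cancer at national level and for
#' selected provinces, as printed in the published national/subnational
#' burden tables.  Used to verify that the package's trend and ratio
#' arithmetic reproduces the published figures.
#'
#' @return data.frame with columns `location`, `metric`, `year_start`,
#'   `value_start`, `year_end`, `value_end`, `published_apc`.
#' @export
referenceEstimates <- function() {
  path <- system.file("extdata", "reference_estimates.csv",
                      package = "RegistryBurden", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
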