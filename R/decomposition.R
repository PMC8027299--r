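## Decomposition of the change in annual new cases between a base and a
## final year into population growth, population ageing and age-specific
## rate change, via two sequential hypothetical populations.

#' Decompose a change in case counts
#'
#' With base-year age-specific rates `r_a` (per `per` person-years), base
#' and final population age vectors `n_a`, `N_a`:
#' \itemize{
#'   \item cases_base `= sum_a r_a n_a / per`
#'   \item H1 `= (sum_a r_a n_a / sum_a n_a) * sum_a N_a / per` (base rates
#'     and base age structure scaled to the final population total)
#'   \item H2 `= sum_a r_a N_a / per` (base rates on the final population)
#' }
#' Growth is `H1 - cases_base`, ageing is `H2 - H1`, and rate change is
#' `cases_final - H2`, so the three contributions always sum exactly to the
#' total change.  `cases_final` is the observed (or estimated) final-year
#' case count, not recomputed from final-year rates.
#'
#' @param ratesBase age-specific rates in the base year, per `per`.
#' @param popBase,popFinal population by age group in the two years.
#' @param casesFinal observed annual cases in the final year.
#' @param per rate denominator (default 100,000).
#' @return A \linkS4class{DecompositionResult}.
#' @examples
#' decomposeChange(c(10, 100), c(1000, 1000), c(1000, 3000), casesFinal = 600)
#' @export
decomposeChange <- function(ratesBase, popBase, popFinal, casesFinal,
                            per = 1e5) {
  if (length(ratesBase) != length(popBase) ||
      length(popBase) != length(popFinal))
    stop("age grids of rates and populations must align")
  if (sum(popBase) <= 0 || sum(popFinal) <= 0)
    stop("total population must be positive")

  casesBase <- sum(ratesBase * popBase) / per
  structBase <- popBase / sum(popBase)
  H1 <- sum(ratesBase * structBase) * sum(popFinal) / per
  H2 <- sum(ratesBase * popFinal) / per

  dGrowth <- H1 - casesBase
  dAging <- H2 - H1
  dRate <- casesFinal - H2

  pct <- function(x) 100 * x / casesBase
  new("DecompositionResult",
      casesBase = casesBase, casesFinal = casesFinal, H1 = H1, H2 = H2,
      deltaGrowth = dGrowth, deltaAging = dAging, deltaRate = dRate,
      pctGrowth = pct(dGrowth), pctAging = pct(dAging), pctRate = pct(dRate))
}
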