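#' Valuation parameters for mortality change
#'
#' Parameters of the full-income valuation: the value-per-statistical-life
#' (VSL) to income ratio, the cut-off age splitting mortality into a young
#' and an old band, and the anchor ages whose remaining-life-expectancy
#' ratio discounts deaths in the old band.
#'
#' @param vsl_income_ratio Dimensionless VSL-to-annual-income ratio
#'   (default 160, the benefit-cost reference-case convention for
#'   cross-country work).
#' @param old_age_cutoff Age separating the young and old bands, years
#'   (default 75).
#' @param adjustment_anchor_ages Pair of ages `(old, young)`: the old-band
#'   value is scaled by `e(old)/e(young)` from a life table
#'   (default `c(80, 40)`).
#' @return Object of class `valuation_params`.
#' @export
valuation_params <- function(vsl_income_ratio = 160, old_age_cutoff = 75,
                             adjustment_anchor_ages = c(80, 40)) {
  if (vsl_income_ratio <= 0) {
    stop("`vsl_income_ratio` must be positive", call. = FALSE)
  }
  if (length(adjustment_anchor_ages) != 2L) {
    stop("`adjustment_anchor_ages` must be a pair of ages", call. = FALSE)
  }
  structure(list(vsl_income_ratio = vsl_income_ratio,
                 old_age_cutoff = old_age_cutoff,
                 adjustment_anchor_ages = as.numeric(adjustment_anchor_ages)),
            class = "valuation_params")
}

#' @export
print.valuation_params <- function(x, ...) {
  cat(sprintf("Valuation: VSL/income = %g, bands split at %g, old band x e(%g)/e(%g)\n",
              x$vsl_income_ratio, x$old_age_cutoff,
              x$adjustment_anchor_ages[1L], x$adjustment_anchor_ages[2L]))
  invisible(x)
}

#' Old-age valuation adjustment from a life table
#'
#' The ratio of remaining life expectancies at the anchor ages,
#' `e(80)/e(40)` by default: deaths in the old band represent fewer lost
#' life years, so their VSL value is discounted by this factor.
#'
#' @param lt A [life_table()] with boundaries at both anchor ages.
#' @param anchor_ages Pair `(old, young)`.
#' @return A scalar in `(0, 1)` for any table with positive mortality
#'   between the anchors.
#' @export
old_age_adjustment <- function(lt, anchor_ages = c(80, 40)) {
  life_expectancy(lt, anchor_ages[1L]) / life_expectancy(lt, anchor_ages[2L])
}

#' Value a mortality change as a percent of per-capita income
#'
#' Converts annual death rates into a welfare value using the VSL-to-income
#' ratio: `100 * ratio * (young_rate + old_rate * adjustment)` percent of
#' per-capita income, where the adjustment is the remaining-life-expectancy
#' ratio [old_age_adjustment()].  With rates per person per year of
#' 3.2/10,000 in the young band only, the default ratio 160 gives 5.1
#' percent of income.
#'
#' @param young_rate Annual death rate (deaths per person per year) below
#'   the cut-off age.
#' @param old_rate Annual death rate at or above the cut-off (default 0).
#' @param adjustment Either a [life_table()] (the ratio is read from it at
#'   the anchor ages in `params`) or a fixed scalar in `[0, 1]`
#'   (default 1, i.e. no old-age discount).
#' @param params A [valuation_params()].
#' @return Object of class `mortality_value`: `value_pct_income` plus the
#'   per-band `components` (which sum to the total).  Method: `print`.
#' @export
mortality_value <- function(young_rate, old_rate = 0, adjustment = 1,
                            params = valuation_params()) {
  if (young_rate < 0 || old_rate < 0) {
    stop("death rates must be non-negative", call. = FALSE)
  }
  adj <- if (inherits(adjustment, "life_table")) {
    old_age_adjustment(adjustment, params$adjustment_anchor_ages)
  } else {
    as.numeric(adjustment)
  }
  components <- c(young = 100 * params$vsl_income_ratio * young_rate,
                  old = 100 * params$vsl_income_ratio * old_rate * adj)
  structure(list(value_pct_income = sum(components),
                 components = components, adjustment = adj,
                 params = params),
            class = "mortality_value")
}

#' @export
print.mortality_value <- function(x, ...) {
  cat(sprintf("Value of mortality change: %.2f%% of per-capita income\n",
              x$value_pct_income))
  cat(sprintf("  young band %.2f%% + old band %.2f%% (adjustment %.3f)\n",
              x$components["young"], x$components["old"], x$adjustment))
  invisible(x)
}

#' Full-income change from its income and mortality components
#'
#' Full income captures both conventional income growth and the monetized
#' value of mortality change; its change is the sum of the two components,
#' each expressed in percent of baseline income.
#'
#' @param income_change_pct Value of income change, percent of baseline
#'   income.
#' @param mortality_value_pct Value of mortality change, percent of
#'   baseline income (as `value_pct_income` from [mortality_value()]).
#' @return Percent of baseline income.
#' @export
full_income_change <- function(income_change_pct, mortality_value_pct) {
  income_change_pct + mortality_value_pct
}

#' Excess death rates below and above a cut-off age
#'
#' Aggregates per-interval excess death counts and population into the two
#' valuation bands and returns annual rates (deaths per person per year).
#'
#' @param excess_deaths_by_age Numeric vector of excess deaths per age
#'   interval (over `years` of exposure).
#' @param pop A [population_structure()] on a grid with a boundary at
#'   `cutoff`.
#' @param cutoff Band cut-off age (default 75).
#' @param years Period length the counts cover, used to annualize
#'   (default 1).
#' @return Named vector `c(young_rate, old_rate)`.
#' @export
excess_rates_by_band <- function(excess_deaths_by_age, pop, cutoff = 75,
                                 years = 1) {
  g <- pop$grid
  if (length(excess_deaths_by_age) != n_intervals(g)) {
    stop_grid_mismatch("excess_rates_by_band()")
  }
  boundary_index(g, cutoff, "excess_rates_by_band()")
  young <- g$starts < cutoff
  n_young <- sum(pop$counts[young]); n_old <- sum(pop$counts[!young])
  if (n_young <= 0 || n_old <= 0) {
    stop("both age bands must have positive population", call. = FALSE)
  }
  c(young_rate = sum(excess_deaths_by_age[young]) / (n_young * years),
    old_rate = sum(excess_deaths_by_age[!young]) / (n_old * years))
}
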