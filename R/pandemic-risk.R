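#' Pandemic severity risk curve
#'
#' Annual exceedance probabilities over death-toll thresholds (the
#' exceedance probability function of catastrophe modelling), optionally
#' with a discrete severity distribution (toll, probability of occurring
#' in a year) and an age pattern of pandemic deaths.  The package consumes
#' these as inputs from an external catastrophe model; it does not
#' simulate pandemics.
#'
#' @param thresholds Death-toll thresholds (increasing, e.g. `1e6, 1e7,
#'   2.5e7, 1e8`).
#' @param annual_exceedance Probability per year that pandemic deaths meet
#'   or exceed each threshold; non-increasing in the threshold.
#' @param severity_pmf Optional data frame with columns `toll`, `prob`:
#'   a discrete distribution of annual pandemic death tolls (probabilities
#'   summing to at most 1; the remainder is the no-pandemic year).
#' @param age_pattern Optional per-age-interval shares of pandemic deaths,
#'   summing to 1.
#' @return Object of class `risk_curve`.
#' @export
risk_curve <- function(thresholds = NULL, annual_exceedance = NULL,
                       severity_pmf = NULL, age_pattern = NULL) {
  if (!is.null(thresholds) || !is.null(annual_exceedance)) {
    if (length(thresholds) != length(annual_exceedance)) {
      stop("`thresholds` and `annual_exceedance` must have equal length",
           call. = FALSE)
    }
    if (any(diff(thresholds) <= 0)) {
      stop("`thresholds` must be strictly increasing", call. = FALSE)
    }
    if (any(annual_exceedance < 0 | annual_exceedance > 1)) {
      stop("exceedance probabilities must be in [0, 1]", call. = FALSE)
    }
    if (any(diff(annual_exceedance) > 1e-12)) {
      stop("exceedance probabilities must be non-increasing in the ",
           "threshold", call. = FALSE)
    }
  }
  if (!is.null(severity_pmf)) {
    if (!all(c("toll", "prob") %in% names(severity_pmf))) {
      stop("`severity_pmf` needs columns `toll` and `prob`", call. = FALSE)
    }
    if (any(severity_pmf$prob < 0) || sum(severity_pmf$prob) > 1 + 1e-12) {
      stop("severity probabilities must be non-negative and sum to at ",
           "most 1", call. = FALSE)
    }
    if (any(severity_pmf$toll < 0)) {
      stop("severity tolls must be non-negative", call. = FALSE)
    }
  }
  if (!is.null(age_pattern)) {
    if (any(age_pattern < 0) || abs(sum(age_pattern) - 1) > 1e-9) {
      stop("`age_pattern` must be non-negative shares summing to 1",
           call. = FALSE)
    }
  }
  if (is.null(thresholds) && is.null(severity_pmf)) {
    stop("supply an exceedance curve, a severity distribution, or both",
         call. = FALSE)
  }
  structure(list(thresholds = thresholds,
                 annual_exceedance = annual_exceedance,
                 severity_pmf = severity_pmf, age_pattern = age_pattern),
            class = "risk_curve")
}

#' @export
print.risk_curve <- function(x, ...) {
  cat("Pandemic risk curve\n")
  if (!is.null(x$thresholds)) {
    for (i in seq_along(x$thresholds)) {
      cat(sprintf("  P(deaths >= %s per year) = %.3f\n",
                  format(x$thresholds[i], big.mark = ","),
                  x$annual_exceedance[i]))
    }
  }
  if (!is.null(x$severity_pmf)) {
    cat(sprintf("  severity pmf over %d outcomes (P(any pandemic) = %.3f)\n",
                nrow(x$severity_pmf), sum(x$severity_pmf$prob)))
  }
  invisible(x)
}

#' Convert an annual exceedance probability to a multi-year horizon
#'
#' Probability of at least one exceedance over `n_years` under independent
#' identical annual risk: `1 - (1 - p)^n`.
#'
#' @param p_annual Annual exceedance probability in `[0, 1]`.
#' @param n_years Horizon in years (integer >= 1).
#' @return Probability in `[0, 1]`.
#' @export
multi_year_exceedance <- function(p_annual, n_years) {
  if (any(p_annual < 0 | p_annual > 1)) {
    stop("`p_annual` must be in [0, 1]", call. = FALSE)
  }
  if (any(n_years < 1)) stop("`n_years` must be >= 1", call. = FALSE)
  1 - (1 - p_annual)^n_years
}

#' Expected annual pandemic deaths
#'
#' The long-run average annual death toll implied by a risk curve: in most
#' years zero, in some years millions.  Computed from the severity
#' distribution when present (`sum(toll * prob)`); otherwise from the step
#' exceedance curve as the threshold integral
#' `sum(p_i * (t_i - t_{i-1}))` with `t_0 = 0`, which equals the
#' expectation of a toll distribution supported on the thresholds.
#'
#' @param curve A [risk_curve()].
#' @return Expected deaths per year.
#' @export
expected_annual_deaths <- function(curve) {
  if (!inherits(curve, "risk_curve")) {
    stop("`curve` must be a risk_curve", call. = FALSE)
  }
  if (!is.null(curve$severity_pmf)) {
    return(sum(curve$severity_pmf$toll * curve$severity_pmf$prob))
  }
  if (is.null(curve$thresholds)) {
    stop("risk curve has neither a severity distribution nor an ",
         "exceedance curve", call. = FALSE)
  }
  sum(curve$annual_exceedance * diff(c(0, curve$thresholds)))
}

#' Impact of expected pandemic mortality on PPD and life expectancy
#'
#' Converts expected annual pandemic deaths into age-specific mortality
#' rate increments (`expected_deaths * share_x / N_x`), rebuilds the life
#' table, and reports the change in the probability of premature death
#' (percentage points) and in life expectancy at birth (years; negative
#' for added mortality).  Mortality added entirely at ages 70 and above
#' leaves PPD unchanged but still lowers life expectancy.
#'
#' @param baseline A [mortality_schedule()].
#' @param expected_deaths Expected pandemic deaths per year.
#' @param age_pattern Per-age-interval shares of pandemic deaths (summing
#'   to 1), aligned to the schedule's grid.
#' @param pop A [population_structure()] on the same grid; intervals
#'   receiving deaths must have positive population.
#' @param ax_rule Life-table rule, see [life_table()].
#' @return List with `delta_ppd` (percentage points), `delta_le` (years),
#'   and the two life tables (`lt_baseline`, `lt_shocked`).
#' @export
pandemic_mortality_impact <- function(baseline, expected_deaths,
                                      age_pattern, pop,
                                      ax_rule = "constant_hazard") {
  g <- baseline$grid
  if (!same_grid(g, pop$grid)) stop_grid_mismatch("pandemic_mortality_impact()")
  if (length(age_pattern) != n_intervals(g)) {
    stop("`age_pattern` must align to the age grid", call. = FALSE)
  }
  if (any(age_pattern < 0) || abs(sum(age_pattern) - 1) > 1e-9) {
    stop("`age_pattern` must be non-negative shares summing to 1",
         call. = FALSE)
  }
  if (expected_deaths < 0) {
    stop("`expected_deaths` must be non-negative", call. = FALSE)
  }
  receiving <- age_pattern > 0 & expected_deaths > 0
  if (any(receiving & pop$counts <= 0)) {
    stop("age interval(s) receiving pandemic deaths have zero population: ",
         paste(which(receiving & pop$counts <= 0), collapse = ", "),
         call. = FALSE)
  }
  delta_mx <- ifelse(receiving, expected_deaths * age_pattern / pop$counts, 0)
  lt0 <- life_table(baseline, ax_rule = ax_rule)
  shocked <- mortality_schedule(g, baseline$mx + delta_mx,
                                location = baseline$label$location,
                                year = baseline$label$year,
                                sex = baseline$label$sex)
  lt1 <- life_table(shocked, ax_rule = ax_rule)
  list(delta_ppd = 100 * (ppd(lt1) - ppd(lt0)),
       delta_le = life_expectancy(lt1) - life_expectancy(lt0),
       lt_baseline = lt0, lt_shocked = lt1)
}

#' Value expected pandemic mortality as a percent of income
#'
#' Delegates to [mortality_value()]: expected annual pandemic death rates
#' per band times the VSL-to-income ratio, with the old band discounted by
#' the remaining-life-expectancy ratio.
#'
#' @param young_rate,old_rate Expected annual pandemic death rates per
#'   person below / at-or-above the cut-off age.
#' @param adjustment,params As in [mortality_value()].
#' @return A `mortality_value` object.
#' @export
pandemic_loss_value <- function(young_rate, old_rate = 0, adjustment = 1,
                                params = valuation_params()) {
  mortality_value(young_rate, old_rate, adjustment, params)
}
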