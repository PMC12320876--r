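#' Average annual rate of decline of PPD
#'
#' The continuous (log-scale) average annual rate of decline between two
#' levels of the probability of premature death:
#' `r = -100 * log(p1/p0) / years`, in percent per year.  Positive values
#' mean improvement; negative values mean PPD is rising.  The continuous
#' convention matches the halving-time identity `69.3 / r`
#' (`69.3 = 100 * log(2)`).
#'
#' @param ppd0,ppd1 PPD levels (fractions or percents, same scale) at the
#'   start and end of the window; both positive.
#' @param years Length of the window in calendar years (e.g. 2010 to 2019
#'   is 9 years).
#' @return Rate of decline in percent per year.
#' @export
annual_decline_rate <- function(ppd0, ppd1, years) {
  if (any(ppd0 <= 0) || any(ppd1 <= 0)) {
    stop("PPD levels must be positive to compute a log rate of decline",
         call. = FALSE)
  }
  if (any(years <= 0)) stop("`years` must be positive", call. = FALSE)
  -100 * log(ppd1 / ppd0) / years
}

#' Time required to halve PPD at a constant decline rate
#'
#' `69.3 / r` years, with `r` in percent per year.  The constant is
#' `100 * log(2) = 69.3147...` (quoted as 69.3 at the precision published
#' tables print), so the identity
#' `halving_time(annual_decline_rate(p, p/2, t)) = t` holds exactly.
#' A non-positive rate never halves and returns `Inf`; presentation layers
#' conventionally print a cap such as ">75" (see [format_halving_time()]).
#'
#' @param r Annual rate of decline in percent per year.
#' @return Years to halve (`Inf` when `r <= 0`).
#' @export
halving_time <- function(r) {
  ifelse(r > 0, 100 * log(2) / r, Inf)
}

#' Format a halving time with a presentation cap
#'
#' @param t Halving time in years.
#' @param cap Cap above which the value prints as `"> cap"`.
#' @return Character vector.
#' @export
format_halving_time <- function(t, cap = 75) {
  ifelse(is.finite(t) & t <= cap, as.character(round_half_up(t)),
         paste0(">", cap))
}

#' Cumulative percent reduction after a horizon
#'
#' Projects a constant annual decline rate forward and returns the
#' cumulative percent reduction.  Rates are *estimated* on the log scale
#' ([annual_decline_rate()]) but *projected* with discrete compounding by
#' default: `100 * (1 - (1 - r/100)^years)`.  The discrete projector
#' reproduces the published milestone arithmetic (2.2 percent per year
#' over 16 years gives a 30 percent reduction); a pure continuous
#' projector (`1 - exp(-r/100 * years)`) is selectable and differs only
#' in the third significant figure at these rates.
#'
#' @param r Annual decline rate, percent per year.
#' @param years Projection horizon in years.
#' @param convention `"discrete"` (default) or `"continuous"`.
#' @return Cumulative reduction in percent (negative if `r < 0`).
#' @export
reduction_after <- function(r, years,
                            convention = c("discrete", "continuous")) {
  convention <- match.arg(convention)
  if (convention == "discrete") {
    100 * (1 - (1 - r / 100)^years)
  } else {
    100 * (1 - exp(-r / 100 * years))
  }
}

#' First calendar year a target PPD reduction is reached
#'
#' Smallest integer year at or after `base_year` by which the cumulative
#' reduction ([reduction_after()]) meets the target.
#'
#' @param base_year Calendar base year (the year of the reference PPD).
#' @param r Annual decline rate, percent per year; must be positive to
#'   reach a positive target.
#' @param target_reduction Target cumulative reduction in percent,
#'   in `[0, 100)`.
#' @param convention Projection convention, as [reduction_after()].
#' @return Integer calendar year, or `NA` when the target is never reached
#'   (`r <= 0` with a positive target).
#' @export
year_reaching_target <- function(base_year, r, target_reduction,
                                 convention = c("discrete", "continuous")) {
  convention <- match.arg(convention)
  if (target_reduction < 0 || target_reduction >= 100) {
    stop("`target_reduction` must be in [0, 100) percent", call. = FALSE)
  }
  if (target_reduction == 0) return(as.integer(base_year))
  if (r <= 0) return(NA_integer_)
  # invert the compounding directly, then round up to a whole year
  years <- if (convention == "discrete") {
    log(1 - target_reduction / 100) / log(1 - r / 100)
  } else {
    -log(1 - target_reduction / 100) / (r / 100)
  }
  as.integer(base_year + ceiling(years - 1e-12))
}

#' Classify a decline rate against the halving-by-2050 pace
#'
#' A rate of at least 2.2 percent per year halves PPD within the 31-year
#' window 2019-2050 ("on track"); below 1 percent per year is "slow";
#' rates in between are "medium".  Boundaries are inclusive on the
#' on-track side (a rate of exactly 2.2 is on track) and exclusive on the
#' slow side (exactly 1.0 is medium).
#'
#' @param r Annual decline rate, percent per year.
#' @param on_track_rate,slow_rate Classification boundaries (defaults 2.2
#'   and 1.0 percent per year).
#' @return Factor with levels `on_track`, `medium`, `slow`.
#' @export
classify_track <- function(r, on_track_rate = 2.2, slow_rate = 1.0) {
  out <- ifelse(r >= on_track_rate, "on_track",
                ifelse(r < slow_rate, "slow", "medium"))
  factor(out, levels = c("on_track", "medium", "slow"))
}

#' Average annual rate of change of a rate (log scale)
#'
#' Signed continuous rate of change between two positive rates:
#' `100 * log(rate1/rate0) / years` percent per year, negative for a
#' decline.  This is the convention used for cause-specific death-rate
#' trends; note the sign is opposite to [annual_decline_rate()], which
#' reports declines as positive.
#'
#' @param rate0,rate1 Positive rates at the window endpoints.
#' @param years Window length in years.
#' @return Percent per year, negative = decline.
#' @export
aarc <- function(rate0, rate1, years) {
  if (any(rate0 <= 0) || any(rate1 <= 0)) {
    stop("rates must be positive to compute a log rate of change",
         call. = FALSE)
  }
  if (any(years <= 0)) stop("`years` must be positive", call. = FALSE)
  100 * log(rate1 / rate0) / years
}

#' Frontier (lowest observed) PPD series across locations
#'
#' Per-year minimum PPD over locations, after excluding locations whose
#' population is below a threshold (small populations give noisy PPD
#' estimates).  With `running = TRUE` the series is the lowest PPD *ever*
#' observed up to each year.
#'
#' @param panel Data frame with columns `location`, `year`, `ppd`, and
#'   (when `min_population > 0`) `population`.
#' @param min_population Locations with population below this are excluded
#'   entirely (default 3e6).
#' @param running Return the running ("ever observed") minimum?
#' @return Data frame with columns `year`, `ppd`, `location` (the location
#'   attaining the per-year minimum).
#' @export
frontier_series <- function(panel, min_population = 3e6, running = FALSE) {
  need <- c("location", "year", "ppd")
  miss <- setdiff(need, names(panel))
  if (length(miss)) {
    stop("panel is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (min_population > 0) {
    if (!"population" %in% names(panel)) {
      stop("panel is missing column(s): population (needed for the ",
           "population filter)", call. = FALSE)
    }
    panel <- panel[panel$population >= min_population, , drop = FALSE]
  }
  if (!nrow(panel)) {
    stop("no locations remain after the population filter", call. = FALSE)
  }
  years <- sort(unique(panel$year))
  idx <- vapply(years, function(y) {
    rows <- which(panel$year == y)
    rows[which.min(panel$ppd[rows])]
  }, integer(1))
  out <- data.frame(year = years, ppd = panel$ppd[idx],
                    location = panel$location[idx],
                    stringsAsFactors = FALSE)
  if (running) {
    out$ppd <- cummin(out$ppd)
    out$location[duplicated(out$ppd) & c(FALSE, diff(out$ppd) == 0)] <-
      NA_character_
    for (i in seq_len(nrow(out))[-1]) {
      if (is.na(out$location[i])) out$location[i] <- out$location[i - 1L]
    }
  }
  out
}

#' Assess a PPD trajectory against halving targets
#'
#' Estimates the average annual decline rate from a PPD series (endpoint
#' log formula by default, or a log-linear regression over all years),
#' then derives the halving time, the years in which 30 and 50 percent
#' reductions from the base-year level would be reached, and the
#' on-track/medium/slow classification.
#'
#' @param ppd Numeric vector of PPD levels (fractions or percents).
#' @param years Calendar years of the observations (same length).
#' @param base_year Base year for target projections (default: last
#'   observation year).
#' @param targets Named numeric vector: target percent reductions with
#'   names giving no deadline semantics here (deadlines belong to the
#'   caller); default `c("30" = 30, "50" = 50)`.
#' @param method `"endpoint"` (two-point log formula, default) or
#'   `"loglinear"` (least-squares slope of `log(ppd)` on year).
#' @param convention Projection convention, see [reduction_after()].
#' @return Object of class `ppd_trajectory` with fields `r`,
#'   `halving_time`, `target_years` (named integer vector), `track_status`,
#'   plus the inputs.  Methods: `print`.
#' @export
assess_trajectory <- function(ppd, years, base_year = max(years),
                              targets = c("30" = 30, "50" = 50),
                              method = c("endpoint", "loglinear"),
                              convention = c("discrete", "continuous")) {
  method <- match.arg(method)
  convention <- match.arg(convention)
  if (length(ppd) != length(years) || length(ppd) < 2L) {
    stop("`ppd` and `years` must have equal length >= 2", call. = FALSE)
  }
  o <- order(years)
  ppd <- ppd[o]; years <- years[o]
  if (any(ppd <= 0)) stop("PPD levels must be positive", call. = FALSE)
  r <- if (method == "endpoint") {
    annual_decline_rate(ppd[1L], ppd[length(ppd)],
                        years[length(years)] - years[1L])
  } else {
    -100 * unname(stats::coef(stats::lm(log(ppd) ~ years))[2L])
  }
  ty <- vapply(targets, function(tg) {
    year_reaching_target(base_year, r, tg, convention)
  }, integer(1))
  structure(list(r = r, halving_time = halving_time(r),
                 target_years = ty, track_status = classify_track(r),
                 base_year = base_year, base_ppd = ppd[which.max(years)],
                 method = method, convention = convention,
                 ppd = ppd, years = years),
            class = "ppd_trajectory")
}

#' @export
print.ppd_trajectory <- function(x, ...) {
  cat("PPD trajectory assessment (", x$method, " rate, ",
      x$convention, " projection)\n", sep = "")
  cat(sprintf("  decline rate r        : %.2f %%/yr (%s)\n",
              x$r, as.character(x$track_status)))
  cat(sprintf("  time to halve         : %s years\n",
              format_halving_time(x$halving_time)))
  for (i in seq_along(x$target_years)) {
    cat(sprintf("  %s%% reduction reached : %s\n",
                names(x$target_years)[i],
                ifelse(is.na(x$target_years[i]), "never",
                       as.character(x$target_years[i]))))
  }
  invisible(x)
}
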