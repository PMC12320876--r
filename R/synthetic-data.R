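#' Specification of a synthetic mortality schedule
#'
#' A Gompertz-Makeham hazard with an added infant hump, emulating the
#' shape of published abridged mortality schedules: a background
#' (age-independent) Makeham term, an exponentially rising senescent
#' Gompertz term, and elevated infant mortality on `[0, 1)`.  The default
#' parameters describe a world-like schedule: probability of premature
#' death around one third and life expectancy at birth in the low 70s.
#'
#' @param makeham_a Background hazard, per year (default 4e-4).
#' @param gompertz_b Gompertz level at age 0, per year (default 5e-5).
#' @param gompertz_c Gompertz slope, per year of age (default 0.092).
#' @param infant_hump Added hazard on the infant interval `[0, 1)`, per
#'   year (default 0.03, i.e. infant mortality around 30 per 1000).
#' @param grid An [age_grid()] (default [default_age_grid()]).
#' @param seed Integer seed carried for reproducibility bookkeeping; the
#'   hazard itself is deterministic.
#' @return Object of class `schedule_spec`.
#' @export
schedule_spec <- function(makeham_a = 4e-4, gompertz_b = 5e-5,
                          gompertz_c = 0.092, infant_hump = 0.03,
                          grid = default_age_grid(), seed = 1L) {
  if (makeham_a < 0 || gompertz_b < 0 || infant_hump < 0) {
    stop("hazard parameters must be non-negative", call. = FALSE)
  }
  if (makeham_a + gompertz_b + infant_hump <= 0) {
    stop("the hazard must be positive somewhere", call. = FALSE)
  }
  structure(list(makeham_a = makeham_a, gompertz_b = gompertz_b,
                 gompertz_c = gompertz_c, infant_hump = infant_hump,
                 grid = grid, seed = as.integer(seed)),
            class = "schedule_spec")
}

# Interval-averaged Gompertz-Makeham hazard: (1/n) * integral of
# a + b*exp(c*t) over [x, x+n).  The open interval is averaged over its
# first 10 years (it has no midpoint).
gm_interval_mean <- function(a, b, c, x, n) {
  n_eff <- ifelse(is.finite(n), n, 10)
  if (b == 0) return(rep(a, length(x)))
  if (c == 0) return(rep(a + b, length(x)))
  a + b * (exp(c * (x + n_eff)) - exp(c * x)) / (c * n_eff)
}

#' Generate a synthetic mortality schedule
#'
#' Evaluates the [schedule_spec()] hazard by exact interval averaging and
#' returns a [mortality_schedule()].  The infant hump is added to the
#' first interval, scaled so that it contributes `infant_hump` person-year
#' hazard on `[0, 1)` regardless of the first interval's width.
#'
#' @param spec A [schedule_spec()].
#' @param location,year,sex Label fields for the schedule.
#' @return A [mortality_schedule()].  Identical specs give bit-identical
#'   schedules.
#' @export
make_schedule <- function(spec, location = "synthetic", year = 2019L,
                          sex = "both") {
  g <- spec$grid
  mx <- gm_interval_mean(spec$makeham_a, spec$gompertz_b, spec$gompertz_c,
                         g$starts, g$widths)
  w1 <- g$widths[1L]
  mx[1L] <- mx[1L] + spec$infant_hump * min(1, w1) / w1
  if (any(!is.finite(mx))) {
    stop("hazard parameters yield non-finite rates; reduce gompertz_c or ",
         "the oldest age group", call. = FALSE)
  }
  mortality_schedule(g, mx, location = location, year = year, sex = sex)
}

default_cause_profile <- function(grid,
                                  causes = c("I-8", "NCD-7", "other")) {
  mids <- grid$starts + ifelse(is.finite(grid$widths), grid$widths / 2, 5)
  raw <- cbind(0.05 + 0.90 * exp(-mids / 12),          # infections: young
               0.10 + 0.90 / (1 + exp(-(mids - 45) / 9)), # NCDs: old
               0.20)                                    # other: flat
  frac <- raw / rowSums(raw)
  colnames(frac) <- causes
  frac
}

#' Specification of a multi-year mortality scenario
#'
#' Describes a cause-structured mortality trajectory: a base schedule,
#' per-cause continuous annual decline rates, an age profile of cause
#' fractions, and optionally a pandemic-style shock for excess-mortality
#' scenarios.  Cause-specific rates decline exactly exponentially, so the
#' declared rates are recovered exactly by [aarc()]; the implied PPD
#' decline rate is close to, but not identical with, the all-cause rate
#' decline because PPD is a nonlinear functional of the rates.
#'
#' @param base A [schedule_spec()] for the first year.
#' @param years Integer vector of calendar years (default `2000:2019`).
#' @param causes Cause labels (default the priority grouping
#'   `I-8`, `NCD-7`, `other`).
#' @param annual_decline Percent-per-year continuous decline per cause,
#'   named or positional (default 2.2 for every cause, the halving-by-2050
#'   pace).
#' @param cause_profile Matrix of base-year cause fractions (intervals x
#'   causes, rows summing to 1); default an age profile with infections
#'   concentrated at young ages and NCDs at old ages.
#' @param shock Optional list for [make_excess_scenario()]:
#'   `p_score` (period excess as percent of baseline),
#'   `annual_change` (baseline trend, percent/yr, default 0),
#'   `start`, `end` (period dates), `wave_months` (length of the wave,
#'   default 18), `wave_start` (month index, default 3), and
#'   `age_pattern` (shares by age of excess deaths; default
#'   old-skewed).
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(base = schedule_spec(), years = 2000:2019,
                          causes = c("I-8", "NCD-7", "other"),
                          annual_decline = rep(2.2, length(causes)),
                          cause_profile = NULL, shock = NULL) {
  if (length(annual_decline) != length(causes)) {
    stop("`annual_decline` needs one rate per cause", call. = FALSE)
  }
  if (is.null(names(annual_decline))) names(annual_decline) <- causes
  if (is.null(cause_profile)) {
    cause_profile <- default_cause_profile(base$grid, causes)
  }
  structure(list(base = base, years = as.integer(years), causes = causes,
                 annual_decline = annual_decline,
                 cause_profile = cause_profile, shock = shock),
            class = "scenario_spec")
}

#' Generate a multi-year cause-structured mortality trajectory
#'
#' Builds, for each scenario year, the cause-specific mortality rates
#' `m_xc(t) = m_x(t0) * f_xc * exp(-r_c/100 * (t - t0))`, the implied
#' all-cause [mortality_schedule()] (the cause sum) and [cause_table()].
#' Because each cause declines exactly exponentially, [aarc()] applied to
#' any cause-specific rate series recovers `-r_c` exactly.
#'
#' @param spec A [scenario_spec()].
#' @return Object of class `mortality_trajectory`: lists `schedules` and
#'   `cause_tables` (one per year, named by year), the `rates` array
#'   (interval x cause x year) and the spec.
#' @export
make_trajectory <- function(spec) {
  g <- spec$base$grid
  base <- make_schedule(spec$base, year = spec$years[1L])
  k <- n_intervals(g)
  nc <- length(spec$causes)
  ny <- length(spec$years)
  rates <- array(NA_real_, dim = c(k, nc, ny),
                 dimnames = list(interval_labels(g), spec$causes,
                                 spec$years))
  schedules <- vector("list", ny)
  cause_tables <- vector("list", ny)
  t0 <- spec$years[1L]
  for (j in seq_len(ny)) {
    decay <- exp(-spec$annual_decline / 100 * (spec$years[j] - t0))
    m_xc <- base$mx * spec$cause_profile *
      matrix(decay, k, nc, byrow = TRUE)
    rates[, , j] <- m_xc
    mx_all <- rowSums(m_xc)
    schedules[[j]] <- mortality_schedule(g, mx_all, location = "synthetic",
                                         year = spec$years[j], sex = "both")
    cause_tables[[j]] <- cause_table(g, fractions = m_xc / mx_all,
                                     causes = spec$causes)
  }
  names(schedules) <- names(cause_tables) <- spec$years
  structure(list(schedules = schedules, cause_tables = cause_tables,
                 rates = rates, spec = spec),
            class = "mortality_trajectory")
}

#' @export
print.mortality_trajectory <- function(x, ...) {
  yrs <- x$spec$years
  cat("Synthetic mortality trajectory,", length(yrs), "years (",
      yrs[1L], "-", yrs[length(yrs)], "),",
      length(x$spec$causes), "causes\n")
  cat("  declared decline rates:",
      paste(sprintf("%s %.2f%%/yr", names(x$spec$annual_decline),
                    x$spec$annual_decline), collapse = ", "), "\n")
  invisible(x)
}

default_shock <- function() {
  list(p_score = 13, annual_change = 0,
       start = "2020-01-01", end = "2023-05-04",
       wave_months = 18L, wave_start = 3L, age_pattern = NULL)
}

#' Generate a pandemic-style excess-mortality scenario
#'
#' Builds a monthly observed death series equal to a trend baseline plus a
#' raised-cosine wave of excess deaths whose total is fixed so that the
#' true period P-score equals the declared `shock$p_score` exactly.  The
#' all-cause annual baseline is read from the scenario's base schedule
#' applied to a stable-population approximation (total deaths =
#' `deaths_per_year` argument if given, else 58 million, a world-scale
#' default).
#'
#' @param spec A [scenario_spec()] whose `shock` field is set (see
#'   [scenario_spec()]); a `NULL` shock uses the defaults (13 percent
#'   P-score over January 2020 to May 4 2023).
#' @param deaths_per_year Baseline annual deaths in the reference year
#'   (default 58e6).
#' @return List with `observed` (named monthly deaths), `spec` (the
#'   [baseline_spec()] used), `true_excess`, `true_p_score`, and
#'   `age_pattern` (shares of excess deaths by age; old-skewed by
#'   default).
#' @export
make_excess_scenario <- function(spec, deaths_per_year = 58e6) {
  shock <- utils::modifyList(default_shock(),
                             if (is.null(spec$shock)) list() else spec$shock)
  bspec <- baseline_spec(deaths_per_year, shock$annual_change,
                         shock$start, shock$end,
                         ref_year = year_of(as.Date(shock$start)) - 1L)
  months <- month_seq(bspec$start, bspec$end)
  base_m <- monthly_baseline(bspec, months)
  # period baseline on the monthly accounting used by the P-score series
  period_base <- sum(base_m)
  true_excess <- shock$p_score / 100 * period_base
  w <- numeric(length(months))
  idx <- shock$wave_start + seq_len(shock$wave_months) - 1L
  idx <- idx[idx <= length(months)]
  shape <- 1 - cos(2 * pi * seq_along(idx) / (length(idx) + 1L))
  w[idx] <- shape / sum(shape)
  observed <- unname(base_m) + true_excess * w
  names(observed) <- months
  age_pattern <- shock$age_pattern
  if (is.null(age_pattern)) {
    g <- spec$base$grid
    mids <- g$starts + ifelse(is.finite(g$widths), g$widths / 2, 5)
    raw <- exp((mids - 60) / 12)   # old-skewed, COVID-like
    age_pattern <- raw / sum(raw)
  }
  list(observed = observed, spec = bspec, true_excess = true_excess,
       true_p_score = shock$p_score, age_pattern = age_pattern)
}
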