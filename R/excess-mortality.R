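#' Baseline death projection specification
#'
#' Defines the counterfactual ("no shock") death baseline for P-score
#' calculations: deaths in a reference year, an average annual rate of
#' change carried forward, and the assessment period.  Yearly baseline
#' deaths compound at the annual change from the reference year; partial
#' calendar years are pro-rated by actual day counts (leap years
#' respected); monthly baselines are the year baseline divided by 12.
#'
#' @param deaths_ref_year Deaths in the reference year (count, > 0).
#' @param annual_change Average annual percent change in deaths carried
#'   forward (default 0); see [mean_annual_change()] to derive it from a
#'   run of pre-period years.
#' @param start,end Period start and end dates (`Date` or `"YYYY-MM-DD"`),
#'   both inclusive.
#' @param ref_year Calendar reference year of `deaths_ref_year`
#'   (default 2019).
#' @return Object of class `baseline_spec`.
#' @export
baseline_spec <- function(deaths_ref_year, annual_change = 0, start, end,
                          ref_year = 2019) {
  if (deaths_ref_year <= 0) {
    stop("reference-year deaths must be positive", call. = FALSE)
  }
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end) || end < start) {
    stop("the period must be a well-ordered pair of dates", call. = FALSE)
  }
  structure(list(deaths_ref_year = deaths_ref_year,
                 annual_change = annual_change,
                 start = start, end = end, ref_year = as.integer(ref_year)),
            class = "baseline_spec")
}

#' @export
print.baseline_spec <- function(x, ...) {
  cat(sprintf("Baseline: %s deaths in %d, %+.2f%%/yr, period %s to %s\n",
              format(x$deaths_ref_year, big.mark = ","), x$ref_year,
              x$annual_change, format(x$start), format(x$end)))
  invisible(x)
}

year_of <- function(d) as.integer(format(d, "%Y"))

days_in_year <- function(y) {
  as.integer(as.Date(sprintf("%d-01-01", y + 1L)) -
               as.Date(sprintf("%d-01-01", y)))
}

#' Baseline deaths in a single calendar year
#'
#' @param spec A [baseline_spec()].
#' @param year Calendar year.
#' @return Projected deaths for that whole year.
#' @export
annual_baseline <- function(spec, year) {
  spec$deaths_ref_year * (1 + spec$annual_change / 100)^(year - spec$ref_year)
}

#' Project total baseline deaths over the period
#'
#' Sums the compounded yearly baselines over the period, pro-rating the
#' first and last calendar years by the number of days of the period they
#' contain (both endpoint dates inclusive).
#'
#' @param spec A [baseline_spec()].
#' @return Projected baseline deaths over the whole period.
#' @export
project_baseline <- function(spec) {
  ys <- year_of(spec$start):year_of(spec$end)
  total <- 0
  for (y in ys) {
    y0 <- max(spec$start, as.Date(sprintf("%d-01-01", y)))
    y1 <- min(spec$end, as.Date(sprintf("%d-12-31", y)))
    frac <- (as.integer(y1 - y0) + 1L) / days_in_year(y)
    total <- total + annual_baseline(spec, y) * frac
  }
  total
}

#' Excess-mortality P-score
#'
#' Excess deaths as a percent of the projected baseline deaths over the
#' same period: `100 * excess / baseline`.  Negative excess (fewer deaths
#' than expected) gives a negative P-score.  Being a ratio of deaths, the
#' P-score is free of population size.
#'
#' @param excess Excess deaths over the period (may be negative).
#' @param baseline Projected baseline deaths (> 0); either a number or a
#'   [baseline_spec()] (projected via [project_baseline()]).
#' @return Percent.
#' @export
p_score <- function(excess, baseline) {
  if (inherits(baseline, "baseline_spec")) {
    baseline <- project_baseline(baseline)
  }
  if (any(baseline <= 0)) {
    stop("baseline deaths must be positive", call. = FALSE)
  }
  100 * excess / baseline
}

month_seq <- function(start, end) {
  s <- as.Date(paste0(format(as.Date(start), "%Y-%m"), "-01"))
  e <- as.Date(paste0(format(as.Date(end), "%Y-%m"), "-01"))
  format(seq(s, e, by = "month"), "%Y-%m")
}

#' Monthly baseline deaths (uniform within each year)
#'
#' The monthly baseline is the projected yearly baseline divided by 12,
#' i.e. deaths are assumed uniform across each calendar year.
#'
#' @param spec A [baseline_spec()].
#' @param months Character vector of months `"YYYY-MM"`; defaults to every
#'   month of the spec's period.
#' @return Named numeric vector of monthly baseline deaths.
#' @export
monthly_baseline <- function(spec, months = month_seq(spec$start, spec$end)) {
  ys <- as.integer(substr(months, 1L, 4L))
  out <- annual_baseline(spec, ys) / 12
  names(out) <- months
  out
}

#' Monthly P-score series
#'
#' Per-month P-scores of an observed monthly death series against the
#' uniform-within-year monthly baseline.  The period P-score over the same
#' months equals total excess over total baseline, which is the
#' baseline-weighted mean of the monthly P-scores.
#'
#' @param observed_monthly Named numeric vector (names `"YYYY-MM"`) or
#'   data frame with columns `month`, `observed_deaths`.
#' @param spec A [baseline_spec()] whose period covers the months.
#' @return Data frame with columns `month`, `observed`, `baseline`,
#'   `excess`, `p_score`, and the period P-score as attribute
#'   `"period_p_score"`.
#' @export
monthly_pscore_series <- function(observed_monthly, spec) {
  if (is.data.frame(observed_monthly)) {
    need <- c("month", "observed_deaths")
    miss <- setdiff(need, names(observed_monthly))
    if (length(miss)) {
      stop("monthly data is missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    months <- as.character(observed_monthly$month)
    obs <- observed_monthly$observed_deaths
  } else {
    months <- names(observed_monthly)
    obs <- as.numeric(observed_monthly)
  }
  if (is.null(months)) stop("months must be named 'YYYY-MM'", call. = FALSE)
  in_period <- months %in% month_seq(spec$start, spec$end)
  if (!all(in_period)) {
    stop("month(s) outside the baseline period: ",
         paste(months[!in_period], collapse = ", "), call. = FALSE)
  }
  base <- monthly_baseline(spec, months)
  out <- data.frame(month = months, observed = obs, baseline = unname(base),
                    excess = obs - unname(base),
                    p_score = p_score(obs - unname(base), unname(base)),
                    stringsAsFactors = FALSE)
  attr(out, "period_p_score") <- p_score(sum(out$excess), sum(out$baseline))
  out
}

#' Average annual change from a run of yearly death counts
#'
#' Geometric mean of the year-over-year ratios, expressed in percent per
#' year; the convention for the pre-period trend fed into
#' [baseline_spec()].
#'
#' @param deaths_by_year Numeric vector of yearly deaths in consecutive
#'   calendar years (length >= 2, all positive).
#' @return Percent per year.
#' @export
mean_annual_change <- function(deaths_by_year) {
  d <- as.numeric(deaths_by_year)
  if (length(d) < 2L || any(d <= 0)) {
    stop("need at least two positive yearly counts", call. = FALSE)
  }
  n <- length(d)
  100 * ((d[n] / d[1L])^(1 / (n - 1L)) - 1)
}
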