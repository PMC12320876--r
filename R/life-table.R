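#' Build an abridged period life table
#'
#' Constructs the synthetic-cohort columns (`qx`, `lx`, `dx`, `Lx`, `Tx`,
#' `ex`) from age-specific central death rates.  The life table answers the
#' question: if a cohort were exposed for life to the current age-specific
#' mortality rates, how would it survive?  Life expectancy at birth and the
#' probability of premature death ([ppd()]) are read from it.
#'
#' Two conversions from `mx` to interval death probabilities `qx` are
#' available:
#' \describe{
#'   \item{`"constant_hazard"` (default)}{assumes the hazard is constant
#'     within each interval, so `qx = 1 - exp(-n * mx)`.  Survivorship at
#'     every grid boundary then equals the closed form
#'     `l(x) = radix * exp(-sum(mx * n))` over the preceding intervals,
#'     which makes results verifiable against exact integrals and
#'     invariant to refining the grid.}
#'   \item{`"midpoint"`}{the classical `ax = n/2` rule (with `a0 = 0.1`
#'     for the infant interval `[0,1)`), `qx = n*mx / (1 + (n - ax)*mx)`,
#'     matching the construction of many published tables.}
#' }
#' The open-ended last interval always has `qx = 1` and
#' `Lx = lx / mx`; a zero `mx` there with survivors present is an error
#' (remaining life expectancy would be undefined).
#'
#' @param x A [mortality_schedule()], or a numeric vector of central death
#'   rates (in which case `grid` must be supplied).
#' @param grid An [age_grid()], only when `x` is a bare numeric vector.
#' @param ax_rule `"constant_hazard"` or `"midpoint"`; see Details.
#' @param radix Cohort size at age 0; conventional 100000.
#' @return An object of class `life_table`: a list with the grid, the input
#'   `mx`, the derived columns `ax`, `qx`, `lx`, `dx`, `Lx`, `Tx`, `ex`,
#'   the radix and the label.  Methods: `print`, `summary`,
#'   `as.data.frame`, `plot`.
#' @examples
#' lt <- life_table(rep(0.01, 21), default_age_grid())
#' ppd(lt)                       # 1 - exp(-0.7)
#' life_expectancy(lt)
#' @export
life_table <- function(x, grid = NULL,
                       ax_rule = c("constant_hazard", "midpoint"),
                       radix = 1e5) {
  ax_rule <- match.arg(ax_rule)
  if (inherits(x, "mortality_schedule")) {
    sched <- x
  } else {
    if (is.null(grid)) {
      stop("when `x` is a numeric vector of rates, `grid` must be supplied",
           call. = FALSE)
    }
    sched <- mortality_schedule(grid, x)
  }
  g <- sched$grid
  boundary_index(g, 70, "the life table (for the premature-death cut-off)")
  k <- n_intervals(g)
  mx <- sched$mx
  n <- g$widths
  open <- k

  if (mx[open] == 0) {
    # Survivors would live forever; ex undefined.  Only legal if nobody
    # reaches the open interval, which cannot be known for mx = 0 upstream
    # unless some closed qx = 1; simplest sound rule: reject unless all
    # preceding survival is annihilated.
    lx_probe <- cumprod(c(1, 1 - qx_closed(mx[-open], n[-open], ax_rule, g)))
    if (lx_probe[open] > 0) {
      stop("open-ended interval has mx = 0 with survivors present; ",
           "remaining life expectancy is undefined", call. = FALSE)
    }
  }

  qx <- numeric(k)
  ax <- numeric(k)
  qx[-open] <- qx_closed(mx[-open], n[-open], ax_rule, g)
  qx[open] <- 1
  # ax consistent with Lx below (reported, not used directly)
  cl <- seq_len(k - 1L)
  ax[cl] <- ifelse(mx[cl] > 0,
                   1 / mx[cl] - n[cl] * (1 - qx[cl]) / qx[cl],
                   n[cl] / 2)
  if (ax_rule == "midpoint") ax[cl] <- ax_midpoint(n[cl], g)
  ax[open] <- ifelse(mx[open] > 0, 1 / mx[open], NA_real_)

  lx <- radix * cumprod(c(1, 1 - qx[-k]))
  dx <- lx * qx
  Lx <- numeric(k)
  if (ax_rule == "constant_hazard") {
    Lx[cl] <- ifelse(mx[cl] > 0, dx[cl] / mx[cl], n[cl] * lx[cl])
  } else {
    Lx[cl] <- n[cl] * (lx[cl] - dx[cl]) + ax[cl] * dx[cl]
  }
  Lx[open] <- if (mx[open] > 0) lx[open] / mx[open] else 0
  Tx <- rev(cumsum(rev(Lx)))
  ex <- ifelse(lx > 0, Tx / lx, 0)

  structure(list(grid = g, mx = mx, ax = ax, qx = qx, lx = lx, dx = dx,
                 Lx = Lx, Tx = Tx, ex = ex, radix = radix,
                 ax_rule = ax_rule, label = sched$label),
            class = "life_table")
}

qx_closed <- function(mx, n, ax_rule, grid) {
  if (ax_rule == "constant_hazard") {
    1 - exp(-n * mx)
  } else {
    ax <- ax_midpoint(n, grid)
    pmin(n * mx / (1 + (n - ax) * mx), 1)
  }
}

# Mid-interval ax, with the conventional low a0 for the infant interval,
# reflecting the concentration of infant deaths near birth.
ax_midpoint <- function(n, grid) {
  ax <- n / 2
  if (grid$starts[1L] == 0 && grid$widths[1L] == 1) ax[1L] <- 0.1
  ax
}

#' @export
print.life_table <- function(x, digits = 4, ...) {
  cat("Abridged life table", format_label(x$label),
      sprintf("(%s rule, radix %g)\n", x$ax_rule, x$radix))
  cat(sprintf("  e0 = %.*f years, PPD (70q0) = %.*f\n",
              digits, x$ex[1L], digits, ppd(x)))
  invisible(x)
}

#' @export
summary.life_table <- function(object, ...) {
  out <- list(e0 = object$ex[1L], ppd = ppd(object),
              label = object$label, ax_rule = object$ax_rule)
  class(out) <- "summary.life_table"
  out
}

#' @export
print.summary.life_table <- function(x, ...) {
  cat("Life table", format_label(x$label), "\n")
  cat(sprintf("  Life expectancy at birth : %.2f years\n", x$e0))
  cat(sprintf("  Probability of death <70 : %.1f%%\n", 100 * x$ppd))
  cat(sprintf("  qx/ax rule               : %s\n", x$ax_rule))
  invisible(x)
}

#' @export
as.data.frame.life_table <- function(x, ...) {
  data.frame(age_start = x$grid$starts,
             age_width = x$grid$widths,
             mx = x$mx, ax = x$ax, qx = x$qx, lx = x$lx,
             dx = x$dx, Lx = x$Lx, Tx = x$Tx, ex = x$ex)
}

#' @export
plot.life_table <- function(x, which = c("lx", "mx"), ...) {
  which <- match.arg(which)
  mids <- x$grid$starts + ifelse(is.finite(x$grid$widths),
                                 x$grid$widths / 2, 5)
  if (which == "lx") {
    graphics::plot(x$grid$starts, x$lx, type = "s",
                   xlab = "Age", ylab = "Survivors lx",
                   main = "Survivorship", ...)
  } else {
    graphics::plot(mids, x$mx, type = "b", log = "y",
                   xlab = "Age (interval midpoint)",
                   ylab = "Central death rate mx (log scale)",
                   main = "Mortality schedule", ...)
  }
  invisible(x)
}

#' Survivors at an exact grid boundary
#'
#' @param lt A [life_table()].
#' @param age A boundary age present in the grid.
#' @return `lx` at that boundary (radix scale).
#' @export
survivors_at <- function(lt, age) {
  i <- boundary_index(lt$grid, age, "survivors_at()")
  lt$lx[i]
}

#' Remaining life expectancy at a grid boundary
#'
#' @inheritParams survivors_at
#' @param age Boundary age (default 0, life expectancy at birth).
#' @return `ex` at that boundary, in years.
#' @export
life_expectancy <- function(lt, age = 0) {
  i <- boundary_index(lt$grid, age, "life_expectancy()")
  lt$ex[i]
}

#' Probability of premature death (death before age 70)
#'
#' The probability that a member of a synthetic cohort exposed to the
#' table's age-specific mortality rates dies before age 70:
#' `1 - l(70)/l(0)`.  Unlike life expectancy it weights all deaths under
#' 70 equally and ignores mortality at 70 and above, which makes it a
#' sharper monitor of premature-mortality progress in low-mortality
#' settings.
#'
#' @param lt A [life_table()] whose grid has a boundary at age 70.
#' @return A probability in `[0, 1]`.  Multiply by 100 for the
#'   conventionally reported percentage.
#' @export
ppd <- function(lt) {
  if (!inherits(lt, "life_table")) {
    stop("`lt` must be a life_table", call. = FALSE)
  }
  1 - survivors_at(lt, 70) / lt$radix
}

#' Signed percent change between two values
#'
#' `100 * (after - before) / before`; the arithmetic behind statements like
#' "PPD dropped from 66\% to 52\%, a 21 percent decrease".
#'
#' @param before,after Scalars; `before` must be non-zero.
#' @return Signed percent change.
#' @export
percent_change <- function(before, after) {
  if (any(before == 0)) {
    stop("percent change is undefined for a zero baseline", call. = FALSE)
  }
  100 * (after - before) / before
}

#' Crude death rate per 1000 population
#'
#' `1000 * sum(mx * Nx) / sum(Nx)`: the all-age death rate implied by an
#' age-specific mortality schedule applied to an actual population age
#' structure.  Unlike PPD and life expectancy it depends on the age
#' pyramid, so ageing populations can show rising crude death rates even
#' as age-specific mortality falls.
#'
#' @param schedule A [mortality_schedule()].
#' @param pop A [population_structure()] on the same grid.
#' @return Deaths per 1000 population per year.
#' @export
crude_death_rate <- function(schedule, pop) {
  if (!same_grid(schedule$grid, pop$grid)) {
    stop_grid_mismatch("crude_death_rate()")
  }
  1000 * sum(schedule$mx * pop$counts) / sum(pop$counts)
}

#' Old-age dependency ratio
#'
#' Population aged 65 and over as a percentage of the working-age
#' population (ages 15-64): `100 * N(65+) / N(15-64)`.
#'
#' @param pop A [population_structure()] whose grid has boundaries at
#'   ages 15 and 65.
#' @return Percent.
#' @export
old_age_dependency_ratio <- function(pop) {
  g <- pop$grid
  boundary_index(g, 15, "old_age_dependency_ratio()")
  boundary_index(g, 65, "old_age_dependency_ratio()")
  working <- sum(pop$counts[g$starts >= 15 & g$starts < 65])
  old <- sum(pop$counts[g$starts >= 65])
  if (working <= 0) {
    stop("old-age dependency ratio is undefined with zero working-age ",
         "population", call. = FALSE)
  }
  100 * old / working
}

#' Round half-up at a fixed number of decimals
#'
#' Presentation-layer rounding used when matching printed tables (R's
#' `round()` rounds half to even).  Internal computations are never
#' rounded.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return `x` rounded half away from zero at `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
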