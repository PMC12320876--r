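#' Abridged age grid
#'
#' An age grid is the sequence of closed-open age intervals `[x, x+n)` on
#' which mortality rates, populations and life tables are tabulated.  The
#' last interval is always open-ended (width `Inf`).  The conventional
#' abridged layout is `0, 1-4, 5-9, ..., 95+` (see [default_age_grid()]).
#'
#' @param starts Numeric vector of interval lower bounds in completed years;
#'   strictly increasing and starting at 0.  Intervals are contiguous by
#'   construction: the width of interval `i` is `starts[i+1] - starts[i]`,
#'   and the final interval is open-ended.
#' @return An object of class `age_grid` with components `starts` and
#'   `widths` (last width `Inf`).
#' @examples
#' g <- age_grid(c(0, 1, seq(5, 95, by = 5)))
#' length(g$starts)
#' @export
age_grid <- function(starts) {
  starts <- as.numeric(starts)
  if (length(starts) < 2L) {
    stop("an age grid needs at least two intervals (one closed, one open)",
         call. = FALSE)
  }
  if (anyNA(starts) || any(!is.finite(starts))) {
    stop("age-group lower bounds must be finite", call. = FALSE)
  }
  if (starts[1L] != 0) {
    stop("the first age group must start at age 0, got ", starts[1L],
         call. = FALSE)
  }
  if (any(diff(starts) <= 0)) {
    stop("age-group lower bounds must be strictly increasing", call. = FALSE)
  }
  structure(list(starts = starts, widths = c(diff(starts), Inf)),
            class = "age_grid")
}

#' Default abridged age grid (0, 1-4, 5-year groups to 95+)
#'
#' The conventional abridged layout used by published period life tables:
#' an infant interval `[0,1)`, a child interval `[1,5)`, then 5-year groups
#' up to the open interval `95+`.  It contains boundaries at ages 15, 65,
#' 70, 75, 80 and 40, as required by the premature-death, dependency-ratio
#' and valuation calculations.
#'
#' @return An [age_grid()].
#' @export
default_age_grid <- function() age_grid(c(0, 1, seq(5, 95, by = 5)))

n_intervals <- function(grid) length(grid$starts)

#' @export
print.age_grid <- function(x, ...) {
  k <- n_intervals(x)
  lab <- paste0(x$starts[-k], "-", x$starts[-1L] - 1)
  lab[x$widths[-k] == 1] <- as.character(x$starts[-k][x$widths[-k] == 1])
  cat("Age grid with", k, "intervals:", paste(lab, collapse = ", "),
      paste0(x$starts[k], "+"), "\n")
  invisible(x)
}

is_age_grid <- function(x) inherits(x, "age_grid")

same_grid <- function(a, b) {
  is_age_grid(a) && is_age_grid(b) &&
    length(a$starts) == length(b$starts) && all(a$starts == b$starts)
}

stop_grid_mismatch <- function(what) {
  stop(what, ": age grids do not match", call. = FALSE)
}

# Index of the interval starting exactly at `age`, or an error naming the
# missing boundary.  Boundaries are never interpolated.
boundary_index <- function(grid, age, context) {
  i <- match(age, grid$starts)
  if (is.na(i)) {
    stop(context, " requires an age-group boundary at exactly age ", age,
         "; the grid has boundaries at ",
         paste(grid$starts, collapse = ", "), call. = FALSE)
  }
  i
}

interval_labels <- function(grid) {
  k <- n_intervals(grid)
  lab <- paste0(grid$starts[-k], "-", grid$starts[-1L] - 1)
  lab[grid$widths[-k] == 1] <- as.character(grid$starts[-k][grid$widths[-k] == 1])
  c(lab, paste0(grid$starts[k], "+"))
}
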