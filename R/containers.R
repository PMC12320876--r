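#' Age-specific mortality schedule
#'
#' Central death rates `mx` (deaths per person-year of exposure) for one
#' (location, year, sex) cell, on an [age_grid()].  This is the universal
#' input from which life tables, premature-death probabilities and crude
#' death rates are derived.
#'
#' @param grid An [age_grid()].
#' @param mx Numeric vector of central death rates, one per age interval;
#'   non-negative and finite.
#' @param location,year,sex Optional label fields identifying the cell.
#' @return An object of class `mortality_schedule`.
#' @examples
#' sched <- mortality_schedule(default_age_grid(),
#'                             rep(0.01, 21), location = "toy")
#' @export
mortality_schedule <- function(grid, mx, location = NA_character_,
                               year = NA_integer_, sex = "both") {
  if (!is_age_grid(grid)) stop("`grid` must be an age_grid", call. = FALSE)
  mx <- as.numeric(mx)
  if (length(mx) != n_intervals(grid)) {
    stop("`mx` has length ", length(mx), " but the grid has ",
         n_intervals(grid), " intervals", call. = FALSE)
  }
  if (anyNA(mx) || any(!is.finite(mx))) {
    stop("mortality rates must be finite and non-missing", call. = FALSE)
  }
  if (any(mx < 0)) {
    stop("mortality rates must be non-negative; got ", min(mx),
         call. = FALSE)
  }
  structure(list(grid = grid, mx = mx,
                 label = list(location = location, year = year, sex = sex)),
            class = "mortality_schedule")
}

#' @export
print.mortality_schedule <- function(x, ...) {
  cat("Mortality schedule", format_label(x$label), "on",
      n_intervals(x$grid), "age intervals\n")
  cat("  mx range:", signif(min(x$mx), 4), "-", signif(max(x$mx), 4), "\n")
  invisible(x)
}

format_label <- function(label) {
  parts <- c(label$location, label$year, label$sex)
  parts <- parts[!is.na(parts)]
  if (!length(parts)) "" else paste0("[", paste(parts, collapse = ", "), "]")
}

#' Population age structure
#'
#' Person counts per age interval on an [age_grid()]; the `N(x)` used by
#' crude death rates, dependency ratios and rate/band calculations.
#'
#' @param grid An [age_grid()].
#' @param counts Non-negative person counts, one per interval; total > 0.
#' @return An object of class `population_structure`.
#' @export
population_structure <- function(grid, counts) {
  if (!is_age_grid(grid)) stop("`grid` must be an age_grid", call. = FALSE)
  counts <- as.numeric(counts)
  if (length(counts) != n_intervals(grid)) {
    stop("`counts` has length ", length(counts), " but the grid has ",
         n_intervals(grid), " intervals", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("population counts must be non-negative and non-missing",
         call. = FALSE)
  }
  if (sum(counts) <= 0) stop("total population must be positive", call. = FALSE)
  structure(list(grid = grid, counts = counts), class = "population_structure")
}

#' @export
print.population_structure <- function(x, ...) {
  cat("Population structure on", n_intervals(x$grid), "age intervals, total",
      format(sum(x$counts), big.mark = ","), "\n")
  invisible(x)
}

#' Cause-of-death composition by age
#'
#' Per-interval shares of deaths by cause, aligned to an [age_grid()].
#' Each row (age interval) must sum to 1.  Supply either `fractions`
#' directly or a matrix of `deaths`, from which fractions are derived.
#'
#' @param grid An [age_grid()].
#' @param fractions Numeric matrix, intervals x causes, rows summing to 1.
#' @param deaths Alternative to `fractions`: death counts by interval and
#'   cause; converted to row shares (rows with zero deaths get an error).
#' @param causes Character vector of unique cause labels; taken from the
#'   matrix column names when omitted.
#' @return An object of class `cause_table`.
#' @seealso [i8_causes()], [ncd7_causes()] for the built-in priority
#'   groupings.
#' @export
cause_table <- function(grid, fractions = NULL, deaths = NULL, causes = NULL) {
  if (!is_age_grid(grid)) stop("`grid` must be an age_grid", call. = FALSE)
  if (is.null(fractions) && is.null(deaths)) {
    stop("supply either `fractions` or `deaths`", call. = FALSE)
  }
  if (is.null(fractions)) {
    deaths <- as.matrix(deaths)
    if (any(deaths < 0)) stop("death counts must be non-negative", call. = FALSE)
    rs <- rowSums(deaths)
    if (any(rs <= 0)) {
      stop("cannot derive cause fractions: zero total deaths in interval(s) ",
           paste(which(rs <= 0), collapse = ", "), call. = FALSE)
    }
    fractions <- deaths / rs
  }
  fractions <- as.matrix(fractions)
  if (is.null(causes)) causes <- colnames(fractions)
  if (is.null(causes)) {
    stop("cause labels missing: name the matrix columns or pass `causes`",
         call. = FALSE)
  }
  if (anyDuplicated(causes)) stop("cause labels must be unique", call. = FALSE)
  if (nrow(fractions) != n_intervals(grid)) {
    stop("fraction matrix has ", nrow(fractions), " rows but the grid has ",
         n_intervals(grid), " intervals", call. = FALSE)
  }
  if (ncol(fractions) != length(causes)) {
    stop("fraction matrix has ", ncol(fractions), " columns but ",
         length(causes), " cause labels were given", call. = FALSE)
  }
  if (anyNA(fractions) || any(fractions < 0)) {
    stop("cause fractions must be non-negative and non-missing", call. = FALSE)
  }
  bad <- which(abs(rowSums(fractions) - 1) > 1e-9)
  if (length(bad)) {
    stop("cause fractions must sum to 1 in every age interval; off in ",
         "interval(s) ", paste(bad, collapse = ", "), call. = FALSE)
  }
  dimnames(fractions) <- list(interval_labels(grid), causes)
  structure(list(grid = grid, causes = causes, fractions = fractions),
            class = "cause_table")
}

#' @export
print.cause_table <- function(x, ...) {
  cat("Cause table:", length(x$causes), "causes x", n_intervals(x$grid),
      "age intervals\n  causes:", paste(x$causes, collapse = ", "), "\n")
  invisible(x)
}

#' Built-in priority cause groupings
#'
#' The eight priority infections and maternal-health conditions (`I-8`) and
#' the seven priority NCD and injury clusters (`NCD-7`) used throughout the
#' decomposition tables, as WHO Global Health Estimates category groups.
#'
#' @return Character vector of cause labels.
#' @export
i8_causes <- function() {
  c("neonatal conditions", "lower respiratory infections",
    "diarrheal diseases", "HIV/AIDS", "tuberculosis", "malaria",
    "childhood-cluster diseases", "maternal conditions")
}

#' @rdname i8_causes
#' @export
ncd7_causes <- function() {
  c("atherosclerotic CVD", "hemorrhagic stroke", "infection-linked NCDs",
    "tobacco-linked NCDs", "diabetes", "road injury", "suicide")
}

#' @rdname i8_causes
#' @param other Label(s) for the residual group.
#' @export
priority_cause_groups <- function(other = "other") {
  list("I-8" = i8_causes(), "NCD-7" = ncd7_causes(), other = other)
}
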