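#' Decompose a life expectancy difference by age (and cause)
#'
#' Attributes the difference in life expectancy at birth between two life
#' tables to age groups with Arriaga's method, and optionally splits each
#' age contribution across causes of death in proportion to the
#' cause-specific rate differences.  Contributions sum exactly to
#' `e_cmp(0) - e_ref(0)`.
#'
#' For closed intervals the age-`x` contribution is the sum of the direct
#' effect (extra person-years lived within the interval) and the
#' indirect-plus-interaction effect (extra survivors reaching the next
#' interval, valued at the comparison table's remaining expectancy):
#' \deqn{\Delta_x = \frac{l^{1}_x}{l^{1}_0}\left(\frac{L^{2}_x}{l^{2}_x} -
#'   \frac{L^{1}_x}{l^{1}_x}\right) + \frac{T^{2}_{x+n}}{l^{1}_0}
#'   \left(\frac{l^{1}_x}{l^{2}_x} -
#'   \frac{l^{1}_{x+n}}{l^{2}_{x+n}}\right)}
#' with the open interval handled through its `Tx` form.  The attribution
#' is mildly asymmetric in the direction of comparison; `average = TRUE`
#' reports the mean of the forward and (negated) reverse runs, which is
#' symmetric by construction.
#'
#' The cause split within age interval `x` is proportional to
#' `m2*f2c - m1*f1c`, the difference in cause-specific mortality rates;
#' cause shares sum to the age contribution exactly.  When the all-cause
#' rates are equal in an interval the age contribution is zero to
#' numerical precision; any residue is allocated proportionally to the
#' mean cause fractions so the age totals are preserved exactly.
#'
#' @param lt_ref,lt_cmp Reference and comparison [life_table()]s on the
#'   same grid and radix.
#' @param causes_ref,causes_cmp Optional [cause_table()]s aligned to the
#'   same grid with identical cause lists; when given, the result carries
#'   a `by_age_cause` matrix.
#' @param average Report the direction-symmetric average decomposition?
#' @return Object of class `le_decomposition` with fields `by_age` (named
#'   numeric), `by_age_cause` (matrix or `NULL`), `total` (years, equal to
#'   `sum(by_age)`), and the inputs' labels.  Methods: `print`, `summary`,
#'   `coef` (the by-age vector), `plot`.
#' @seealso [gap_accounting()] to express cause-group totals as percent of
#'   the gap; [death_change_decomposition()] for death counts.
#' @export
decompose_le <- function(lt_ref, lt_cmp, causes_ref = NULL,
                         causes_cmp = NULL, average = FALSE) {
  if (!inherits(lt_ref, "life_table") || !inherits(lt_cmp, "life_table")) {
    stop("`lt_ref` and `lt_cmp` must be life_table objects", call. = FALSE)
  }
  if (!same_grid(lt_ref$grid, lt_cmp$grid)) {
    stop_grid_mismatch("decompose_le()")
  }
  if (lt_ref$radix != lt_cmp$radix) {
    stop("life tables must share a radix", call. = FALSE)
  }
  by_age <- arriaga_age(lt_ref, lt_cmp)
  if (average) {
    by_age <- (by_age - arriaga_age(lt_cmp, lt_ref)) / 2
  }
  total <- lt_cmp$ex[1L] - lt_ref$ex[1L]

  by_age_cause <- NULL
  if (!is.null(causes_ref) || !is.null(causes_cmp)) {
    if (is.null(causes_ref) || is.null(causes_cmp)) {
      stop("supply both `causes_ref` and `causes_cmp` or neither",
           call. = FALSE)
    }
    by_age_cause <- partition_by_cause(by_age, lt_ref$mx, lt_cmp$mx,
                                       causes_ref, causes_cmp,
                                       lt_ref$grid)
  }
  structure(list(by_age = by_age, by_age_cause = by_age_cause,
                 total = total, average = average,
                 label_ref = lt_ref$label, label_cmp = lt_cmp$label),
            class = "le_decomposition")
}

# Arriaga age decomposition of e_cmp(0) - e_ref(0); exact by telescoping.
arriaga_age <- function(lt_ref, lt_cmp) {
  g <- lt_ref$grid
  k <- n_intervals(g)
  l1 <- lt_ref$lx / lt_ref$radix
  l2 <- lt_cmp$lx / lt_cmp$radix
  L1 <- lt_ref$Lx / lt_ref$radix
  L2 <- lt_cmp$Lx / lt_cmp$radix
  T1 <- lt_ref$Tx / lt_ref$radix
  T2 <- lt_cmp$Tx / lt_cmp$radix
  cc <- numeric(k)
  for (i in seq_len(k - 1L)) {
    if (l1[i] <= 0 || l2[i] <= 0) next   # nobody alive in either table
    direct <- l1[i] * (L2[i] / l2[i] - L1[i] / l1[i])
    nxt <- if (l2[i + 1L] > 0) {
      T2[i + 1L] * (l1[i] / l2[i] - l1[i + 1L] / l2[i + 1L])
    } else {
      # comparison cohort extinct beyond x+n: remaining-life value is 0
      0
    }
    cc[i] <- direct + nxt
  }
  if (l1[k] > 0 && l2[k] > 0) {
    cc[k] <- l1[k] * (T2[k] / l2[k] - T1[k] / l1[k])
  }
  names(cc) <- interval_labels(g)
  cc
}

partition_by_cause <- function(by_age, mx_ref, mx_cmp, causes_ref,
                               causes_cmp, grid) {
  if (!inherits(causes_ref, "cause_table") ||
      !inherits(causes_cmp, "cause_table")) {
    stop("cause inputs must be cause_table objects", call. = FALSE)
  }
  if (!same_grid(causes_ref$grid, grid) || !same_grid(causes_cmp$grid, grid)) {
    stop_grid_mismatch("cause partition")
  }
  if (!identical(causes_ref$causes, causes_cmp$causes)) {
    stop("cause lists differ between the two cause tables", call. = FALSE)
  }
  d <- mx_cmp * causes_cmp$fractions - mx_ref * causes_ref$fractions
  denom <- rowSums(d)              # = mx_cmp - mx_ref, fractions sum to 1
  share <- d / ifelse(abs(denom) > 0, denom, 1)
  flat <- abs(denom) == 0
  if (any(flat)) {
    # equal all-cause rates: age contribution is ~0; keep row sums exact
    w <- (causes_ref$fractions[flat, , drop = FALSE] +
            causes_cmp$fractions[flat, , drop = FALSE]) / 2
    share[flat, ] <- w
  }
  out <- share * by_age
  dimnames(out) <- list(interval_labels(grid), causes_ref$causes)
  out
}

#' @export
print.le_decomposition <- function(x, digits = 3, ...) {
  cat("Life expectancy decomposition",
      if (x$average) "(direction-symmetric average)" else "", "\n")
  cat(sprintf("  total difference: %+.3f years\n", x$total))
  top <- sort(abs(x$by_age), decreasing = TRUE)
  show <- names(top)[seq_len(min(3L, length(top)))]
  for (a in show) {
    cat(sprintf("  ages %-6s : %+.*f years\n", a, digits, x$by_age[a]))
  }
  if (!is.null(x$by_age_cause)) {
    cat("  by cause (totals):\n")
    tot <- colSums(x$by_age_cause)
    for (i in seq_along(tot)) {
      cat(sprintf("    %-28s %+.*f years\n", names(tot)[i], digits, tot[i]))
    }
  }
  invisible(x)
}

#' @export
coef.le_decomposition <- function(object, ...) object$by_age

#' @export
summary.le_decomposition <- function(object, ...) {
  out <- list(total = object$total, by_age = object$by_age,
              by_cause = if (!is.null(object$by_age_cause))
                colSums(object$by_age_cause) else NULL)
  class(out) <- "summary.le_decomposition"
  out
}

#' @export
print.summary.le_decomposition <- function(x, ...) {
  cat(sprintf("Total LE difference: %+.4f years\n", x$total))
  print(round(x$by_age, 4))
  if (!is.null(x$by_cause)) {
    cat("By cause:\n"); print(round(x$by_cause, 4))
  }
  invisible(x)
}

#' @export
plot.le_decomposition <- function(x, ...) {
  graphics::barplot(x$by_age, las = 2, ylab = "Years of life expectancy",
                    main = "Age contributions to LE difference", ...)
  invisible(x)
}

#' Percent of a life expectancy gap accounted for by cause groups
#'
#' Sums per-cause contributions of a decomposition into named groups and
#' expresses each group as a percent of the signed total gap.  A cause
#' working against the overall direction of the gap yields a negative
#' percent.
#'
#' @param decomp An [decompose_le()] result carrying `by_age_cause`.
#' @param groups Named list of character vectors partitioning the cause
#'   list, e.g. [priority_cause_groups()].
#' @return Named numeric vector of percents (one per group), with the
#'   group years as attribute `"years"`.
#' @export
gap_accounting <- function(decomp, groups = priority_cause_groups()) {
  if (!inherits(decomp, "le_decomposition") || is.null(decomp$by_age_cause)) {
    stop("`decomp` must be a le_decomposition with a cause partition",
         call. = FALSE)
  }
  causes <- colnames(decomp$by_age_cause)
  flat <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(flat) || !setequal(flat, causes)) {
    stop("`groups` must partition the cause list exactly; causes are: ",
         paste(causes, collapse = ", "), call. = FALSE)
  }
  if (decomp$total == 0) {
    stop("gap accounting is undefined for a zero total gap", call. = FALSE)
  }
  years <- vapply(groups, function(g) {
    sum(decomp$by_age_cause[, g, drop = FALSE])
  }, numeric(1))
  pct <- 100 * years / decomp$total
  attr(pct, "years") <- years
  pct
}

#' Decompose a change in death counts into demographic and rate components
#'
#' Splits the change in total deaths `sum(N1*m1) - sum(N0*m0)` between two
#' periods into three exactly additive components: population growth
#' (change in total population size), population ageing (change in the age
#' structure), and mortality change (change in age-specific rates).  Uses
#' the symmetric average-weight (Das Gupta) allocation, writing deaths as
#' `P * c_x * m_x` (total population x age share x rate) and valuing each
#' factor's change at the standardized average of the other two, so the
#' split is exact and reversing the periods negates every component.
#'
#' @param pop0,pop1 [population_structure()]s at the two periods.
#' @param sched0,sched1 [mortality_schedule()]s at the two periods; all
#'   four on a common grid.
#' @return Object of class `death_change_decomposition` with fields
#'   `total_change`, `pop_size_component`, `age_structure_component`,
#'   `rate_component` (deaths; components sum to the total), and
#'   `deaths0`, `deaths1`.  Method: `print`.
#' @export
death_change_decomposition <- function(pop0, sched0, pop1, sched1) {
  g <- pop0$grid
  if (!same_grid(g, sched0$grid) || !same_grid(g, pop1$grid) ||
      !same_grid(g, sched1$grid)) {
    stop_grid_mismatch("death_change_decomposition()")
  }
  P0 <- sum(pop0$counts); P1 <- sum(pop1$counts)
  c0 <- pop0$counts / P0; c1 <- pop1$counts / P1
  m0 <- sched0$mx;        m1 <- sched1$mx

  D0 <- sum(pop0$counts * m0)
  D1 <- sum(pop1$counts * m1)

  # Das Gupta three-factor standardization weights, applied per age and
  # aggregated: effect of factor a = (a1 - a0) * [ (b0c0 + b1c1)/3 +
  # (b0c1 + b1c0)/6 ] summed over ages.
  w3 <- function(b0, c0, b1, c1) (b0 * c0 + b1 * c1) / 3 +
    (b0 * c1 + b1 * c0) / 6
  pop_size <- sum((P1 - P0) * w3(c0, m0, c1, m1))
  age_structure <- sum((c1 - c0) * w3(P0, m0, P1, m1))
  rate <- sum((m1 - m0) * w3(P0, c0, P1, c1))

  structure(list(total_change = D1 - D0,
                 pop_size_component = pop_size,
                 age_structure_component = age_structure,
                 rate_component = rate,
                 deaths0 = D0, deaths1 = D1),
            class = "death_change_decomposition")
}

#' @export
print.death_change_decomposition <- function(x, ...) {
  fmt <- function(v) formatC(v, format = "f", digits = 1, big.mark = ",")
  cat("Change in deaths:", fmt(x$total_change),
      sprintf("(%s -> %s)\n", fmt(x$deaths0), fmt(x$deaths1)))
  cat("  population size :", fmt(x$pop_size_component), "\n")
  cat("  age structure   :", fmt(x$age_structure_component), "\n")
  cat("  mortality rates :", fmt(x$rate_component), "\n")
  invisible(x)
}
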