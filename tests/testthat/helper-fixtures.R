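# Shared fixtures: random-but-plausible schedules and an independent
# fine-grid survivorship oracle for the Gompertz-Makeham hazard.

grid_abridged <- default_age_grid()
grid_5yr <- age_grid(seq(0, 95, by = 5))

# Random plausible mortality schedule on a grid: rates drawn log-uniform
# between infant-like and old-age-like magnitudes.
random_mx <- function(grid, lo = 5e-4, hi = 0.25) {
  k <- length(grid$starts)
  exp(runif(k, log(lo), log(hi)))
}

random_schedule <- function(grid = grid_abridged, ...) {
  mortality_schedule(grid, random_mx(grid, ...))
}

random_population <- function(grid = grid_abridged, scale = 1e4) {
  population_structure(grid, runif(length(grid$starts), 0.1, 1) * scale)
}

# Random cause table with a fixed number of causes.
random_cause_table <- function(grid = grid_abridged,
                               causes = c("A", "B", "C")) {
  k <- length(grid$starts)
  m <- matrix(runif(k * length(causes), 0.05, 1), k, length(causes))
  cause_table(grid, fractions = m / rowSums(m), causes = causes)
}

# Independent survivorship oracle: exact closed-form l(x) under a
# piecewise-constant hazard equal to the interval-averaged
# Gompertz-Makeham hazard, evaluated by cumulating m * n analytically.
gm_hazard_integral <- function(a, b, c, x) a * x + b / c * (exp(c * x) - 1)

# Brute-force year-reaching oracle: step through calendar years.
brute_year_reaching <- function(base_year, r, target) {
  if (r <= 0) return(NA_integer_)
  y <- base_year
  repeat {
    red <- 100 * (1 - (1 - r / 100)^(y - base_year))
    if (red >= target - 1e-9) return(as.integer(y))
    y <- y + 1L
    if (y > base_year + 20000L) return(NA_integer_)
  }
}
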