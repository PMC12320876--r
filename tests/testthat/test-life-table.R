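test_that("zero mortality on closed intervals yields full survivorship", {
  mx <- rep(0, 21)
  mx[21] <- 0.2                       # open interval must absorb everyone
  lt <- life_table(mx, grid_abridged)
  expect_equal(unname(lt$lx), rep(1e5, 21))
  expect_equal(unname(lt$qx[-21]), rep(0, 20))
  expect_equal(lt$qx[21], 1)
  expect_equal(ppd(lt), 0)
})

test_that("constant-hazard survivorship matches the exponential closed form", {
  lt <- life_table(rep(0.01, 21), grid_abridged)
  expect_equal(survivors_at(lt, 70) / lt$radix, exp(-0.7), tolerance = 1e-12)
  expect_equal(ppd(lt), 1 - exp(-0.7), tolerance = 1e-12)
  # every boundary, not just 70
  H <- cumsum(c(0, 0.01 * grid_abridged$widths[-21]))
  expect_equal(unname(lt$lx), 1e5 * exp(-H), tolerance = 1e-12)
  # life expectancy of a constant hazard is 1/m
  expect_equal(life_expectancy(lt), 100, tolerance = 1e-9)
})

test_that("a Gompertz-Makeham abridged table matches single-year integration", {
  a <- 4e-4; b <- 5e-5; cc <- 0.092
  avg <- function(x0, x1) (gm_hazard_integral(a, b, cc, x1) -
                             gm_hazard_integral(a, b, cc, x0)) / (x1 - x0)
  # 5-year abridged schedule
  s5 <- grid_5yr$starts
  mx5 <- c(mapply(avg, s5[-20], s5[-1]), avg(95, 105))
  lt5 <- life_table(mx5, grid_5yr)
  # single-year brute-force integration of the same hazard
  g1 <- age_grid(0:95)
  s1 <- g1$starts
  mx1 <- c(mapply(avg, s1[-96], s1[-1]), avg(95, 105))
  lt1 <- life_table(mx1, g1)
  common <- match(s5, s1)
  expect_equal(unname(lt5$lx), unname(lt1$lx[common]), tolerance = 1e-9)
})

test_that("survivorship conserves the radix and lx is non-increasing", {
  set.seed(41)
  for (i in 1:20) {
    lt <- life_table(random_schedule())
    expect_equal(sum(lt$dx), lt$radix, tolerance = 1e-9 * lt$radix)
    expect_true(all(diff(lt$lx) <= 1e-12))
    expect_true(all(lt$qx >= 0 & lt$qx <= 1))
    expect_equal(unname(lt$Tx), rev(cumsum(rev(lt$Lx))))
  }
})

test_that("refining the grid under a shared hazard leaves boundary lx unchanged", {
  set.seed(42)
  mx5 <- random_mx(grid_5yr)
  lt5 <- life_table(mx5, grid_5yr)
  g1 <- age_grid(0:95)
  mx1 <- rep(mx5, times = c(rep(5, 19), 1))   # same step hazard, 1-year steps
  lt1 <- life_table(mx1, g1)
  expect_equal(unname(lt5$lx), unname(lt1$lx[match(grid_5yr$starts, 0:95)]),
               tolerance = 1e-9)
})

test_that("ppd responds only to mortality below age 70", {
  set.seed(43)
  mx <- random_mx(grid_abridged, lo = 1e-3, hi = 0.05)
  base <- ppd(life_table(mx, grid_abridged))
  below <- which(grid_abridged$starts < 70)
  for (i in below) {
    up <- mx; up[i] <- up[i] * 1.5
    expect_gt(ppd(life_table(up, grid_abridged)), base)
  }
  above <- which(grid_abridged$starts >= 70)
  for (i in above) {
    up <- mx; up[i] <- up[i] * 5
    expect_equal(ppd(life_table(up, grid_abridged)), base, tolerance = 1e-15)
  }
})

test_that("degenerate tables bracket ppd at 0 and 1", {
  mx <- rep(0, 21); mx[21] <- 0.1
  expect_equal(ppd(life_table(mx, grid_abridged)), 0)
  mx_hi <- rep(5, 21)                    # essentially nobody reaches 70
  expect_equal(ppd(life_table(mx_hi, grid_abridged)), 1, tolerance = 1e-9)
})

test_that("midpoint rule reproduces the classical qx conversion", {
  mx <- rep(0.01, 21)
  lt <- life_table(mx, grid_abridged, ax_rule = "midpoint")
  # infant interval: a0 = 0.1
  expect_equal(lt$qx[1], 0.01 / (1 + 0.9 * 0.01), tolerance = 1e-12)
  # generic 5-year interval: ax = 2.5
  expect_equal(lt$qx[3], 5 * 0.01 / (1 + 2.5 * 0.01), tolerance = 1e-12)
  expect_equal(sum(lt$dx), lt$radix, tolerance = 1e-6)
})

test_that("the open interval rejects zero mortality with survivors", {
  mx <- rep(0.01, 21); mx[21] <- 0
  expect_error(life_table(mx, grid_abridged), "undefined")
})

test_that("percent change matches the published survival comparisons", {
  # sub-Saharan Africa 2000-2019: PPD 66% -> 52%, LE 50.8 -> 60.9 years
  expect_equal(round_half_up(percent_change(66, 52)), -21)
  expect_equal(round_half_up(percent_change(50.8, 60.9)), 20)
  expect_equal(percent_change(3, 3), 0)
  expect_error(percent_change(0, 1), "zero baseline")
})

test_that("crude death rate weights rates by the population pyramid", {
  g <- age_grid(c(0, 50))
  pop <- population_structure(g, c(100, 100))
  sched <- mortality_schedule(g, c(0.002, 0.012))
  expect_equal(crude_death_rate(sched, pop), 7.0)

  uniform <- mortality_schedule(grid_abridged, rep(0.007, 21))
  set.seed(44)
  for (i in 1:5) {
    expect_equal(crude_death_rate(uniform, random_population()), 7)
  }

  # shifting weight toward the high-mortality group raises the CDR
  older <- population_structure(g, c(50, 150))
  expect_gt(crude_death_rate(sched, older), crude_death_rate(sched, pop))
  expect_error(crude_death_rate(sched, random_population(grid_abridged)),
               "grids do not match")
})

test_that("old-age dependency ratio uses the 15-64 working-age base", {
  g <- age_grid(c(0, 15, 65))
  expect_equal(old_age_dependency_ratio(population_structure(g, c(30, 60, 12))),
               20)
  expect_equal(old_age_dependency_ratio(population_structure(g, c(5, 80, 80))),
               100)
  # persons under 15 are irrelevant
  expect_equal(old_age_dependency_ratio(population_structure(g, c(500, 60, 12))),
               20)
  expect_error(old_age_dependency_ratio(population_structure(g, c(10, 0, 10))),
               "working-age")
})

test_that("life table accessors and methods are coherent", {
  lt <- life_table(make_schedule(schedule_spec()))
  df <- as.data.frame(lt)
  expect_equal(nrow(df), 21)
  expect_equal(df$ex[1], life_expectancy(lt))
  expect_output(print(lt), "PPD")
  expect_output(print(summary(lt)), "Life expectancy at birth")
})
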