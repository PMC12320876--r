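test_that("decline rate and halving time are mutually consistent", {
  # halving over 31 years needs the log rate 100*log(2)/31 = 2.2 %/yr
  expect_equal(round_half_up(annual_decline_rate(0.31, 0.155, 31), 1), 2.2)
  expect_equal(annual_decline_rate(0.4, 0.4, 9), 0)
  expect_equal(annual_decline_rate(0.40, 0.20, 20), 100 * log(2) / 20,
               tolerance = 1e-12)
  expect_error(annual_decline_rate(0, 0.1, 5), "positive")

  # formula identities at the published precision (the constant is
  # 100*log(2), printed as 69.3)
  expect_equal(round_half_up(halving_time(6.93), 1), 10)
  expect_equal(round_half_up(halving_time(2.2), 1), 31.5)
  expect_equal(round_half_up(halving_time(69.3), 2), 1)
  expect_equal(halving_time(100 * log(2) / 10), 10, tolerance = 1e-12)
  expect_identical(halving_time(0), Inf)
  expect_identical(halving_time(-1.5), Inf)
  expect_equal(format_halving_time(halving_time(-1.5)), ">75")
  expect_equal(format_halving_time(c(31.5, 80)), c("32", ">75"))

  # round trip: estimating from a halving series recovers the horizon
  set.seed(51)
  for (i in 1:50) {
    p <- runif(1, 0.05, 0.9); t <- runif(1, 1, 80)
    expect_equal(halving_time(annual_decline_rate(p, p / 2, t)), t,
                 tolerance = 1e-9)
  }
})

test_that("discrete projection reproduces the 30-by-35 milestone arithmetic", {
  # 2.2 %/yr over 2019-2035 (16 years) gives a 30% cumulative reduction
  expect_equal(round_half_up(reduction_after(2.2, 16)), 30)
  # and is consistent with halving by 2050 (31 years)
  expect_equal(round_half_up(reduction_after(2.2, 31)), 50)
  expect_equal(reduction_after(0, 40), 0)
  # continuous projector is selectable and close but not identical
  expect_equal(reduction_after(2.2, 16, convention = "continuous"),
               100 * (1 - exp(-0.022 * 16)), tolerance = 1e-12)
  expect_false(reduction_after(2.2, 16) ==
                 reduction_after(2.2, 16, convention = "continuous"))
})

test_that("reduction_after is strictly increasing in rate and horizon", {
  rs <- seq(0.5, 10, by = 0.5)
  expect_true(all(diff(reduction_after(rs, 20)) > 0))
  ys <- 1:60
  expect_true(all(diff(reduction_after(2.2, ys)) > 0))
})

test_that("year_reaching_target agrees with a year-by-year oracle", {
  set.seed(52)
  for (i in 1:1000) {
    r <- runif(1, -1, 8)
    target <- runif(1, 5, 95)
    base <- sample(2000:2030, 1)
    expect_identical(year_reaching_target(base, r, target),
                     brute_year_reaching(base, r, target))
  }
  # degenerate and constructed cases
  expect_identical(year_reaching_target(2019, 3, 0), 2019L)
  r_half31 <- 100 * (1 - 0.5^(1 / 31))       # exactly 50% at 31 years
  expect_identical(year_reaching_target(2019, r_half31, 50), 2050L)
  expect_true(is.na(year_reaching_target(2019, -0.5, 30)))
})

test_that("a fast-decline trajectory reaches 30% well before 50%", {
  # rapid-improver pattern: 50% reduction reached around 2041
  y30 <- year_reaching_target(2019, 3.15, 30)
  y50 <- year_reaching_target(2019, 3.15, 50)
  expect_lt(y30, y50)
  expect_identical(y50, 2041L)
  expect_identical(y30, brute_year_reaching(2019, 3.15, 30))
})

test_that("track classification boundaries are inclusive as published", {
  expect_identical(as.character(classify_track(2.2)), "on_track")
  expect_identical(as.character(classify_track(2.2 + 1e-12)), "on_track")
  expect_identical(as.character(classify_track(2.2 - 1e-9)), "medium")
  expect_identical(as.character(classify_track(1.0)), "medium")
  expect_identical(as.character(classify_track(1.0 - 1e-9)), "slow")
  expect_identical(as.character(classify_track(0.9)), "slow")
  expect_identical(as.character(classify_track(1.5)), "medium")
  expect_identical(as.character(classify_track(-2)), "slow")
})

test_that("aarc is the signed log rate of change", {
  expect_equal(aarc(10, 5, 10), -100 * log(2) / 10, tolerance = 1e-12)
  expect_equal(aarc(7, 7, 4), 0)
  # tuberculosis-style decline: rate 42 to 17 per 100k over 19 years
  expect_equal(round_half_up(aarc(42, 17, 19), 1), -4.8)
  expect_error(aarc(0, 1, 5), "positive")
})

test_that("the frontier series is the eligible pointwise minimum", {
  panel <- expand.grid(location = c("A", "B", "C"), year = 2000:2010)
  set.seed(53)
  panel$ppd <- runif(nrow(panel), 0.1, 0.6)
  panel$population <- ifelse(panel$location == "C", 1e6, 1e7)

  fr <- frontier_series(panel, min_population = 3e6)
  for (j in seq_len(nrow(fr))) {
    elig <- panel[panel$year == fr$year[j] & panel$location != "C", ]
    expect_equal(fr$ppd[j], min(elig$ppd))
  }
  expect_false(any(fr$location == "C"))

  solo <- panel[panel$location == "A", ]
  expect_equal(frontier_series(solo, min_population = 0)$ppd, solo$ppd)

  run <- frontier_series(panel, min_population = 3e6, running = TRUE)
  expect_true(all(diff(run$ppd) <= 0))
  expect_equal(run$ppd, cummin(fr$ppd))

  tiny <- panel[panel$location == "C", ]
  expect_error(frontier_series(tiny, min_population = 3e6),
               "population filter")
})

test_that("trajectory assessment ties the pieces together", {
  years <- 2010:2019
  ppd <- 0.40 * exp(-0.025 * (years - 2010))
  a <- assess_trajectory(ppd, years, base_year = 2019)
  expect_equal(a$r, 2.5, tolerance = 1e-9)
  expect_identical(as.character(a$track_status), "on_track")
  expect_equal(a$halving_time, 100 * log(2) / a$r)
  expect_identical(unname(a$target_years["50"]),
                   brute_year_reaching(2019, a$r, 50))
  # log-linear fit recovers the same rate on exact exponential data
  b <- assess_trajectory(ppd, years, method = "loglinear")
  expect_equal(b$r, 2.5, tolerance = 1e-9)
  expect_output(print(a), "on_track")
})
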