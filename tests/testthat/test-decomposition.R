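test_that("identical life tables decompose to zero everywhere", {
  lt <- life_table(make_schedule(schedule_spec()))
  d <- decompose_le(lt, lt)
  expect_equal(unname(d$by_age), rep(0, 21))
  expect_equal(d$total, 0)
})

test_that("a single-interval rate difference is attributed to that interval", {
  set.seed(61)
  mx1 <- random_mx(grid_abridged, lo = 1e-3, hi = 0.05)
  mx2 <- mx1
  i50 <- which(grid_abridged$starts == 50)
  mx2[i50] <- mx1[i50] * 0.5
  lt1 <- life_table(mx1, grid_abridged)
  lt2 <- life_table(mx2, grid_abridged)
  d <- decompose_le(lt1, lt2)
  direct_le <- life_expectancy(lt2) - life_expectancy(lt1)
  expect_equal(sum(d$by_age), direct_le, tolerance = 1e-9)
  expect_equal(unname(d$by_age[i50]), direct_le, tolerance = 1e-9)
  expect_equal(unname(d$by_age[-i50]), rep(0, 20), tolerance = 1e-12)
})

test_that("age contributions always sum exactly to the LE difference", {
  set.seed(62)
  for (i in 1:200) {
    lt1 <- life_table(random_schedule())
    lt2 <- life_table(random_schedule())
    d <- decompose_le(lt1, lt2)
    expect_equal(sum(d$by_age),
                 life_expectancy(lt2) - life_expectancy(lt1),
                 tolerance = 1e-9)
  }
})

test_that("reversing the comparison negates the total; averaging symmetrizes", {
  set.seed(63)
  lt1 <- life_table(random_schedule())
  lt2 <- life_table(random_schedule())
  fwd <- decompose_le(lt1, lt2)
  rev <- decompose_le(lt2, lt1)
  expect_equal(fwd$total, -rev$total, tolerance = 1e-12)
  expect_equal(sum(fwd$by_age), -sum(rev$by_age), tolerance = 1e-9)
  avg12 <- decompose_le(lt1, lt2, average = TRUE)
  avg21 <- decompose_le(lt2, lt1, average = TRUE)
  expect_equal(unname(avg12$by_age), -unname(avg21$by_age),
               tolerance = 1e-12)
  expect_equal(sum(avg12$by_age), avg12$total, tolerance = 1e-9)
})

test_that("a single catch-all cause reproduces the age decomposition", {
  set.seed(64)
  s1 <- random_schedule(); s2 <- random_schedule()
  all1 <- cause_table(grid_abridged, fractions = matrix(1, 21, 1),
                      causes = "all")
  d <- decompose_le(life_table(s1), life_table(s2), all1, all1)
  expect_equal(unname(d$by_age_cause[, "all"]), unname(d$by_age))
})

test_that("only the cause whose rate differs receives the contribution", {
  set.seed(65)
  mxA <- random_mx(grid_abridged, lo = 1e-3, hi = 0.03)
  mxB <- random_mx(grid_abridged, lo = 1e-3, hi = 0.03)
  s1 <- mortality_schedule(grid_abridged, mxA + mxB)
  s2 <- mortality_schedule(grid_abridged, 0.6 * mxA + mxB)
  f1 <- cbind(A = mxA, B = mxB) / (mxA + mxB)
  f2 <- cbind(A = 0.6 * mxA, B = mxB) / (0.6 * mxA + mxB)
  ct1 <- cause_table(grid_abridged, fractions = f1)
  ct2 <- cause_table(grid_abridged, fractions = f2)
  d <- decompose_le(life_table(s1), life_table(s2), ct1, ct2)
  expect_equal(unname(d$by_age_cause[, "A"]), unname(d$by_age),
               tolerance = 1e-9)
  expect_equal(max(abs(d$by_age_cause[, "B"])), 0, tolerance = 1e-12)
})

test_that("cause partition preserves age totals and matches cause deletion", {
  set.seed(66)
  # three causes with independent rate changes
  base <- sapply(1:3, function(j) random_mx(grid_abridged,
                                            lo = 5e-4, hi = 0.02))
  scale <- matrix(runif(21 * 3, 0.5, 1.2), 21, 3)
  m1c <- base
  m2c <- base * scale
  colnames(m1c) <- colnames(m2c) <- c("A", "B", "C")
  s1 <- mortality_schedule(grid_abridged, rowSums(m1c))
  s2 <- mortality_schedule(grid_abridged, rowSums(m2c))
  ct1 <- cause_table(grid_abridged, fractions = m1c / rowSums(m1c))
  ct2 <- cause_table(grid_abridged, fractions = m2c / rowSums(m2c))
  d <- decompose_le(life_table(s1), life_table(s2), ct1, ct2)

  # exact within-age preservation (definitional)
  expect_equal(unname(rowSums(d$by_age_cause)), unname(d$by_age),
               tolerance = 1e-12)

  # cause-deletion oracle: rebuild the comparison table replacing one
  # cause's rates at a time; cross-terms make this approximate, with the
  # discrepancy a small fraction of the total change
  for (j in 1:3) {
    m_cf <- m2c; m_cf[, j] <- m1c[, j]
    lt_cf <- life_table(rowSums(m_cf), grid_abridged)
    deletion_effect <- life_expectancy(life_table(s2)) -
      life_expectancy(lt_cf)
    expect_equal(sum(d$by_age_cause[, j]), deletion_effect,
                 tolerance = 0.05 * max(abs(d$total), 0.1))
  }
})

test_that("gap accounting expresses cause groups as percents of the gap", {
  by_age_cause <- matrix(c(3, 1, 1), 1, 3,
                         dimnames = list("0+", c("I", "N", "other")))
  d <- structure(list(by_age = c(`0+` = 5), by_age_cause = by_age_cause,
                      total = 5, average = FALSE),
                 class = "le_decomposition")
  pct <- gap_accounting(d, list(I = "I", N = "N", other = "other"))
  expect_equal(unname(pct[c("I", "N")]), c(60, 20))
  expect_equal(sum(pct[c("I", "N")]), 80)
  expect_equal(unname(gap_accounting(d, list(all = c("I", "N", "other")))),
               100, ignore_attr = TRUE)

  # a cause working against the gap direction yields a negative percent
  d$by_age_cause[1, 2] <- -1; d$by_age <- c(`0+` = 3); d$total <- 3
  pct <- gap_accounting(d, list(I = "I", N = "N", other = "other"))
  expect_lt(pct["N"], 0)

  expect_error(gap_accounting(d, list(I = "I")), "partition")
  d$total <- 0
  expect_error(gap_accounting(d, list(I = "I", N = "N", other = "other")),
               "zero total gap")
})

test_that("death-change decomposition is exact, additive and antisymmetric", {
  g <- grid_abridged
  set.seed(67)
  pop0 <- random_population(); s0 <- random_schedule()

  # no change at all
  d0 <- death_change_decomposition(pop0, s0, pop0, s0)
  expect_equal(d0$total_change, 0)
  expect_equal(d0$pop_size_component, 0)
  expect_equal(d0$age_structure_component, 0)
  expect_equal(d0$rate_component, 0)

  # pure uniform growth: all change is population size
  pop2 <- population_structure(g, 2 * pop0$counts)
  dg <- death_change_decomposition(pop0, s0, pop2, s0)
  D0 <- sum(pop0$counts * s0$mx)
  expect_equal(dg$pop_size_component, D0, tolerance = 1e-9)
  expect_equal(dg$age_structure_component, 0, tolerance = 1e-9 * D0)
  expect_equal(dg$rate_component, 0, tolerance = 1e-9 * D0)

  # random perturbations: exact additivity and antisymmetry
  for (i in 1:100) {
    p0 <- random_population(); p1 <- random_population()
    m0 <- random_schedule();   m1 <- random_schedule()
    fwd <- death_change_decomposition(p0, m0, p1, m1)
    expect_equal(fwd$pop_size_component + fwd$age_structure_component +
                   fwd$rate_component, fwd$total_change,
                 tolerance = 1e-9 * max(1, abs(fwd$total_change)))
    bwd <- death_change_decomposition(p1, m1, p0, m0)
    expect_equal(fwd$pop_size_component, -bwd$pop_size_component,
                 tolerance = 1e-9)
    expect_equal(fwd$age_structure_component, -bwd$age_structure_component,
                 tolerance = 1e-9)
    expect_equal(fwd$rate_component, -bwd$rate_component, tolerance = 1e-9)
  }

  expect_error(death_change_decomposition(pop0, s0,
                                          random_population(grid_5yr),
                                          s0),
               "grids do not match")
})
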