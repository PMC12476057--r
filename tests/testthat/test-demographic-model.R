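test_that("child survival matches closed forms and a brute-force product", {
  years <- 1950:2010
  surv0 <- child_survival(flat_child_mortality(0, years))
  expect_equal(survival_prob(surv0, c(0, 5, 17), c(1980, 1990, 1985)), rep(1, 3))

  surv_half <- child_survival(flat_child_mortality(0.5, years))
  expect_equal(survival_prob(surv_half, 2, 1980), 0.25)

  q <- random_surface("child_mortality", 0:17, years, max_rate = 0.1, seed = 5)
  surv <- child_survival(q)
  for (b in c(1955, 1970, 1990)) for (k in c(1, 7, 17)) {
    brute <- prod(vapply(0:(k - 1), function(j)
      1 - q$values[j + 1L, match(b + j, years)], numeric(1)))
    expect_equal(survival_prob(surv, k, b), brute)
  }
})

test_that("survival diagonals leaving the surface are errors naming the cell", {
  surv <- child_survival(flat_child_mortality(0.01, 1990:2000))
  expect_error(survival_prob(surv, 17, 1995), "age 6, year 2001")
  expect_error(survival_prob(surv, 1, 1985), "year 1985")
  expect_equal(survival_prob(surv, 0, 1985), 1)   # no factor needed at age 0
})

test_that("expected children profile reproduces the hand-computed sum", {
  fert <- flat_fertility(0.1)
  surv <- child_survival(flat_child_mortality(0))
  p <- expected_children_profile(30, 2000, fert, surv, rr = 1)
  expect_equal(p[1:16], rep(0.1, 16))   # k = 0..15: mother aged 30-k in 15-49
  expect_equal(p[17:18], c(0, 0))       # mother would have been under 15
  expect_equal(sum(p), 1.6)
  expect_equal(expected_children_profile(30, 2000, flat_fertility(0), surv),
               numeric(18))
})

test_that("the parity RR is a single multiplicative factor on the profile", {
  fert <- flat_fertility(0.08)
  surv <- child_survival(random_surface("child_mortality", 0:17, 1950:2010,
                                        max_rate = 0.05, seed = 2))
  for (age in c(22, 35, 50, 66)) {
    p1 <- expected_children_profile(age, 2005, fert, surv, rr = 1)
    p8 <- expected_children_profile(age, 2005, fert, surv, rr = 0.8)
    expect_equal(p8, 0.8 * p1)
  }
})

test_that("new affected counts match the single-event hand example", {
  fert <- flat_fertility(0.1)
  surv <- child_survival(flat_child_mortality(0))
  est <- new_affected(single_event(30, 2000), fert, surv)
  expect_equal(sum(est$counts[, match(2000, est$years)]), 1.6)
  expect_equal(sum(est$counts[, est$years != 2000]), 0)
  # zero events give a zero estimate
  z <- event_surface(matrix(0, 52, 61), cancer_site("X"), "diagnosis", 15:66, 1950:2010)
  expect_true(all(new_affected(z, fert, surv)$counts == 0))
})

test_that("estimates are linear in the event surface", {
  fert <- random_surface("fertility", 15:49, 1950:2010, max_rate = 0.12, seed = 7)
  surv <- child_survival(random_surface("child_mortality", 0:17, 1950:2010,
                                        max_rate = 0.02, seed = 8))
  set.seed(11)
  m <- matrix(runif(52 * 61, 0, 3), 52, 61)
  site <- cancer_site("X")
  e1 <- event_surface(m, site, "diagnosis", 15:66, 1950:2010)
  e2 <- event_surface(2 * m, site, "diagnosis", 15:66, 1950:2010)
  expect_equal(new_affected(e2, fert, surv)$counts,
               2 * new_affected(e1, fert, surv)$counts)
  expect_equal(prevalent_affected(e2, fert, surv)$counts,
               2 * prevalent_affected(e1, fert, surv)$counts)
})

test_that("feasible output years require the 17-year lookback", {
  fert <- flat_fertility(0.1, years = 1951:2022)
  surv <- child_survival(flat_child_mortality(0.01, years = 1951:2022))
  ev <- event_surface(matrix(1, 52, 70), cancer_site("X"), "diagnosis",
                      15:66, 1953:2022)
  na <- new_affected(ev, fert, surv)
  expect_equal(na$years[1L], 1968)      # fertility from 1951 -> outputs from 1968
  pv <- prevalent_affected(ev, fert, surv)
  expect_equal(pv$years[1L], 1970)      # events from 1953 -> prevalence from 1970
  expect_error(new_affected(ev, fert, surv, years = 1960), "1968")
  expect_error(prevalent_affected(ev, fert, surv, years = 1969),
               "first feasible output year is 1970")
})

test_that("degenerate one-year event history makes prevalent equal new", {
  fert <- random_surface("fertility", 15:49, 1950:2010, max_rate = 0.1, seed = 13)
  surv <- child_survival(flat_child_mortality(0, 1950:2010))
  ev <- single_event(38, 2000)
  na <- new_affected(ev, fert, surv, years = 2000)
  pv <- prevalent_affected(ev, fert, surv, years = 2000)
  expect_equal(pv$counts, na$counts)
})

test_that("prevalence under zero child mortality equals brute-force ageing of new counts", {
  years <- 1950:2010
  fert <- random_surface("fertility", 15:49, years, max_rate = 0.1, seed = 21)
  surv <- child_survival(flat_child_mortality(0, years))
  set.seed(22)
  ev <- event_surface(matrix(runif(52 * 61, 0, 2), 52, 61), cancer_site("X"),
                      "death", 15:66, years)
  na <- new_affected(ev, fert, surv)
  pv <- prevalent_affected(ev, fert, surv)
  # brute force: a child aged k at an event d years ago is now aged k + d
  for (y in c(1985, 2000, 2010)) {
    brute <- numeric(18)
    for (d in 0:17) {
      nw <- na$counts[, match(y - d, na$years)]
      for (k in 0:(17 - d)) brute[k + d + 1L] <- brute[k + d + 1L] + nw[k + 1L]
    }
    expect_equal(pv$counts[, match(y, pv$years)], brute,
                 ignore_attr = TRUE)
  }
})

test_that("stationary rates give time-constant prevalence", {
  years <- 1950:2010
  fert <- flat_fertility(0.09, years)
  surv <- child_survival(flat_child_mortality(0.005, years))
  ev <- event_surface(matrix(0.5, 52, 61), cancer_site("X"), "death", 15:66, years)
  pv <- prevalent_affected(ev, fert, surv)
  expect_lt(max(abs(sweep(pv$counts, 1, pv$counts[, 1L]))), 1e-9)
})

test_that("mothers-of-minors pair counts match brute-force enumeration", {
  years <- 1950:2010
  f <- 0.07; pop <- 500
  fert <- flat_fertility(f, years)
  surv <- child_survival(flat_child_mortality(0, years))
  mm <- mothers_of_minors(fert, flat_female_pop(pop, years), surv, years = 2000)
  # uniform world: pairs(a) = pop * f * #{k in 0..17 : 15 <= a-k <= 49}
  expected <- vapply(15:66, function(a)
    pop * f * sum((a - 0:17) >= 15 & (a - 0:17) <= 49), numeric(1))
  expect_equal(as.vector(mm$by_age), expected)
  # group aggregation preserves the total
  expect_equal(sum(mm$by_group), sum(mm$by_age))
})

test_that("an ageing fertility schedule raises the mean age of mothers of minors", {
  years <- 1950:2010
  sc <- scenario(years = years,
                 fertility = list(tfr_start = 1.8, tfr_end = 1.8,
                                  peak_start = 26, peak_end = 32, sd = 5),
                 child_mortality = list(q0 = 0, apc = 0, shape_decay = 1,
                                        shape_floor = 0))
  surf <- generate_surfaces(sc)
  surv <- child_survival(surf$child_mortality)
  mm <- mothers_of_minors(surf$fertility, surf$female_pop, surv)
  mean_age <- colSums(15:66 * mm$by_age) / colSums(mm$by_age)
  expect_true(all(diff(mean_age) > 0))
})

test_that("per-event expected children are bounded by rr x 35 x max fertility", {
  fert <- random_surface("fertility", 15:49, 1950:2010, max_rate = 0.2, seed = 31)
  surv <- child_survival(random_surface("child_mortality", 0:17, 1950:2010,
                                        max_rate = 0.1, seed = 32))
  for (age in c(20, 40, 60)) {
    p <- expected_children_profile(age, 2005, fert, surv, rr = 0.8)
    expect_true(all(p >= 0))
    expect_lte(sum(p), 0.8 * 35 * max(fert$values))
  }
})
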