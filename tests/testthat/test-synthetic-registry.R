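test_that("generated surfaces are deterministic and satisfy their invariants", {
  sc <- fixture_small()
  s1 <- generate_surfaces(sc)
  s2 <- generate_surfaces(sc)
  expect_equal(s1, s2)
  expect_s3_class(s1$fertility, "rate_surface")
  expect_true(all(s1$fertility$values >= 0))
  # total fertility declines linearly between the endpoints
  tfr <- colSums(s1$fertility$values)
  expect_equal(tfr[1], 2.6, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(tfr[length(tfr)], 1.4, tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(diff(tfr) < 0))
  # mortality never exceeds incidence
  for (s in s1$sites)
    expect_true(all(s$mortality$values <= s$incidence$values))
  expect_true(all(s1$child_mortality$values >= 0 & s1$child_mortality$values <= 1))
})

test_that("a constructed incidence APC appears in the generated surface", {
  sc <- scenario(years = 1980:2009,
                 sites = list(site_scenario("X", incidence = trend_spec(5e-4, 0.05, apcs = 1.3),
                                            mortality = trend_spec(1e-4, 0.05, apcs = 0))))
  surf <- generate_surfaces(sc)
  inc <- colSums(surf$sites$X$incidence$values)
  slopes <- diff(log(inc))
  expect_equal(slopes, rep(log(1.013), 29), tolerance = 1e-9, ignore_attr = TRUE)
  # zero rates stay zero
  sc0 <- scenario(years = 1980:1999,
                  sites = list(site_scenario("Z", incidence = trend_spec(0),
                                             mortality = trend_spec(0))))
  surf0 <- generate_surfaces(sc0)
  expect_true(all(surf0$sites$Z$incidence$values == 0))
})

test_that("scenarios with mortality above incidence are rejected", {
  sc <- scenario(years = 1990:1999,
                 sites = list(site_scenario("Bad",
                                            incidence = trend_spec(1e-4, 0, apcs = 0),
                                            mortality = trend_spec(2e-4, 0, apcs = 0))))
  expect_error(generate_surfaces(sc), "mortality exceeds incidence")
})

test_that("microsimulation is deterministic given the seed and respects zero rates", {
  sc <- fixture_small()
  m1 <- microsimulate(sc, n_women_per_cohort = 50, seed = 99, sites = "Ovary")
  m2 <- microsimulate(sc, n_women_per_cohort = 50, seed = 99, sites = "Ovary")
  expect_equal(m1$tallies, m2$tallies)
  # zero event rates -> zero affected counts
  sc0 <- scenario(years = 1980:1999,
                  sites = list(site_scenario("Z", incidence = trend_spec(0),
                                             mortality = trend_spec(0))))
  m0 <- microsimulate(sc0, n_women_per_cohort = 100, seed = 1)
  expect_true(all(microsim_counts(m0, "Z", "diagnosis", "new") == 0))
  # zero fertility -> zero affected counts despite positive event rates
  scf <- scenario(years = 1980:1999,
                  fertility = list(tfr_start = 0, tfr_end = 0,
                                   peak_start = 28, peak_end = 28, sd = 5),
                  sites = list(site_scenario("Z", incidence = trend_spec(1e-3),
                                             mortality = trend_spec(1e-4))))
  mf <- microsimulate(scf, n_women_per_cohort = 100, seed = 1)
  expect_true(all(microsim_counts(mf, "Z", "diagnosis", "new") == 0))
})

test_that("realised microsim birth rates converge to the scenario ASFR", {
  sc <- scenario(years = 1975:1999,
                 fertility = list(tfr_start = 1.8, tfr_end = 1.8,
                                  peak_start = 28, peak_end = 28, sd = 5.5),
                 sites = list(site_scenario("X", parity_rr = 0.8,
                                            incidence = trend_spec(2e-3, 0.03),
                                            mortality = trend_spec(5e-4, 0.03))))
  surf <- generate_surfaces(sc)
  err <- sapply(c(300, 3000), function(n) {
    ms <- microsimulate(sc, n_women_per_cohort = n, seed = 4, events = "diagnosis")
    sel <- ms$birth_exposure > 0
    target <- 0.8 * surf$fertility$values
    sum(abs(ms$births[sel] / ms$birth_exposure[sel] - target[sel]) *
          ms$birth_exposure[sel]) / sum(ms$birth_exposure[sel])
  })
  expect_lt(err[2], err[1])
})

test_that("prevalent tallies reconcile with the ageing of realised new tallies", {
  # zero child mortality: every realised new child stays counted until 18
  sc <- scenario(years = 1975:1999,
                 child_mortality = list(q0 = 0, apc = 0, shape_decay = 1,
                                        shape_floor = 0),
                 sites = list(site_scenario("X", incidence = trend_spec(2e-3, 0.03),
                                            mortality = trend_spec(5e-4, 0.03))))
  ms <- microsimulate(sc, n_women_per_cohort = 400, seed = 12, events = "diagnosis")
  new <- microsim_counts(ms, "X", "diagnosis", "new", scaled = FALSE)
  prev <- microsim_counts(ms, "X", "diagnosis", "prevalent", scaled = FALSE)
  yrs <- ms$years
  for (y in c(1995, 1999)) {
    brute <- numeric(18)
    for (d in 0:17) {
      nw <- new[, match(y - d, yrs)]
      for (k in 0:(17 - d)) brute[k + d + 1L] <- brute[k + d + 1L] + nw[k + 1L]
    }
    expect_equal(prev[, match(y, yrs)], brute, ignore_attr = TRUE)
  }
  expect_true(all(prev >= new))
})

test_that("a built-in orphan mortality break survives the full pipeline", {
  # stationary fertility so the convolution transmits the mortality trend
  # unbent: APC +0.9% before 1997, -1.2% after, outputs 1968-2022
  sc <- scenario(
    years = 1951:2022,
    fertility = list(tfr_start = 1.8, tfr_end = 1.8, peak_start = 28,
                     peak_end = 28, sd = 5.5),
    child_mortality = list(q0 = 0.01, apc = 0, shape_decay = 0.9,
                           shape_floor = 0.03),
    sites = list(site_scenario("X",
                               incidence = trend_spec(2e-3, 0.05, apcs = 0),
                               mortality = trend_spec(3e-4, 0.05,
                                                      apcs = c(0.9, -1.2),
                                                      breaks = 1997L))))
  surf <- generate_surfaces(sc)
  surv <- child_survival(surf$child_mortality)
  ev <- make_events(surf$sites$X$mortality, surf$female_pop, cancer_site("X"),
                    "death")
  est <- new_affected(ev, surf$fertility, surv)
  fit <- select_changepoints(make_trend_input(est, surf$child_pop))
  expect_gte(length(fit$changepoints), 1L)
  expect_lte(min(abs(fit$changepoints - 1997)), 3L)
  last <- nrow(fit$segments)
  expect_lte(fit$segments$apc_lo[last], -1.2)
  expect_gte(fit$segments$apc_hi[last], -1.2)
})

test_that("the small fixture runs the full pipeline quickly and reproducibly", {
  sc <- fixture_small()
  surf <- generate_surfaces(sc)
  surv <- child_survival(surf$child_mortality)
  site <- cancer_site("Ovary", "C56", 0.8)
  ev <- make_events(surf$sites$Ovary$mortality, surf$female_pop, site, "death")
  est <- new_affected(ev, surf$fertility, surv)
  rs <- standardised_rate(est, surf$child_pop)
  ti <- make_trend_input(est, surf$child_pop)
  fit <- select_changepoints(ti)
  expect_s3_class(fit, "segmented_trend_fit")
  # prevalent series needs exactly the 17 warm-up years
  pv <- prevalent_affected(ev, surf$fertility, surv)
  expect_equal(pv$years[1L], sc$years[1L] + 17L)
})
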