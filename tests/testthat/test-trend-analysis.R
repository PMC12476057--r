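# deterministic piecewise log-linear count series
piecewise_counts <- function(years, level, apcs, breaks) {
  slopes <- log(1 + apcs / 100)
  bounds <- c(years[1], breaks, years[length(years)])
  seg <- pmin(pmax(findInterval(years[-1] - 1, bounds, rightmost.closed = TRUE), 1),
              length(slopes))
  level * exp(cumsum(c(0, slopes[seg])))
}

test_that("APC transform matches its closed forms", {
  expect_equal(apc_with_ci(0, 0), c(apc = 0, lo = 0, hi = 0))
  expect_equal(apc_with_ci(log(1.013), 0)[["apc"]], 1.3)
  expect_equal(apc_with_ci(log(0.988), 0)[["apc"]], -1.2)
  a <- apc_with_ci(0, 0.01)
  # symmetric around 0 in the log domain
  expect_equal(log(1 + a[["hi"]] / 100), -log(1 + a[["lo"]] / 100))
  expect_error(apc_with_ci(0, -1), "non-negative")
})

test_that("noiseless single-slope data recover their APC and select 0 changepoints", {
  years <- 1968:2022
  cnt <- round(1000 * exp(log(1.013) * (years - 1968)))
  ti <- data.frame(year = years, count = cnt, exposure = 1e5)
  f <- fit_segmented(ti, 0)
  expect_lt(abs(f$segments$apc - 1.3), 0.1)
  sel <- select_changepoints(ti)
  expect_length(sel$changepoints, 0L)
  expect_lt(abs(sel$segments$apc - 1.3), 0.1)
})

test_that("a noiseless two-segment trend recovers its changepoint (grid-search oracle)", {
  years <- 1968:2022
  cnt <- piecewise_counts(years, 500, c(3, -1), 1997)   # break at year 30 of 55
  ti <- data.frame(year = years, count = cnt, exposure = 1e5)
  f <- fit_segmented(ti, 1)
  expect_lte(abs(f$changepoints - 1997), 1)
  expect_equal(f$segments$apc, c(3, -1), tolerance = 1e-4)
  # independent oracle: profile the Poisson deviance over every break year
  oracle <- sapply(1971:2019, function(cp) {
    x <- years - 1968; h <- pmax(years - cp, 0)
    fit <- suppressWarnings(glm(cnt ~ x + h, family = quasipoisson,
                                offset = rep(log(1e5), 55)))
    ll <- sum(ifelse(cnt > 0, cnt * log(fitted(fit)), 0) - fitted(fit) - lgamma(cnt + 1))
    ll
  })
  expect_equal(f$changepoints, (1971:2019)[which.max(oracle)])
  # and BIC prefers the segmented model here
  sel <- select_changepoints(ti)
  expect_gte(length(sel$changepoints), 1L)
})

test_that("the selected fit attains the minimal BIC among candidate counts", {
  years <- 1980:2019
  set.seed(101)
  cnt <- rpois(40, piecewise_counts(years, 800, c(2, -2), 1999))
  ti <- data.frame(year = years, count = cnt, exposure = 5e4)
  sel <- select_changepoints(ti, max_changepoints = 2)
  bics <- sapply(0:2, function(nc) fit_segmented(ti, nc)$bic)
  expect_equal(sel$bic, min(bics))
})

test_that("doubling exposures with counts fixed leaves APCs unchanged", {
  years <- 1980:2019
  set.seed(7)
  cnt <- rpois(40, 600 * exp(0.01 * (0:39)))
  t1 <- data.frame(year = years, count = cnt, exposure = 1e5)
  t2 <- data.frame(year = years, count = cnt, exposure = 2e5)
  f1 <- fit_segmented(t1, 1)
  f2 <- fit_segmented(t2, 1)
  expect_equal(f1$segments$apc, f2$segments$apc, tolerance = 1e-8)
  expect_equal(f1$changepoints, f2$changepoints)
  # intercept absorbs the shift
  expect_equal(f2$coefficients[["(Intercept)"]],
               f1$coefficients[["(Intercept)"]] - log(2), tolerance = 1e-6)
})

test_that("stratified fits absorb stratum levels as additive effects", {
  years <- 1980:2019
  base <- 300 * exp(log(1.01) * (0:39))
  ti <- rbind(
    data.frame(year = years, stratum = "0-5", count = base, exposure = 1e5),
    data.frame(year = years, stratum = "6-11", count = 2 * base, exposure = 1e5),
    data.frame(year = years, stratum = "12-17", count = 4 * base, exposure = 1e5))
  f <- fit_segmented(ti, 0)
  expect_lt(abs(f$segments$apc - 1), 0.05)
  expect_equal(unname(f$coefficients["stratum6-11"]), log(2), tolerance = 1e-6)
  expect_equal(f$n, 120L)
  expect_equal(f$p, 4L)                 # intercept + slope + 2 stratum effects
})

test_that("degenerate trend inputs raise informative errors", {
  years <- 2000:2019
  ti <- data.frame(year = years, count = 0, exposure = 1e4)
  expect_error(fit_segmented(ti, 0), "all counts are zero")
  # first segment all-zero for every admissible split
  cnt <- c(rep(0, 18), 50, 60)
  ti2 <- data.frame(year = years, count = cnt, exposure = 1e4)
  expect_error(fit_segmented(ti2, 1), "unidentifiable")
  expect_error(fit_segmented(data.frame(year = 2000:2004, count = 1, exposure = 1),
                             2), "too few years")
})

test_that("BIC selection rarely overfits a single log-linear Poisson trend", {
  years <- 1968:2022
  mu <- 1000 * exp(log(1.005) * (years - 1968))
  set.seed(20220101)
  hits <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    ti <- data.frame(year = years, count = rpois(55, mu), exposure = 1e5)
    hits <- hits + (length(select_changepoints(ti)$changepoints) == 0L)
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("changepoint estimation error shrinks as counts scale up", {
  years <- 1968:2022
  set.seed(555)
  err_at_scale <- sapply(c(30, 300, 3000), function(level) {
    errs <- replicate(40, {
      cnt <- rpois(55, piecewise_counts(years, level, c(0.9, -1.2), 1997))
      f <- tryCatch(fit_segmented(data.frame(year = years, count = cnt,
                                             exposure = 1e5), 1),
                    error = function(e) NULL)
      if (is.null(f)) NA_real_ else abs(f$changepoints - 1997)
    })
    mean(errs, na.rm = TRUE)
  })
  expect_gt(err_at_scale[1], err_at_scale[3])
  expect_lte(err_at_scale[3], 1)
})
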