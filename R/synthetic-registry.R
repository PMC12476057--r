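#' Piecewise log-linear temporal trend specification
#'
#' Describes one synthetic rate component: a baseline rate at the reference
#' age, a log-linear age profile, and a piecewise log-linear calendar trend
#' given as annual percent changes per segment.
#'
#' @param base rate per person-year at the reference age in the first year.
#' @param age_slope log-linear slope per year of age (rates increase with
#'   age for adult cancers).
#' @param apcs annual percent changes, one per trend segment.
#' @param breaks calendar years where the APC changes (length
#'   `length(apcs) - 1`); the log-trend is continuous at breaks.
#' @param ref_age age at which `base` applies (default 45).
#' @return a `trend_spec` list.
#' @export
trend_spec <- function(base, age_slope = 0, apcs = 0, breaks = integer(0),
                       ref_age = 45) {
  if (length(breaks) != length(apcs) - 1L)
    stop("breaks must have one fewer element than apcs")
  if (base < 0) stop("base rate must be non-negative")
  structure(list(base = base, age_slope = age_slope, apcs = apcs,
                 breaks = as.integer(breaks), ref_age = ref_age),
            class = "trend_spec")
}

# continuous piecewise log-linear multiplier T(y), T(year_min) = 1
.trend_multiplier <- function(spec, years) {
  slopes <- log(1 + spec$apcs / 100)
  bounds <- c(years[1L], spec$breaks, years[length(years)])
  logT <- numeric(length(years))
  for (i in seq_along(years)[-1L]) {
    seg <- findInterval(years[i] - 1L, bounds, left.open = FALSE,
                        rightmost.closed = TRUE)
    seg <- min(max(seg, 1L), length(slopes))
    logT[i] <- logT[i - 1L] + slopes[seg]
  }
  exp(logT)
}

.rate_matrix <- function(spec, ages, years) {
  outer(exp(spec$age_slope * (ages - spec$ref_age)) * spec$base,
        .trend_multiplier(spec, years))
}

#' One synthetic cancer site
#'
#' @param name site label.
#' @param parity_rr parity relative risk (multiplicative, see
#'   [cancer_site()]).
#' @param incidence,mortality [trend_spec()]s for the site's incidence and
#'   cancer mortality rates (mortality must not exceed incidence anywhere).
#' @param icd10 optional ICD-10 label carried through.
#' @return a `site_scenario` list.
#' @export
site_scenario <- function(name, parity_rr = 1.0, incidence, mortality,
                          icd10 = "") {
  stopifnot(inherits(incidence, "trend_spec"), inherits(mortality, "trend_spec"))
  structure(list(name = name, parity_rr = parity_rr, icd10 = icd10,
                 incidence = incidence, mortality = mortality),
            class = "site_scenario")
}

#' Parameterise a synthetic registry world
#'
#' A `scenario` fully determines (given its seed) every input surface of the
#' estimation pipeline and the microsimulation that realises the same rates
#' as individual life histories. The defaults emulate a Nordic registry
#' setting: a Gaussian-shaped fertility schedule whose peak age drifts from
#' 27 to 31 across the period while total fertility declines from 2.6 to
#' 1.4 children per woman; cancer rates rising log-linearly with age with
#' piecewise log-linear calendar trends; child mortality starting at an
#' infant death probability of 3% and declining 4% per year; and constant
#' population counts per single-year age.
#'
#' @param years calendar years covered by all surfaces.
#' @param fertility list: `tfr_start`, `tfr_end` (total fertility at the
#'   first/last year, linear in between), `peak_start`, `peak_end` (modal
#'   maternal age, linear drift), `sd` (spread of the age schedule, years).
#' @param child_mortality list: `q0` (infant death probability in the first
#'   year), `apc` (annual percent change of all child mortality),
#'   `shape_decay`, `shape_floor` (log-decay of the age profile above age 0
#'   and its floor relative to age 0).
#' @param sites list of [site_scenario()]s.
#' @param female_pop women per (age, year) cell, constant.
#' @param child_pop children per (age, year) cell, constant.
#' @param seed default seed for [microsimulate()].
#' @return a `scenario` object.
#' @export
scenario <- function(years = 1951:2022,
                     fertility = list(tfr_start = 2.6, tfr_end = 1.4,
                                      peak_start = 27, peak_end = 31, sd = 5.5),
                     child_mortality = list(q0 = 0.03, apc = -4,
                                            shape_decay = 0.9, shape_floor = 0.03),
                     sites = list(
                       site_scenario("Breast", parity_rr = 1.0, icd10 = "C50",
                                     incidence = trend_spec(1.8e-3, 0.08, apcs = c(2.2, 1.2),
                                                            breaks = 1999L),
                                     mortality = trend_spec(4.5e-4, 0.08, apcs = c(0.5, -1.2),
                                                            breaks = 1995L)),
                       site_scenario("Ovary", parity_rr = 0.8, icd10 = "C56",
                                     incidence = trend_spec(2.5e-4, 0.09, apcs = 0),
                                     mortality = trend_spec(1.2e-4, 0.09,
                                                            apcs = c(0.9, -1.2),
                                                            breaks = 1998L))),
                     female_pop = 35000, child_pop = 30000,
                     seed = 20220101L) {
  years <- as.integer(years)
  if (any(diff(years) != 1L)) stop("scenario years must be consecutive")
  stopifnot(all(vapply(sites, inherits, logical(1), "site_scenario")))
  nm <- vapply(sites, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate site name in scenario")
  names(sites) <- nm
  structure(list(years = years, fertility = fertility,
                 child_mortality = child_mortality, sites = sites,
                 female_pop = female_pop, child_pop = child_pop,
                 seed = as.integer(seed)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> years %d-%d, %d site(s): %s; seed %d\n",
              x$years[1L], x$years[length(x$years)], length(x$sites),
              paste(names(x$sites), collapse = ", "), x$seed))
  invisible(x)
}

#' Generate the rate and population surfaces of a scenario
#'
#' Deterministic given the scenario (no sampling noise in rates). The
#' fertility surface satisfies \eqn{\sum_a f(a, y) = TFR(y)}; per-site
#' mortality is validated against incidence cell by cell; child mortality
#' probabilities stay within `[0, 1]`.
#'
#' @param sc a [scenario()].
#' @return list with elements `fertility`, `child_mortality`
#'   ([rate_surface()]s), `female_pop`, `child_pop`
#'   ([population_surface()]s), and `sites`: per site a list of `incidence`
#'   and `mortality` surfaces.
#' @export
generate_surfaces <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  yrs <- sc$years
  t01 <- if (length(yrs) > 1L) (yrs - yrs[1L]) / (yrs[length(yrs)] - yrs[1L]) else 0
  fe <- sc$fertility
  tfr <- fe$tfr_start + (fe$tfr_end - fe$tfr_start) * t01
  peak <- fe$peak_start + (fe$peak_end - fe$peak_start) * t01
  fages <- 15:49
  fvals <- vapply(seq_along(yrs), function(i) {
    w <- stats::dnorm(fages, peak[i], fe$sd)
    tfr[i] * w / sum(w)
  }, numeric(length(fages)))
  fert <- rate_surface(fvals, "fertility", fages, yrs)

  cm <- sc$child_mortality
  shape <- pmax(exp(-cm$shape_decay * (0:17)), cm$shape_floor)
  qvals <- outer(shape * cm$q0, (1 + cm$apc / 100)^(yrs - yrs[1L]))
  if (any(qvals < 0 | qvals > 1))
    stop("scenario child mortality leaves [0, 1]")
  child_mort <- rate_surface(qvals, "child_mortality", 0:17, yrs)

  sages <- 15:66
  sites <- lapply(sc$sites, function(s) {
    inc <- .rate_matrix(s$incidence, sages, yrs)
    mor <- .rate_matrix(s$mortality, sages, yrs)
    if (any(mor > inc)) {
      idx <- which(mor > inc, arr.ind = TRUE)[1L, ]
      stop(sprintf("site %s: mortality exceeds incidence at (age %d, year %d)",
                   s$name, sages[idx[1L]], yrs[idx[2L]]))
    }
    list(incidence = rate_surface(inc, "incidence", sages, yrs),
         mortality = rate_surface(mor, "mortality", sages, yrs))
  })

  list(fertility = fert,
       child_mortality = child_mort,
       female_pop = population_surface(
         matrix(sc$female_pop, length(sages), length(yrs)), sages, yrs),
       child_pop = population_surface(
         matrix(sc$child_pop, 18L, length(yrs)), 0:17, yrs),
       sites = sites)
}

#' A small end-to-end test scenario
#'
#' A 30-year, 2-site scenario sized so the full pipeline (generate ->
#' estimate -> standardise -> trends) runs in seconds; used throughout the
#' test suite. The second site's mortality trend carries a built-in
#' changepoint (APC +3% then -6% from 1992) inside the feasible output
#' years, so trend machinery is exercised end to end.
#'
#' @param seed scenario seed.
#' @return a [scenario()] spanning 1970-1999.
#' @export
fixture_small <- function(seed = 20220101L) {
  scenario(
    years = 1970:1999,
    sites = list(
      site_scenario("Breast", parity_rr = 1.0, icd10 = "C50",
                    incidence = trend_spec(1.8e-3, 0.08, apcs = 1.3),
                    mortality = trend_spec(4.5e-4, 0.08, apcs = -0.8)),
      site_scenario("Ovary", parity_rr = 0.8, icd10 = "C56",
                    incidence = trend_spec(6e-4, 0.09, apcs = 1.0),
                    mortality = trend_spec(2.5e-4, 0.09, apcs = c(3, -6),
                                           breaks = 1992L))),
    seed = seed)
}

#' Realise a scenario as individual life histories
#'
#' The independent oracle for the analytic estimators. Each simulated woman
#' experiences maternal events as independent annual Bernoulli draws with
#' probability equal to the site's event rate at her age and year (the
#' recurrent-hazard convention matching the analytic estimand
#' events = rate x population); event-experiencing women's births are annual
#' Bernoulli draws with probability `parity_rr x ASFR` (the multiplicative
#' RR convention); each child's survival is realised by exact binomial
#' thinning with the year-by-year death probabilities q. Realised new and
#' prevalent affected children are tallied per (calendar year, child age)
#' and scaled to population counts by `female_pop / n_women_per_cohort`.
#'
#' New-count tallies are complete from the 18th scenario year onwards
#' (births before the first scenario year are not simulated), matching the
#' analytic model's feasible years.
#'
#' @param sc a [scenario()].
#' @param n_women_per_cohort simulated women per birth cohort.
#' @param seed RNG seed (default the scenario's).
#' @param sites site names to simulate (default all).
#' @param events `"diagnosis"`, `"death"` or both.
#' @return a `microsim_result`: raw tallies, the population scale factor,
#'   and realised birth tallies for rate-convergence checks. Use
#'   [microsim_counts()] and [microsim_se()] to extract scaled counts and
#'   Monte-Carlo standard errors.
#' @export
microsimulate <- function(sc, n_women_per_cohort = 500L, seed = sc$seed,
                          sites = names(sc$sites),
                          events = c("diagnosis", "death")) {
  stopifnot(inherits(sc, "scenario"), n_women_per_cohort >= 1L)
  events <- match.arg(events, several.ok = TRUE)
  surf <- generate_surfaces(sc)
  yrs <- sc$years
  ny <- length(yrs)
  n <- as.integer(n_women_per_cohort)
  fmat <- matrix(0, 35L, ny)                       # ages 15:49
  fmat[, ] <- surf$fertility$values[match(15:49, surf$fertility$ages), ]
  qmat <- surf$child_mortality$values              # ages 0:17
  if (any(fmat >= 1)) stop("fertility rate >= 1/year: annual Bernoulli model invalid")
  set.seed(seed)
  tallies <- list()
  births_tally <- matrix(0, 35L, ny, dimnames = list(age = 15:49, year = yrs))
  expo_tally <- matrix(0, 35L, ny, dimnames = list(age = 15:49, year = yrs))
  for (site_name in sites) {
    s <- sc$sites[[site_name]]
    rr <- s$parity_rr
    if (any(rr * fmat >= 1)) stop("parity_rr x fertility >= 1/year")
    for (ev in events) {
      lam <- if (ev == "diagnosis") surf$sites[[site_name]]$incidence$values
             else surf$sites[[site_name]]$mortality$values   # ages 15:66
      if (any(lam >= 1)) stop("event rate >= 1/year: annual Bernoulli model invalid")
      new <- matrix(0, 18L, ny, dimnames = list(child_age = 0:17, year = yrs))
      prev <- matrix(0, 18L, ny, dimnames = list(child_age = 0:17, year = yrs))
      for (coh in (yrs[1L] - 66L):(yrs[ny] - 15L)) {
        a_all <- 15:66
        a_all <- a_all[coh + a_all >= yrs[1L] & coh + a_all <= yrs[ny]]
        if (length(a_all) == 0L) next
        m <- stats::rbinom(length(a_all), n, lam[cbind(a_all - 14L, coh + a_all - yrs[1L] + 1L)])
        for (ai in which(m > 0L)) {
          a0 <- a_all[ai]; t0 <- coh + a0; mm <- m[ai]
          ab <- seq.int(max(15L, a0 - 17L), min(49L, a0))
          ab <- ab[coh + ab >= yrs[1L]]
          if (length(ab) == 0L) next
          jb <- coh + ab - yrs[1L] + 1L
          births <- stats::rbinom(length(ab), mm, rr * fmat[cbind(ab - 14L, jb)])
          births_tally[cbind(ab - 14L, jb)] <- births_tally[cbind(ab - 14L, jb)] + births
          expo_tally[cbind(ab - 14L, jb)] <- expo_tally[cbind(ab - 14L, jb)] + mm
          k <- a0 - ab
          S <- vapply(seq_along(ab), function(i) {
            if (k[i] == 0L) return(1)
            jj <- seq.int(0L, k[i] - 1L)          # lexis diagonal of the birth cohort
            prod(1 - qmat[cbind(jj + 1L, coh + ab[i] + jj - yrs[1L] + 1L)])
          }, numeric(1))
          alive <- stats::rbinom(length(ab), births, S)
          ti <- t0 - yrs[1L] + 1L
          new[cbind(k + 1L, ti)] <- new[cbind(k + 1L, ti)] + alive
          # age the realised children forward under continued survival
          cur <- alive; kk <- k
          for (t in t0:yrs[ny]) {
            age_now <- kk + (t - t0)
            keep <- age_now <= 17L & cur > 0L
            if (!any(keep)) break
            cur <- cur[keep]; kk <- kk[keep]; age_now <- age_now[keep]
            tj <- t - yrs[1L] + 1L
            prev[cbind(age_now + 1L, tj)] <- prev[cbind(age_now + 1L, tj)] + cur
            if (t < yrs[ny])
              cur <- stats::rbinom(length(cur), cur, 1 - qmat[age_now + 1L, tj])
          }
        }
      }
      tallies[[paste(site_name, ev, sep = "|")]] <-
        list(site = site_name, event = ev, new = new, prevalent = prev)
    }
  }
  structure(list(years = yrs, n_women_per_cohort = n,
                 scale = sc$female_pop / n, tallies = tallies,
                 births = births_tally, birth_exposure = expo_tally,
                 seed = seed),
            class = "microsim_result")
}

#' Extract scaled microsimulation tallies
#'
#' @param res a `microsim_result`.
#' @param site,event,measure which tally (`measure`: `"new"` or
#'   `"prevalent"`).
#' @param scaled scale raw counts to population counts (default)?
#' @return 18 x years matrix of (scaled) realised counts.
#' @export
microsim_counts <- function(res, site, event = c("diagnosis", "death"),
                            measure = c("new", "prevalent"), scaled = TRUE) {
  event <- match.arg(event); measure <- match.arg(measure)
  key <- paste(site, event, sep = "|")
  if (is.null(res$tallies[[key]])) stop("no tally for ", key)
  m <- res$tallies[[key]][[measure]]
  if (scaled) m * res$scale else m
}

#' Monte-Carlo standard errors of scaled microsimulation tallies
#'
#' Tallies are sums of many independent Bernoulli child indicators, so the
#' raw counts are Poisson-like; the per-cell standard error of the scaled
#' count is `scale * sqrt(raw count)`.
#'
#' @inheritParams microsim_counts
#' @return 18 x years matrix of standard errors.
#' @export
microsim_se <- function(res, site, event = c("diagnosis", "death"),
                        measure = c("new", "prevalent")) {
  raw <- microsim_counts(res, site, event, measure, scaled = FALSE)
  res$scale * sqrt(pmax(raw, 1))
}

#' @export
print.microsim_result <- function(x, ...) {
  cat(sprintf("<microsim_result> years %d-%d, %d women/cohort (scale %.3g), tallies: %s\n",
              x$years[1L], x$years[length(x$years)], x$n_women_per_cohort,
              x$scale, paste(names(x$tallies), collapse = ", ")))
  invisible(x)
}
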