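#' Maternal cancer event surfaces
#'
#' An `event_surface` holds expected numbers of maternal events (cancer
#' diagnoses or cancer deaths) per (maternal age, calendar year) cell, for
#' one cancer site. The standard route is [make_events()], which multiplies a
#' site-specific rate surface by the female population at risk; a counts
#' matrix can also be supplied directly (e.g. realised microsimulation
#' tallies).
#'
#' @param counts non-negative matrix of expected event counts, ages x years.
#' @param site a [cancer_site()] (carries the parity RR applied downstream).
#' @param event `"diagnosis"` or `"death"`.
#' @param ages consecutive maternal ages, within 15-66 (the oldest mother of
#'   a child under 18 is 49 + 17 = 66).
#' @param years consecutive calendar years.
#' @return an object of class `event_surface`.
#' @export
event_surface <- function(counts, site, event = c("diagnosis", "death"),
                          ages, years) {
  event <- match.arg(event)
  stopifnot(inherits(site, "cancer_site"))
  ages <- as.integer(ages)
  years <- as.integer(years)
  if (any(ages < 15L) || any(ages > 66L))
    stop("maternal event ages must lie within 15-66")
  if (any(diff(ages) != 1L) || any(diff(years) != 1L))
    stop("ages and years must be consecutive integers")
  counts <- as.matrix(counts)
  if (nrow(counts) != length(ages) || ncol(counts) != length(years))
    stop("counts must be a ", length(ages), " x ", length(years), " matrix")
  if (anyNA(counts) || any(counts < 0)) stop("event counts must be non-negative and complete")
  dimnames(counts) <- list(age = ages, year = years)
  structure(list(site = site, event = event, ages = ages, years = years,
                 counts = counts),
            class = "event_surface")
}

#' @rdname event_surface
#' @param rates a [rate_surface()] of kind `incidence` (for diagnoses) or
#'   `mortality` (for deaths), per person-year.
#' @param female_pop a [population_surface()] of women; must cover the rate
#'   surface's ages and years.
#' @export
make_events <- function(rates, female_pop, site, event = c("diagnosis", "death")) {
  event <- match.arg(event)
  stopifnot(inherits(rates, "rate_surface"), inherits(female_pop, "population_surface"))
  if (!(rates$kind %in% c("incidence", "mortality")))
    stop("event rates must be an incidence or mortality surface")
  grid <- expand.grid(age = rates$ages, year = rates$years, KEEP.OUT.ATTRS = FALSE)
  pop <- matrix(surface_at(female_pop, grid$age, grid$year, "counts"),
                length(rates$ages), length(rates$years))
  event_surface(rates$values * pop, site = site, event = event,
                ages = rates$ages, years = rates$years)
}

#' @export
print.event_surface <- function(x, ...) {
  cat(sprintf("<event_surface: %s, %s> ages %d-%d, years %d-%d, total %.6g\n",
              x$site$name, x$event, min(x$ages), max(x$ages),
              min(x$years), max(x$years), sum(x$counts)))
  invisible(x)
}

#' Expected children under 18 of a woman with an event
#'
#' For a woman experiencing her event (diagnosis or death) at age `a` in
#' calendar year `y`, the expected number of her children aged exactly `k`
#' (0-17) at the event is
#' \deqn{rr \cdot f(a - k,\; y - k) \cdot S(k;\; y - k)}
#' where `f` is the age-specific fertility rate of the mother's cohort at the
#' child's birth, `S` the child's cohort survival to age `k`, and `rr` the
#' site's parity relative risk. Entries where the maternal age at birth
#' `a - k` falls outside the fertile range 15-49 are zero. The RR enters as a
#' single multiplicative factor, so dividing the profile by `rr` recovers the
#' unadjusted profile exactly.
#'
#' @param mother_age maternal age at the event (completed years).
#' @param event_year calendar year of the event.
#' @param fert a fertility [rate_surface()].
#' @param surv a [child_survival()] object.
#' @param rr parity relative risk (positive scalar).
#' @return numeric vector of length 18, child ages 0-17.
#' @export
expected_children_profile <- function(mother_age, event_year, fert, surv, rr = 1.0) {
  stopifnot(length(mother_age) == 1L, length(event_year) == 1L, rr > 0)
  k <- 0:17
  ba <- mother_age - k
  out <- numeric(18L)
  valid <- ba >= 15L & ba <= 49L
  if (any(valid)) {
    f <- surface_at(fert, ba[valid], event_year - k[valid])
    S <- survival_prob(surv, k[valid], event_year - k[valid])
    out[valid] <- rr * f * S
  }
  out
}

# Fertility-x-survival profile matrix for one calendar year: entry [k+1, i]
# = f(a_i - k, y - k) * S(k; y - k) for event ages a (zero outside 15-49).
# The parity RR is applied by the caller.
.profile_matrix <- function(ages, y, fert, surv) {
  k <- 0:17
  S <- survival_prob(surv, k, y - k)
  P <- matrix(0, 18L, length(ages))
  ba <- outer(-k, ages, `+`)                    # ba[k+1, i] = a_i - k
  valid <- ba >= 15L & ba <= 49L
  if (any(valid)) {
    kk <- row(ba)[valid] - 1L
    P[valid] <- surface_at(fert, ba[valid], y - kk) * S[kk + 1L]
  }
  P
}

.mother_group_levels <- c("15-24", "25-34", "35-44", "45-54", "55-66")

# completed maternal age -> the five reporting age groups
mother_age_group <- function(age) {
  cut(age, breaks = c(15, 25, 35, 45, 55, 67), right = FALSE,
      labels = .mother_group_levels)
}

# Feasible output years for the convolution given the input surfaces.
# `lookback_events` adds the 17-year event history needed for prevalence.
.feasible_years <- function(events, fert, surv, lookback_events = FALSE) {
  first <- max(events$years[1L] + if (lookback_events) 17L else 0L,
               fert$years[1L] + 17L,
               surv$q_year_min + 17L)
  last <- min(events$years[length(events$years)],
              fert$years[length(fert$years)],
              surv$q_year_max + 1L)
  if (first > last)
    stop(sprintf("input surfaces support no output year: first feasible year is %d but coverage ends %d",
                 first, last))
  first:last
}

.check_years <- function(years, feasible, measure) {
  if (is.null(years)) return(feasible)
  years <- as.integer(years)
  if (any(!(years %in% feasible)))
    stop(sprintf("requested %s year %d lies outside the feasible range %d-%d (17-year lookback of fertility%s required); first feasible output year is %d",
                 measure, years[!(years %in% feasible)][1L],
                 feasible[1L], feasible[length(feasible)],
                 if (measure == "prevalent") ", child mortality and events" else " and child mortality",
                 feasible[1L]))
  years
}

.affected_estimate <- function(counts, by_mother, site, event, measure, years, rr) {
  dimnames(counts) <- list(child_age = 0:17, year = years)
  structure(list(site = site, event = event, measure = measure,
                 years = years, rr = rr, counts = counts,
                 by_mother_age = by_mother),
            class = "affected_estimate")
}

#' @export
print.affected_estimate <- function(x, ...) {
  cat(sprintf("<affected_estimate: %s, %s, %s> years %d-%d, RR %.3g, total %.6g\n",
              x$site$name, x$measure, x$event, x$years[1L],
              x$years[length(x$years)], x$rr, sum(x$counts)))
  invisible(x)
}

#' Expected new affected children per year and child age
#'
#' Convolves maternal event counts with the fertility-survival profile of
#' [expected_children_profile()]:
#' \deqn{N(y, k) = \sum_{a=15}^{66} E(a, y)\; rr\, f(a-k, y-k)\, S(k; y-k).}
#' `N(y, k)` is the expected number of children aged `k` whose mother is
#' diagnosed with (or dies of) the site's cancer in year `y`. The estimate is
#' linear in the event surface and in fertility. Feasible output years
#' require a 17-year fertility and child-mortality lookback (e.g. fertility
#' from 1951 supports outputs from 1968).
#'
#' @param events an [event_surface()].
#' @param fert fertility [rate_surface()].
#' @param surv a [child_survival()] object.
#' @param years output years; default all feasible years.
#' @param by_mother_age if `TRUE`, also retain the maternal age dimension
#'   (five groups 15-24 ... 55-66) in `$by_mother_age`, an 18 x 5 x years
#'   array used for maternal-age-adjusted trend rates.
#' @return an `affected_estimate` with `measure = "new"`: `$counts` is an
#'   18 x years matrix of expected child counts.
#' @export
new_affected <- function(events, fert, surv, years = NULL, by_mother_age = FALSE) {
  stopifnot(inherits(events, "event_surface"))
  years <- .check_years(years, .feasible_years(events, fert, surv), "new")
  rr <- events$site$parity_rr
  counts <- matrix(0, 18L, length(years))
  bym <- if (by_mother_age)
    array(0, c(18L, 5L, length(years)),
          dimnames = list(child_age = 0:17, mother_age = .mother_group_levels,
                          year = years))
  grp <- as.integer(mother_age_group(events$ages))
  for (i in seq_along(years)) {
    y <- years[i]
    P <- rr * .profile_matrix(events$ages, y, fert, surv)
    ev <- events$counts[, match(y, events$years)]
    counts[, i] <- P %*% ev
    if (by_mother_age)
      for (g in 1:5) {
        sel <- grp == g
        if (any(sel)) bym[, g, i] <- P[, sel, drop = FALSE] %*% ev[sel]
      }
  }
  .affected_estimate(counts, bym, events$site, events$event, "new", years, rr)
}

#' Expected prevalent affected children per year and current child age
#'
#' A child aged `c` in year `y` is a prevalent affected child if the mother's
#' event occurred in any year `y - d` (`0 <= d <= c`) when the child, born in
#' year `y - c`, was already alive and under 18:
#' \deqn{P(y, c) = \sum_{d=0}^{c} \sum_{a} E(a, y-d)\; rr\,
#'   f(a - (c-d),\; y - c)\, S(c;\; y - c).}
#' Each past event thus contributes its then-under-18 children aged forward
#' `d` years under continued background child survival, retained only while
#' still under 18. Only children born on or before the event year are
#' counted; the mother's own post-event survival is not tracked.
#'
#' @inheritParams new_affected
#' @param by_mother_age if `TRUE`, retain the mother's *current* age group
#'   (age at event plus elapsed years; by construction within 15-66).
#' @return an `affected_estimate` with `measure = "prevalent"`. Feasible
#'   output years additionally require the 17 preceding event years (e.g.
#'   events from 1953 support prevalence from 1970).
#' @export
prevalent_affected <- function(events, fert, surv, years = NULL, by_mother_age = FALSE) {
  stopifnot(inherits(events, "event_surface"))
  years <- .check_years(years,
                        .feasible_years(events, fert, surv, lookback_events = TRUE),
                        "prevalent")
  rr <- events$site$parity_rr
  a <- events$ages
  counts <- matrix(0, 18L, length(years))
  bym <- if (by_mother_age)
    array(0, c(18L, 5L, length(years)),
          dimnames = list(child_age = 0:17, mother_age = .mother_group_levels,
                          year = years))
  for (i in seq_along(years)) {
    y <- years[i]
    for (cc in 0:17) {
      b <- y - cc                               # birth year of children currently aged cc
      S_c <- survival_prob(surv, cc, b)
      for (d in 0:cc) {
        k <- cc - d                             # child age at the event
        ba <- a - k                             # maternal age at birth
        sel <- ba >= 15L & ba <= 49L
        if (!any(sel)) next
        ev <- events$counts[sel, match(y - d, events$years)]
        contrib <- ev * rr * surface_at(fert, ba[sel], rep(b, sum(sel))) * S_c
        counts[cc + 1L, i] <- counts[cc + 1L, i] + sum(contrib)
        if (by_mother_age) {
          g <- as.integer(mother_age_group(a[sel] + d))   # mother's current age
          for (gg in unique(g))
            bym[cc + 1L, gg, i] <- bym[cc + 1L, gg, i] + sum(contrib[g == gg])
        }
      }
    }
  }
  .affected_estimate(counts, bym, events$site, events$event, "prevalent", years, rr)
}

#' Expected mother-child pairs by maternal age
#'
#' The expected number of (mother, child under 18) pairs with the mother aged
#' `a` in year `y`:
#' \deqn{M(a, y) = \mathrm{pop}(a, y) \sum_{k=0}^{17} f(a-k,\, y-k)\, S(k;\, y-k),}
#' aggregated to the five maternal age groups 15-24, 25-34, 35-44, 45-54 and
#' 55-66. This is the maternal-age distribution of mothers of minors, and
#' serves as the exposure for maternal-age-adjusted trend rates.
#'
#' @param fert fertility [rate_surface()].
#' @param female_pop a [population_surface()] covering ages 15-66.
#' @param surv a [child_survival()] object.
#' @param years output years; default all feasible.
#' @param keep_child_age if `TRUE`, also return the pairs disaggregated by
#'   current child age (a 52 x 18 x years array), used to build stratified
#'   trend exposures.
#' @return an object of class `mothers_of_minors`: list with `by_age`
#'   (ages 15-66 x years matrix), `by_group` (5 x years), and optionally
#'   `by_age_child`.
#' @export
mothers_of_minors <- function(fert, female_pop, surv, years = NULL,
                              keep_child_age = FALSE) {
  stopifnot(inherits(female_pop, "population_surface"))
  ages <- 15:66
  if (!all(ages %in% female_pop$ages))
    stop("female population surface must cover ages 15-66")
  pseudo <- list(years = female_pop$years)      # reuse year-feasibility logic
  feasible <- .feasible_years(pseudo, fert, surv)
  years <- .check_years(years, feasible, "new")
  by_age <- matrix(0, length(ages), length(years),
                   dimnames = list(age = ages, year = years))
  by_child <- if (keep_child_age)
    array(0, c(length(ages), 18L, length(years)),
          dimnames = list(age = ages, child_age = 0:17, year = years))
  for (i in seq_along(years)) {
    y <- years[i]
    P <- .profile_matrix(ages, y, fert, surv)   # [child age, mother age]
    pop <- surface_at(female_pop, ages, rep(y, length(ages)), "counts")
    pairs <- t(P) * pop                         # [mother age, child age]
    by_age[, i] <- rowSums(pairs)
    if (keep_child_age) by_child[, , i] <- pairs
  }
  grp <- mother_age_group(ages)
  by_group <- rowsum(by_age, grp)
  structure(list(by_age = by_age, by_group = by_group,
                 by_age_child = by_child, years = years),
            class = "mothers_of_minors")
}

#' @export
print.mothers_of_minors <- function(x, ...) {
  cat(sprintf("<mothers_of_minors> years %d-%d, mean pairs/year %.6g\n",
              x$years[1L], x$years[length(x$years)], mean(colSums(x$by_age))))
  invisible(x)
}
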