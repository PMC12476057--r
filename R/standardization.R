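#' Crude and age-standardised rates per 100,000 children
#'
#' Direct standardisation of an affected-children estimate over child age:
#' \deqn{\mathrm{ASR}(y) = 100{,}000 \sum_{k=0}^{17} w_k\,
#'   \frac{n_k(y)}{\mathrm{pop}_k(y)}, \qquad \sum_k w_k = 1,}
#' with the crude rate \eqn{100{,}000 \sum_k n_k / \sum_k \mathrm{pop}_k}.
#' Standardising with the observed population as the standard reproduces the
#' crude rate, and a uniform age-specific rate is reproduced unchanged for
#' any weights.
#'
#' @param est an `affected_estimate` (see [new_affected()]).
#' @param child_pop a [population_surface()] of children covering ages 0-17
#'   for every estimate year; all cells must be positive.
#' @param std a [standard_population_0_17()] (or any 18 positive weights over
#'   ages 0-17; weights are renormalised to sum to 1).
#' @return a `data.frame` (class `rate_series`) with columns `year`, `count`
#'   (total expected children), `crude_rate` and `std_rate` (per 100,000
#'   children), carrying `site`, `event`, `measure` attributes.
#' @export
standardised_rate <- function(est, child_pop, std = standard_population_0_17()) {
  stopifnot(inherits(est, "affected_estimate"), inherits(child_pop, "population_surface"))
  w <- as.numeric(std)
  if (length(w) != 18L || any(w <= 0)) stop("standard population must be 18 positive weights")
  w <- w / sum(w)
  grid <- expand.grid(age = 0:17, year = est$years, KEEP.OUT.ATTRS = FALSE)
  pop <- matrix(surface_at(child_pop, grid$age, grid$year, "counts"),
                18L, length(est$years))
  if (any(pop == 0)) {
    idx <- which(pop == 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("zero child population at (age %d, year %d): rate undefined",
                 idx[1L] - 1L, est$years[idx[2L]]))
  }
  out <- data.frame(
    year = est$years,
    count = colSums(est$counts),
    crude_rate = colSums(est$counts) / colSums(pop) * 1e5,
    std_rate = colSums(w * est$counts / pop) * 1e5
  )
  attr(out, "site") <- est$site$name
  attr(out, "event") <- est$event
  attr(out, "measure") <- est$measure
  class(out) <- c("rate_series", "data.frame")
  out
}

#' Period averages of a rate series
#'
#' Arithmetic means of the annual expected counts and standardised rates over
#' an inclusive calendar-year window, as used for 5-year period summaries at
#' the start and end of a study period and around trend changepoints.
#'
#' @param series a `rate_series` from [standardised_rate()].
#' @param start,end inclusive window bounds (calendar years) within the
#'   series range.
#' @return named numeric vector `c(mean_count, mean_std_rate)`.
#' @export
period_average <- function(series, start, end) {
  stopifnot(inherits(series, "data.frame"), start <= end)
  if (start < min(series$year) || end > max(series$year))
    stop(sprintf("window %d-%d outside series range %d-%d",
                 start, end, min(series$year), max(series$year)))
  sel <- series$year >= start & series$year <= end
  c(mean_count = mean(series$count[sel]),
    mean_std_rate = mean(series$std_rate[sel]))
}

#' Centred 5-year window around a changepoint
#'
#' @param changepoint_year estimated changepoint (calendar year).
#' @return integer vector `c(start, end)` = changepoint year +/- 2, the
#'   centred 5-year window used for period-average reporting (e.g. a 1996
#'   changepoint gives 1994-1998).
#' @export
changepoint_window <- function(changepoint_year) {
  c(start = as.integer(changepoint_year) - 2L,
    end = as.integer(changepoint_year) + 2L)
}

.child_group_levels <- c("0-5", "6-11", "12-17")

# completed child age -> the three 6-year reporting groups
child_age_group <- function(age) {
  cut(age, breaks = c(0, 6, 12, 18), right = FALSE, labels = .child_group_levels)
}

#' Build a trend-model input table
#'
#' Aggregates an affected-children estimate and its child-population
#' denominator into the per-(year, stratum) count/exposure table consumed by
#' [fit_segmented()]. Strata are the three 6-year child age groups 0-5, 6-11
#' and 12-17 (counts and populations summed within group); with
#' `mothers` supplied, strata are the child age group crossed with the five
#' maternal age groups, the exposure being the expected mother-child pairs,
#' for rates adjusted for the shifting age distribution of mothers.
#'
#' @param est an `affected_estimate` (computed with `by_mother_age = TRUE`
#'   when `mothers` is supplied).
#' @param child_pop a [population_surface()] covering ages 0-17.
#' @param mothers optional [mothers_of_minors()] result computed with
#'   `keep_child_age = TRUE`, for maternal-age-adjusted rates.
#' @return a `data.frame` with columns `year`, `stratum` (factor), `count`,
#'   `exposure`; attribute `adjustment` is `"none"` or `"mother_age"`.
#' @export
make_trend_input <- function(est, child_pop, mothers = NULL) {
  stopifnot(inherits(est, "affected_estimate"))
  cg <- child_age_group(0:17)
  if (is.null(mothers)) {
    grid <- expand.grid(age = 0:17, year = est$years, KEEP.OUT.ATTRS = FALSE)
    pop <- matrix(surface_at(child_pop, grid$age, grid$year, "counts"),
                  18L, length(est$years))
    cnt <- rowsum(est$counts, cg)
    expo <- rowsum(pop, cg)
    out <- data.frame(
      year = rep(est$years, each = nlevels(cg)),
      stratum = factor(rep(levels(cg), length(est$years)), levels = levels(cg)),
      count = as.vector(cnt), exposure = as.vector(expo)
    )
    attr(out, "adjustment") <- "none"
  } else {
    stopifnot(inherits(mothers, "mothers_of_minors"))
    if (is.null(est$by_mother_age))
      stop("maternal-age adjustment needs an estimate computed with by_mother_age = TRUE")
    if (is.null(mothers$by_age_child))
      stop("maternal-age adjustment needs mothers_of_minors(keep_child_age = TRUE)")
    yrs <- intersect(est$years, mothers$years)
    if (length(yrs) == 0L) stop("estimate and mothers_of_minors share no years")
    mg <- mother_age_group(15:66)
    strata <- as.vector(outer(levels(cg), .mother_group_levels, paste, sep = " x "))
    rows <- list()
    for (i in seq_along(yrs)) {
      y <- yrs[i]
      cnt3x5 <- rowsum(est$by_mother_age[, , match(y, est$years)], cg)   # child grp x mother grp
      pairs <- mothers$by_age_child[, , match(y, mothers$years)]         # mother age x child age
      expo3x5 <- t(rowsum(t(rowsum(pairs, mg)), cg))                     # mother grp x child grp
      rows[[i]] <- data.frame(
        year = y,
        stratum = factor(as.vector(outer(levels(cg), .mother_group_levels,
                                         paste, sep = " x ")), levels = strata),
        count = as.vector(cnt3x5),
        exposure = as.vector(t(expo3x5))
      )
    }
    out <- do.call(rbind, rows)
    # drop empty strata (no mother-child pairs): rates undefined there
    keep <- tapply(out$exposure, out$stratum, sum) > 0
    out <- out[out$stratum %in% names(keep)[keep], ]
    out$stratum <- droplevels(out$stratum)
    attr(out, "adjustment") <- "mother_age"
  }
  if (any(out$exposure <= 0)) stop("trend exposure must be positive in every stratum-year")
  out
}
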