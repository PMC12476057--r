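#' Cohort child survival from an annual death-probability surface
#'
#' Converts a `child_mortality` rate surface (annual probabilities q(age,
#' year) of dying during the age-year) into cumulative cohort survival
#' probabilities read along lexis diagonals:
#' \deqn{S(k; b) = \prod_{j=0}^{k-1} (1 - q(j, b + j)),\qquad S(0; b) = 1,}
#' the probability that a child born in calendar year `b` survives to
#' completed age `k`.
#'
#' @param child_mort a [rate_surface()] of kind `child_mortality` covering
#'   ages 0-17.
#' @return an object of class `child_survival` with matrix `S` (rows = ages
#'   0-17, columns = birth years). Diagonals that leave the surface's year
#'   range are `NA`; accessing them through [survival_prob()] is an error
#'   naming the missing cell.
#' @export
child_survival <- function(child_mort) {
  stopifnot(inherits(child_mort, "rate_surface"))
  if (child_mort$kind != "child_mortality")
    stop("child_survival() needs a surface of kind 'child_mortality'")
  if (!all(0:17 %in% child_mort$ages))
    stop("child mortality surface must cover ages 0-17")
  q <- child_mort$values[match(0:17, child_mort$ages), , drop = FALSE]
  years <- child_mort$years
  nb <- length(years)
  S <- matrix(NA_real_, 18L, nb, dimnames = list(age = 0:17, birth_year = years))
  S[1L, ] <- 1                                  # S(0; b) = 1 for any birth year
  for (k in 1:17) {
    if (nb - k + 1L < 1L) break                 # surface narrower than the diagonal
    # surviving age k-1 during year b + k - 1
    j <- seq_len(nb - k + 1L)                   # birth-year columns with q(k-1, b+k-1) in range
    S[k + 1L, j] <- S[k, j] * (1 - q[k, j + k - 1L])
  }
  structure(list(S = S, birth_years = years,
                 q_year_min = years[1L], q_year_max = years[nb]),
            class = "child_survival")
}

#' Look up cohort survival probabilities
#'
#' @param surv a [child_survival()] object.
#' @param k completed child age(s), 0-17.
#' @param birth_year birth cohort year(s); recycled against `k`.
#' @return numeric vector of survival probabilities S(k; birth_year).
#' @export
survival_prob <- function(surv, k, birth_year) {
  n <- max(length(k), length(birth_year))
  k <- rep_len(as.integer(k), n)
  birth_year <- rep_len(as.integer(birth_year), n)
  if (any(k < 0L | k > 17L)) stop("child age must be within 0-17")
  out <- rep(NA_real_, n)
  out[k == 0L] <- 1                             # no survival factor needed
  pos <- k > 0L
  if (any(pos)) {
    j <- birth_year[pos] - surv$birth_years[1L] + 1L
    ok <- j >= 1L & j <= length(surv$birth_years)
    if (!all(ok)) {
      b <- which(pos)[which(!ok)[1L]]
      stop(sprintf("required cell (age 0, year %d) is outside the child mortality surface (years %d-%d)",
                   birth_year[b], surv$q_year_min, surv$q_year_max))
    }
    out[pos] <- surv$S[cbind(k[pos] + 1L, j)]
  }
  if (anyNA(out)) {
    b <- which(is.na(out))[1L]
    miss_age <- surv$q_year_max + 1L - birth_year[b]   # first year off the surface
    stop(sprintf("cohort diagonal leaves the child mortality surface: missing (age %d, year %d)",
                 miss_age, surv$q_year_max + 1L))
  }
  out
}

#' @export
print.child_survival <- function(x, ...) {
  cat(sprintf("<child_survival> birth cohorts %d-%d (q years %d-%d)\n",
              x$birth_years[1L], x$birth_years[length(x$birth_years)],
              x$q_year_min, x$q_year_max))
  invisible(x)
}
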