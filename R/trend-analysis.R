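#' Annual percent change from a log-linear slope
#'
#' @param beta slope per calendar year on the log scale.
#' @param se standard error of `beta` (non-negative).
#' @param z normal quantile for the confidence level (1.96 for 95%).
#' @return named vector `c(apc, lo, hi)`: `APC = 100 (e^beta - 1)` with the
#'   Wald interval `100 (e^{beta +/- z se} - 1)`.
#' @examples
#' apc_with_ci(log(1.013), 0)   # APC 1.3
#' @export
apc_with_ci <- function(beta, se, z = 1.96) {
  if (any(se < 0)) stop("standard error must be non-negative")
  c(apc = 100 * (exp(beta) - 1),
    lo = 100 * (exp(beta - z * se) - 1),
    hi = 100 * (exp(beta + z * se) - 1))
}

# Piecewise-linear (continuous) design in calendar year: intercept, centred
# year, one hinge max(year - cp, 0) per changepoint, then stratum dummies.
.segment_design <- function(year, stratum, cps, year_ref) {
  X <- cbind(`(Intercept)` = 1, x = year - year_ref)
  for (cp in cps) X <- cbind(X, pmax(year - cp, 0))
  if (length(cps)) colnames(X)[2L + seq_along(cps)] <- paste0("hinge", seq_along(cps))
  if (!is.null(stratum) && nlevels(stratum) > 1L) {
    D <- stats::model.matrix(~stratum)[, -1L, drop = FALSE]
    colnames(D) <- paste0("stratum", levels(stratum)[-1L])
    X <- cbind(X, D)
  }
  X
}

# Poisson log-likelihood at real-valued responses (continuous extension);
# the lgamma(y+1) term is constant across candidate models on fixed data.
.pois_loglik <- function(y, mu) {
  sum(ifelse(y > 0, y * log(mu), 0) - mu - lgamma(y + 1))
}

# One Poisson GLM at fixed changepoints. quasipoisson() fits the identical
# MLE without non-integer warnings (responses are model-based expectations);
# the covariance is rescaled to dispersion 1 (plain Poisson) unless
# overdispersion inflation is requested.
.fit_at <- function(y, X, off, quasi = FALSE) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, offset = off, family = stats::quasipoisson())
  )
  ll <- .pois_loglik(y, fit$fitted.values)
  list(fit = fit, loglik = ll)
}

# Profile log-likelihood only, via bare IRLS on .lm.fit: the exhaustive
# changepoint search evaluates ~10^3 candidate designs, where glm.fit's
# bookkeeping dominates. Identical maximum to .fit_at (same IRLS updates).
.profile_loglik <- function(y, X, off, tol = 1e-9, maxit = 30L) {
  eta <- log(pmax(y, 0.1)) - off
  ll_old <- -Inf
  for (it in seq_len(maxit)) {
    mu <- exp(eta + off)
    w <- sqrt(mu)
    z <- eta + (y - mu) / mu
    cf <- .lm.fit(X * w, z * w)$coefficients
    eta <- drop(X %*% cf)
    ll <- .pois_loglik(y, exp(eta + off))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) return(ll)
    ll_old <- ll
  }
  ll_old
}

.glm_vcov <- function(fit, dispersion = 1) {
  p1 <- seq_len(fit$rank)
  piv <- fit$qr$pivot[p1]
  cov <- chol2inv(qr.R(fit$qr)[p1, p1, drop = FALSE])
  out <- matrix(NA_real_, ncol(fit$qr$qr), ncol(fit$qr$qr))
  out[piv, piv] <- cov * dispersion
  dimnames(out) <- list(colnames(fit$qr$qr), colnames(fit$qr$qr))
  out
}

# candidate changepoint sets for ncp in {0,1,2}: integer years, each segment
# spanning >= min_segment years, changepoints >= min_segment years apart
.cp_candidates <- function(years, ncp, min_segment) {
  y0 <- years[1L]; y1 <- years[length(years)]
  if (ncp == 0L) return(list(integer(0)))
  inner <- seq.int(y0 + min_segment, y1 - min_segment)
  if (length(inner) == 0L || inner[1L] > inner[length(inner)]) return(list())
  if (ncp == 1L) return(lapply(inner, identity))
  out <- list()
  for (c1 in inner) {
    c2s <- inner[inner >= c1 + min_segment]
    for (c2 in c2s) out[[length(out) + 1L]] <- c(c1, c2)
  }
  out
}

# TRUE if some segment has zero total count (log-scale slope unidentifiable)
.zero_segment <- function(input, cps, years) {
  bounds <- c(years[1L] - 1L, cps, years[length(years)])
  seg <- findInterval(input$year, bounds, left.open = TRUE)
  any(tapply(input$count, factor(seg, levels = seq_len(length(bounds) - 1L)), sum,
             default = 0) == 0)
}

.zero_segment_name <- function(input, cps, years) {
  bounds <- c(years[1L] - 1L, cps, years[length(years)])
  seg <- findInterval(input$year, bounds, left.open = TRUE)
  tot <- tapply(input$count, factor(seg, levels = seq_len(length(bounds) - 1L)), sum,
                default = 0)
  i <- which(tot == 0)[1L]
  sprintf("%d-%d", bounds[i] + 1L, bounds[i + 1L])
}

#' Fit a segmented log-linear Poisson trend
#'
#' Maximises the Poisson log-likelihood of a continuous piecewise-linear
#' predictor in calendar year on the log scale,
#' \deqn{\log \mu_{ys} = \alpha + \beta_1 (y - y_0) + \sum_j \gamma_j
#'   (y - c_j)_+ + \delta_s + \log E_{ys},}
#' with log-exposure offset and additive stratum effects. Changepoints
#' \eqn{c_j} are chosen by exhaustive search over integer candidate years
#' (each segment spanning at least `min_segment` years) -- a reproducible
#' global argmin rather than an iterative local search. Segment slopes are
#' reported as annual percent changes, \eqn{APC = 100(e^{\beta}-1)}, with
#' 95% Wald confidence intervals on the log scale.
#'
#' Responses may be non-integer (model-based expected counts); the same
#' log-likelihood expression is evaluated at real values. BIC is
#' \eqn{-2\log L + p \log n} with `p` counting intercept, slopes,
#' changepoint locations and stratum effects.
#'
#' @param input data.frame with columns `year`, `count`, `exposure` and
#'   optionally `stratum` (see [make_trend_input()]).
#' @param n_changepoints number of changepoints to fit (0, 1 or 2).
#' @param min_segment minimum years spanned by each segment (default 3).
#' @param quasi if `TRUE`, inflate standard errors by the Pearson
#'   overdispersion estimate (off by default: plain Poisson likelihood).
#' @param changepoints optionally, fixed changepoint years: skips the search
#'   and fits the piecewise trend at these locations (overrides
#'   `n_changepoints`). Wald CIs are then conditional on known breakpoints.
#' @return an object of class `segmented_trend_fit`: changepoint years,
#'   per-segment slope/APC/CI table, log-likelihood, BIC, and metadata.
#' @export
fit_segmented <- function(input, n_changepoints = 0L, min_segment = 3L,
                          quasi = FALSE, changepoints = NULL) {
  input <- .check_trend_input(input)
  years <- sort(unique(input$year))
  if (!is.null(changepoints)) {
    cps <- sort(as.integer(changepoints))
    if (length(cps) &&
        (cps[1L] < years[1L] + min_segment ||
         cps[length(cps)] > years[length(years)] - min_segment ||
         any(diff(cps) < min_segment)))
      stop("fixed changepoints violate the minimum segment length")
    if (.zero_segment(input, cps, years))
      stop(sprintf("segment %s has all-zero counts: slope unidentifiable",
                   .zero_segment_name(input, cps, years)))
    return(.finalise_fit(input, cps, years, min_segment, quasi))
  }
  ncp <- as.integer(n_changepoints)
  if (!(ncp %in% 0:2)) stop("n_changepoints must be 0, 1 or 2")
  span <- years[length(years)] - years[1L]
  if (span < (ncp + 1L) * min_segment)
    stop(sprintf("too few years (%d spanned) for %d changepoint(s) with minimum segment length %d",
                 span, ncp, min_segment))
  if (sum(input$count) == 0) stop("all counts are zero: trend not estimable")
  cands <- .cp_candidates(years, ncp, min_segment)
  if (length(cands) == 0L)
    stop("no admissible changepoint candidates for the given year range")
  off <- log(input$exposure)
  strat <- if (is.null(input$stratum)) NULL else input$stratum
  # cumulative year totals make the all-zero-segment screen O(ncp) per candidate
  ytot <- rowsum(input$count, factor(input$year, levels = years))[, 1L]
  ycum <- c(0, cumsum(ytot))
  seg_zero <- function(cps) {
    idx <- c(0L, findInterval(cps, years), length(years))
    any(diff(ycum[idx + 1L]) == 0)
  }
  best <- NULL
  for (cps in cands) {
    if (ncp > 0L && seg_zero(cps)) next
    X <- .segment_design(input$year, strat, cps, years[1L])
    ll <- .profile_loglik(input$count, X, off)
    if (is.null(best) || ll > best$loglik)
      best <- list(cps = cps, loglik = ll)
  }
  if (is.null(best)) {
    bad <- .zero_segment_name(input, cands[[1L]], years)
    stop(sprintf("segment %s has all-zero counts in every admissible split: slope unidentifiable",
                 bad))
  }
  if (ncp == 0L && .zero_segment(input, integer(0), years))
    stop(sprintf("segment %s has all-zero counts: slope unidentifiable",
                 .zero_segment_name(input, integer(0), years)))
  .finalise_fit(input, best$cps, years, min_segment, quasi)
}

.check_trend_input <- function(input) {
  stopifnot(is.data.frame(input), all(c("year", "count", "exposure") %in% names(input)))
  if (any(input$count < 0)) stop("trend counts must be non-negative")
  if (any(input$exposure <= 0)) stop("trend exposures must be positive")
  if (!is.null(input$stratum)) input$stratum <- droplevels(factor(input$stratum))
  input
}

.finalise_fit <- function(input, cps, years, min_segment, quasi) {
  strat <- if (is.null(input$stratum)) NULL else input$stratum
  X <- .segment_design(input$year, strat, cps, years[1L])
  f <- .fit_at(input$count, X, log(input$exposure))
  fit <- f$fit
  dispersion <- 1
  if (quasi) {
    pr <- (input$count - fit$fitted.values) / sqrt(fit$fitted.values)
    dispersion <- max(1, sum(pr^2) / fit$df.residual)
  }
  V <- .glm_vcov(fit, dispersion)
  cf <- fit$coefficients
  ncp <- length(cps)
  n_strat <- if (is.null(strat)) 1L else nlevels(strat)
  p <- 1L + (ncp + 1L) + ncp + (n_strat - 1L)
  n <- nrow(input)
  bounds <- c(years[1L], cps, years[length(years)])
  segs <- data.frame(start = bounds[-length(bounds)], end = bounds[-1L])
  slope_cols <- c("x", if (ncp) paste0("hinge", seq_len(ncp)))
  segs$slope <- segs$se <- segs$apc <- segs$apc_lo <- segs$apc_hi <- NA_real_
  for (j in seq_len(ncp + 1L)) {
    sel <- slope_cols[seq_len(j)]
    segs$slope[j] <- sum(cf[sel])
    segs$se[j] <- sqrt(sum(V[sel, sel]))
    a <- apc_with_ci(segs$slope[j], segs$se[j])
    segs$apc[j] <- a[["apc"]]; segs$apc_lo[j] <- a[["lo"]]; segs$apc_hi[j] <- a[["hi"]]
  }
  structure(list(
    changepoints = cps,
    segments = segs[, c("start", "end", "slope", "se", "apc", "apc_lo", "apc_hi")],
    coefficients = cf, vcov = V,
    loglik = f$loglik, bic = -2 * f$loglik + p * log(n),
    n = n, p = p, min_segment = min_segment,
    adjustment = attr(input, "adjustment") %||% "none",
    quasi = quasi, dispersion = dispersion,
    years = c(years[1L], years[length(years)])
  ), class = "segmented_trend_fit")
}

#' Select the number of changepoints by BIC
#'
#' Fits segmented Poisson trends with 0, 1 and up to `max_changepoints`
#' changepoints ([fit_segmented()]) and returns the fit minimising
#' \eqn{BIC = -2\log L + p\log n}. Ties favour the simpler model.
#'
#' @inheritParams fit_segmented
#' @param max_changepoints maximum changepoints considered (default 2).
#' @return the BIC-minimising `segmented_trend_fit`.
#' @export
select_changepoints <- function(input, max_changepoints = 2L, min_segment = 3L,
                                quasi = FALSE) {
  input <- .check_trend_input(input)
  years <- sort(unique(input$year))
  span <- years[length(years)] - years[1L]
  best <- NULL
  for (ncp in 0:max_changepoints) {
    if (span < (ncp + 1L) * min_segment) break
    f <- tryCatch(fit_segmented(input, ncp, min_segment, quasi),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$bic < best$bic)) best <- f
  }
  if (is.null(best)) stop("no segmented trend model could be fitted")
  best
}

#' @export
print.segmented_trend_fit <- function(x, ...) {
  cat(sprintf("<segmented_trend_fit> years %d-%d, %d changepoint(s)%s, BIC %.2f, adjustment: %s\n",
              x$years[1L], x$years[2L], length(x$changepoints),
              if (length(x$changepoints)) paste0(" at ", paste(x$changepoints, collapse = ", ")) else "",
              x$bic, x$adjustment))
  s <- x$segments
  for (j in seq_len(nrow(s)))
    cat(sprintf("  %d-%d: APC %+.2f%% (95%% CI %+.2f to %+.2f)\n",
                s$start[j], s$end[j], s$apc[j], s$apc_lo[j], s$apc_hi[j]))
  invisible(x)
}

#' Tidy the segment table of a trend fit
#'
#' @param fit a `segmented_trend_fit`.
#' @return data.frame with one row per changepoint section: `start`, `end`,
#'   `apc`, `apc_lo`, `apc_hi`, `adjustment`.
#' @export
trend_table <- function(fit) {
  stopifnot(inherits(fit, "segmented_trend_fit"))
  out <- fit$segments[, c("start", "end", "apc", "apc_lo", "apc_hi")]
  out$adjustment <- fit$adjustment
  out
}
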