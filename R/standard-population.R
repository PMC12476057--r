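#' World Standard Population 2000 weights for child ages 0-17
#'
#' One-year age weights for direct standardisation of child rates, taken from
#' the WHO World Standard Population (Ahmad et al. 2001, "Age standardization
#' of rates: a new WHO standard", GPE Discussion Paper No. 31). The WHO
#' standard is published in 5-year groups (per 100: ages 0-4 = 8.86,
#' 5-9 = 8.69, 10-14 = 8.60, 15-19 = 8.47); each group is split uniformly
#' into 1-year ages and the ages 0-17 slice is renormalised to sum to 1.
#'
#' @return an object of class `standard_population`: a named numeric vector
#'   of 18 positive weights (ages `0` through `17`) summing to exactly 1 and
#'   non-increasing with age.
#' @examples
#' w <- standard_population_0_17()
#' sum(w)   # 1
#' @export
standard_population_0_17 <- function() {
  per5 <- c(8.86, 8.69, 8.60, 8.47)                 # WHO 2000 std, % per 5-year group
  w <- rep(per5 / 5, times = c(5L, 5L, 5L, 5L))[1:18]
  w <- w / sum(w)
  names(w) <- 0:17
  structure(w, class = "standard_population")
}

#' @export
print.standard_population <- function(x, ...) {
  cat("<standard_population> ages 0-17, weights sum", format(sum(x)), "\n")
  print(round(unclass(x), 5))
  invisible(x)
}
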