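# Shared toy-world builders for the unit tests.

flat_fertility <- function(rate = 0.1, years = 1950:2010) {
  rate_surface(matrix(rate, 35L, length(years)), "fertility", 15:49, years)
}

flat_child_mortality <- function(q = 0, years = 1950:2010) {
  rate_surface(matrix(q, 18L, length(years)), "child_mortality", 0:17, years)
}

flat_female_pop <- function(n = 1000, years = 1950:2010) {
  population_surface(matrix(n, 52L, length(years)), 15:66, years)
}

flat_child_pop <- function(n = 1000, years = 1950:2010) {
  population_surface(matrix(n, 18L, length(years)), 0:17, years)
}

# single-cell event surface: one expected event at (age, year)
single_event <- function(age, year, site = cancer_site("X"),
                         event = "diagnosis", years = 1950:2010) {
  m <- matrix(0, 52L, length(years))
  m[age - 14L, match(year, years)] <- 1
  event_surface(m, site, event, 15:66, years)
}

# random small positive rate surface, reproducible
random_surface <- function(kind, ages, years, max_rate = 0.05, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::runif(length(ages) * length(years), 0, max_rate),
              length(ages), length(years))
  rate_surface(m, kind, ages, years)
}
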