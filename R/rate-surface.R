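#' Rate surfaces indexed by age and calendar year
#'
#' A `rate_surface` holds per-person-year rates on a dense rectangle of
#' completed ages x calendar years. It is the universal input object of the
#' estimation pipeline: age-specific fertility rates (ASFR, ages 15-49),
#' female cancer incidence and cancer mortality rates (ages 15-66), and
#' annual child death probabilities (ages 0-17).
#'
#' @param values numeric matrix, `length(ages)` rows by `length(years)`
#'   columns; rates per person-year (for `kind = "child_mortality"`, annual
#'   probabilities of death in `[0, 1]`).
#' @param kind one of `"fertility"`, `"incidence"`, `"mortality"`,
#'   `"child_mortality"`.
#' @param ages integer vector of consecutive completed ages (rows).
#' @param years integer vector of consecutive calendar years (columns).
#'
#' @details Kind-specific invariants are enforced at construction: all rates
#'   are non-negative; fertility is zero outside ages 15-49; child mortality
#'   values are annual death probabilities q(age, year) in `[0, 1]` (callers
#'   holding central death rates m must convert with `q = 1 - exp(-m)`
#'   themselves -- the constructor does not convert).
#'
#' @return an object of class `rate_surface`.
#' @seealso [read_rate_surface()], [population_surface()]
#' @export
rate_surface <- function(values, kind, ages, years) {
  kind <- match.arg(kind, c("fertility", "incidence", "mortality", "child_mortality"))
  ages <- as.integer(ages)
  years <- as.integer(years)
  if (any(diff(ages) != 1L)) stop("ages must be consecutive integers")
  if (any(diff(years) != 1L)) stop("years must be consecutive integers")
  values <- as.matrix(values)
  if (nrow(values) != length(ages) || ncol(values) != length(years))
    stop("values must be a ", length(ages), " x ", length(years), " matrix")
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing rate at (age %d, year %d)", ages[idx[1L]], years[idx[2L]]))
  }
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative rate at (age %d, year %d)", ages[idx[1L]], years[idx[2L]]))
  }
  if (kind == "fertility") {
    outside <- ages < 15L | ages > 49L
    if (any(values[outside, , drop = FALSE] != 0)) {
      bad <- which(values[outside, , drop = FALSE] != 0, arr.ind = TRUE)[1L, ]
      stop(sprintf("fertility must be zero outside ages 15-49; nonzero at (age %d, year %d)",
                   ages[outside][bad[1L]], years[bad[2L]]))
    }
  }
  if (kind == "child_mortality" && any(values > 1)) {
    idx <- which(values > 1, arr.ind = TRUE)[1L, ]
    stop(sprintf("child mortality probability > 1 at (age %d, year %d)",
                 ages[idx[1L]], years[idx[2L]]))
  }
  dimnames(values) <- list(age = ages, year = years)
  structure(
    list(kind = kind, ages = ages, years = years, values = values),
    class = "rate_surface"
  )
}

#' Population count surfaces
#'
#' Person counts per (completed age, calendar year) cell; used as the female
#' population at risk (to turn rates into expected event counts) and as the
#' child population denominator of rates per 100,000 children.
#'
#' @param counts numeric matrix of non-negative person counts.
#' @param ages,years consecutive integer axes, as in [rate_surface()].
#' @return an object of class `population_surface`.
#' @export
population_surface <- function(counts, ages, years) {
  ages <- as.integer(ages)
  years <- as.integer(years)
  if (any(diff(ages) != 1L)) stop("ages must be consecutive integers")
  if (any(diff(years) != 1L)) stop("years must be consecutive integers")
  counts <- as.matrix(counts)
  if (nrow(counts) != length(ages) || ncol(counts) != length(years))
    stop("counts must be a ", length(ages), " x ", length(years), " matrix")
  if (anyNA(counts) || any(counts < 0)) stop("population counts must be non-negative and complete")
  dimnames(counts) <- list(age = ages, year = years)
  structure(
    list(ages = ages, years = years, counts = counts),
    class = "population_surface"
  )
}

#' @export
print.rate_surface <- function(x, ...) {
  cat(sprintf("<rate_surface: %s> ages %d-%d, years %d-%d, mean rate %.4g\n",
              x$kind, min(x$ages), max(x$ages), min(x$years), max(x$years),
              mean(x$values)))
  invisible(x)
}

#' @export
print.population_surface <- function(x, ...) {
  cat(sprintf("<population_surface> ages %d-%d, years %d-%d, total %.6g\n",
              min(x$ages), max(x$ages), min(x$years), max(x$years), sum(x$counts)))
  invisible(x)
}

# Cell lookup with an informative error when (age, year) leaves the rectangle.
surface_at <- function(s, age, year, what = c("values", "counts")) {
  what <- match.arg(what)
  i <- age - s$ages[1L] + 1L
  j <- year - s$years[1L] + 1L
  bad <- i < 1L | i > length(s$ages) | j < 1L | j > length(s$years)
  if (any(bad)) {
    b <- which(bad)[1L]
    stop(sprintf("required cell (age %d, year %d) is outside the surface (ages %d-%d, years %d-%d)",
                 age[b], year[b], s$ages[1L], s$ages[length(s$ages)],
                 s$years[1L], s$years[length(s$years)]))
  }
  s[[what]][cbind(i, j)]
}

#' Read a rate table from delimited text
#'
#' Reads a comma-delimited table with header columns `age,year,rate` (one row
#' per cell) and returns a dense [rate_surface()] over the bounding rectangle
#' of the ages and years present. Every cell inside the rectangle must be
#' present exactly once; the declared `kind`'s invariants are enforced.
#'
#' @param path path to a CSV file with columns `age`, `year`, `rate`.
#' @param kind surface kind, see [rate_surface()].
#' @return a `rate_surface`.
#' @export
read_rate_surface <- function(path, kind) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "year", "rate")
  if (!all(need %in% names(tab)))
    stop("rate table must have header columns age, year, rate: ", path)
  rate_surface(.table_to_matrix(tab, "rate", path), kind = kind,
               ages = seq.int(min(tab$age), max(tab$age)),
               years = seq.int(min(tab$year), max(tab$year)))
}

#' Read a population table from delimited text
#'
#' @param path path to a CSV file with columns `age`, `year`, `count`.
#' @return a `population_surface`.
#' @rdname read_rate_surface
#' @export
read_population_surface <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "year", "count")
  if (!all(need %in% names(tab)))
    stop("population table must have header columns age, year, count: ", path)
  population_surface(.table_to_matrix(tab, "count", path),
                     ages = seq.int(min(tab$age), max(tab$age)),
                     years = seq.int(min(tab$year), max(tab$year)))
}

# Long (age, year, value) rows -> dense matrix over the bounding rectangle,
# erroring on duplicate or missing cells (named in the message).
.table_to_matrix <- function(tab, value_col, path) {
  if (nrow(tab) == 0L) stop("empty table: ", path)
  if (anyNA(tab$age) || anyNA(tab$year) || anyNA(tab[[value_col]]))
    stop("table contains missing values: ", path)
  ages <- seq.int(min(tab$age), max(tab$age))
  years <- seq.int(min(tab$year), max(tab$year))
  m <- matrix(NA_real_, length(ages), length(years))
  i <- tab$age - ages[1L] + 1L
  j <- tab$year - years[1L] + 1L
  if (anyDuplicated(cbind(i, j))) {
    d <- which(duplicated(cbind(i, j)))[1L]
    stop(sprintf("duplicate cell (age %d, year %d) in %s", tab$age[d], tab$year[d], path))
  }
  m[cbind(i, j)] <- tab[[value_col]]
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("incomplete rectangle in %s: missing (age %d, year %d)",
                 path, ages[idx[1L]], years[idx[2L]]))
  }
  m
}

#' Write a surface to delimited text
#'
#' Writes the long `age,year,rate` (or `age,year,count`) form read back by
#' [read_rate_surface()] / [read_population_surface()]; read-write-read is
#' the identity on valid tables.
#'
#' @param s a `rate_surface` or `population_surface`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rate_surface <- function(s, path) {
  stopifnot(inherits(s, "rate_surface"))
  df <- expand.grid(age = s$ages, year = s$years, KEEP.OUT.ATTRS = FALSE)
  df$rate <- as.vector(s$values)
  utils::write.csv(df[order(df$age, df$year), ], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rate_surface
#' @export
write_population_surface <- function(s, path) {
  stopifnot(inherits(s, "population_surface"))
  df <- expand.grid(age = s$ages, year = s$years, KEEP.OUT.ATTRS = FALSE)
  df$count <- as.vector(s$counts)
  utils::write.csv(df[order(df$age, df$year), ], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
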