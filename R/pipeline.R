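#' Configure a pipeline run
#'
#' Bundles everything a pipeline stage needs: either a [scenario()] (the
#' synthetic-registry route) or a set of input table paths, the site panel,
#' output directory, and trend options.
#'
#' @param outdir output directory (created if missing).
#' @param scenario a [scenario()], or `NULL` when reading tables from disk.
#' @param inputs when `scenario` is `NULL`: a list with paths `fertility`,
#'   `child_mortality`, `female_pop`, `child_pop`, and `sites` -- a named
#'   list of `list(incidence = path, mortality = path)` per site.
#' @param site_config optional path to a YAML site config supplying parity
#'   RRs for path-based inputs (default: the shipped [default_panel()]).
#' @param sites site names to process (default all available).
#' @param events,measures subsets of diagnosis/death and new/prevalent.
#' @param adjustments trend adjustments to run: subset of `"none"`,
#'   `"mother_age"`.
#' @param max_changepoints,min_segment trend options, see
#'   [select_changepoints()].
#' @param seed seed recorded in the manifest and used for any simulation.
#' @return a `run_config` list.
#' @export
run_config <- function(outdir, scenario = NULL, inputs = NULL,
                       site_config = NULL, sites = NULL,
                       events = c("diagnosis", "death"),
                       measures = c("new", "prevalent"),
                       adjustments = c("none", "mother_age"),
                       max_changepoints = 2L, min_segment = 3L,
                       seed = 20220101L) {
  if (is.null(scenario) && is.null(inputs))
    stop("run_config needs either a scenario or input table paths")
  if (!is.null(inputs)) {
    paths <- c(inputs$fertility, inputs$child_mortality, inputs$female_pop,
               inputs$child_pop, unlist(inputs$sites, use.names = FALSE))
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("input stage: missing input file(s): ", paste(missing, collapse = ", "))
  }
  if (!is.null(site_config) && !file.exists(site_config))
    stop("input stage: site config not found: ", site_config)
  events <- match.arg(events, several.ok = TRUE)
  measures <- match.arg(measures, several.ok = TRUE)
  adjustments <- match.arg(adjustments, several.ok = TRUE)
  structure(list(outdir = outdir, scenario = scenario, inputs = inputs,
                 site_config = site_config, sites = sites, events = events,
                 measures = measures, adjustments = adjustments,
                 max_changepoints = as.integer(max_changepoints),
                 min_segment = as.integer(min_segment),
                 seed = as.integer(seed)),
            class = "run_config")
}

# Load every surface a run needs, from the scenario or from disk.
.load_world <- function(config) {
  if (!is.null(config$scenario)) {
    surf <- generate_surfaces(config$scenario)
    sites <- lapply(names(surf$sites), function(nm) {
      s <- config$scenario$sites[[nm]]
      list(site = cancer_site(nm, s$icd10, s$parity_rr),
           incidence = surf$sites[[nm]]$incidence,
           mortality = surf$sites[[nm]]$mortality)
    })
    names(sites) <- names(surf$sites)
  } else {
    panel <- if (is.null(config$site_config)) default_panel()
             else load_site_config(config$site_config)
    surf <- list(
      fertility = read_rate_surface(config$inputs$fertility, "fertility"),
      child_mortality = read_rate_surface(config$inputs$child_mortality, "child_mortality"),
      female_pop = read_population_surface(config$inputs$female_pop),
      child_pop = read_population_surface(config$inputs$child_pop))
    sites <- lapply(names(config$inputs$sites), function(nm) {
      site <- if (nm %in% names(panel)) panel[[nm]] else cancer_site(nm)
      list(site = site,
           incidence = read_rate_surface(config$inputs$sites[[nm]]$incidence, "incidence"),
           mortality = read_rate_surface(config$inputs$sites[[nm]]$mortality, "mortality"))
    })
    names(sites) <- names(config$inputs$sites)
  }
  if (!is.null(config$sites)) {
    unknown <- setdiff(config$sites, names(sites))
    if (length(unknown)) stop("unknown site(s): ", paste(unknown, collapse = ", "))
    sites <- sites[config$sites]
  }
  c(surf["fertility"], surf["child_mortality"], surf["female_pop"],
    surf["child_pop"], list(sites = sites))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

.write_manifest <- function(config, outdir, files) {
  cfg_yaml <- tempfile(fileext = ".yaml")
  on.exit(unlink(cfg_yaml))
  # canonical config serialisation (scenario objects included) for hashing;
  # the output location does not identify the run
  hashed <- config
  hashed$outdir <- NULL
  yaml::write_yaml(.canonical(hashed), cfg_yaml)
  manifest <- list(
    package = "kinloss",
    version = as.character(utils::packageVersion("kinloss")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_yaml)),
    outputs = lapply(file.path(outdir, files), function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

.canonical <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), .canonical))
  if (is.numeric(x)) return(as.vector(x))
  x
}

#' Run the estimation stage
#'
#' Computes, per site and event type, the new and prevalent affected-children
#' estimates, their crude and age-standardised rate series, a
#' period-average summary (first/last 5-year periods, changepoint windows,
#' final-year values) and a per-site period table; writes everything as CSV
#' plus a `manifest.json` with the config hash and output checksums. Reruns
#' with the same config reproduce identical tables and manifest.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the estimates, rate series, summary and
#'   period tables, and the manifest.
#' @export
run_estimate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  world <- .stage("input", .load_world(config))
  surv <- .stage("survival", child_survival(world$child_mortality))
  std <- standard_population_0_17()
  estimates <- list(); series <- list()
  est_rows <- list(); series_rows <- list()
  for (nm in names(world$sites)) {
    w <- world$sites[[nm]]
    for (ev in config$events) {
      rates <- if (ev == "diagnosis") w$incidence else w$mortality
      events <- .stage("events", make_events(rates, world$female_pop, w$site, ev))
      for (me in config$measures) {
        est <- .stage("model", if (me == "new")
          new_affected(events, world$fertility, surv, by_mother_age = TRUE)
        else
          prevalent_affected(events, world$fertility, surv, by_mother_age = TRUE))
        rs <- .stage("standardise", standardised_rate(est, world$child_pop, std))
        key <- paste(nm, ev, me, sep = "|")
        estimates[[key]] <- est; series[[key]] <- rs
        est_rows[[key]] <- data.frame(
          year = rep(est$years, each = 18L), child_age = rep(0:17, length(est$years)),
          site = nm, measure = me, event = ev,
          expected_count = as.vector(est$counts))
        series_rows[[key]] <- data.frame(site = nm, measure = me, event = ev,
                                         rs, check.names = FALSE)
      }
    }
  }
  est_tab <- do.call(rbind, est_rows)
  ser_tab <- do.call(rbind, series_rows)
  summary_tab <- .stage("summarise",
                        summarise_estimates(series, config$max_changepoints,
                                            config$min_segment))
  period_tab <- .stage("summarise", period_table(series))
  files <- c("estimates.csv", "rate_series.csv", "summary.csv", "periods.csv")
  utils::write.csv(est_tab, file.path(config$outdir, files[1L]), row.names = FALSE)
  utils::write.csv(ser_tab, file.path(config$outdir, files[2L]), row.names = FALSE)
  utils::write.csv(summary_tab, file.path(config$outdir, files[3L]), row.names = FALSE)
  utils::write.csv(period_tab, file.path(config$outdir, files[4L]), row.names = FALSE)
  manifest <- .write_manifest(config, config$outdir, files)
  invisible(list(estimates = estimates, series = series,
                 summary = summary_tab, periods = period_tab,
                 manifest = manifest))
}

#' Period-average summary of rate series
#'
#' One row per (site, measure, event, quantity in count/standardised rate):
#' averages over the first and last 5-year periods, over the centred 5-year
#' windows around BIC-selected changepoints of the count series, and the
#' final-year value. Counts are displayed rounded to integers and rates to
#' one decimal; returned values are unrounded.
#'
#' @param series named list of `rate_series` (keys `site|event|measure`).
#' @param max_changepoints,min_segment options for the changepoint fit that
#'   locates the summary windows.
#' @return a data.frame.
#' @export
summarise_estimates <- function(series, max_changepoints = 2L, min_segment = 3L) {
  rows <- list()
  for (key in names(series)) {
    rs <- series[[key]]
    parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
    yr <- range(rs$year)
    p1 <- c(yr[1L], min(yr[1L] + 4L, yr[2L]))
    p2 <- c(max(yr[2L] - 4L, yr[1L]), yr[2L])
    cps <- tryCatch({
      ti <- data.frame(year = rs$year, count = rs$count,
                       exposure = rs$count / pmax(rs$crude_rate, 1e-12) * 1e5)
      select_changepoints(ti, max_changepoints, min_segment)$changepoints
    }, error = function(e) integer(0))
    cp_cols <- list()
    for (i in seq_along(cps)) {
      w <- changepoint_window(cps[i])
      w[1L] <- max(w[1L], yr[1L]); w[2L] <- min(w[2L], yr[2L])
      avg <- period_average(rs, w[1L], w[2L])
      cp_cols[[i]] <- data.frame(changepoint = cps[i],
                                 cp_mean_count = avg[["mean_count"]],
                                 cp_mean_std_rate = avg[["mean_std_rate"]])
    }
    first <- period_average(rs, p1[1L], p1[2L])
    last <- period_average(rs, p2[1L], p2[2L])
    base <- data.frame(
      site = parts[1L], event = parts[2L], measure = parts[3L],
      first_period = sprintf("%d-%d", p1[1L], p1[2L]),
      first_mean_count = first[["mean_count"]],
      first_mean_std_rate = first[["mean_std_rate"]],
      changepoints = paste(cps, collapse = ";"),
      last_period = sprintf("%d-%d", p2[1L], p2[2L]),
      last_mean_count = last[["mean_count"]],
      last_mean_std_rate = last[["mean_std_rate"]],
      final_year = yr[2L],
      final_count = rs$count[rs$year == yr[2L]],
      final_std_rate = rs$std_rate[rs$year == yr[2L]])
    rows[[key]] <- base
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-site period table
#'
#' Average annual expected counts per site over 5-year windows at the start,
#' middle and end of each series.
#'
#' @param series named list of `rate_series` (keys `site|event|measure`).
#' @return a data.frame with one row per (site, event, measure, period).
#' @export
period_table <- function(series) {
  rows <- list()
  for (key in names(series)) {
    rs <- series[[key]]
    parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
    yr <- range(rs$year)
    mid <- (yr[1L] + yr[2L]) %/% 2L
    windows <- list(c(yr[1L], min(yr[1L] + 4L, yr[2L])),
                    c(max(mid - 2L, yr[1L]), min(mid + 2L, yr[2L])),
                    c(max(yr[2L] - 4L, yr[1L]), yr[2L]))
    for (w in windows) {
      avg <- period_average(rs, w[1L], w[2L])
      rows[[length(rows) + 1L]] <- data.frame(
        site = parts[1L], event = parts[2L], measure = parts[3L],
        period = sprintf("%d-%d", w[1L], w[2L]),
        mean_count = avg[["mean_count"]],
        mean_std_rate = avg[["mean_std_rate"]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the trend stage
#'
#' Fits BIC-selected segmented Poisson trends per (site, event, measure) and
#' requested adjustment, and writes a changepoint-section table mirroring
#' the estimate stage's outputs: one row per trend section with APC and 95%
#' CI. Sites whose series cannot be fitted (e.g. all-zero counts) are
#' reported as `not estimable` rather than failing the run.
#'
#' @param config a [run_config()].
#' @return (invisibly) the trend table (also written to
#'   `<outdir>/trends.csv`) and the fitted objects.
#' @export
run_trends <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  world <- .stage("input", .load_world(config))
  surv <- .stage("survival", child_survival(world$child_mortality))
  mothers <- if ("mother_age" %in% config$adjustments)
    .stage("model", mothers_of_minors(world$fertility, world$female_pop, surv,
                                      keep_child_age = TRUE))
  rows <- list(); fits <- list()
  for (nm in names(world$sites)) {
    w <- world$sites[[nm]]
    for (ev in config$events) {
      rates <- if (ev == "diagnosis") w$incidence else w$mortality
      events <- .stage("events", make_events(rates, world$female_pop, w$site, ev))
      for (me in config$measures) {
        est <- .stage("model", if (me == "new")
          new_affected(events, world$fertility, surv, by_mother_age = TRUE)
        else
          prevalent_affected(events, world$fertility, surv, by_mother_age = TRUE))
        for (adj in config$adjustments) {
          ti <- tryCatch(
            make_trend_input(est, world$child_pop,
                             mothers = if (adj == "mother_age") mothers),
            error = function(e) NULL)
          fit <- if (is.null(ti)) NULL else
            tryCatch(select_changepoints(ti, config$max_changepoints,
                                         config$min_segment),
                     error = function(e) NULL)
          key <- paste(nm, ev, me, adj, sep = "|")
          if (is.null(fit)) {
            rows[[key]] <- data.frame(site = nm, event = ev, measure = me,
                                      adjustment = adj, start = NA_integer_,
                                      end = NA_integer_, apc = NA_real_,
                                      apc_lo = NA_real_, apc_hi = NA_real_,
                                      status = "not estimable")
          } else {
            fits[[key]] <- fit
            tt <- trend_table(fit)
            rows[[key]] <- data.frame(site = nm, event = ev, measure = me,
                                      adjustment = adj,
                                      tt[, c("start", "end", "apc", "apc_lo", "apc_hi")],
                                      status = "ok")
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, file.path(config$outdir, "trends.csv"), row.names = FALSE)
  invisible(list(table = out, fits = fits))
}

#' Run the simulation stage
#'
#' Writes a scenario's generated surfaces as the standard delimited tables
#' and, when `n_women_per_cohort > 0`, the scaled microsimulation tallies.
#'
#' @param config a [run_config()] with a scenario.
#' @param n_women_per_cohort women per cohort for the microsimulation; 0
#'   skips it.
#' @return (invisibly) the paths written.
#' @export
run_simulate <- function(config, n_women_per_cohort = 0L) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$scenario)) stop("[stage simulate] config has no scenario")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  surf <- generate_surfaces(config$scenario)
  paths <- c(
    fertility = write_rate_surface(surf$fertility, file.path(config$outdir, "fertility.csv")),
    child_mortality = write_rate_surface(surf$child_mortality,
                                         file.path(config$outdir, "child_mortality.csv")),
    female_pop = write_population_surface(surf$female_pop,
                                          file.path(config$outdir, "female_pop.csv")),
    child_pop = write_population_surface(surf$child_pop,
                                         file.path(config$outdir, "child_pop.csv")))
  for (nm in names(surf$sites)) {
    slug <- gsub("[^A-Za-z0-9]+", "_", tolower(nm))
    paths[paste0(nm, "_incidence")] <- write_rate_surface(
      surf$sites[[nm]]$incidence, file.path(config$outdir, paste0(slug, "_incidence.csv")))
    paths[paste0(nm, "_mortality")] <- write_rate_surface(
      surf$sites[[nm]]$mortality, file.path(config$outdir, paste0(slug, "_mortality.csv")))
  }
  if (n_women_per_cohort > 0L) {
    res <- microsimulate(config$scenario, n_women_per_cohort, seed = config$seed)
    rows <- list()
    for (key in names(res$tallies)) {
      tl <- res$tallies[[key]]
      for (me in c("new", "prevalent")) {
        m <- tl[[me]] * res$scale
        rows[[paste(key, me)]] <- data.frame(
          year = rep(res$years, each = 18L), child_age = rep(0:17, length(res$years)),
          site = tl$site, measure = me, event = tl$event,
          count = as.vector(m))
      }
    }
    p <- file.path(config$outdir, "microsim_tallies.csv")
    utils::write.csv(do.call(rbind, rows), p, row.names = FALSE)
    paths["microsim"] <- p
  }
  invisible(paths)
}
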