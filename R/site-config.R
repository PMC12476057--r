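#' Cancer sites and parity relative risks
#'
#' A `cancer_site` couples a site label with its ICD-10 code group (carried
#' as an opaque string; no record-level ICD parsing is done, the pipeline's
#' unit of input is a site-specific rate surface) and a parity relative risk.
#' The parity RR is the relative risk of the cancer in parous versus
#' nulliparous women; it enters the estimation model as a single
#' multiplicative factor on the fertility attributed to women with that
#' cancer, and is assumed constant with respect to maternal age.
#'
#' @param name site label, e.g. `"Breast"`.
#' @param icd10 ICD-10 code group string, e.g. `"C50"` or `"C51-58"`.
#' @param parity_rr positive parity relative risk; default 1 (no adjustment).
#' @return an object of class `cancer_site`.
#' @export
cancer_site <- function(name, icd10 = "", parity_rr = 1.0) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("site name must be a non-empty string")
  parity_rr <- as.numeric(parity_rr)
  if (length(parity_rr) != 1L || is.na(parity_rr) || parity_rr <= 0)
    stop("parity_rr must be a positive number (site ", name, ")")
  structure(list(name = name, icd10 = as.character(icd10), parity_rr = parity_rr),
            class = "cancer_site")
}

#' @export
print.cancer_site <- function(x, ...) {
  cat(sprintf("<cancer_site> %s (%s), parity RR %.3g\n", x$name, x$icd10, x$parity_rr))
  invisible(x)
}

#' Load a cancer-site configuration
#'
#' Reads a YAML site configuration of the form
#' \preformatted{
#' sites:
#'   - name: Breast
#'     icd10: C50
#'     parity_rr: 1.0
#' }
#' `parity_rr` is optional and defaults to 1. Site names must be unique.
#'
#' @param path path to a YAML config file.
#' @return a list of [cancer_site()] objects, of class `site_panel`.
#' @export
load_site_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$sites) || length(cfg$sites) == 0L)
    stop("site config has no 'sites' entries: ", path)
  sites <- lapply(cfg$sites, function(s) {
    if (is.null(s$name)) stop("site entry without a name in ", path)
    cancer_site(s$name, icd10 = s$icd10 %||% "",
                parity_rr = s$parity_rr %||% 1.0)
  })
  site_panel(sites)
}

#' Write a cancer-site configuration
#'
#' Inverse of [load_site_config()]; the panel round-trips exactly.
#'
#' @param panel a `site_panel` or list of `cancer_site`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_site_config <- function(panel, path) {
  yaml::write_yaml(list(sites = lapply(panel, function(s)
    list(name = s$name, icd10 = s$icd10, parity_rr = s$parity_rr))), path)
  invisible(path)
}

#' Assemble a site panel
#'
#' @param sites list of [cancer_site()] objects with unique names.
#' @return the list, classed `site_panel`.
#' @export
site_panel <- function(sites) {
  stopifnot(all(vapply(sites, inherits, logical(1), "cancer_site")))
  nm <- vapply(sites, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate site name: ", nm[duplicated(nm)][1L])
  names(sites) <- nm
  structure(sites, class = "site_panel")
}

#' @export
print.site_panel <- function(x, ...) {
  cat("<site_panel>", length(x), "sites\n")
  for (s in x)
    cat(sprintf("  %-38s %-55s RR %.3g\n", s$name, paste0("(", s$icd10, ")"), s$parity_rr))
  invisible(x)
}

#' The default cancer-site panel
#'
#' Returns the shipped panel of 14 cancer-type groups used for reporting by
#' site, plus an "All sites" aggregate and a site-specific "Ovary" entry.
#' Parity relative risks default to 1.0 throughout: parity RRs for breast and
#' cervical cancer are known to exist but no authoritative default values are
#' shipped, so users supply their own via [load_site_config()]. The ovarian
#' entry carries the one established value, parity RR 0.8; it applies only
#' when an ovarian-specific rate surface is analysed, not to the
#' "Female genital organs" aggregate.
#'
#' @return a `site_panel`.
#' @export
default_panel <- function() {
  load_site_config(system.file("extdata", "site_panel.yaml", package = "kinloss",
                               mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
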