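#' Record bundles
#'
#' A *record bundle* carries the four per-site EPR extracts — the maternity
#' spine plus the neonatal, ultrasound and hospital-activity satellites — at a
#' named pipeline stage. Maternity and neonatal tables are wide (one row per
#' baby born); ultrasound and activity tables are long (one row per scan,
#' appointment or admission).
#'
#' @param maternity,neonatal,ultrasound,activity Tibbles (satellites may be
#'   `NULL` when a site could not provide an extract).
#' @param site Site code the bundle belongs to.
#' @param stage Pipeline stage label, one of
#'   `c("raw", "pseudonymised", "harmonised", "linked", "cleaned", "imputed")`.
#' @return A `record_bundle` object (a named list with attributes).
#' @export
record_bundle <- function(maternity, neonatal = NULL, ultrasound = NULL,
                          activity = NULL, site, stage = "raw") {
  stage <- match.arg(stage, BUNDLE_STAGES)
  tables <- list(maternity = maternity, neonatal = neonatal,
                 ultrasound = ultrasound, activity = activity)
  for (nm in names(tables)) {
    if (!is.null(tables[[nm]]) && !is.data.frame(tables[[nm]]))
      config_error(paste0("bundle table '", nm, "' must be a data frame"))
  }
  structure(tables, class = "record_bundle", site = site, stage = stage)
}

BUNDLE_STAGES <- c("raw", "pseudonymised", "harmonised", "linked",
                   "cleaned", "imputed")

#' @export
print.record_bundle <- function(x, ...) {
  cat("<record_bundle> site=", attr(x, "site"),
      " stage=", attr(x, "stage"), "\n", sep = "")
  for (nm in names(x)) {
    if (is.null(x[[nm]])) {
      cat(sprintf("  %-10s <absent>\n", nm))
    } else {
      cat(sprintf("  %-10s %d rows x %d cols\n", nm, nrow(x[[nm]]),
                  ncol(x[[nm]])))
    }
  }
  invisible(x)
}

bundle_site <- function(bundle) attr(bundle, "site")
bundle_stage <- function(bundle) attr(bundle, "stage")

set_stage <- function(bundle, stage) {
  attr(bundle, "stage") <- match.arg(stage, BUNDLE_STAGES)
  bundle
}

# map each table over a function, keeping NULL tables NULL
map_tables <- function(bundle, f, ...) {
  for (nm in names(bundle)) {
    if (!is.null(bundle[[nm]])) bundle[[nm]] <- f(bundle[[nm]], nm, ...)
  }
  bundle
}

#' Write a bundle to a directory as CSV files
#'
#' One file per table, named `<site>_<table>.csv`. Absent tables are skipped.
#'
#' @param bundle A `record_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  site <- bundle_site(bundle)
  paths <- character(0)
  for (nm in names(bundle)) {
    if (is.null(bundle[[nm]])) next
    p <- file.path(dir, paste0(site, "_", nm, ".csv"))
    readr::write_csv(bundle[[nm]], p, na = "")
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a bundle from per-table CSV or XLSX files
#'
#' Looks for `<site>_<table>.csv` (or `.xlsx`, requiring the readxl package)
#' for each of the four tables; missing satellite files yield `NULL` tables,
#' a missing maternity file is an error.
#'
#' @param dir Directory containing the files.
#' @param site Site code used in the file names.
#' @param stage Stage label to attach.
#' @return A `record_bundle`.
#' @export
read_bundle <- function(dir, site, stage = "raw") {
  read_one <- function(nm) {
    csv <- file.path(dir, paste0(site, "_", nm, ".csv"))
    xlsx <- file.path(dir, paste0(site, "_", nm, ".xlsx"))
    if (file.exists(csv)) {
      readr::read_csv(csv, show_col_types = FALSE, progress = FALSE,
                      col_types = readr::cols(.default = readr::col_guess()))
    } else if (file.exists(xlsx)) {
      if (!requireNamespace("readxl", quietly = TRUE))
        config_error("reading XLSX requires the readxl package")
      as_tibble(readxl::read_xlsx(xlsx))
    } else {
      NULL
    }
  }
  mat <- read_one("maternity")
  if (is.null(mat))
    config_error(paste0("no maternity extract found for site ", site,
                        " in ", dir))
  record_bundle(mat, read_one("neonatal"), read_one("ultrasound"),
                read_one("activity"), site = site, stage = stage)
}
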