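#' Site configuration for the synthetic EPR generator
#'
#' Describes one simulated maternity unit: its size, which source-system
#' dialect renders its extracts, clinical rates, the missingness to inject,
#' and the rates of the data defects the downstream pipeline must detect.
#'
#' @param site_code Short unique site code, e.g. `"S01"`.
#' @param n_women Number of women to simulate.
#' @param dialect One of `"alpha"`, `"bravo"`, `"charlie"` — three maternity
#'   source-system profiles differing in variable names, category
#'   vocabularies, date formats and unit systems.
#' @param twin_rate Probability a pregnancy is a twin pregnancy.
#' @param neonatal_admission_rate Probability a baby has a neonatal-unit
#'   record.
#' @param missingness Named list: canonical variable name (one of
#'   `"height"`, `"weight"`, `"ethnicity"`, `"parity"`, `"ga"`, `"sex"`,
#'   `"birthweight"`) to a list with elements `mechanism` (`"MCAR"` or
#'   `"MAR"`), `rate` in \[0,1\], and for MAR optionally `driver` (a canonical
#'   continuous variable, default `"weight"`) and `site_shift` (logit-scale
#'   shift, default +0.5).
#' @param defect_rates Named list over
#'   `c("duplicate_row", "per_pregnancy_multiple", "out_of_window_date",
#'   "implausible_value", "affirmative_only_binary")`; all default 0.
#' @param date_window Length-2 Date vector: start and end of the simulated
#'   trial phase; all deliveries fall inside it.
#' @param dob_range Maternal date-of-birth range.
#' @param second_pregnancy_rate Probability a woman has a second pregnancy
#'   (realised only when it fits inside `date_window`).
#' @return A `site_config` object.
#' @export
site_config <- function(site_code,
                        n_women,
                        dialect = c("alpha", "bravo", "charlie"),
                        twin_rate = 0.015,
                        neonatal_admission_rate = 0.10,
                        missingness = list(),
                        defect_rates = list(),
                        date_window = as.Date(c("2017-01-01", "2018-11-30")),
                        dob_range = as.Date(c("1978-01-01", "2003-12-31")),
                        second_pregnancy_rate = 0.04) {
  dialect <- match.arg(dialect)
  date_window <- as.Date(date_window)
  dob_range <- as.Date(dob_range)
  if (!is.character(site_code) || length(site_code) != 1L || !nzchar(site_code))
    config_error("site_code must be a non-empty string")
  if (!is_scalar_number(n_women) || n_women < 1)
    config_error("n_women must be a positive integer")
  for (p in c(twin_rate, neonatal_admission_rate, second_pregnancy_rate)) {
    if (!is_scalar_number(p) || p < 0 || p > 1)
      config_error("rates must lie in [0, 1]")
  }
  if (length(date_window) != 2L || anyNA(date_window) ||
      date_window[1] >= date_window[2])
    config_error("date_window start must precede end")
  defaults <- list(duplicate_row = 0, per_pregnancy_multiple = 0,
                   out_of_window_date = 0, implausible_value = 0,
                   affirmative_only_binary = 0)
  unknown <- setdiff(names(defect_rates), names(defaults))
  if (length(unknown))
    config_error(paste0("unknown defect type(s): ",
                        paste(unknown, collapse = ", ")))
  defaults[names(defect_rates)] <- defect_rates
  for (r in defaults) {
    if (!is_scalar_number(r) || r < 0 || r > 1)
      config_error("defect rates must lie in [0, 1]")
  }
  miss_vars <- c("height", "weight", "ethnicity", "parity", "ga", "sex",
                 "birthweight")
  for (v in names(missingness)) {
    if (!v %in% miss_vars)
      config_error(paste0("missingness configured for unknown variable: ", v))
    m <- missingness[[v]]
    if (!is.list(m) || is.null(m$mechanism) || is.null(m$rate) ||
        !m$mechanism %in% c("MCAR", "MAR") || m$rate < 0 || m$rate > 1)
      config_error(paste0("bad missingness spec for variable: ", v))
  }
  structure(list(site_code = site_code, n_women = as.integer(n_women),
                 dialect = dialect, twin_rate = twin_rate,
                 neonatal_admission_rate = neonatal_admission_rate,
                 missingness = missingness, defect_rates = defaults,
                 date_window = date_window, dob_range = dob_range,
                 second_pregnancy_rate = second_pregnancy_rate),
            class = "site_config")
}

#' Read site configurations from a YAML file
#'
#' The file holds a list of site entries whose keys mirror the arguments of
#' [site_config()]; dates may be given as ISO strings.
#'
#' @param path Path to the YAML configuration.
#' @return List of `site_config` objects.
#' @export
read_site_configs <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sites)) raw <- raw$sites
  lapply(raw, function(entry) {
    for (k in c("date_window", "dob_range")) {
      if (!is.null(entry[[k]])) entry[[k]] <- as.Date(unlist(entry[[k]]))
    }
    do.call(site_config, entry)
  })
}
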