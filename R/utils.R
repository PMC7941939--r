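# internal helpers shared across modules

# identifier columns that must never survive pseudonymisation
IDENTIFIER_COLS <- c("nhs_number", "hospital_number", "dob", "postcode")

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg, class = "eprlink_error")
  invisible(TRUE)
}

config_error <- function(msg) {
  abort(msg, class = c("eprlink_config_error", "eprlink_error"))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# parse dates that may arrive as ISO strings, DD/MM/YYYY strings or
# spreadsheet serial numbers (days since 1899-12-30, the Excel convention)
parse_mixed_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  if (is.numeric(x)) return(as.Date(x, origin = "1899-12-30"))
  x <- as.character(x)
  out <- rep(as.Date(NA), length(x))
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  dmy <- grepl("^\\d{1,2}/\\d{1,2}/\\d{4}$", x)
  ser <- grepl("^\\d+(\\.0+)?$", x)
  out[iso] <- as.Date(x[iso], format = "%Y-%m-%d")
  out[dmy] <- as.Date(x[dmy], format = "%d/%m/%Y")
  if (any(ser)) out[ser] <- as.Date(as.numeric(x[ser]), origin = "1899-12-30")
  out
}

# render a Date per dialect convention
render_date <- function(d, style) {
  switch(style,
    iso    = format(d, "%Y-%m-%d"),
    dmy    = format(d, "%d/%m/%Y"),
    serial = as.numeric(d - as.Date("1899-12-30")),
    config_error(paste0("unknown date style: ", style))
  )
}

logit <- function(p) log(p / (1 - p))

# first existing column among `names`, else NULL (tibbles warn on `$` misses)
col_or_null <- function(tab, ...) {
  for (nm in c(...)) if (nm %in% names(tab)) return(tab[[nm]])
  NULL
}
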