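# Dictionary-driven harmonisation of heterogeneous per-site extracts into one
# schema, under the nomenclature <source>_<r|h|c>_<name>: source in
# {mat, neo, uss, act}, stage tag r = raw, h = harmonised, c = calculated.
# Raw columns are always retained (renamed to the _r_ name, untouched); every
# change is appended to an audit trail whose replay reproduces the output.

DICT_SOURCES <- c("mat", "neo", "uss", "act")
DICT_STAGES <- c(r = "raw", h = "harmonised", c = "calculated")
DICT_DTYPES <- c("continuous", "categorical", "binary", "date", "text")
UNIT_RULES <- c("identity", "numeric", "cm_to_m", "ftin_to_m", "lb_to_kg",
                "stlb_to_kg", "g_to_g", "ga_to_days", "date", "merge_any",
                "bmi")

# which bundle table each source prefix lives in
SOURCE_TABLE <- c(mat = "maternity", neo = "neonatal", uss = "ultrasound",
                  act = "activity")

#' Load and validate a data dictionary
#'
#' The dictionary is a CSV with one row per (harmonised variable, site):
#' columns `harmonised_name`, `source`, `stage`, `dtype`, `unit`,
#' `description`, `site`, `raw_name`, `unit_rule`, `recode_map`
#' (`"raw=>target"` pairs joined by `|`), `binary_mode` (`full` /
#' `affirmative_only`), `categories` (allowed harmonised categories joined by
#' `|`). The `site` key may name a source-system dialect shared by several
#' sites; `"all"` applies to every site. The bundled dictionary for the
#' synthetic dialects is at
#' `system.file("extdata", "dictionary_synthetic.csv", package = "eprlink")`.
#'
#' @param path CSV path, or a data frame already in that shape.
#' @return An `epr_dictionary` (validated tibble).
#' @export
load_dictionary <- function(path) {
  d <- if (is.data.frame(path)) as_tibble(path) else
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  required <- c("harmonised_name", "source", "stage", "dtype", "site",
                "raw_name", "unit_rule")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    config_error(paste0("dictionary lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  for (col in c("recode_map", "binary_mode", "categories", "unit",
                "description")) {
    if (!col %in% names(d)) d[[col]] <- NA_character_
  }
  problems <- character(0)
  bad_name <- !grepl("^(mat|neo|uss|act)_(r|h|c)_[a-z0-9]+$",
                     d$harmonised_name)
  if (any(bad_name))
    problems <- c(problems, paste0("nomenclature violation: ",
                                   unique(d$harmonised_name[bad_name])))
  pref <- sub("^([a-z]+)_.*$", "\\1", d$harmonised_name)
  tag <- sub("^[a-z]+_([rhc])_.*$", "\\1", d$harmonised_name)
  if (any(!bad_name & pref != d$source))
    problems <- c(problems,
                  paste0("source prefix mismatch: ",
                         unique(d$harmonised_name[!bad_name &
                                                    pref != d$source])))
  if (any(!bad_name & unname(DICT_STAGES[tag]) != d$stage))
    problems <- c(problems,
                  paste0("stage tag mismatch: ",
                         unique(d$harmonised_name[!bad_name &
                                 unname(DICT_STAGES[tag]) != d$stage])))
  if (any(!d$dtype %in% DICT_DTYPES))
    problems <- c(problems, paste0("unknown dtype: ",
                                   unique(d$dtype[!d$dtype %in% DICT_DTYPES])))
  if (any(!d$unit_rule %in% UNIT_RULES))
    problems <- c(problems,
                  paste0("unknown unit_rule: ",
                         unique(d$unit_rule[!d$unit_rule %in% UNIT_RULES])))
  dup <- duplicated(d[, c("harmonised_name", "site")])
  if (any(dup))
    problems <- c(problems, paste0("duplicate entry: ",
                                   d$harmonised_name[dup], " @ ",
                                   d$site[dup]))
  # every recode target must sit inside the entry's declared category set
  for (i in which(!is.na(d$recode_map) & nzchar(d$recode_map))) {
    map <- parse_recode_map(d$recode_map[i])
    cats <- parse_categories(d$categories[i])
    if (length(cats) && !all(map %in% cats))
      problems <- c(problems,
                    paste0("recode target outside category set in ",
                           d$harmonised_name[i], " @ ", d$site[i], ": ",
                           paste(setdiff(map, cats), collapse = ", ")))
  }
  if (length(problems))
    config_error(paste0("dictionary validation failed:\n  ",
                        paste(problems, collapse = "\n  ")))
  structure(d, class = c("epr_dictionary", class(d)))
}

parse_recode_map <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character(0))
  pairs <- strsplit(s, "|", fixed = TRUE)[[1]]
  kv <- strsplit(pairs, "=>", fixed = TRUE)
  setNames(vapply(kv, function(p) trimws(p[2]), character(1)),
           vapply(kv, function(p) trimws(p[1]), character(1)))
}

parse_categories <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character(0))
  trimws(strsplit(s, "|", fixed = TRUE)[[1]])
}

#' Convert raw values to canonical units
#'
#' Supported rules: `cm_to_m`, `ftin_to_m` (strings like `"5ft 4in"`),
#' `lb_to_kg`, `stlb_to_kg` (`"10st 6lb"`), `g_to_g`/`numeric`, `identity`,
#' `ga_to_days` (accepts `"40+2"`, decimal weeks, or completed days), and
#' `date` (ISO, DD/MM/YYYY or spreadsheet serial). Unparseable values become
#' missing.
#'
#' @param value Vector of raw values.
#' @param unit_rule One of the supported rules.
#' @return Canonical values (numeric, or Date for `date`).
#' @export
convert_units <- function(value, unit_rule) {
  switch(unit_rule,
    identity = value,
    numeric = ,
    g_to_g = suppressWarnings(as.numeric(value)),
    cm_to_m = suppressWarnings(as.numeric(value)) / 100,
    lb_to_kg = suppressWarnings(as.numeric(value)) * 0.45359237,
    ftin_to_m = parse_ftin(value),
    stlb_to_kg = parse_stlb(value),
    ga_to_days = parse_ga(value),
    date = parse_mixed_date(value),
    config_error(paste0("unknown unit rule: ", unit_rule)))
}

parse_ftin <- function(x) {
  x <- as.character(x)
  m <- regmatches(x, regexec("^\\s*(\\d+)\\s*ft\\s*(\\d+)\\s*in\\s*$", x,
                             ignore.case = TRUE))
  vapply(m, function(g) {
    if (length(g) < 3) return(NA_real_)
    (as.numeric(g[2]) * 12 + as.numeric(g[3])) * 0.0254
  }, numeric(1))
}

parse_stlb <- function(x) {
  x <- as.character(x)
  m <- regmatches(x, regexec("^\\s*(\\d+)\\s*st\\s*(\\d+)\\s*lb\\s*$", x,
                             ignore.case = TRUE))
  vapply(m, function(g) {
    if (length(g) < 3) return(NA_real_)
    (as.numeric(g[2]) * 14 + as.numeric(g[3])) * 0.45359237
  }, numeric(1))
}

# gestational age to completed days; accepts "40+2" (weeks+days), decimal
# weeks (< 50) or integer days
parse_ga <- function(x) {
  x <- as.character(x)
  out <- rep(NA_real_, length(x))
  plus <- grepl("^\\s*\\d{1,2}\\+\\d\\s*$", x)
  if (any(plus)) {
    parts <- strsplit(trimws(x[plus]), "+", fixed = TRUE)
    out[plus] <- vapply(parts, function(p)
      as.numeric(p[1]) * 7 + as.numeric(p[2]), numeric(1))
  }
  num <- !plus & grepl("^\\s*\\d+(\\.\\d+)?\\s*$", x)
  v <- suppressWarnings(as.numeric(x[num]))
  out[num] <- ifelse(v < 50, round(v * 7), v)
  out
}

#' Body mass index from canonical units
#'
#' @param weight_kg Weight in kilograms.
#' @param height_m Height in metres.
#' @return `weight / height^2` rounded to 2 decimal places; missing where
#'   either input is missing or height is non-positive.
#' @export
calculate_bmi <- function(weight_kg, height_m) {
  out <- ifelse(is.na(weight_kg) | is.na(height_m) | height_m <= 0,
                NA_real_, weight_kg / height_m^2)
  round(out, 2)
}

#' Recode raw categorical values into harmonised categories
#'
#' Unmapped non-missing raw values become missing and are reported
#' separately from true missingness (the caller logs them in the audit
#' trail); raw values are never altered in place.
#'
#' @param raw_value Character vector of raw values.
#' @param recode_map Named character vector `raw -> harmonised`.
#' @return List: `values` (harmonised), `unmapped` (distinct raw values that
#'   had no mapping).
#' @export
recode_categorical <- function(raw_value, recode_map) {
  raw_chr <- as.character(raw_value)
  mapped <- unname(recode_map[raw_chr])
  unmapped <- sort(unique(raw_chr[!is.na(raw_chr) & is.na(mapped)]))
  list(values = mapped, unmapped = unmapped)
}

#' Apply the declared binary-missingness rule
#'
#' `affirmative_only`: the source only ever records the affirmative, so
#' missing is interpreted as (and set to) the explicit negative. `full`: the
#' source records both polarities, so missing stays missing.
#'
#' @param column Character vector coded `"yes"` / `"no"` / `NA`.
#' @param binary_mode `"affirmative_only"` or `"full"`.
#' @return The adjusted column.
#' @export
apply_binary_rule <- function(column, binary_mode) {
  binary_mode <- match.arg(binary_mode, c("full", "affirmative_only"))
  bad <- !is.na(column) & !column %in% c("yes", "no")
  if (any(bad))
    abort(paste0("binary column holds non-binary value(s): ",
                 paste(unique(column[bad]), collapse = ", ")),
          class = "eprlink_error")
  if (binary_mode == "affirmative_only") column[is.na(column)] <- "no"
  column
}

#' Merge one clinical fact recorded in several sources
#'
#' Any affirmative record makes the merged value affirmative, even if other
#' sources are negative or silent; negative only when at least one source is
#' negative and none affirmative; missing only when every source is missing.
#'
#' @param ... Two or more character vectors coded `"yes"` / `"no"` / `NA`.
#' @return The merged column.
#' @export
merge_multisource <- function(...) {
  cols <- list(...)
  if (length(cols) == 1L && is.list(cols[[1]]) && !is.data.frame(cols[[1]]))
    cols <- cols[[1]]
  assert_that(length(cols) >= 2L, "merge_multisource needs >= 2 columns")
  m <- do.call(cbind, lapply(cols, as.character))
  any_yes <- rowSums(m == "yes", na.rm = TRUE) > 0
  any_no <- rowSums(m == "no", na.rm = TRUE) > 0
  out <- rep(NA_character_, nrow(m))
  out[any_no] <- "no"
  out[any_yes] <- "yes"
  out
}

# ---- the engine -------------------------------------------------------------

new_audit <- function() {
  tibble(seq = integer(0), site = character(0), table = character(0),
         target = character(0), rule = character(0), params = character(0),
         rows_affected = integer(0), note = character(0))
}

audit_add <- function(trail, site, table, target, rule, params, rows, note = "") {
  bind_rows(trail, tibble(seq = nrow(trail) + 1L, site = site, table = table,
                          target = target, rule = rule,
                          params = as.character(
                            jsonlite::toJSON(params, auto_unbox = TRUE,
                                             null = "null")),
                          rows_affected = as.integer(rows), note = note))
}

#' Harmonise a bundle under a data dictionary
#'
#' Realises every dictionary entry for the bundle's tables: renames raw
#' columns to their `_r_` names (retained untouched), converts units,
#' recodes categories, applies binary-missingness rules, merges multi-source
#' variables and computes calculated variables, appending every step to an
#' audit trail. A variable whose raw source is absent at this site is
#' emitted fully missing and reported. Running the engine on its own output
#' is a no-op.
#'
#' @param bundle A pseudonymised [record_bundle()].
#' @param dictionary An `epr_dictionary` from [load_dictionary()].
#' @param site Dictionary site key for this bundle (a site code or the
#'   dialect name used in the dictionary); rows with site `"all"` always
#'   apply.
#' @return List: `bundle` (stage `"harmonised"`), `audit` (the trail),
#'   `report` (tibble of variables emitted fully missing or with unmapped
#'   values).
#' @export
harmonise_bundle <- function(bundle, dictionary, site) {
  if (!inherits(dictionary, "epr_dictionary"))
    dictionary <- load_dictionary(dictionary)
  trail <- new_audit()
  report <- list()
  site_code <- bundle_site(bundle)

  d <- dictionary[dictionary$site %in% c(site, "all"), , drop = FALSE]
  # prefer a site-specific row over an "all" row for the same variable
  d <- d[order(d$harmonised_name, d$site != site), , drop = FALSE]
  d <- d[!duplicated(d$harmonised_name), , drop = FALSE]
  # names defined anywhere in the dictionary: absent here -> fully missing
  all_names <- unique(dictionary$harmonised_name)

  for (src in DICT_SOURCES) {
    tbl_name <- SOURCE_TABLE[[src]]
    tab <- bundle[[tbl_name]]
    if (is.null(tab)) next
    src_names <- all_names[startsWith(all_names, paste0(src, "_"))]
    # plain entries first, then merges, then calculated
    rules <- d$unit_rule[match(src_names, d$harmonised_name)]
    ord <- order(match(ifelse(is.na(rules), "missing",
                              ifelse(rules == "merge_any", "merge",
                                     ifelse(rules == "bmi", "calc", "plain"))),
                       c("plain", "merge", "calc", "missing")))
    for (hname in src_names[ord]) {
      if (hname %in% names(tab)) next  # already harmonised: no-op
      row <- d[d$harmonised_name == hname, , drop = FALSE]
      if (nrow(row) == 0L || is.na(row$raw_name) || !nzchar(row$raw_name)) {
        tab[[hname]] <- NA
        trail <- audit_add(trail, site_code, tbl_name, hname, "emit_missing",
                           list(), nrow(tab),
                           "no raw source at this site")
        report[[length(report) + 1L]] <-
          tibble(site = site_code, table = tbl_name, variable = hname,
                 issue = "fully_missing", detail = "no raw source")
        next
      }
      rule <- row$unit_rule
      if (rule == "merge_any") {
        comps <- trimws(strsplit(row$raw_name, ";", fixed = TRUE)[[1]])
        missing_comp <- setdiff(comps, names(tab))
        if (length(missing_comp)) {
          tab[[hname]] <- NA_character_
          trail <- audit_add(trail, site_code, tbl_name, hname,
                             "emit_missing", list(), nrow(tab),
                             "merge component absent")
          next
        }
        tab[[hname]] <- merge_multisource(lapply(comps, function(cc)
          tab[[cc]]))
        trail <- audit_add(trail, site_code, tbl_name, hname, "merge_any",
                           list(components = comps), nrow(tab))
      } else if (rule == "bmi") {
        comps <- trimws(strsplit(row$raw_name, ";", fixed = TRUE)[[1]])
        w <- tab[[comps[1]]] %||% rep(NA_real_, nrow(tab))
        h <- tab[[comps[2]]] %||% rep(NA_real_, nrow(tab))
        nonpos <- sum(!is.na(h) & h <= 0)
        tab[[hname]] <- calculate_bmi(w, h)
        trail <- audit_add(trail, site_code, tbl_name, hname, "bmi",
                           list(weight = comps[1], height = comps[2]),
                           nrow(tab),
                           if (nonpos) paste0(nonpos, " non-positive height(s)")
                           else "")
      } else {
        raw_col <- row$raw_name
        r_name <- sub(paste0("^", src, "_h_"), paste0(src, "_r_"), hname)
        if (!raw_col %in% names(tab) && r_name %in% names(tab))
          raw_col <- r_name  # already renamed by an earlier pass
        if (!raw_col %in% names(tab)) {
          tab[[hname]] <- NA
          trail <- audit_add(trail, site_code, tbl_name, hname,
                             "emit_missing", list(raw = raw_col), nrow(tab),
                             "raw column absent from extract")
          report[[length(report) + 1L]] <-
            tibble(site = site_code, table = tbl_name, variable = hname,
                   issue = "fully_missing",
                   detail = paste0("raw column ", raw_col, " absent"))
          next
        }
        # retain the raw column untouched under its _r_ name
        if (raw_col != r_name) {
          names(tab)[names(tab) == raw_col] <- r_name
          trail <- audit_add(trail, site_code, tbl_name, r_name, "copy_raw",
                             list(from = raw_col), nrow(tab))
        }
        raw_vals <- tab[[r_name]]
        map <- parse_recode_map(row$recode_map)
        if (length(map)) {
          rec <- recode_categorical(raw_vals, map)
          vals <- rec$values
          trail <- audit_add(trail, site_code, tbl_name, hname, "recode",
                             list(from = r_name, map = as.list(map)),
                             sum(!is.na(vals)))
          if (length(rec$unmapped)) {
            trail <- audit_add(trail, site_code, tbl_name, hname,
                               "unmapped_values",
                               list(values = rec$unmapped),
                               sum(!is.na(raw_vals) & is.na(vals)))
            report[[length(report) + 1L]] <-
              tibble(site = site_code, table = tbl_name, variable = hname,
                     issue = "unmapped_values",
                     detail = paste(rec$unmapped, collapse = "; "))
          }
        } else {
          vals <- convert_units(raw_vals, rule)
          unparse <- sum(!is.na(raw_vals) & is.na(vals))
          trail <- audit_add(trail, site_code, tbl_name, hname, "convert",
                             list(from = r_name, unit_rule = rule),
                             sum(!is.na(vals)),
                             if (unparse) paste0(unparse, " unparseable")
                             else "")
        }
        if (row$dtype == "binary" && !is.na(row$binary_mode) &&
            nzchar(row$binary_mode)) {
          n_before <- sum(is.na(vals))
          vals <- apply_binary_rule(vals, row$binary_mode)
          trail <- audit_add(trail, site_code, tbl_name, hname,
                             "binary_rule", list(mode = row$binary_mode),
                             n_before - sum(is.na(vals)))
        }
        tab[[hname]] <- vals
      }
    }
    bundle[[tbl_name]] <- tab
  }
  list(bundle = set_stage(bundle, "harmonised"), audit = trail,
       report = if (length(report)) bind_rows(report) else
         tibble(site = character(0), table = character(0),
                variable = character(0), issue = character(0),
                detail = character(0)))
}

#' Replay an audit trail on raw tables
#'
#' Applies the recorded steps, in order, to a raw (pseudonymised) bundle
#' using the same primitives the engine used. Replay on the engine's input
#' reproduces the engine's output exactly — the audit-completeness contract.
#'
#' @param bundle The raw bundle the trail was recorded against.
#' @param trail An audit tibble from [harmonise_bundle()].
#' @return The reconstructed bundle.
#' @export
replay_audit <- function(bundle, trail) {
  for (i in seq_len(nrow(trail))) {
    step <- trail[i, ]
    tab <- bundle[[step$table]]
    if (is.null(tab)) next
    p <- jsonlite::fromJSON(step$params)
    tab <- switch(step$rule,
      copy_raw = { names(tab)[names(tab) == p$from] <- step$target; tab },
      convert = { tab[[step$target]] <- convert_units(tab[[p$from]],
                                                      p$unit_rule); tab },
      recode = {
        tab[[step$target]] <-
          recode_categorical(tab[[p$from]], unlist(p$map))$values
        tab
      },
      unmapped_values = tab,
      binary_rule = {
        tab[[step$target]] <- apply_binary_rule(tab[[step$target]], p$mode)
        tab
      },
      merge_any = {
        tab[[step$target]] <- merge_multisource(lapply(p$components,
                                                       function(cc)
                                                         tab[[cc]]))
        tab
      },
      bmi = {
        tab[[step$target]] <- calculate_bmi(tab[[p$weight]], tab[[p$height]])
        tab
      },
      emit_missing = { tab[[step$target]] <- NA; tab },
      tab)
    bundle[[step$table]] <- tab
  }
  set_stage(bundle, "harmonised")
}

#' Path to the bundled dictionary for the synthetic dialects
#' @return File path.
#' @export
synthetic_dictionary_path <- function() {
  system.file("extdata", "dictionary_synthetic.csv", package = "eprlink")
}
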