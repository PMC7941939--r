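# Staged data-quality auditing: the 7-item first-download checklist, the
# 6-item second-download checklist, duplicate classification, distribution
# summaries, outlier screening and the clinician-consensus outlier policy.

#' Clinician-consensus plausibility limits
#'
#' Default limits, in canonical units (height in metres even though the
#' consensus table is printed in centimetres): maternal age 13-60 years,
#' height 1.20-2.00 m, weight 30-200 kg, BMI 13-70 kg/m2, estimated blood
#' loss 1-15000 mL, birthweight 100-6000 g. Values strictly outside the
#' limits are implausible; the limits themselves are retained.
#'
#' @param path Optional YAML file with entries `variable: {lower, upper}`
#'   overriding or extending the defaults.
#' @return A tibble with columns `variable`, `lower`, `upper`.
#' @export
outlier_policy <- function(path = NULL) {
  pol <- tibble(
    variable = c("age_at_delivery", "mat_h_height", "mat_h_weight",
                 "mat_c_bmi", "mat_h_ebl", "mat_h_bwt", "neo_h_bwt"),
    lower = c(13, 1.20, 30, 13, 1, 100, 100),
    upper = c(60, 2.00, 200, 70, 15000, 6000, 6000))
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    extra <- tibble(variable = names(y),
                    lower = vapply(y, function(e) as.numeric(e$lower),
                                   numeric(1)),
                    upper = vapply(y, function(e) as.numeric(e$upper),
                                   numeric(1)))
    pol <- bind_rows(extra, pol[!pol$variable %in% extra$variable, ])
  }
  if (any(pol$lower >= pol$upper))
    config_error("outlier policy requires lower < upper for every variable")
  pol
}

#' Distribution summary of a continuous variable
#'
#' Range, median and the 5th, 25th, 75th and 95th centiles, with missing
#' values excluded. Centiles use linear interpolation between order
#' statistics (quantile type 7), the convention stated in report headers.
#'
#' @param values Numeric vector.
#' @return One-row tibble `n, n_missing, min, p5, p25, median, p75, p95,
#'   max`; an all-missing column yields an empty (all-`NA`) summary.
#' @export
distribution_summary <- function(values) {
  v <- suppressWarnings(as.numeric(values))
  n_missing <- sum(is.na(v))
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    return(tibble(n = 0L, n_missing = n_missing, min = NA_real_,
                  p5 = NA_real_, p25 = NA_real_, median = NA_real_,
                  p75 = NA_real_, p95 = NA_real_, max = NA_real_))
  }
  q <- quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7, names = FALSE)
  tibble(n = length(v), n_missing = n_missing, min = min(v), p5 = q[1],
         p25 = q[2], median = q[3], p75 = q[4], p95 = q[5], max = max(v))
}

#' Classify repeated study-ID rows: multiple birth or true duplicate
#'
#' Rows of the maternity table sharing (study ID, delivery date) are either
#' babies of a multiple birth (differing in baby-level fields) or true
#' duplicates (identical across all fields). When ultrasound data are
#' available and the pregnancy's scans report a single fetus, repeated rows
#' are classified true duplicates even if baby fields differ.
#'
#' @param maternity Pseudonymised maternity table with `study_id` and a
#'   delivery-date column.
#' @param ultrasound Optional ultrasound table with `study_id`, an event
#'   date and `fetal_count` (or `uss_h_fetalcount`).
#' @return Character vector, one class per maternity row:
#'   `"unique"`, `"multiple_birth"` or `"true_duplicate"`.
#' @export
classify_duplicates <- function(maternity, ultrasound = NULL) {
  dod <- episode_dod(maternity)
  key <- paste(maternity$study_id, dod)
  dup_key <- key %in% key[duplicated(key)]
  cls <- rep("unique", nrow(maternity))
  if (!any(dup_key)) return(cls)

  # fields compared exclude plumbing columns
  cmp_cols <- setdiff(names(maternity), c("record_id"))
  # singleton pregnancies per ultrasound: max fetal count over scans in the
  # 310 days before delivery
  singleton_ids <- character(0)
  if (!is.null(ultrasound)) {
    fc <- suppressWarnings(as.numeric(col_or_null(ultrasound, "uss_h_fetalcount",
                                                  "fetal_count")))
    sd_col <- col_or_null(ultrasound, "uss_h_scandate", "event_date")
    if (!is.null(fc) && !is.null(sd_col)) {
      scan_date <- as.Date(parse_mixed_date(sd_col))
      uss <- tibble(study_id = ultrasound$study_id, fc = fc,
                    scan_date = scan_date)
      mat_keys <- tibble(study_id = maternity$study_id, dod = dod,
                         key = key) %>% distinct()
      per_preg <- inner_join(uss, mat_keys, by = "study_id",
                             relationship = "many-to-many") %>%
        filter(!is.na(.data$scan_date), !is.na(.data$dod),
               .data$scan_date <= .data$dod,
               .data$scan_date >= .data$dod - 310L) %>%
        group_by(.data$key) %>%
        summarise(max_fc = max(.data$fc, na.rm = TRUE), .groups = "drop")
      singleton_ids <- per_preg$key[is.finite(per_preg$max_fc) &
                                      per_preg$max_fc == 1]
    }
  }
  for (k in unique(key[dup_key])) {
    idx <- which(key == k)
    sub <- maternity[idx, cmp_cols, drop = FALSE]
    exact_extra <- duplicated(sub)
    if (k %in% singleton_ids) {
      cls[idx] <- c("unique", rep("true_duplicate", length(idx) - 1L))
    } else if (all(exact_extra[-1])) {
      cls[idx] <- c("unique", rep("true_duplicate", length(idx) - 1L))
    } else {
      cls[idx] <- "multiple_birth"
      cls[idx][exact_extra] <- "true_duplicate"
    }
  }
  cls
}

#' Screen a continuous variable for outlier candidates
#'
#' Computes the 3rd, 4th and 5th sample-standard-deviation limits and the
#' 1st and 99th centiles and lists the values beyond each. The lists are
#' advisory — screening highlights possible erroneous entries for clinical
#' adjudication and never mutates data.
#'
#' @param values Numeric vector with at least 10 non-missing values.
#' @return Named list of index vectors: `sd3`, `sd4`, `sd5`, `below_p1`,
#'   `above_p99`.
#' @export
flag_outlier_candidates <- function(values) {
  v <- suppressWarnings(as.numeric(values))
  ok <- which(!is.na(v))
  assert_that(length(ok) >= 10L, "need >= 10 non-missing values to screen")
  m <- mean(v[ok]); s <- sd(v[ok])
  q <- quantile(v[ok], c(0.01, 0.99), type = 7, names = FALSE)
  lim <- function(k) ok[abs(v[ok] - m) > k * s]
  list(sd3 = lim(3), sd4 = lim(4), sd5 = lim(5),
       below_p1 = ok[v[ok] < q[1]], above_p99 = ok[v[ok] > q[2]])
}

#' Apply the consensus outlier policy: implausible values become missing
#'
#' Values strictly outside a variable's `[lower, upper]` limits are
#' converted to missing; boundary values are retained. The operation is
#' idempotent and never alters a retained value.
#'
#' @param bundle A harmonised (or linked) [record_bundle()].
#' @param policy Tibble from [outlier_policy()]. Variables absent from every
#'   table raise a configuration error.
#' @return List: `bundle` (stage `"cleaned"`) and `removals` — counts per
#'   variable per table.
#' @export
apply_outlier_policy <- function(bundle, policy = outlier_policy()) {
  removals <- list()
  site <- bundle_site(bundle)
  found <- setNames(rep(FALSE, nrow(policy)), policy$variable)
  for (nm in names(bundle)) {
    tab <- bundle[[nm]]
    if (is.null(tab)) next
    for (i in seq_len(nrow(policy))) {
      var <- policy$variable[i]
      if (!var %in% names(tab)) next
      found[var] <- TRUE
      v <- suppressWarnings(as.numeric(tab[[var]]))
      out <- !is.na(v) & (v < policy$lower[i] | v > policy$upper[i])
      tab[[var]][out] <- NA
      removals[[paste(nm, var)]] <- tibble(site = site, table = nm,
                                           variable = var,
                                           removed = sum(out))
    }
    bundle[[nm]] <- tab
  }
  if (any(!found))
    config_error(paste0("outlier policy variable(s) absent from bundle: ",
                        paste(names(found)[!found], collapse = ", ")))
  list(bundle = set_stage(bundle, "cleaned"),
       removals = bind_rows(removals))
}

# ---- checklists -------------------------------------------------------------

qc_check <- function(status, evidence = list()) {
  list(status = status, evidence = evidence)
}

# requested raw variables per table, from the dictionary's single-source rows
requested_variables <- function(dictionary, site) {
  d <- dictionary[dictionary$site %in% c(site, "all") &
                    !dictionary$unit_rule %in% c("merge_any", "bmi") &
                    !is.na(dictionary$raw_name) & nzchar(dictionary$raw_name),
                  , drop = FALSE]
  split(d$raw_name, unname(SOURCE_TABLE[d$source]))
}

completeness_table <- function(bundle, vars_by_table) {
  rows <- list()
  for (nm in names(vars_by_table)) {
    tab <- bundle[[nm]]
    if (is.null(tab)) next
    for (v in vars_by_table[[nm]]) {
      col <- if (v %in% names(tab)) tab[[v]] else NULL
      rows[[paste(nm, v)]] <- tibble(
        table = nm, variable = v, present = !is.null(col),
        n = if (is.null(col)) 0L else length(col),
        complete_pct = if (is.null(col) || !length(col)) NA_real_ else
          100 * mean(!is.na(col) & col != ""))
    }
  }
  if (length(rows)) bind_rows(rows) else
    tibble(table = character(0), variable = character(0),
           present = logical(0), n = integer(0), complete_pct = numeric(0))
}

date_range_check <- function(bundle, expected_window) {
  expected_window <- as.Date(expected_window)
  rows <- list()
  specs <- list(maternity = "dod", ultrasound = "event_date",
                activity = "event_date", neonatal = "neonatal_dob")
  for (nm in names(specs)) {
    tab <- bundle[[nm]]
    if (is.null(tab)) next
    col <- intersect(c(specs[[nm]], "mat_h_dod", "uss_h_scandate",
                       "act_h_eventdate", "neo_h_dob"), names(tab))[1]
    if (is.na(col)) next
    # antenatal events for births early in the window legitimately predate
    # it by up to a full pregnancy; their window opens ~300 days earlier
    lo <- if (nm %in% c("ultrasound", "activity"))
      expected_window[1] - 300L else expected_window[1]
    d <- as.Date(parse_mixed_date(tab[[col]]))
    viol <- !is.na(d) & (d < lo | d > expected_window[2])
    rows[[nm]] <- tibble(table = nm, column = col,
                         n_dated = sum(!is.na(d)), n_outside = sum(viol),
                         min_date = suppressWarnings(min(d, na.rm = TRUE)),
                         max_date = suppressWarnings(max(d, na.rm = TRUE)))
  }
  bind_rows(rows)
}

#' First-download quality checklist (7 checks)
#'
#' 1. presence of all four requested datasets; 2. duplicate study IDs with
#' multiple-birth / true-duplicate classification; 3. matching of study IDs
#' across the four datasets; 4. presence of the requested variables;
#' 5. completeness of the requested variables; 6. range, median and
#' 5th/25th/75th/95th centiles of continuous variables; 7. date range of
#' births and hospital activities against the requested window. Problems are
#' report content, never exceptions.
#'
#' @param bundle A pseudonymised [record_bundle()].
#' @param expected_window Length-2 Date vector of the requested timeframe.
#' @param dictionary Dictionary used to derive the requested variable list.
#' @param site Dictionary site key for the bundle.
#' @return A `qc_report` (list of 7 named checks plus metadata).
#' @export
first_download_checks <- function(bundle, expected_window, dictionary = NULL,
                                  site = bundle_site(bundle)) {
  checks <- list()
  expected_tables <- c("maternity", "neonatal", "ultrasound", "activity")
  present <- vapply(expected_tables, function(nm) !is.null(bundle[[nm]]),
                    logical(1))
  checks$datasets_present <- qc_check(
    if (all(present)) "pass" else "fail",
    list(missing = expected_tables[!present]))

  cls <- classify_duplicates(bundle$maternity, bundle$ultrasound)
  n_true <- sum(cls == "true_duplicate")
  checks$duplicate_study_ids <- qc_check(
    if (n_true == 0L) "pass" else "warn",
    list(classification = table(cls), n_true_duplicates = n_true,
         n_multiple_birth_rows = sum(cls == "multiple_birth")))

  spine <- unique(bundle$maternity$study_id)
  match_rows <- list()
  for (nm in c("neonatal", "ultrasound", "activity")) {
    tab <- bundle[[nm]]
    if (is.null(tab)) next
    ids <- unique(tab$study_id)
    match_rows[[nm]] <- tibble(table = nm, n_ids = length(ids),
                               pct_on_spine = if (length(ids)) 100 *
                                   mean(ids %in% spine) else NA_real_)
  }
  match_tbl <- bind_rows(match_rows)
  checks$id_matching <- qc_check(
    if (nrow(match_tbl) && all(match_tbl$pct_on_spine == 100,
                               na.rm = TRUE)) "pass" else "warn",
    list(matching = match_tbl))

  vars <- if (!is.null(dictionary)) requested_variables(dictionary, site)
          else lapply(bundle[!vapply(bundle, is.null, logical(1))], names)
  comp <- completeness_table(bundle, vars)
  checks$variables_present <- qc_check(
    if (all(comp$present)) "pass" else "fail",
    list(missing_variables = comp[!comp$present,
                                  c("table", "variable")]))
  checks$completeness <- qc_check(
    if (nrow(comp) && all(comp$complete_pct[comp$present] > 0,
                          na.rm = TRUE)) "pass" else "warn",
    list(completeness = comp))

  dist_rows <- list()
  for (nm in names(bundle)) {
    tab <- bundle[[nm]]
    if (is.null(tab)) next
    for (v in names(tab)[vapply(tab, is.numeric, logical(1))]) {
      if (v %in% c("record_id", "episode_n")) next
      dist_rows[[paste(nm, v)]] <-
        bind_cols(tibble(table = nm, variable = v),
                  distribution_summary(tab[[v]]))
    }
  }
  checks$distributions <- qc_check("pass",
                                   list(summaries = bind_rows(dist_rows),
                                        convention = "linear interpolation (type 7)"))

  dr <- date_range_check(bundle, expected_window)
  checks$date_range <- qc_check(
    if (nrow(dr) && sum(dr$n_outside) == 0L) "pass" else
      if (!nrow(dr)) "warn" else "fail",
    list(ranges = dr, expected = as.Date(expected_window)))

  structure(list(checklist = "first_download", site = bundle_site(bundle),
                 checks = checks),
            class = "qc_report")
}

#' Second-download quality checklist (6 checks)
#'
#' Re-evaluates the issues raised at the first download, then runs the
#' focused checks: duplicate study IDs, completeness of the variables key to
#' the primary outcome (flagging site-variables completely missing),
#' distribution of the key continuous variables, value responses of the key
#' categorical variables, and the date-range check.
#'
#' @param bundle The second-download pseudonymised [record_bundle()].
#' @param prior_issues The first download's `qc_report` (or `NULL`).
#' @param key_vars Named list `table -> character vector` of the variables
#'   key to the primary outcome.
#' @param expected_window Requested timeframe.
#' @param categories Optional named list `variable -> allowed values` for
#'   the categorical-value check.
#' @return A `qc_report` with 6 checks (5 when there were no prior issues).
#' @export
second_download_checks <- function(bundle, prior_issues = NULL, key_vars,
                                   expected_window, categories = list()) {
  checks <- list()
  if (!is.null(prior_issues)) {
    prior_fail <- names(prior_issues$checks)[
      vapply(prior_issues$checks, function(ch) ch$status == "fail",
             logical(1))]
    rerun <- first_download_checks(bundle, expected_window)
    resolution <- tibble(
      check = prior_fail,
      resolved = vapply(prior_fail, function(ch)
        rerun$checks[[ch]]$status != "fail", logical(1)))
    checks$prior_issue_resolution <- qc_check(
      if (all(resolution$resolved)) "pass" else "fail",
      list(resolution = resolution))
  }

  cls <- classify_duplicates(bundle$maternity, bundle$ultrasound)
  checks$duplicate_study_ids <- qc_check(
    if (!any(cls == "true_duplicate")) "pass" else "warn",
    list(classification = table(cls)))

  comp <- completeness_table(bundle, key_vars)
  comp$completely_missing <- !comp$present |
    (!is.na(comp$complete_pct) & comp$complete_pct == 0)
  checks$key_variable_completeness <- qc_check(
    if (!any(comp$completely_missing)) "pass" else "fail",
    list(completeness = comp,
         completely_missing = comp[comp$completely_missing,
                                   c("table", "variable")]))

  dist_rows <- list()
  for (nm in names(key_vars)) {
    tab <- bundle[[nm]]
    if (is.null(tab)) next
    for (v in intersect(key_vars[[nm]], names(tab))) {
      col <- suppressWarnings(as.numeric(tab[[v]]))
      if (all(is.na(col))) next
      dist_rows[[paste(nm, v)]] <-
        bind_cols(tibble(table = nm, variable = v),
                  distribution_summary(col))
    }
  }
  checks$key_distributions <- qc_check("pass",
                                       list(summaries = bind_rows(dist_rows)))

  cat_rows <- list()
  for (v in names(categories)) {
    for (nm in names(bundle)) {
      tab <- bundle[[nm]]
      if (is.null(tab) || !v %in% names(tab)) next
      vals <- unique(as.character(tab[[v]]))
      vals <- vals[!is.na(vals)]
      bad <- setdiff(vals, categories[[v]])
      cat_rows[[paste(nm, v)]] <- tibble(table = nm, variable = v,
                                         n_values = length(vals),
                                         unexpected = paste(bad,
                                                            collapse = "; "))
    }
  }
  cat_tbl <- if (length(cat_rows)) bind_rows(cat_rows) else
    tibble(table = character(0), variable = character(0),
           n_values = integer(0), unexpected = character(0))
  checks$categorical_values <- qc_check(
    if (!nrow(cat_tbl) || all(cat_tbl$unexpected == "")) "pass" else "warn",
    list(values = cat_tbl))

  dr <- date_range_check(bundle, expected_window)
  checks$date_range <- qc_check(
    if (nrow(dr) && sum(dr$n_outside) == 0L) "pass" else
      if (!nrow(dr)) "warn" else "fail",
    list(ranges = dr, expected = as.Date(expected_window)))

  structure(list(checklist = "second_download", site = bundle_site(bundle),
                 checks = checks),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", x$checklist, " @ ", x$site, "\n", sep = "")
  for (nm in names(x$checks)) {
    cat(sprintf("  [%s] %s\n", toupper(x$checks[[nm]]$status), nm))
  }
  invisible(x)
}

#' Write a QC report as JSON
#'
#' @param report A `qc_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, force = TRUE,
                       null = "null", na = "null", Date = "ISO8601")
  invisible(path)
}
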