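# End-to-end orchestration: pseudonymise -> QC(first or second) ->
# harmonise -> link -> QC/outliers -> (optionally) impute, with a manifest
# recording seeds, stage row counts and output digests. The two-download
# workflow is modelled as two runs sharing a key sink, the second consuming
# the first run's QC reports.

#' Label births by trial phase
#'
#' Each record is labelled by which phase window contains its delivery date;
#' records outside every window are excluded and counted.
#'
#' @param records Table with a delivery-date column (`mat_h_dod` or `dod`).
#' @param phase_windows Named list `phase -> c(start, end)` (Dates,
#'   inclusive); windows must not overlap.
#' @return List: `records` (with a `phase` column, excluded rows removed)
#'   and `excluded` (count).
#' @export
phase_tag <- function(records, phase_windows) {
  wins <- lapply(phase_windows, as.Date)
  for (w in wins) {
    if (length(w) != 2L || anyNA(w) || w[1] > w[2])
      config_error("each phase window must be two ordered dates")
  }
  nm <- names(wins)
  if (length(wins) > 1L) {
    for (i in seq_along(wins)) for (j in seq_along(wins)) {
      if (i < j && wins[[i]][1] <= wins[[j]][2] &&
          wins[[j]][1] <= wins[[i]][2])
        config_error(paste0("phase windows overlap: ", nm[i], " and ", nm[j]))
    }
  }
  dod <- episode_dod(records)
  phase <- rep(NA_character_, nrow(records))
  for (p in nm) {
    inside <- !is.na(dod) & dod >= wins[[p]][1] & dod <= wins[[p]][2]
    phase[inside] <- p
  }
  keep <- !is.na(phase)
  records$phase <- phase
  list(records = records[keep, , drop = FALSE], excluded = sum(!keep))
}

#' Run configuration for the end-to-end pipeline
#'
#' @param salt Pseudonymisation salt.
#' @param key_sink Directory for key files; must not lie inside
#'   `output_dir`.
#' @param output_dir Directory for stage outputs and the manifest.
#' @param dictionary Dictionary path or object (default: the bundled
#'   synthetic-dialect dictionary).
#' @param dict_sites Named character vector mapping site code to its
#'   dictionary site key (e.g. its dialect).
#' @param expected_window Requested date window for QC.
#' @param phase_windows Named list of trial-phase windows (or `NULL` to skip
#'   phase tagging).
#' @param policy Outlier policy tibble (default [outlier_policy()]).
#' @param postcode_lookup Lookup tibble or path (optional).
#' @param impute_spec An [imputation_spec()] or `NULL`.
#' @param prior_qc Named list `site -> qc_report` from a first-download run,
#'   switching QC to the second-download checklist.
#' @param key_vars Key-variable list for the second-download checklist.
#' @param seed Integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(salt, key_sink, output_dir,
                       dictionary = synthetic_dictionary_path(),
                       dict_sites, expected_window,
                       phase_windows = NULL, policy = outlier_policy(),
                       postcode_lookup = NULL, impute_spec = NULL,
                       prior_qc = NULL, key_vars = NULL, seed = 1L) {
  norm <- function(p) normalizePath(p, mustWork = FALSE)
  if (startsWith(norm(key_sink), norm(output_dir)))
    config_error("key sink must not lie inside the output directory")
  if (is.character(postcode_lookup))
    postcode_lookup <- read_postcode_lookup(postcode_lookup)
  structure(list(salt = salt, key_sink = key_sink, output_dir = output_dir,
                 dictionary = dictionary, dict_sites = dict_sites,
                 expected_window = as.Date(expected_window),
                 phase_windows = phase_windows, policy = policy,
                 postcode_lookup = postcode_lookup,
                 impute_spec = impute_spec, prior_qc = prior_qc,
                 key_vars = key_vars, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the pipeline over per-site raw bundles
#'
#' Executes, per site: pseudonymisation (key file to the key sink), the
#' staged QC checklist, off-spine removal, harmonisation, true-duplicate
#' removal, linkage, the outlier policy, and phase tagging; then assembles
#' the combined analysis table and, if configured, imputes it. Every stage
#' writes outputs under the run's output directory and the manifest records
#' row counts and content digests.
#'
#' @param bundles Named list `site -> record_bundle` at stage `"raw"`.
#' @param config A [run_config()].
#' @return List: `bundles` (cleaned per-site bundles), `qc` (per-site
#'   reports), `link_reports`, `analysis` (combined table or `NULL`),
#'   `completed` (imputations or `NULL`), `manifest`.
#' @export
run_pipeline <- function(bundles, config) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  dict <- if (inherits(config$dictionary, "epr_dictionary"))
    config$dictionary else load_dictionary(config$dictionary)
  qc <- list(); link_reports <- list(); out_bundles <- list()
  audits <- list(); removals <- list()
  stage_log <- list()

  for (site in names(bundles)) {
    b <- bundles[[site]]
    ps <- pseudonymise_bundle(b, config$salt,
                              postcode_lookup = config$postcode_lookup,
                              key_sink = config$key_sink)
    b <- ps$bundle
    stage_log[[paste0(site, ":pseudonymised")]] <- table_rows(b)

    qc[[site]] <- if (is.null(config$prior_qc)) {
      first_download_checks(b, config$expected_window, dict,
                            site = config$dict_sites[[site]])
    } else {
      second_download_checks(b, config$prior_qc[[site]],
                             key_vars = config$key_vars %||%
                               list(maternity = c("mat_h_bwt", "mat_h_ga")),
                             expected_window = config$expected_window)
    }

    b <- drop_off_spine(b)$bundle
    h <- harmonise_bundle(b, dict, site = config$dict_sites[[site]])
    b <- h$bundle
    audits[[site]] <- h$audit
    stage_log[[paste0(site, ":harmonised")]] <- table_rows(b)

    # drop true duplicates before episode assignment
    cls <- classify_duplicates(b$maternity, b$ultrasound)
    b$maternity <- b$maternity[cls != "true_duplicate", , drop = FALSE]

    lk <- link_bundle(b)
    b <- lk$bundle
    link_reports[[site]] <- dplyr::mutate(lk$report, site = site)

    pol <- config$policy[config$policy$variable %in%
                           unlist(lapply(b, names)), , drop = FALSE]
    oc <- apply_outlier_policy(b, pol)
    b <- oc$bundle
    removals[[site]] <- oc$removals
    stage_log[[paste0(site, ":cleaned")]] <- table_rows(b)

    if (!is.null(config$phase_windows)) {
      pt <- phase_tag(b$maternity, config$phase_windows)
      b$maternity <- pt$records
      stage_log[[paste0(site, ":phase_excluded")]] <- pt$excluded
    }
    out_bundles[[site]] <- b
    write_bundle(b, file.path(config$output_dir, "cleaned"))
  }

  analysis <- build_analysis_table(out_bundles)
  completed <- NULL
  if (!is.null(analysis)) {
    readr::write_csv(analysis, file.path(config$output_dir, "analysis.csv"),
                     na = "")
    if (!is.null(config$impute_spec)) {
      completed <- mice_impute(analysis, config$impute_spec)
      long <- bind_rows(lapply(seq_along(completed), function(i)
        mutate(completed[[i]], .imp = i)))
      readr::write_csv(long, file.path(config$output_dir, "imputed_long.csv"),
                       na = "")
    }
  }

  # identifier columns must not survive anywhere downstream
  leaked <- identifier_leaks(out_bundles)
  if (length(leaked))
    abort(paste0("identifier column(s) survived pseudonymisation: ",
                 paste(leaked, collapse = ", ")), class = "eprlink_error")

  out_files <- sort(list.files(config$output_dir, recursive = TRUE,
                               full.names = TRUE))
  manifest <- list(
    package_version = as.character(utils::packageVersion("eprlink")),
    seed = config$seed,
    sites = names(bundles),
    stage_rows = stage_log,
    digests = setNames(as.vector(tools::md5sum(out_files)),
                       basename(out_files)))
  jsonlite::write_json(manifest, file.path(config$output_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(bundles = out_bundles, qc = qc, link_reports = bind_rows(link_reports),
       audits = audits, removals = bind_rows(removals),
       analysis = analysis, completed = completed, manifest = manifest)
}

table_rows <- function(bundle) {
  vapply(bundle, function(t) if (is.null(t)) 0L else nrow(t), integer(1))
}

identifier_leaks <- function(bundles) {
  leaks <- character(0)
  for (site in names(bundles)) {
    for (nm in names(bundles[[site]])) {
      tab <- bundles[[site]][[nm]]
      if (is.null(tab)) next
      hit <- intersect(IDENTIFIER_COLS, names(tab))
      if (length(hit))
        leaks <- c(leaks, paste0(site, "/", nm, ": ",
                                 paste(hit, collapse = ",")))
    }
  }
  leaks
}

#' Assemble the combined analysis table from linked, cleaned bundles
#'
#' One row per baby (maternity row), with `site`, the harmonised maternal
#' and infant variables, and `sga_detected_antenatal` — `"yes"` when any
#' ultrasound scan linked to the pregnancy carries a suspected-SGA flag.
#'
#' @param bundles Named list `site -> record_bundle` (linked/cleaned).
#' @return A tibble, or `NULL` when no bundle has a maternity table.
#' @export
build_analysis_table <- function(bundles) {
  rows <- list()
  for (site in names(bundles)) {
    b <- bundles[[site]]
    mat <- b$maternity
    if (is.null(mat)) next
    mat$site <- site
    det <- rep("no", nrow(mat))
    if (!is.null(b$ultrasound) && "episode_id" %in% names(b$ultrasound) &&
        "uss_h_sgaflag" %in% names(b$ultrasound)) {
      flagged <- unique(b$ultrasound$episode_id[
        !is.na(b$ultrasound$episode_id) &
          b$ultrasound$uss_h_sgaflag == "yes"])
      det[mat$episode_id %in% flagged] <- "yes"
    }
    mat$sga_detected_antenatal <- det
    keep <- intersect(c("site", "study_id", "episode_id", "record_id",
                        "phase", "age_at_delivery", "imd",
                        grep("^(mat)_(h|c)_", names(mat), value = TRUE),
                        "sga_detected_antenatal"), names(mat))
    rows[[site]] <- mat[, keep, drop = FALSE]
  }
  if (!length(rows)) return(NULL)
  bind_rows(rows)
}
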