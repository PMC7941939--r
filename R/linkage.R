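# Deterministic linkage of the satellites onto the maternity spine using
# three rules: (i) shared study ID, (ii) neonatal date of birth within 7 days
# of the mother's delivery, (iii) event dates inside the closed pregnancy
# window [EDC, DOD], where EDC = date of delivery - gestational age + 14 days.
# Pregnancy episodes are numbered per woman by the "_n" suffix.

#' Estimated date of conception
#'
#' `EDC = date of delivery - gestational age at birth + 14 days`, exact
#' calendar arithmetic with gestational age in completed days.
#'
#' @param dod Delivery date(s).
#' @param ga_days Gestational age at birth in completed days (0-330).
#' @return Date vector; missing gestational age gives a missing EDC.
#' @export
compute_edc <- function(dod, ga_days) {
  dod <- as.Date(dod)
  bad <- !is.na(ga_days) & (ga_days < 0 | ga_days > 330)
  if (any(bad)) config_error("ga_days outside [0, 330]")
  out <- dod - ga_days + 14L
  out[is.na(ga_days)] <- NA
  out
}

#' Assign pregnancy-episode identifiers on the maternity spine
#'
#' Within each woman (study ID), distinct delivery dates sorted ascending
#' receive episode numbers 1, 2, ...; rows sharing a delivery date — babies
#' of one multiple birth — share the episode. The episode identifier is
#' rendered `study_id + "_n"`. Rows with a missing delivery date are flagged
#' unlinkable and excluded from numbering.
#'
#' @param maternity Harmonised maternity table with `study_id` and
#'   `mat_h_dod` (or `dod`).
#' @return The table with `episode_n` and `episode_id` columns (`NA` for
#'   unlinkable rows).
#' @export
assign_episodes <- function(maternity) {
  dod <- episode_dod(maternity)
  out <- maternity
  out$.dod <- dod
  if (anyNA(dod))
    warn(paste0(sum(is.na(dod)), " maternity row(s) lack a delivery date; ",
                "flagged unlinkable"))
  out <- out %>%
    group_by(.data$study_id) %>%
    mutate(episode_n = ifelse(is.na(.data$.dod), NA_integer_,
                              dense_rank(.data$.dod))) %>%
    ungroup()
  out$episode_id <- ifelse(is.na(out$episode_n), NA_character_,
                           paste0(out$study_id, "_", out$episode_n))
  out$.dod <- NULL
  out
}

episode_dod <- function(maternity) {
  d <- col_or_null(maternity, "mat_h_dod", "dod")
  if (is.null(d)) config_error("maternity table has no delivery-date column")
  as.Date(parse_mixed_date(d))
}

episode_ga <- function(maternity) {
  g <- col_or_null(maternity, "mat_h_ga", "ga_days")
  if (is.null(g)) config_error("maternity table has no gestational-age column")
  suppressWarnings(as.numeric(g))
}

# one row per episode with its window
episode_table <- function(maternity) {
  dod <- episode_dod(maternity)
  ga <- episode_ga(maternity)
  tab <- tibble(study_id = maternity$study_id,
                episode_id = maternity$episode_id,
                dod = dod, ga_days = ga) %>%
    filter(!is.na(.data$episode_id)) %>%
    distinct(.data$episode_id, .keep_all = TRUE)
  tab$edc <- as.Date(rep(NA, nrow(tab)))
  ok <- !is.na(tab$ga_days)
  if (any(!ok))
    warn(paste0(sum(!ok), " episode(s) lack gestational age; excluded from ",
                "window linkage"))
  tab$edc[ok] <- compute_edc(tab$dod[ok], tab$ga_days[ok])
  tab
}

#' Link neonatal records to the correct mother, pregnancy and baby
#'
#' A neonatal row attaches to the episode with the same study ID whose
#' delivery date lies within 7 days of the neonatal date of birth. If two
#' episodes qualify (deliveries under 14 days apart — only possible through
#' a data error) the closest date wins, then the earlier episode, and the row
#' is logged ambiguous. Within a multiple-birth episode the neonatal row is
#' assigned to one baby row by sex, then nearest birthweight, then first
#' unclaimed birth order.
#'
#' @param maternity Maternity table with episodes assigned.
#' @param neonatal Harmonised neonatal table with `study_id`, `neo_h_dob`
#'   and optionally `neo_h_sex` / `neo_h_bwt`.
#' @return List: `assignments` (neonatal `record_id`, `episode_id`,
#'   maternity `record_id` of the matched baby row, status), `report` (a
#'   [link_report()] row).
#' @export
link_neonatal <- function(maternity, neonatal) {
  eps <- episode_table(maternity)
  ndob <- as.Date(parse_mixed_date(col_or_null(neonatal, "neo_h_dob",
                                               "neonatal_dob")))
  nn <- nrow(neonatal)
  cand <- tibble(idx = seq_len(nn), study_id = neonatal$study_id,
                 ndob = ndob) %>%
    inner_join(select(eps, "study_id", "episode_id", "dod"),
               by = "study_id", relationship = "many-to-many") %>%
    mutate(diff = abs(as.integer(.data$ndob - .data$dod))) %>%
    filter(!is.na(.data$diff), .data$diff <= 7L)
  cand <- cand %>%
    group_by(.data$idx) %>%
    mutate(n_cand = dplyr::n_distinct(.data$episode_id)) %>%
    arrange(.data$diff, .data$dod, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
  status <- rep("unmatched", nn)
  episode <- rep(NA_character_, nn)
  status[cand$idx] <- ifelse(cand$n_cand > 1, "ambiguous", "matched")
  episode[cand$idx] <- cand$episode_id

  # assign each matched neonatal row to a distinct baby row of its episode
  baby_rid <- rep(NA_character_, nn)
  mat_eps <- maternity[!is.na(maternity$episode_id), , drop = FALSE]
  neo_sex <- col_or_null(neonatal, "neo_h_sex") %||% rep(NA_character_, nn)
  neo_bwt <- suppressWarnings(as.numeric(col_or_null(neonatal, "neo_h_bwt") %||%
                                           rep(NA_real_, nn)))
  for (i in which(!is.na(episode))) {
    rows <- mat_eps[mat_eps$episode_id == episode[i] &
                      !(mat_eps$record_id %in% baby_rid), , drop = FALSE]
    if (nrow(rows) == 0L) { status[i] <- "unmatched"; episode[i] <- NA; next }
    score <- rep(0, nrow(rows))
    if (!is.na(neo_sex[i]) && "mat_h_sex" %in% names(rows))
      score <- score + ifelse(!is.na(rows$mat_h_sex) &
                                rows$mat_h_sex == neo_sex[i], -1000, 0)
    if (!is.na(neo_bwt[i]) && "mat_h_bwt" %in% names(rows))
      score <- score + ifelse(is.na(rows$mat_h_bwt), 500,
                              abs(rows$mat_h_bwt - neo_bwt[i]))
    baby_rid[i] <- rows$record_id[order(score)[1]]
  }
  assignments <- tibble(record_id = col_or_null(neonatal, "record_id") %||%
                          as.character(seq_len(nn)),
                        episode_id = episode, baby_record_id = baby_rid,
                        status = status)
  list(assignments = assignments,
       report = link_report_row("neonatal", assignments, eps))
}

#' Link long-format events (ultrasound or activity) to pregnancy windows
#'
#' An event attaches to the episode of the same study ID whose closed
#' window `[EDC, DOD]` contains the event date; postnatal events are never
#' linked. An event date falling in two windows (a data error) goes to the
#' episode with the latest EDC and is logged ambiguous.
#'
#' @param maternity Maternity table with episodes assigned.
#' @param events Long-format table with `study_id` and an event-date column
#'   (`uss_h_scandate`, `act_h_eventdate` or `event_date`).
#' @param kind `"ultrasound"` or `"activity"` (report labelling only).
#' @return List: `assignments` (event `record_id`, `episode_id`, status) and
#'   `report`.
#' @export
link_window <- function(maternity, events, kind = c("ultrasound",
                                                    "activity")) {
  kind <- match.arg(kind)
  eps <- episode_table(maternity)
  date_col <- intersect(c("uss_h_scandate", "act_h_eventdate", "event_date"),
                        names(events))[1]
  if (is.na(date_col)) config_error("events table has no event-date column")
  ev_date <- as.Date(parse_mixed_date(events[[date_col]]))
  ne <- nrow(events)
  cand <- tibble(idx = seq_len(ne), study_id = events$study_id,
                 date = ev_date) %>%
    inner_join(select(eps, "study_id", "episode_id", "edc", "dod"),
               by = "study_id", relationship = "many-to-many") %>%
    filter(!is.na(.data$date), !is.na(.data$edc),
           .data$date >= .data$edc, .data$date <= .data$dod)
  cand <- cand %>%
    group_by(.data$idx) %>%
    mutate(n_cand = dplyr::n_distinct(.data$episode_id)) %>%
    arrange(dplyr::desc(.data$edc), .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
  status <- rep("unmatched", ne)
  episode <- rep(NA_character_, ne)
  status[cand$idx] <- ifelse(cand$n_cand > 1, "ambiguous", "matched")
  episode[cand$idx] <- cand$episode_id
  assignments <- tibble(record_id = col_or_null(events, "record_id") %||%
                          as.character(seq_len(ne)),
                        episode_id = episode, status = status)
  list(assignments = assignments,
       report = link_report_row(kind, assignments, eps))
}

link_report_row <- function(table, assignments, eps) {
  tibble(table = table,
         matched = sum(assignments$status == "matched"),
         unmatched = sum(assignments$status == "unmatched"),
         ambiguous = sum(assignments$status == "ambiguous"),
         spine_pregnancies = nrow(eps),
         linked_pregnancies = dplyr::n_distinct(
           assignments$episode_id[!is.na(assignments$episode_id)]),
         linkage_rate = dplyr::n_distinct(
           assignments$episode_id[!is.na(assignments$episode_id)]) /
           max(nrow(eps), 1L))
}

#' Link a whole bundle and report per-table linkage rates
#'
#' Assigns episodes on the spine, links each satellite with its rule, writes
#' `episode_id` columns onto the satellites, and reports per-table matched /
#' unmatched / ambiguous counts and the linkage rate (linked pregnancies /
#' spine pregnancies). A satellite the site could not provide is reported
#' with rate 0 and flagged.
#'
#' @param bundle A harmonised [record_bundle()].
#' @return List: `bundle` (stage `"linked"`), `report` (one row per
#'   satellite), `assignments` (per-satellite assignment tables).
#' @export
link_bundle <- function(bundle) {
  mat <- assign_episodes(bundle$maternity)
  bundle$maternity <- mat
  report <- list(); assignments <- list()
  eps <- episode_table(mat)

  if (!is.null(bundle$neonatal)) {
    res <- link_neonatal(mat, bundle$neonatal)
    bundle$neonatal$episode_id <- res$assignments$episode_id
    bundle$neonatal$baby_record_id <- res$assignments$baby_record_id
    bundle$neonatal$link_status <- res$assignments$status
    report$neonatal <- res$report
    assignments$neonatal <- res$assignments
  } else {
    report$neonatal <- absent_report_row("neonatal", eps)
  }
  for (kind in c("ultrasound", "activity")) {
    if (!is.null(bundle[[kind]])) {
      res <- link_window(mat, bundle[[kind]], kind)
      bundle[[kind]]$episode_id <- res$assignments$episode_id
      bundle[[kind]]$link_status <- res$assignments$status
      report[[kind]] <- res$report
      assignments[[kind]] <- res$assignments
    } else {
      report[[kind]] <- absent_report_row(kind, eps)
    }
  }
  list(bundle = set_stage(bundle, "linked"), report = bind_rows(report),
       assignments = assignments)
}

absent_report_row <- function(table, eps) {
  tibble(table = table, matched = 0L, unmatched = 0L, ambiguous = 0L,
         spine_pregnancies = nrow(eps), linked_pregnancies = 0L,
         linkage_rate = 0, note = "extract not provided")
}
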