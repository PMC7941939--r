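# Pseudonymisation: the 20-character study identifier.
#
# Characters 1-19 are the decimal rendering of a salt-keyed cryptographic
# digest (HMAC-SHA256) of NHS number and date of birth; character 20 is a
# check letter over characters 1-19. The same woman therefore always receives
# the same identifier at a site, no identifier substring survives verbatim,
# and single-character transcription errors are caught by the check letter.

# check-letter weights: positions 1..19, with the weight divisible by 13
# replaced, so that w * delta is never 0 mod 26 for a single digit
# substitution (|delta| <= 9) and every such error is detected
CHECK_WEIGHTS <- c(1:12, 14:20)

# character value: digits 0-9 -> 0-9, letters A-Z -> 10-35 (manual IDs carry
# letters in the body)
char_values <- function(chars) {
  v <- match(chars, c(as.character(0:9), LETTERS)) - 1L
  v
}

check_char <- function(body19) {
  vals <- char_values(strsplit(body19, "")[[1]])
  if (anyNA(vals)) return(NA_character_)
  LETTERS[(sum(CHECK_WEIGHTS * vals) %% 26L) + 1L]
}

# vectorised check letters for a character vector of 19-char bodies
check_chars <- function(bodies) {
  m <- matrix(char_values(unlist(strsplit(bodies, ""), use.names = FALSE)),
              ncol = 19, byrow = TRUE)
  LETTERS[(as.vector(m %*% CHECK_WEIGHTS) %% 26L) + 1L]
}

#' Generate the automated 20-character study identifier
#'
#' Deterministic pseudonymisation of one woman: HMAC-SHA256 keyed by the
#' site salt over the NHS number and date of birth, rendered as 19 decimal
#' digits, plus a check letter. Only the NHS number and DOB enter the digest,
#' so a woman keeps one identifier across pregnancies and across extracts.
#'
#' @param nhs_number 10-digit NHS number(s); must pass
#'   [validate_nhs_number()].
#' @param dob Date(s) of birth.
#' @param site_salt Secret salt string (per site or trial-wide, by
#'   configuration).
#' @return Character vector of 20-character study IDs (19 digits + check
#'   letter). Elements with a missing or invalid NHS number or missing DOB
#'   are `NA` — callers must route those women through [make_manual_id()].
#' @export
make_study_id <- function(nhs_number, dob, site_salt) {
  assert_that(is.character(site_salt) && length(site_salt) == 1L &&
                nzchar(site_salt), "site_salt must be a non-empty string")
  dob <- as.Date(dob)
  n <- max(length(nhs_number), length(dob))
  nhs_number <- rep_len(as.character(nhs_number), n)
  dob <- rep_len(dob, n)
  ok <- validate_nhs_number(nhs_number) & !is.na(dob)
  out <- rep(NA_character_, n)
  if (!any(ok)) return(out)
  msg <- paste0(nhs_number[ok], "|", format(dob[ok], "%Y-%m-%d"))
  digest <- as.character(openssl::sha256(msg, key = site_salt))
  # first 19 bytes of the digest, each reduced mod 10, give the digit body
  bytes <- matrix(strtoi(substring(rep(digest, each = 19),
                                   seq_len(19) * 2 - 1, seq_len(19) * 2),
                         base = 16L),
                  nrow = 19)
  digits <- bytes %% 10L
  body <- apply(digits, 2, paste0, collapse = "")
  out[ok] <- paste0(body, check_chars(body))
  out
}

#' Generate a manual study identifier
#'
#' Issued when a woman lacks the NHS number or DOB the automated tool needs.
#' Manual IDs occupy a disjoint namespace: they start with `"M"` (automated
#' IDs are all digits up to the check letter). A manual ID denotes a unique
#' *pregnancy* — the same identifier-less woman receives a new manual ID for
#' each birth.
#'
#' @param site_code Site code (letters/digits; embedded, padded to 6).
#' @param counter Positive integer, unique per site per run; width 12.
#' @return A 20-character ID: `"M"` + padded site + 12-digit counter + check
#'   letter.
#' @export
make_manual_id <- function(site_code, counter) {
  n <- max(length(site_code), length(counter))
  site_code <- rep_len(site_code, n); counter <- rep_len(counter, n)
  if (any(counter < 1 | counter > 999999999999))
    abort("manual ID counter outside the fixed 12-digit width",
          class = "eprlink_error")
  site <- toupper(gsub("[^A-Z0-9]", "", toupper(site_code)))
  site <- sprintf("%-6s", substr(site, 1, 6))
  site <- gsub(" ", "0", site, fixed = TRUE)
  body <- paste0("M", site, sprintf("%012.0f", as.numeric(counter)))
  paste0(body, check_chars(body))
}

#' Verify the check character of a study identifier
#'
#' @param id Character vector of candidate IDs.
#' @return Logical: `TRUE` iff the string is 20 characters over `[0-9A-Z]`
#'   and its 20th character equals the weighted checksum of characters 1-19.
#' @export
verify_check_char <- function(id) {
  x <- as.character(id)
  ok <- !is.na(x) & grepl("^[0-9A-Z]{19}[A-Z]$", x)
  out <- rep(FALSE, length(x))
  if (!any(ok)) return(out)
  body <- substr(x[ok], 1, 19)
  out[ok] <- check_chars(body) == substr(x[ok], 20, 20)
  out
}

#' Simulate study-ID collisions on a fictitious cohort
#'
#' Generates `n` identifier sets (distinct NHS numbers, DOBs uniform in
#' `dob_range`), attaches delivery dates from `dod_range`, pseudonymises each
#' woman, and counts duplicate identifiers (extras beyond the first
#' occurrence). Narrow date ranges stress the risk that different women
#' receive the same ID.
#'
#' @param n Cohort size.
#' @param dob_range,dod_range Date intervals for maternal DOB and delivery.
#' @param seed Integer seed.
#' @param site_salt Salt used for the run.
#' @param id_fn Optional alternative ID function `(nhs_number, dob, dod) ->
#'   id`, used to study deliberately lossy schemes; default uses
#'   [make_study_id()] (which ignores the delivery date).
#' @return List: `duplicates` (count of extra occurrences), `n`, and the
#'   `ids` themselves (invisible content for further checks).
#' @export
simulate_collisions <- function(n, dob_range = as.Date(c("1989-01-01",
                                                         "1990-12-31")),
                                dod_range = as.Date(c("2017-01-01",
                                                      "2018-11-30")),
                                seed = 1L, site_salt = "trial-salt",
                                id_fn = NULL) {
  assert_that(is_scalar_number(n) && n >= 1, "n must be >= 1")
  ids <- generate_identifiers(n, dob_range, seed = seed)
  dod_range <- as.Date(dod_range)
  set.seed(seed + 1L)
  span <- as.integer(dod_range[2] - dod_range[1])
  dod <- dod_range[1] + sample.int(span + 1L, n, replace = TRUE) - 1L
  study_ids <- if (is.null(id_fn)) {
    make_study_id(ids$nhs_number, ids$dob, site_salt)
  } else {
    id_fn(ids$nhs_number, ids$dob, dod)
  }
  list(duplicates = as.integer(sum(duplicated(study_ids))), n = n,
       ids = study_ids)
}

#' Pseudonymise a bundle: attach study IDs, derive demographics, strip
#' identifiers
#'
#' Attaches a `study_id` to every row of every table, derives age at delivery
#' and deprivation measures on the maternity spine, removes every
#' identifiable column (NHS number, hospital number, DOB, postcode) from all
#' emitted tables, and returns the key file linking study IDs back to
#' identifiers — which must be written only to `key_sink` and never travel
#' with the de-identified bundle.
#'
#' @param bundle A raw [record_bundle()] carrying identifier columns.
#' @param site_salt Salt for [make_study_id()].
#' @param postcode_lookup Tibble with columns `postcode`, `imd`, `lsoa`,
#'   `msoa` (see [read_postcode_lookup()]).
#' @param key_sink Directory the key file is written to, or `NULL` to skip
#'   writing (the key file is still returned).
#' @return List: `bundle` (stage `"pseudonymised"`), `key_file` (study ID,
#'   identifiers, site, creation time), `n_manual` (women routed through
#'   manual IDs).
#' @export
pseudonymise_bundle <- function(bundle, site_salt, postcode_lookup = NULL,
                                key_sink = NULL) {
  site <- bundle_site(bundle)
  mat <- bundle$maternity
  assert_that(all(c("nhs_number", "dob") %in% names(mat)),
              "maternity table must carry nhs_number and dob")
  mat$dob <- parse_mixed_date(mat$dob)
  auto_id <- make_study_id(mat$nhs_number, mat$dob, site_salt)

  # women lacking NHS number or DOB get a manual ID per pregnancy
  needs_manual <- is.na(auto_id)
  study_id <- auto_id
  n_manual <- 0L
  if (any(needs_manual)) {
    # one manual ID per pregnancy: rows sharing (hospital number, delivery
    # date) — one pregnancy's babies — share the ID; a later birth of the
    # same woman gets a new one; rows with no hospital number stand alone
    hosp <- as.character(col_or_null(mat, "hospital_number") %||%
                           rep(NA_character_, nrow(mat)))
    dodc <- as.character(col_or_null(mat, "dod") %||% rep(NA_character_, nrow(mat)))
    key <- ifelse(is.na(hosp), paste0("row", seq_len(nrow(mat))),
                  paste(hosp, dodc))
    grp <- match(key[needs_manual], unique(key[needs_manual]))
    study_id[needs_manual] <- make_manual_id(site, grp)
    n_manual <- length(unique(grp))
  }

  dod <- parse_mixed_date(col_or_null(mat, "dod"))
  demo <- derive_demographics(mat$dob, dod, col_or_null(mat, "postcode"),
                              postcode_lookup)
  mat_out <- bind_cols(tibble(study_id = study_id), mat, demo)
  mat_out <- select(mat_out, -any_of(IDENTIFIER_COLS))

  # key file: one row per distinct automated (site, woman) + manual entries
  key_file <- tibble(study_id = study_id,
                     nhs_number = as.character(mat$nhs_number),
                     hospital_number = as.character(col_or_null(mat, "hospital_number") %||%
                                                      NA_character_),
                     dob = mat$dob,
                     postcode = as.character(col_or_null(mat, "postcode") %||% NA_character_),
                     site_code = site,
                     created_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")) %>%
    distinct(.data$study_id, .keep_all = TRUE)

  # satellites: same digest on their own identifier columns
  lookup_tbl <- NULL
  for (nm in c("neonatal", "ultrasound", "activity")) {
    tab <- bundle[[nm]]
    if (is.null(tab)) next
    sid <- make_study_id(tab$nhs_number, parse_mixed_date(tab$dob), site_salt)
    tab <- bind_cols(tibble(study_id = sid), tab)
    tab <- select(tab, -any_of(IDENTIFIER_COLS))
    bundle[[nm]] <- tab
  }
  bundle$maternity <- mat_out
  bundle <- set_stage(bundle, "pseudonymised")

  if (!is.null(key_sink)) {
    dir.create(key_sink, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(key_file, file.path(key_sink,
                                         paste0(site, "_keyfile.csv")),
                     na = "")
  }
  list(bundle = bundle, key_file = key_file, n_manual = n_manual)
}

# age at delivery (completed years) and deprivation via the postcode lookup
derive_demographics <- function(dob, dod, postcode, lookup) {
  age <- floor(as.numeric(lubridate::interval(dob, dod) /
                            lubridate::years(1)))
  out <- tibble(age_at_delivery = age)
  if (!is.null(lookup) && !is.null(postcode)) {
    pc <- normalise_postcode(postcode)
    lookup$postcode <- normalise_postcode(lookup$postcode)
    idx <- match(pc, lookup$postcode)
    if (anyNA(idx[!is.na(pc)])) {
      warn(paste0(sum(is.na(idx[!is.na(pc)])),
                  " postcode(s) absent from lookup; deprivation left missing"))
    }
    out$imd <- lookup$imd[idx]
    out$lsoa <- lookup$lsoa[idx]
    out$msoa <- lookup$msoa[idx]
  } else {
    out$imd <- NA_real_; out$lsoa <- NA_character_; out$msoa <- NA_character_
  }
  out
}

# uppercase, single internal space before lookup
normalise_postcode <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- gsub("\\s+", "", x)
  ifelse(is.na(x) | nchar(x) < 5, x,
         paste(substr(x, 1, nchar(x) - 3),
               substr(x, nchar(x) - 2, nchar(x))))
}

#' Read a postcode-to-deprivation lookup table
#'
#' CSV with columns `postcode`, `imd`, `lsoa`, `msoa`. The package bundles a
#' synthetic stand-in for the national postcode lookup at
#' `system.file("extdata", "synthetic_postcode_lookup.csv", package =
#' "eprlink")`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_postcode_lookup <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Drop satellite rows with no birth on the maternity spine
#'
#' Women appearing in the neonatal, ultrasound or activity extracts without a
#' maternity birth record cannot be analysed and are removed.
#'
#' @param bundle A pseudonymised [record_bundle()].
#' @return List: `bundle` with off-spine satellite rows removed, and
#'   `removed` — a named count per satellite table.
#' @export
drop_off_spine <- function(bundle) {
  spine <- unique(bundle$maternity$study_id)
  if (length(spine) == 0L)
    warn("maternity spine is empty; all satellite rows will be removed")
  removed <- c(neonatal = 0L, ultrasound = 0L, activity = 0L)
  for (nm in names(removed)) {
    tab <- bundle[[nm]]
    if (is.null(tab)) next
    keep <- tab$study_id %in% spine
    removed[[nm]] <- sum(!keep)
    bundle[[nm]] <- tab[keep, , drop = FALSE]
  }
  list(bundle = bundle, removed = removed)
}

#' Deterministic synthetic postcode lookup for a set of postcodes
#'
#' Builds a deprivation lookup (IMD rank, LSOA, MSOA codes) covering the
#' given postcodes. Values are a synthetic, deterministic function of the
#' postcode text — a stand-in for the national postcode lookup, suitable for
#' exercising the derivation path, never for real geography.
#'
#' @param postcodes Character vector.
#' @param coverage Fraction of postcodes present in the lookup (the rest are
#'   omitted, emulating unmatched postcodes).
#' @return Tibble with columns `postcode`, `imd`, `lsoa`, `msoa`.
#' @export
synthetic_postcode_lookup <- function(postcodes, coverage = 1) {
  pc <- unique(normalise_postcode(postcodes))
  pc <- pc[!is.na(pc)]
  h <- openssl::md5(pc)
  num <- strtoi(substr(as.character(h), 1, 6), base = 16L)
  keep <- (num %% 1000L) < round(coverage * 1000)
  tibble(postcode = pc[keep],
         imd = 1L + (num[keep] %% 32844L),
         lsoa = sprintf("E01%06d", num[keep] %% 1000000L),
         msoa = sprintf("E02%06d", (num[keep] %/% 7L) %% 1000000L))
}
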