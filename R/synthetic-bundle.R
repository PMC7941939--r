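# Synthetic multi-site EPR bundles with known ground truth.
#
# The generator draws a cohort of women and pregnancies, renders the four
# extracts (maternity spine, neonatal / ultrasound / activity satellites) in
# one of three source-system dialects, then injects configured defects and
# missingness, logging every corruption so downstream stages can be tested
# against truth.

# ---- dialect profiles -------------------------------------------------------

# vocabularies: each canonical category maps to >=1 raw terms the dialect uses
DIALECTS <- list(
  alpha = list(
    date_style = "iso",
    cols = c(ga = "GestationAtDelivery", height = "HeightCm",
             weight = "WeightKg", ethnicity = "Ethnicity",
             modebirth = "DeliveryMode", parity = "Parity",
             chronichtn = "ChronicHTN", analg_labour = "LabourAnalgesia",
             analg_birth = "BirthAnalgesia", ebl = "BloodLossMl",
             sex = "InfantSex", birthweight = "BirthweightG"),
    ga_style = "weeks_plus_days",
    height_unit = "cm", weight_unit = "kg",
    ethnicity = list(White = c("White British", "White Other"),
                     Black = c("Black African", "Black Caribbean"),
                     Asian = c("Asian - Indian", "Asian - Other"),
                     Mixed = "Mixed", Other = "Any Other"),
    modebirth = list(`unassisted vaginal` = "SVD",
                     `assisted vaginal` = c("Ventouse", "Forceps"),
                     `caesarean section` = c("Em LSCS", "El LSCS")),
    sex = c(male = "M", female = "F"),
    binary = c(yes = "Y", no = "N"),
    epidural_term = "Epidural",
    analg_other = c("Entonox", "Pethidine", "None"),
    affirmative_only = character(0)
  ),
  bravo = list(
    date_style = "dmy",
    cols = c(ga = "gest_wks", height = "height_ftin",
             weight = "weight_stlb", ethnicity = "ethnic_group",
             modebirth = "birth_method", parity = "para",
             chronichtn = "htn_chronic", analg_labour = "analgesia_labour",
             analg_birth = "analgesia_birth", ebl = "ebl_ml",
             sex = "infant_sex", birthweight = "bwt_grams"),
    ga_style = "decimal_weeks",
    height_unit = "ft_in", weight_unit = "st_lb",
    ethnicity = list(White = c("British", "Irish", "White other"),
                     Black = c("African", "Caribbean"),
                     Asian = c("Indian", "Pakistani", "Chinese"),
                     Mixed = "Mixed background", Other = "Other group"),
    modebirth = list(`unassisted vaginal` = "Normal Delivery",
                     `assisted vaginal` = c("Instrumental - Ventouse",
                                            "Instrumental - Forceps"),
                     `caesarean section` = c("Emergency Caesarean",
                                             "Elective Caesarean")),
    sex = c(male = "Male", female = "Female"),
    binary = c(yes = "Yes", no = "No"),
    epidural_term = "EPIDURAL",
    analg_other = c("GAS & AIR", "TENS", "NIL"),
    affirmative_only = character(0)
  ),
  charlie = list(
    date_style = "serial",
    cols = c(ga = "ga_days", height = "height_m", weight = "weight_kg",
             ethnicity = "ethnicity_code", modebirth = "mode_del",
             parity = "parity_group", chronichtn = "pet_htn",
             analg_labour = "epidural_flag", analg_birth = "analgesia_text",
             ebl = "blood_loss", sex = "sex_code",
             birthweight = "birth_weight"),
    ga_style = "days",
    height_unit = "m", weight_unit = "kg",
    ethnicity = list(White = c("WB", "WO"), Black = c("BA", "BC"),
                     Asian = c("AI", "AO"), Mixed = "MX", Other = "OT"),
    modebirth = list(`unassisted vaginal` = "spont vertex",
                     `assisted vaginal` = c("ventouse del", "forceps del"),
                     `caesarean section` = c("lscs emergency",
                                             "lscs elective")),
    sex = c(male = "1", female = "2"),
    binary = c(yes = "1", no = "0"),
    # parity only collected as a binary group at this dialect
    parity_binary = TRUE,
    epidural_term = "1",
    analg_other = c("spinal", "remifentanil", "none recorded"),
    # these two are recorded affirmative-only at source
    affirmative_only = c("chronichtn", "analg_labour")
  )
)

dialect_profile <- function(name) {
  p <- DIALECTS[[name]]
  if (is.null(p)) config_error(paste0("unknown dialect: ", name))
  p$parity_binary <- isTRUE(p$parity_binary)
  p
}

# ---- birthweight model (also the bundled centile stand-in) ------------------

#' Synthetic birthweight model and small-for-gestational-age cutoff
#'
#' Median birthweight follows a quadratic-in-log gestational-age curve with a
#' multiplicative sex effect; spread is proportional to the median. The 10th
#' centile of this model is the package's *synthetic* stand-in for the
#' customised-centile calculator used at analysis time (the real calculator
#' is external and pluggable).
#'
#' @param ga_days Gestational age at birth in completed days.
#' @param sex `"male"` or `"female"`.
#' @return For `synthetic_bw_median`, the model median in grams; for
#'   `synthetic_sga_cutoff`, the 10th-centile cutoff in grams.
#' @export
synthetic_bw_median <- function(ga_days, sex) {
  wk <- ga_days / 7
  mu <- exp(0.578 + 0.332 * wk - 0.00354 * wk^2)
  mu * ifelse(sex == "male", 1.025, 0.975)
}

#' @rdname synthetic_bw_median
#' @export
synthetic_sga_cutoff <- function(ga_days, sex) {
  mu <- synthetic_bw_median(ga_days, sex)
  qnorm(0.10, mean = mu, sd = 0.11 * mu)
}

# ---- cohort truth -----------------------------------------------------------

draw_cohort <- function(config) {
  n <- config$n_women
  ids <- generate_identifiers(n, config$dob_range,
                              seed = sample.int(.Machine$integer.max, 1),
                              site_code = config$site_code)
  eth <- sample(c("White", "Black", "Asian", "Mixed", "Other"), n,
                replace = TRUE, prob = c(0.55, 0.15, 0.18, 0.03, 0.09))
  women <- tibble(
    woman_uid = sprintf("W%06d", seq_len(n)),
    nhs_number = ids$nhs_number, hospital_number = ids$hospital_number,
    dob = ids$dob, postcode = ids$postcode,
    height = round(rnorm(n, 1.64, 0.07), 3),
    ethnicity = eth,
    chronic_htn = runif(n) < 0.04,
    parity_first = pmin(rpois(n, 0.9), 8L)
  )
  women$height <- pmin(pmax(women$height, 1.30), 1.95)
  # weight via a BMI draw so that all true values sit strictly inside the
  # plausibility limits (only injected defects may fall outside)
  bmi <- pmin(pmax(exp(rnorm(n, log(24.5), 0.18)), 17), 54)
  women$weight <- pmin(pmax(round(bmi * women$height^2, 1), 31), 199)

  win <- config$date_window
  win_days <- as.integer(win[2] - win[1])
  dod1 <- win[1] + sample.int(win_days + 1L, n, replace = TRUE) - 1L
  second <- runif(n) < config$second_pregnancy_rate
  gap <- 290L + sample.int(200L, n, replace = TRUE)
  dod2 <- dod1 + gap
  second <- second & dod2 <= win[2]

  preg_rows <- function(widx, pidx, dod) {
    np <- length(widx)
    ga <- draw_ga(np)
    tibble(
      preg_uid = sprintf("P%06d_%d", widx, pidx),
      woman_uid = women$woman_uid[widx],
      preg_index = pidx,
      dod = dod, ga_days = ga,
      edc = dod - ga + 14L,
      n_babies = 1L + (runif(np) < config$twin_rate),
      epidural = runif(np) < 0.25,
      modebirth = sample(c("unassisted vaginal", "assisted vaginal",
                           "caesarean section"), np, replace = TRUE,
                         prob = c(0.60, 0.13, 0.27)),
      ebl = pmin(pmax(round(exp(rnorm(np, log(300), 0.55))), 5), 4000),
      parity = women$parity_first[widx] + (pidx - 1L),
      had_scans = runif(np) > 0.10,
      had_activity = runif(np) > 0.08
    )
  }
  preg <- bind_rows(preg_rows(seq_len(n), 1L, dod1),
                    preg_rows(which(second), 2L, dod2[second])) %>%
    arrange(.data$woman_uid, .data$preg_index)

  babies <- preg %>%
    dplyr::reframe(birth_order = seq_len(.data$n_babies),
                   .by = c("preg_uid", "woman_uid", "dod", "ga_days",
                           "n_babies"))
  nb <- nrow(babies)
  babies$sex <- sample(c("male", "female"), nb, replace = TRUE)
  mu <- synthetic_bw_median(babies$ga_days, babies$sex) *
    ifelse(babies$n_babies > 1, 0.85, 1)
  babies$birthweight <- round(pmin(pmax(rnorm(nb, mu, 0.11 * mu), 310), 5900))
  babies$sga <- babies$birthweight <
    synthetic_sga_cutoff(babies$ga_days, babies$sex)
  babies$admitted <- runif(nb) < config$neonatal_admission_rate
  babies$baby_uid <- sprintf("B%06d", seq_len(nb))
  list(women = women, pregnancies = preg, babies = babies)
}

# gestational age in completed days: mostly term, a preterm tail, clipped to
# the generator's supported range 154-301
draw_ga <- function(n) {
  pre <- runif(n) < 0.07
  ga <- ifelse(pre, rnorm(n, 245, 25), rnorm(n, 281, 8))
  as.integer(pmin(pmax(round(ga), 154), 301))
}

# ---- rendering --------------------------------------------------------------

render_ga <- function(ga_days, style) {
  switch(style,
    weeks_plus_days = paste0(ga_days %/% 7, "+", ga_days %% 7),
    decimal_weeks = sprintf("%.2f", ga_days / 7),
    days = as.character(ga_days),
    config_error(paste0("unknown ga style: ", style)))
}

# render metres in the dialect unit; returns list(raw, canonical) where
# canonical is the value a correct parser recovers (rendering may quantise)
render_height <- function(m, unit) {
  switch(unit,
    m  = list(raw = sprintf("%.3f", m), canonical = round(m, 3)),
    cm = list(raw = sprintf("%.1f", m * 100), canonical = round(m * 100, 1) / 100),
    ft_in = {
      tot_in <- round(m / 0.0254)
      list(raw = sprintf("%dft %din", tot_in %/% 12, tot_in %% 12),
           canonical = tot_in * 0.0254)
    },
    config_error(paste0("unknown height unit: ", unit)))
}

render_weight <- function(kg, unit) {
  switch(unit,
    kg = list(raw = sprintf("%.1f", kg), canonical = round(kg, 1)),
    st_lb = {
      tot_lb <- round(kg / 0.45359237)
      list(raw = sprintf("%dst %dlb", tot_lb %/% 14, tot_lb %% 14),
           canonical = tot_lb * 0.45359237)
    },
    config_error(paste0("unknown weight unit: ", unit)))
}

pick_term <- function(canonical, vocab) {
  vapply(canonical, function(v) {
    terms <- vocab[[v]]
    if (is.null(terms)) NA_character_ else sample(terms, 1L)
  }, character(1), USE.NAMES = FALSE)
}

# analgesia pair: ensure the epidural term appears in >=1 column iff epidural
render_analgesia <- function(epidural, prof) {
  np <- length(epidural)
  lab <- sample(prof$analg_other, np, replace = TRUE)
  birth <- sample(prof$analg_other, np, replace = TRUE)
  where <- sample(c("lab", "birth", "both"), np, replace = TRUE,
                  prob = c(0.5, 0.2, 0.3))
  lab[epidural & where != "birth"] <- prof$epidural_term
  birth[epidural & where != "lab"] <- prof$epidural_term
  if ("analg_labour" %in% prof$affirmative_only) {
    # flag-style source records affirmative only
    lab <- ifelse(epidural & where != "birth", prof$epidural_term,
                  NA_character_)
  }
  list(labour = lab, birth = birth)
}

# ---- the generator ----------------------------------------------------------

#' Generate a synthetic per-site EPR bundle with ground truth
#'
#' Draws a cohort under `config`, renders the four extracts in the site's
#' dialect, injects the configured defects and missingness, and returns both
#' the (corrupted) bundle and a truth object logging every corruption.
#'
#' @param config A [site_config()].
#' @param seed Integer seed; output is deterministic given `(config, seed)`.
#' @return A list with elements `bundle` (a [record_bundle()] at stage
#'   `"raw"`) and `truth` (class `epr_truth`: cohort tables plus corruption
#'   logs).
#' @export
generate_bundle <- function(config, seed = 1L) {
  if (!inherits(config, "site_config"))
    config_error("config must be a site_config object")
  set.seed(seed)
  prof <- dialect_profile(config$dialect)
  cohort <- draw_cohort(config)
  women <- cohort$women; preg <- cohort$pregnancies; babies <- cohort$babies

  # one maternity row per baby (wide)
  mat_truth <- babies %>%
    left_join(select(preg, "preg_uid", "edc", "epidural", "modebirth",
                     "ebl", "parity"), by = "preg_uid") %>%
    left_join(women, by = "woman_uid")
  mat_truth$record_id <- sprintf("M%06d", seq_len(nrow(mat_truth)))
  babies$record_id <- mat_truth$record_id

  # quantise height/weight to what the dialect rendering can carry, and keep
  # that as canonical truth so a correct harmoniser recovers it exactly
  h <- render_height(mat_truth$height, prof$height_unit)
  w <- render_weight(mat_truth$weight, prof$weight_unit)
  mat_truth$height <- h$canonical
  mat_truth$weight <- w$canonical
  analg <- render_analgesia(mat_truth$epidural, prof)

  nmat <- nrow(mat_truth)
  mat <- tibble(record_id = mat_truth$record_id,
                nhs_number = mat_truth$nhs_number,
                hospital_number = mat_truth$hospital_number,
                dob = render_date(mat_truth$dob, prof$date_style),
                postcode = mat_truth$postcode,
                dod = render_date(mat_truth$dod, prof$date_style))
  mat[[prof$cols[["ga"]]]] <- render_ga(mat_truth$ga_days, prof$ga_style)
  mat[[prof$cols[["height"]]]] <- h$raw
  mat[[prof$cols[["weight"]]]] <- w$raw
  mat[[prof$cols[["ethnicity"]]]] <- pick_term(mat_truth$ethnicity,
                                               prof$ethnicity)
  mat[[prof$cols[["modebirth"]]]] <- pick_term(mat_truth$modebirth,
                                               prof$modebirth)
  if (prof$parity_binary) {
    mat[[prof$cols[["parity"]]]] <- ifelse(mat_truth$parity >= 1,
                                           "Multiparous", "Nulliparous")
  } else {
    mat[[prof$cols[["parity"]]]] <- as.character(mat_truth$parity)
  }
  htn_raw <- unname(prof$binary[ifelse(mat_truth$chronic_htn, "yes", "no")])
  if ("chronichtn" %in% prof$affirmative_only)
    htn_raw[!mat_truth$chronic_htn] <- NA_character_
  mat[[prof$cols[["chronichtn"]]]] <- htn_raw
  mat[[prof$cols[["analg_labour"]]]] <- analg$labour
  mat[[prof$cols[["analg_birth"]]]] <- analg$birth
  mat[[prof$cols[["ebl"]]]] <- as.character(mat_truth$ebl)
  mat[[prof$cols[["sex"]]]] <- unname(prof$sex[mat_truth$sex])
  mat[[prof$cols[["birthweight"]]]] <- as.character(mat_truth$birthweight)

  # neonatal: one row per admitted baby, single national system (fixed names)
  adm <- mat_truth[mat_truth$admitted, , drop = FALSE]
  neo <- tibble(record_id = sprintf("N%06d", seq_len(nrow(adm))),
                nhs_number = adm$nhs_number, dob = format(adm$dob, "%Y-%m-%d"),
                hospital_number = adm$hospital_number,
                neonatal_dob = format(adm$dod, "%Y-%m-%d"),
                neo_sex = ifelse(adm$sex == "male", "M", "F"),
                neo_bwt_g = adm$birthweight,
                admission_reason = sample(c("Prematurity", "Resp distress",
                                            "Hypoglycaemia", "Jaundice"),
                                          nrow(adm), replace = TRUE))

  # ultrasound: long, >=1 scan per scanned pregnancy, dates in [edc+56, dod]
  scan_preg <- preg[preg$had_scans, , drop = FALSE]
  n_scans <- 1L + stats::rpois(nrow(scan_preg), 2)
  uss_truth <- scan_preg[rep(seq_len(nrow(scan_preg)), n_scans), ] %>%
    select("preg_uid", "woman_uid", "edc", "dod", "n_babies", "ga_days")
  span <- pmax(as.integer(uss_truth$dod - uss_truth$edc) - 56L, 1L)
  uss_truth$scan_date <- uss_truth$edc + 56L +
    vapply(span, function(s) sample.int(s, 1L) - 1L, integer(1))
  # last scan of a pregnancy may carry a suspected-SGA flag
  uss_truth <- uss_truth %>%
    group_by(.data$preg_uid) %>%
    mutate(is_last = row_number(.data$scan_date) == n()) %>%
    ungroup()
  preg_sga <- babies %>%
    group_by(.data$preg_uid) %>%
    summarise(any_sga = any(.data$sga), .groups = "drop")
  uss_truth <- left_join(uss_truth, preg_sga, by = "preg_uid")
  det <- ifelse(uss_truth$any_sga, 0.6, 0.05)
  uss_truth$sga_suspected <- uss_truth$is_last & runif(nrow(uss_truth)) < det
  uss_truth$record_id <- sprintf("U%06d", seq_len(nrow(uss_truth)))
  uss_truth <- left_join(uss_truth,
                         select(women, "woman_uid", "nhs_number", "dob"),
                         by = "woman_uid")
  uss <- tibble(record_id = uss_truth$record_id,
                nhs_number = uss_truth$nhs_number,
                dob = render_date(uss_truth$dob, prof$date_style),
                event_date = render_date(uss_truth$scan_date,
                                         prof$date_style),
                fetal_count = uss_truth$n_babies,
                efw_g = round(synthetic_bw_median(
                  pmax(as.integer(uss_truth$scan_date - uss_truth$edc) + 14L,
                       120L), "female")),
                sga_suspected = ifelse(uss_truth$sga_suspected, "Y", "N"))

  # hospital activity: long, dates in [edc, dod]
  act_preg <- preg[preg$had_activity, , drop = FALSE]
  n_ev <- 1L + stats::rpois(nrow(act_preg), 6)
  act_truth <- act_preg[rep(seq_len(nrow(act_preg)), n_ev), ] %>%
    select("preg_uid", "woman_uid", "edc", "dod")
  span <- pmax(as.integer(act_truth$dod - act_truth$edc), 1L)
  act_truth$event_date <- act_truth$edc +
    vapply(span, function(s) sample.int(s + 1L, 1L) - 1L, integer(1))
  act_truth$event_type <- sample(c("OP appointment", "IP admission"),
                                 nrow(act_truth), replace = TRUE,
                                 prob = c(0.85, 0.15))
  act_truth$record_id <- sprintf("A%06d", seq_len(nrow(act_truth)))
  act_truth <- left_join(act_truth,
                         select(women, "woman_uid", "nhs_number", "dob"),
                         by = "woman_uid")
  act <- tibble(record_id = act_truth$record_id,
                nhs_number = act_truth$nhs_number,
                dob = render_date(act_truth$dob, prof$date_style),
                event_date = render_date(act_truth$event_date,
                                         prof$date_style),
                event_type = act_truth$event_type)

  # ---- defect injection ----
  logs <- list()
  dr <- config$defect_rates

  # per-pregnancy reporting: drop non-first twin rows from the maternity table
  babies$dropped <- FALSE
  if (dr$per_pregnancy_multiple > 0) {
    cand <- which(mat_truth$n_babies > 1 & mat_truth$birth_order > 1)
    drop_idx <- cand[runif(length(cand)) < dr$per_pregnancy_multiple]
    if (length(drop_idx)) {
      babies$dropped[match(mat_truth$record_id[drop_idx],
                           babies$record_id)] <- TRUE
      logs$dropped_rows <- tibble(table = "maternity",
                                  record_id = mat_truth$record_id[drop_idx])
      mat <- mat[-drop_idx, , drop = FALSE]
    }
  }
  logs$dropped_rows <- logs$dropped_rows %||%
    tibble(table = character(0), record_id = character(0))

  # implausible values: strictly outside the consensus plausibility limits
  logs$implausible <- inject_implausible(mat, mat_truth, prof, dr$implausible_value)
  mat <- logs$implausible$table
  logs$implausible <- logs$implausible$log

  # out-of-window event dates on the satellites
  oow <- list()
  if (dr$out_of_window_date > 0) {
    u <- move_out_of_window(uss, uss_truth$scan_date, uss_truth$edc,
                            uss_truth$dod, prof$date_style,
                            dr$out_of_window_date, "ultrasound")
    uss <- u$table; oow[["u"]] <- u$log
    a <- move_out_of_window(act, act_truth$event_date, act_truth$edc,
                            act_truth$dod, prof$date_style,
                            dr$out_of_window_date, "activity")
    act <- a$table; oow[["a"]] <- a$log
  }
  logs$out_of_window <- if (length(oow)) bind_rows(oow) else
    tibble(table = character(0), record_id = character(0),
           true_date = as.Date(character(0)),
           injected_date = as.Date(character(0)))

  # affirmative-only defect: blank recorded negatives in the binary column
  logs$affirmative_blanked <- tibble(table = character(0),
                                     record_id = character(0),
                                     column = character(0))
  if (dr$affirmative_only_binary > 0 &&
      !"chronichtn" %in% prof$affirmative_only) {
    col <- prof$cols[["chronichtn"]]
    neg <- which(mat[[col]] == unname(prof$binary[["no"]]))
    hit <- neg[runif(length(neg)) < dr$affirmative_only_binary]
    if (length(hit)) {
      logs$affirmative_blanked <- tibble(table = "maternity",
                                         record_id = mat$record_id[hit],
                                         column = col)
      mat[[col]][hit] <- NA_character_
    }
  }

  # configured missingness (MCAR / MAR) on the maternity extract
  miss <- config$missingness
  if (length(miss)) {
    spec <- list()
    for (v in names(miss)) {
      entry <- miss[[v]]
      entry$variable <- v
      drv <- entry$driver %||% "weight"
      entry$driver_values <- mat_truth[[drv]][match(mat$record_id,
                                                    mat_truth$record_id)]
      entry$driver <- drv
      spec[[prof$cols[[v]]]] <- entry
    }
    inj <- inject_missingness(mat, spec,
                              seed = sample.int(.Machine$integer.max, 1))
    mat <- inj$table
    logs$missingness <- inj$log
    logs$mar_models <- inj$models
  } else {
    logs$missingness <- tibble(table = character(0), record_id = character(0),
                               column = character(0), variable = character(0))
    logs$mar_models <- tibble(variable = character(0), column = character(0),
                              mechanism = character(0), rate = numeric(0),
                              intercept = numeric(0), site_shift = numeric(0),
                              beta = numeric(0), driver = character(0))
  }
  if (nrow(logs$missingness)) logs$missingness$table <- "maternity"

  # exact duplicate maternity rows, appended then shuffled in
  logs$duplicates <- tibble(table = character(0), record_id = character(0))
  if (dr$duplicate_row > 0) {
    hit <- which(runif(nrow(mat)) < dr$duplicate_row)
    if (length(hit)) {
      logs$duplicates <- tibble(table = "maternity",
                                record_id = mat$record_id[hit])
      mat <- bind_rows(mat, mat[hit, , drop = FALSE])
      mat <- mat[sample.int(nrow(mat)), , drop = FALSE]
    }
  }

  truth <- structure(
    list(site_code = config$site_code, dialect = config$dialect,
         config = config,
         women = women, pregnancies = preg, babies = babies,
         maternity = select(mat_truth, -"admitted"),
         ultrasound = select(uss_truth, "record_id", "preg_uid", "scan_date",
                             "edc", "dod", "n_babies", "sga_suspected"),
         activity = select(act_truth, "record_id", "preg_uid", "event_date",
                           "edc", "dod", "event_type"),
         logs = logs),
    class = "epr_truth")

  bundle <- record_bundle(mat, neo, uss, act, site = config$site_code,
                          stage = "raw")
  list(bundle = bundle, truth = truth)
}

# replace a sample of cells with values strictly outside the plausibility
# limits, rendering them in the dialect's unit
inject_implausible <- function(mat, mat_truth, prof, rate) {
  log <- tibble(table = character(0), record_id = character(0),
                variable = character(0), column = character(0),
                true_value = character(0), injected_value = numeric(0))
  if (rate <= 0) return(list(table = mat, log = log))
  targets <- list(
    height = list(col = prof$cols[["height"]],
                  bad = function(n) sample(c(0.9, 2.3, 2.8), n, TRUE),
                  render = function(v) vapply(v, function(x)
                    render_height(x, prof$height_unit)$raw, character(1))),
    weight = list(col = prof$cols[["weight"]],
                  bad = function(n) sample(c(8, 250, 402), n, TRUE),
                  render = function(v) vapply(v, function(x)
                    render_weight(x, prof$weight_unit)$raw, character(1))),
    ebl = list(col = prof$cols[["ebl"]],
               bad = function(n) sample(c(0, 20000, 55000), n, TRUE),
               render = as.character),
    birthweight = list(col = prof$cols[["birthweight"]],
                       bad = function(n) sample(c(20, 90, 6400, 9000), n, TRUE),
                       render = as.character)
  )
  rows <- list()
  for (v in names(targets)) {
    t <- targets[[v]]
    idx <- which(!is.na(mat[[t$col]]) & runif(nrow(mat)) < rate)
    if (!length(idx)) next
    bad <- t$bad(length(idx))
    rows[[v]] <- tibble(table = "maternity", record_id = mat$record_id[idx],
                        variable = v, column = t$col,
                        true_value = as.character(mat[[t$col]][idx]),
                        injected_value = bad)
    mat[[t$col]][idx] <- t$render(bad)
  }
  list(table = mat, log = bind_rows(log, bind_rows(rows)))
}

# push a sample of event dates strictly outside [edc, dod]
move_out_of_window <- function(tab, true_dates, edc, dod, style, rate,
                               table_name) {
  idx <- which(runif(nrow(tab)) < rate)
  if (!length(idx)) {
    return(list(table = tab,
                log = tibble(table = character(0), record_id = character(0),
                             true_date = as.Date(character(0)),
                             injected_date = as.Date(character(0)))))
  }
  after <- runif(length(idx)) < 0.6
  new_int <- ifelse(after,
                    as.integer(dod[idx]) + 7L +
                      sample.int(120L, length(idx), replace = TRUE),
                    as.integer(edc[idx]) -
                      sample.int(90L, length(idx), replace = TRUE))
  new_date <- as.Date(new_int, origin = "1970-01-01")
  tab$event_date[idx] <- render_date(new_date, style)
  list(table = tab,
       log = tibble(table = table_name, record_id = tab$record_id[idx],
                    true_date = true_dates[idx], injected_date = new_date))
}

#' Inject MCAR or MAR missingness into a table
#'
#' MCAR blanks cells independently of everything; MAR blanks with probability
#' from a logistic model `logit(p) = logit(rate) + site_shift + beta * z`
#' where `z` is the standardised driver covariate. The fitted coefficients
#' are returned so tests can recompute the expected per-row rates.
#'
#' @param table A data frame.
#' @param spec Named list: column name to a list with `mechanism`
#'   (`"MCAR"`/`"MAR"`), `rate`, and for MAR `driver_values` (numeric vector,
#'   one per row), optional `site_shift` (default 0.5) and `beta`
#'   (default 0.5).
#' @param seed Integer seed.
#' @return List with the blanked `table`, a `log` tibble of blanked cells
#'   (with the pre-blanking value), and `models` describing the MAR models.
#' @export
inject_missingness <- function(table, spec, seed = 1L) {
  unknown <- setdiff(names(spec), names(table))
  if (length(unknown))
    config_error(paste0("missingness spec names unknown column(s): ",
                        paste(unknown, collapse = ", ")))
  set.seed(seed)
  log <- list(); models <- list()
  rid <- table$record_id %||% as.character(seq_len(nrow(table)))
  for (col in names(spec)) {
    e <- spec[[col]]
    rate <- e$rate
    if (rate <= 0) next
    if (identical(e$mechanism, "MCAR")) {
      p <- rep(rate, nrow(table))
      models[[col]] <- tibble(variable = e$variable %||% col, column = col,
                              mechanism = "MCAR", rate = rate,
                              intercept = logit(rate), site_shift = 0,
                              beta = 0, driver = NA_character_)
    } else {
      z <- e$driver_values
      if (is.null(z)) config_error(paste0("MAR spec for ", col,
                                          " needs driver_values"))
      z <- (z - mean(z, na.rm = TRUE)) / (sd(z, na.rm = TRUE) + 1e-12)
      z[is.na(z)] <- 0
      shift <- e$site_shift %||% 0.5
      beta <- e$beta %||% 0.5
      p <- plogis(logit(rate) + shift + beta * z)
      models[[col]] <- tibble(variable = e$variable %||% col, column = col,
                              mechanism = "MAR", rate = rate,
                              intercept = logit(rate), site_shift = shift,
                              beta = beta, driver = e$driver %||% "driver")
    }
    hit <- which(runif(nrow(table)) < p & !is.na(table[[col]]))
    if (length(hit)) {
      true_vals <- as.character(table[[col]][hit])
      log[[col]] <- tibble(table = NA_character_, record_id = rid[hit],
                           column = col,
                           variable = e$variable %||% col,
                           true_value = true_vals)
      table[[col]][hit] <- NA
    }
  }
  list(table = table,
       log = if (length(log)) bind_rows(log) else
         tibble(table = character(0), record_id = character(0),
                column = character(0), variable = character(0),
                true_value = character(0)),
       models = if (length(models)) bind_rows(models) else
         tibble(variable = character(0), column = character(0),
                mechanism = character(0), rate = numeric(0),
                intercept = numeric(0), site_shift = numeric(0),
                beta = numeric(0), driver = character(0)))
}

#' Write truth tables to CSV
#'
#' @param truth An `epr_truth` object.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  flat <- c(truth[c("women", "pregnancies", "babies", "maternity",
                    "ultrasound", "activity")], truth$logs)
  for (nm in names(flat)) {
    if (!is.data.frame(flat[[nm]])) next
    p <- file.path(dir, paste0(truth$site_code, "_truth_", nm, ".csv"))
    readr::write_csv(flat[[nm]], p, na = "")
    paths <- c(paths, p)
  }
  invisible(paths)
}
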