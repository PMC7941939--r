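# Dictionary validation, unit conversion, recoding, binary rules,
# multi-source merging and the harmonisation engine's contracts.

test_that("dictionary validation enforces the nomenclature", {
  d <- test_dictionary()
  expect_s3_class(d, "epr_dictionary")

  bad <- tibble::tibble(harmonised_name = "birthmode", source = "mat",
                        stage = "harmonised", dtype = "categorical",
                        site = "alpha", raw_name = "x",
                        unit_rule = "identity")
  expect_error(load_dictionary(bad), "nomenclature")

  bad2 <- tibble::tibble(harmonised_name = "mat_h_modebirth",
                         source = "mat", stage = "harmonised",
                         dtype = "categorical", site = "alpha",
                         raw_name = "x", unit_rule = "identity",
                         recode_map = "SVD=>water birth",
                         categories = paste("unassisted vaginal",
                                            "assisted vaginal",
                                            "caesarean section",
                                            sep = "|"))
  expect_error(load_dictionary(bad2), "mat_h_modebirth")

  dup <- bad2
  dup$recode_map <- "SVD=>unassisted vaginal"
  expect_error(load_dictionary(dplyr::bind_rows(dup, dup)), "duplicate")
})

test_that("unit conversions are exact where the arithmetic is exact", {
  expect_equal(convert_units("5ft 4in", "ftin_to_m"), 64 * 0.0254)
  expect_equal(convert_units("5ft 4in", "ftin_to_m"), 1.6256)
  expect_equal(convert_units("40+2", "ga_to_days"), 282)
  expect_equal(convert_units(164, "cm_to_m"), 1.64)
  expect_equal(convert_units("10st 6lb", "stlb_to_kg"), 146 * 0.45359237)
  expect_equal(convert_units("40.29", "ga_to_days"), 282)
  expect_equal(convert_units("259", "ga_to_days"), 259)
  expect_true(is.na(convert_units("tall", "ftin_to_m")))
  expect_error(convert_units(1, "furlongs"), class = "eprlink_config_error")
  # the three date renderings all round-trip
  d <- as.Date("2017-10-10")
  expect_equal(convert_units("2017-10-10", "date"), d)
  expect_equal(convert_units("10/10/2017", "date"), d)
  expect_equal(convert_units(as.numeric(d - as.Date("1899-12-30")), "date"),
               d)
})

test_that("BMI: arithmetic, missing propagation, non-positive height", {
  expect_equal(calculate_bmi(66.0, 1.64), 24.54)
  expect_equal(calculate_bmi(30, 1.2), 20.83)
  expect_true(is.na(calculate_bmi(66, NA)))
  expect_true(is.na(calculate_bmi(NA, 1.64)))
  expect_true(is.na(calculate_bmi(66, 0)))
})

test_that("categorical recoding maps, preserves missing, logs unmapped", {
  map <- c("Em LSCS" = "caesarean section", "SVD" = "unassisted vaginal")
  r <- recode_categorical(c("Em LSCS", NA, "SVD", "Unknown xyz", "Odd"),
                          map)
  expect_equal(r$values, c("caesarean section", NA, "unassisted vaginal",
                           NA, NA))
  expect_equal(r$unmapped, c("Odd", "Unknown xyz"))
})

test_that("binary rules: affirmative-only maps missing to negative, full
          preserves missing", {
  expect_equal(apply_binary_rule(c("yes", NA, "yes"), "affirmative_only"),
               c("yes", "no", "yes"))
  expect_equal(apply_binary_rule(c("yes", "no", NA), "full"),
               c("yes", "no", NA))
  expect_equal(apply_binary_rule(c(NA_character_, NA), "affirmative_only"),
               c("no", "no"))
  expect_error(apply_binary_rule(c("yes", "maybe"), "full"), "non-binary")
})

test_that("multi-source merge equals its exhaustive truth-table oracle", {
  # example from the rule: epidural in one source, silent in the other
  expect_equal(merge_multisource(c("yes"), c(NA)), "yes")
  expect_equal(merge_multisource(c("no"), c("no")), "no")

  oracle <- function(vals) {
    if (any(vals == "yes", na.rm = TRUE)) return("yes")
    if (any(vals == "no", na.rm = TRUE)) return("no")
    NA_character_
  }
  states <- c("yes", "no", NA)
  # all 27 three-column combinations
  grid <- expand.grid(a = states, b = states, c = states,
                      stringsAsFactors = FALSE)
  got <- merge_multisource(grid$a, grid$b, grid$c)
  want <- apply(grid, 1, oracle)
  expect_equal(got, unname(want))
  # and all 9 two-column combinations
  grid2 <- expand.grid(a = states, b = states, stringsAsFactors = FALSE)
  expect_equal(merge_multisource(grid2$a, grid2$b),
               unname(apply(grid2, 1, oracle)))
})

test_that("harmonised values equal generator truth on every dialect", {
  for (dia in c("alpha", "bravo", "charlie")) {
    fx <- clean_site(dia)
    hm <- fx$harmonised$maternity
    tr <- fx$truth$maternity
    m <- tr[match(hm$record_id, tr$record_id), ]
    expect_equal(hm$mat_h_height, m$height, tolerance = 1e-12, info = dia)
    expect_equal(hm$mat_h_weight, m$weight, tolerance = 1e-12, info = dia)
    expect_equal(hm$mat_h_ga, m$ga_days, info = dia)
    expect_equal(hm$mat_h_dod, m$dod, info = dia)
    expect_equal(hm$mat_h_ethnicity, m$ethnicity, info = dia)
    expect_equal(hm$mat_h_modebirth, m$modebirth, info = dia)
    expect_equal(hm$mat_h_sex, m$sex, info = dia)
    expect_equal(hm$mat_h_bwt, m$birthweight, info = dia)
    expect_equal(hm$mat_h_ebl, m$ebl, info = dia)
    expect_equal(hm$mat_h_chronichtn,
                 ifelse(m$chronic_htn, "yes", "no"), info = dia)
    expect_equal(hm$mat_h_epidural,
                 ifelse(m$epidural, "yes", "no"), info = dia)
    expect_equal(hm$mat_c_bmi, round(m$weight / m$height^2, 2),
                 info = dia)
  }
})

test_that("harmonisation is idempotent and retains raw columns untouched", {
  for (dia in c("alpha", "bravo", "charlie")) {
    fx <- clean_site(dia)
    h2 <- harmonise_bundle(fx$harmonised, test_dictionary(), site = dia)
    for (nm in names(fx$harmonised)) {
      expect_identical(as.data.frame(h2$bundle[[nm]]),
                       as.data.frame(fx$harmonised[[nm]]),
                       info = paste(dia, nm))
    }
    expect_equal(nrow(h2$audit), 0L, info = dia)

    # raw-retention: each single-source harmonised column has a _r_ twin
    # holding the original raw values
    hm <- fx$harmonised$maternity
    raw <- fx$pseudonymised$maternity
    prof_raw <- list(alpha = "HeightCm", bravo = "height_ftin",
                     charlie = "height_m")[[dia]]
    expect_true("mat_r_height" %in% names(hm))
    expect_identical(hm$mat_r_height, raw[[prof_raw]])
  }
})

test_that("replaying the audit trail reproduces the engine output exactly", {
  for (dia in c("alpha", "bravo", "charlie")) {
    fx <- clean_site(dia)
    replayed <- replay_audit(fx$pseudonymised, fx$audit)
    for (nm in names(fx$harmonised)) {
      expect_identical(as.data.frame(replayed[[nm]]),
                       as.data.frame(fx$harmonised[[nm]]),
                       info = paste(dia, nm))
    }
  }
})

test_that("a variable with no raw source is emitted fully missing and
          reported", {
  fx <- clean_site("alpha")
  b <- fx$pseudonymised
  b$maternity$HeightCm <- NULL
  h <- harmonise_bundle(b, test_dictionary(), site = "alpha")
  expect_true(all(is.na(h$bundle$maternity$mat_h_height)))
  expect_true(any(h$report$variable == "mat_h_height" &
                    h$report$issue == "fully_missing"))
  # parity at the binary-only dialect is the built-in instance
  fxc <- clean_site("charlie")
  expect_true(all(is.na(fxc$harmonised$maternity$mat_h_parity)))
  expect_true(any(fxc$report$variable == "mat_h_parity"))
  expect_true(all(fxc$harmonised$maternity$mat_h_multiparous %in%
                    c("yes", "no")))
})

test_that("unmapped raw categories are audited distinctly from true
          missing", {
  fx <- clean_site("alpha")
  b <- fx$pseudonymised
  b$maternity$DeliveryMode[1:3] <- "Water birth"
  b$maternity$DeliveryMode[4:5] <- NA
  h <- harmonise_bundle(b, test_dictionary(), site = "alpha")
  expect_true(all(is.na(h$bundle$maternity$mat_h_modebirth[1:5])))
  un <- h$audit[h$audit$rule == "unmapped_values" &
                  h$audit$target == "mat_h_modebirth", ]
  expect_equal(nrow(un), 1L)
  expect_equal(un$rows_affected, 3L)
  expect_match(un$params, "Water birth")
})
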