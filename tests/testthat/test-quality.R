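# Checklists, distribution summaries, duplicate classification, outlier
# screening and the consensus outlier policy.

test_that("distribution summary follows the linear-interpolation
          convention", {
  s <- distribution_summary(1:100)
  expect_equal(s$median, 50.5)
  expect_equal(s$p5, 5.95)
  expect_equal(s$p95, 95.05)
  expect_equal(s$p25, 25.75)
  expect_equal(s$min, 1)
  expect_equal(s$max, 100)

  cc <- distribution_summary(rep(7, 20))
  expect_equal(cc$min, 7); expect_equal(cc$max, 7)
  expect_equal(cc$median, 7)

  em <- distribution_summary(c(NA, NA))
  expect_equal(em$n, 0L)
  expect_true(is.na(em$median))

  # sort-based oracle equivalence on random columns
  set.seed(42)
  for (i in 1:200) {
    v <- rnorm(sample(10:200, 1))
    s <- distribution_summary(v)
    sv <- sort(v)
    oracle_q <- function(p) {
      h <- (length(sv) - 1) * p + 1
      lo <- floor(h); hi <- ceiling(h)
      sv[lo] + (h - lo) * (sv[hi] - sv[lo])
    }
    expect_equal(s$p5, oracle_q(0.05))
    expect_equal(s$median, oracle_q(0.5))
    expect_equal(s$p95, oracle_q(0.95))
  }
})

test_that("duplicate classification separates multiple births from true
          duplicates", {
  base <- tibble::tibble(
    record_id = c("r1", "r2", "r3", "r4", "r5", "r6"),
    study_id = c("w1", "w1", "w2", "w2", "w3", "w4"),
    dod = as.Date(c("2017-01-01", "2017-01-01", "2017-02-02", "2017-02-02",
                    "2017-03-03", "2017-04-04")),
    sex = c("M", "M", "M", "F", "F", "M"),
    bwt = c(3000, 3000, 2500, 2600, 3300, 3100))
  cls <- classify_duplicates(base)
  # identical rows -> true duplicate; differing baby fields -> multiple birth
  expect_equal(cls, c("unique", "true_duplicate", "multiple_birth",
                      "multiple_birth", "unique", "unique"))

  # an ultrasound record showing one fetus overrides toward true duplicate
  uss <- tibble::tibble(study_id = "w2", event_date = "2016-12-01",
                        fetal_count = 1)
  cls2 <- classify_duplicates(base, uss)
  expect_equal(cls2[3:4], c("unique", "true_duplicate"))

  # and a twin scan keeps the multiple-birth classification
  uss3 <- tibble::tibble(study_id = "w2", event_date = "2016-12-01",
                         fetal_count = 2)
  expect_equal(classify_duplicates(base, uss3)[3:4],
               rep("multiple_birth", 2))
})

test_that("outlier screening lists candidates without mutating anything", {
  set.seed(7)
  v <- rnorm(10000)
  fl <- flag_outlier_candidates(v)
  # |z| > 3 mass is about 0.27%
  expect_gt(length(fl$sd3), 10)
  expect_lt(length(fl$sd3), 60)
  expect_true(all(abs(v[fl$sd4]) > 4 * sd(v) - abs(mean(v))))
  expect_true(all(fl$sd5 %in% fl$sd4), all(fl$sd4 %in% fl$sd3))
  # centile lists hold about 1% each
  expect_equal(length(fl$below_p1) / 10000, 0.01, tolerance = 0.3)
  expect_equal(length(fl$above_p99) / 10000, 0.01, tolerance = 0.3)

  expect_length(flag_outlier_candidates(rep(5, 50))$sd3, 0L)
  expect_error(flag_outlier_candidates(c(1, 2, 3)), "10")
})

test_that("outlier policy: strict outside converted, boundaries retained,
          idempotent", {
  mat <- tibble::tibble(
    record_id = as.character(1:8),
    mat_h_bwt = c(6001, 6000, 100, 99, 3000, NA, 500, 7000),
    age_at_delivery = c(12, 13, 60, 61, 30, 25, NA, 40),
    mat_h_height = 1.6, mat_h_weight = 70, mat_c_bmi = 27.3,
    mat_h_ebl = 300)
  b <- record_bundle(mat, site = "S", stage = "harmonised")
  res <- apply_outlier_policy(b, outlier_policy()[
    outlier_policy()$variable != "neo_h_bwt", ])
  out <- res$bundle$maternity
  expect_equal(out$mat_h_bwt, c(NA, 6000, 100, NA, 3000, NA, 500, NA))
  expect_equal(out$age_at_delivery, c(NA, 13, 60, NA, 30, 25, NA, 40))
  expect_equal(res$removals$removed[res$removals$variable == "mat_h_bwt"],
               3L)
  # brute-force recount
  expect_equal(sum(res$removals$removed),
               sum(mat$mat_h_bwt < 100 | mat$mat_h_bwt > 6000,
                   na.rm = TRUE) +
                 sum(mat$age_at_delivery < 13 | mat$age_at_delivery > 60,
                     na.rm = TRUE))
  # idempotence: a second application removes nothing
  res2 <- apply_outlier_policy(res$bundle, outlier_policy()[
    outlier_policy()$variable != "neo_h_bwt", ])
  expect_equal(sum(res2$removals$removed), 0L)
  expect_identical(as.data.frame(res2$bundle$maternity),
                   as.data.frame(out))

  expect_error(
    apply_outlier_policy(b, tibble::tibble(variable = "not_here",
                                           lower = 0, upper = 1)),
    class = "eprlink_config_error")
})

test_that("removal counts equal injected implausible counts per variable", {
  cfg <- site_config("SOUT", 800, dialect = "bravo",
                     defect_rates = list(implausible_value = 0.01))
  g <- generate_bundle(cfg, seed = 5)
  ps <- pseudonymise_bundle(g$bundle, "s")
  h <- harmonise_bundle(drop_off_spine(ps$bundle)$bundle,
                        test_dictionary(), site = "bravo")
  pol <- outlier_policy()
  pol <- pol[pol$variable != "neo_h_bwt", ]
  res <- apply_outlier_policy(h$bundle, pol)
  inj <- table(g$truth$logs$implausible$variable)
  rem <- stats::setNames(res$removals$removed, res$removals$variable)
  expect_equal(unname(rem["mat_h_height"]), unname(inj["height"]))
  expect_equal(unname(rem["mat_h_weight"]), unname(inj["weight"]))
  expect_equal(unname(rem["mat_h_ebl"]), unname(inj["ebl"]))
  expect_equal(unname(rem["mat_h_bwt"]), unname(inj["birthweight"]))
})

test_that("first-download checklist: clean pass, missing extract, injected
          missingness", {
  fx <- clean_site("charlie")
  win <- fx$config$date_window
  qc <- first_download_checks(fx$pseudonymised, win, test_dictionary(),
                              site = "charlie")
  expect_s3_class(qc, "qc_report")
  expect_length(qc$checks, 7L)
  expect_true(all(vapply(qc$checks, function(ch) ch$status, "") == "pass"))

  # a bundle missing its activity extract fails check 1, naming activity
  b2 <- fx$pseudonymised
  b2$activity <- NULL
  qc2 <- first_download_checks(b2, win, test_dictionary(),
                               site = "charlie")
  expect_equal(qc2$checks$datasets_present$status, "fail")
  expect_equal(qc2$checks$datasets_present$evidence$missing, "activity")

  # 20% MCAR on height shows up as ~80% completeness
  cfg <- site_config("SQC", 2000, dialect = "alpha",
                     missingness = list(height = list(mechanism = "MCAR",
                                                      rate = 0.2)))
  g <- generate_bundle(cfg, seed = 8)
  qc3 <- first_download_checks(pseudonymise_bundle(g$bundle, "s")$bundle,
                               cfg$date_window, test_dictionary(),
                               site = "alpha")
  comp <- qc3$checks$completeness$evidence$completeness
  hrow <- comp[comp$variable == "HeightCm", ]
  n <- hrow$n
  bounds <- binom_bounds(n, 0.8)
  expect_gte(hrow$complete_pct / 100 * n, bounds[1])
  expect_lte(hrow$complete_pct / 100 * n, bounds[2])
})

test_that("second-download checklist: resolution, completely-missing flags,
          no-prior-issues shape", {
  fx <- clean_site("bravo")
  win <- fx$config$date_window
  # a first download missing its activity extract
  b1 <- fx$pseudonymised
  b1$activity <- NULL
  qc1 <- first_download_checks(b1, win, test_dictionary(), site = "bravo")
  expect_equal(qc1$checks$datasets_present$status, "fail")

  key_vars <- list(maternity = c("bwt_grams", "gest_wks", "infant_sex"))
  # second download provides the extract: prior issue resolved
  qc2 <- second_download_checks(fx$pseudonymised, qc1, key_vars, win)
  expect_length(qc2$checks, 6L)
  expect_equal(qc2$checks$prior_issue_resolution$status, "pass")

  # a key variable absent from the extract is flagged completely missing
  b3 <- fx$pseudonymised
  b3$maternity$bwt_grams <- NULL
  qc3 <- second_download_checks(b3, NULL, key_vars, win)
  expect_length(qc3$checks, 5L)  # no prior issues: 5 remaining checks
  cm <- qc3$checks$key_variable_completeness$evidence$completely_missing
  expect_true("bwt_grams" %in% cm$variable)
  expect_equal(qc3$checks$key_variable_completeness$status, "fail")

  # categorical value-response check spots unexpected vocabulary
  b4 <- fx$pseudonymised
  b4$maternity$infant_sex[1] <- "Unknown"
  qc4 <- second_download_checks(b4, NULL, key_vars, win,
                                categories = list(infant_sex = c("Male",
                                                                 "Female")))
  cv <- qc4$checks$categorical_values$evidence$values
  expect_match(cv$unexpected[cv$variable == "infant_sex"], "Unknown")
})

test_that("QC reports serialise to JSON", {
  fx <- clean_site("alpha")
  qc <- first_download_checks(fx$pseudonymised, fx$config$date_window,
                              test_dictionary(), site = "alpha")
  path <- tempfile(fileext = ".json")
  write_qc_report(qc, path)
  parsed <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_equal(parsed$checklist, "first_download")
  expect_length(parsed$checks, 7L)
})
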