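# The chained-equations engine: immutability, determinism, scoping, the
# outcome triple, the parity rule, and observed-vs-imputed comparison.

make_impute_table <- function(n = 500, miss = 0.15, seed = 11) {
  set.seed(seed)
  site <- rep(c("A", "B"), each = n / 2)
  height <- rnorm(n, 1.64, 0.07) + ifelse(site == "A", 0.01, -0.01)
  weight <- 24 * height^2 + rnorm(n, 0, 8)
  eth <- sample(c("White", "Black", "Asian"), n, TRUE,
                prob = c(0.6, 0.2, 0.2))
  parity <- rpois(n, 0.9)
  tab <- tibble::tibble(site = site, height = height, weight = weight,
                        eth = eth, parity = parity,
                        age = round(runif(n, 18, 42)))
  truth <- tab
  tab$height[sample(n, n * miss)] <- NA
  tab$weight[sample(n, n * miss)] <- NA
  tab$eth[sample(n, n * miss)] <- NA
  list(table = tab, truth = truth)
}

default_spec <- function(m = 3, iterations = 3, seed = 9) {
  imputation_spec(
    variables = list(
      height = list(family = "pmm", scope = "across_clusters"),
      weight = list(family = "pmm", scope = "across_clusters"),
      eth = list(family = "multinomial", scope = "within_cluster")),
    predictors = c("site", "height", "weight", "eth", "age"),
    m = m, iterations = iterations, seed = seed)
}

test_that("a table with no missing values passes through unchanged", {
  x <- make_impute_table(miss = 0)
  out <- mice_impute(x$table, default_spec())
  expect_length(out, 3L)
  for (tt in out) expect_identical(tt, x$table)
})

test_that("observed cells are immutable and runs are seed-deterministic", {
  x <- make_impute_table()
  s <- default_spec()
  out1 <- mice_impute(x$table, s)
  out2 <- mice_impute(x$table, s)
  expect_identical(out1, out2)

  s2 <- default_spec(seed = 10)
  out3 <- mice_impute(x$table, s2)
  expect_false(identical(out1[[1]]$height, out3[[1]]$height))
  # observed cells identical across seeds and imputations, cell-wise
  for (v in c("height", "weight", "eth")) {
    obs <- !is.na(x$table[[v]])
    for (tt in c(out1, out3)) {
      expect_identical(tt[[v]][obs], x$table[[v]][obs])
      expect_false(anyNA(tt[[v]]))
    }
  }
})

test_that("within-cluster scoping isolates sites from each other", {
  x <- make_impute_table(seed = 21)
  spec <- imputation_spec(
    variables = list(
      height = list(family = "pmm", scope = "within_cluster"),
      eth = list(family = "multinomial", scope = "within_cluster")),
    predictors = c("height", "eth", "age", "weight"),
    m = 2, iterations = 3, seed = 5)
  tab <- x$table
  tab$weight <- x$truth$weight  # fully observed predictor
  out <- mice_impute(tab, spec)
  # permute site B's rows among themselves; site A imputations unchanged
  idxB <- which(tab$site == "B")
  set.seed(99); perm <- sample(idxB)
  tab2 <- tab
  tab2[idxB, ] <- tab[perm, ]
  out2 <- mice_impute(tab2, spec)
  ia <- which(tab$site == "A")
  for (m in seq_along(out)) {
    expect_identical(out[[m]]$height[ia], out2[[m]]$height[ia])
    expect_identical(out[[m]]$eth[ia], out2[[m]]$eth[ia])
  }
})

test_that("a within-cluster variable with an empty site is a hard error
          naming variable and site", {
  x <- make_impute_table()
  tab <- x$table
  tab$eth[tab$site == "B"] <- NA
  spec <- imputation_spec(
    variables = list(eth = list(family = "multinomial",
                                scope = "within_cluster")),
    predictors = c("age", "weight"), m = 2, iterations = 2, seed = 1)
  tab$weight <- x$truth$weight
  expect_error(mice_impute(tab, spec), "eth.*site.*B",
               class = "eprlink_scope_error")
  # the same variable across clusters imputes fine
  spec$variables$eth$scope <- "across_clusters"
  out <- mice_impute(tab, spec)
  expect_false(anyNA(out[[1]]$eth))
})

test_that("MCAR blanking is recovered within Monte-Carlo bounds", {
  x <- make_impute_table(n = 1000, miss = 0.2, seed = 33)
  out <- mice_impute(x$table, default_spec(m = 5, iterations = 5))
  mis <- which(is.na(x$table$height))
  truth_vals <- x$truth$height[mis]
  pooled <- rowMeans(sapply(out, function(tt) tt$height[mis]))
  se <- sd(truth_vals) / sqrt(length(mis))
  expect_lt(abs(mean(pooled) - mean(truth_vals)), 3 * se)
})

test_that("outcome triple: computed from components, recomputed after
          imputation, consistent on observed rows", {
  fx <- clean_site("alpha", n = 300, seed = 55)
  lk <- link_bundle(fx$harmonised)
  an <- build_analysis_table(stats::setNames(list(lk$bundle), "TA"))
  an$outcome_triple <- compute_outcome_triple(an)
  expect_true(all(an$outcome_triple %in%
                    c("SGA_detected", "SGA_not_detected", "not_SGA")))
  # triple recomputable: born-small babies split by the antenatal flag
  sga <- an$mat_h_bwt < synthetic_sga_cutoff(an$mat_h_ga, an$mat_h_sex)
  expect_equal(an$outcome_triple == "not_SGA", !sga)
  expect_equal(an$outcome_triple[sga] == "SGA_detected",
               an$sga_detected_antenatal[sga] == "yes")

  # blank some components and impute; fully observed rows never change
  set.seed(3)
  tab <- an
  blank <- sample(nrow(tab), 60)
  tab$mat_h_bwt[blank] <- NA
  tab$outcome_triple <- compute_outcome_triple(tab)
  expect_true(all(is.na(tab$outcome_triple[blank])))
  spec <- imputation_spec(
    variables = list(
      mat_h_bwt = list(family = "pmm", scope = "across_clusters"),
      outcome_triple = list(family = "multinomial",
                            scope = "across_clusters")),
    predictors = c("mat_h_bwt", "mat_h_ga", "outcome_triple",
                   "age_at_delivery"),
    m = 3, iterations = 3, seed = 17)
  out <- impute_outcome_triple(tab, spec)
  obs <- setdiff(seq_len(nrow(tab)), blank)
  for (tt in out) {
    expect_false(anyNA(tt$outcome_triple))
    # recomputation agrees with direct computation everywhere
    expect_equal(tt$outcome_triple, compute_outcome_triple(tt))
    # fully observed rows keep their observed category
    expect_identical(tt$outcome_triple[obs], an$outcome_triple[obs])
  }
  expect_error(impute_outcome_triple(tab, spec, centile_fn = NULL),
               class = "eprlink_config_error")
})

test_that("parity floor: known-multiparous women never keep parity zero", {
  tab <- tibble::tibble(mat_h_parity = c(0, 0, 2, 0, 1),
                        mat_h_multiparous = c("yes", "no", "yes", NA,
                                              "yes"))
  out <- apply_parity_rule(tab, tab$mat_h_multiparous)
  expect_equal(out$mat_h_parity, c(1, 0, 2, 0, 1))
  flagged <- out$mat_h_multiparous == "yes" & !is.na(out$mat_h_multiparous)
  expect_true(min(out$mat_h_parity[flagged]) >= 1)
})

test_that("observed-vs-imputed comparison: identical with no missing,
          concordant medians under MCAR", {
  x <- make_impute_table(n = 600, miss = 0, seed = 44)
  out <- mice_impute(x$table, default_spec())
  cmp <- compare_observed_imputed(x$table, out, grouping = "site",
                                  variables = c("height", "eth"))
  wide <- tidyr::pivot_wider(cmp, names_from = "source",
                             values_from = c("median", "pct"),
                             id_cols = c("group", "variable", "category"))
  expect_equal(wide$median_observed, wide$median_imputed)
  expect_equal(wide$pct_observed, wide$pct_imputed)

  y <- make_impute_table(n = 1000, miss = 0.2, seed = 45)
  out2 <- mice_impute(y$table, default_spec(m = 5, iterations = 4))
  cmp2 <- compare_observed_imputed(y$table, out2,
                                   variables = "height")
  med_obs <- cmp2$median[cmp2$source == "observed"]
  med_imp <- cmp2$median[cmp2$source == "imputed"]
  expect_lt(abs(med_obs - med_imp), 0.02)
})

test_that("a missing-ridden predictor outside the imputation list is
          rejected", {
  x <- make_impute_table()
  spec <- imputation_spec(
    variables = list(height = list(family = "pmm",
                                   scope = "across_clusters")),
    predictors = c("weight", "age"), m = 2, iterations = 2, seed = 2)
  expect_error(mice_impute(x$table, spec), "weight",
               class = "eprlink_config_error")
})
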