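# Multiple imputation by chained equations, with the structure this pipeline
# needs: m completed datasets, per-variable conditional models (linear +
# predictive-mean-matching, logistic, multinomial, rounded PMM for ordinal
# counts), within-cluster or across-cluster fitting scope, a three-category
# primary-outcome variable that is imputed like any other but finally
# recomputed from its imputed components, and the parity floor rule.

#' Imputation specification
#'
#' @param variables Named list: variable name to a list with `family`
#'   (`"pmm"`, `"pmm_round"`, `"logistic"`, `"multinomial"`) and `scope`
#'   (`"within_cluster"` default, or `"across_clusters"`).
#' @param predictors Common predictor set (column names). Predictors with
#'   missing values must themselves appear in `variables`.
#' @param m Number of imputations (default 10).
#' @param iterations Chained cycles per imputation (default 10).
#' @param pmm_k Donor-pool size for predictive mean matching (default 5).
#' @param site_col Cluster column (default `"site"`).
#' @param seed Integer seed.
#' @return An `imputation_spec` object.
#' @export
imputation_spec <- function(variables, predictors, m = 10L, iterations = 10L,
                            pmm_k = 5L, site_col = "site", seed = 1L) {
  assert_that(length(variables) >= 1L, "at least one variable to impute")
  assert_that(length(predictors) >= 1L,
              "every imputed variable needs >= 1 predictor")
  for (v in names(variables)) {
    e <- variables[[v]]
    if (is.null(e$family) ||
        !e$family %in% c("pmm", "pmm_round", "logistic", "multinomial"))
      config_error(paste0("unknown model family for ", v))
    variables[[v]]$scope <- match.arg(e$scope %||% "within_cluster",
                                      c("within_cluster", "across_clusters"))
  }
  structure(list(variables = variables, predictors = predictors,
                 m = as.integer(m), iterations = as.integer(iterations),
                 pmm_k = as.integer(pmm_k), site_col = site_col,
                 seed = as.integer(seed)),
            class = "imputation_spec")
}

#' Read an imputation specification from YAML
#'
#' Layout: top-level `predictors`, `m`, `iterations`, `seed`, and
#' `variables:` mapping each variable to `family` and `scope`.
#'
#' @param path YAML path.
#' @return An `imputation_spec`.
#' @export
read_imputation_spec <- function(path) {
  y <- yaml::read_yaml(path)
  imputation_spec(variables = y$variables,
                  predictors = unlist(y$predictors),
                  m = y$m %||% 10L, iterations = y$iterations %||% 10L,
                  pmm_k = y$pmm_k %||% 5L, site_col = y$site_col %||% "site",
                  seed = y$seed %||% 1L)
}

# design matrix for the conditional model of `target`: all predictors and
# all other imputed variables except the target, dummy-coded with levels
# taken from the full data
impute_design <- function(data, cols) {
  parts <- list(`(Intercept)` = rep(1, nrow(data)))
  for (cc in cols) {
    v <- data[[cc]]
    if (is.numeric(v)) {
      parts[[cc]] <- v
    } else {
      v <- as.character(v)
      lv <- sort(unique(v[!is.na(v)]))
      for (l in lv[-1]) parts[[paste0(cc, "::", l)]] <- as.numeric(v == l)
    }
  }
  X <- do.call(cbind, parts)
  # drop zero-variance columns (keep intercept)
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(col)
    isTRUE(stats::var(col) > 0)))
  X[, keep, drop = FALSE]
}

fit_predict_lm <- function(X, y, obs) {
  qr_fit <- qr(X[obs, , drop = FALSE])
  beta <- qr.coef(qr_fit, y[obs])
  beta[is.na(beta)] <- 0
  as.vector(X %*% beta)
}

# type-0 predictive mean matching: draw an observed donor among the pmm_k
# closest predicted values
pmm_draw <- function(pred_obs, y_obs, pred_mis, k) {
  ord <- order(pred_obs)
  sp <- pred_obs[ord]; sy <- y_obs[ord]
  n <- length(sp)
  vapply(pred_mis, function(p) {
    pos <- findInterval(p, sp)
    lo <- max(1L, pos - k); hi <- min(n, pos + k)
    idx <- lo:hi
    d <- abs(sp[idx] - p)
    pool <- idx[order(d)][seq_len(min(k, length(idx)))]
    sy[pool[sample.int(length(pool), 1L)]]
  }, y_obs[1])
}

fit_draw_logistic <- function(X, y, obs, mis) {
  yy <- as.numeric(y[obs] == "yes" | y[obs] == TRUE | y[obs] == 1)
  if (length(unique(yy)) < 2L) {
    p <- rep(mean(yy), length(mis))
  } else {
    fit <- suppressWarnings(glm.fit(X[obs, , drop = FALSE], yy,
                                    family = binomial()))
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    p <- plogis(as.vector(X[mis, , drop = FALSE] %*% beta))
  }
  draw <- runif(length(mis)) < p
  if (is.logical(y)) draw else ifelse(draw, "yes", "no")
}

fit_draw_multinomial <- function(X, y, obs, mis) {
  cls <- sort(unique(as.character(y[obs])))
  if (length(cls) < 2L) return(rep(cls[1] %||% NA_character_, length(mis)))
  df_obs <- data.frame(.y = factor(y[obs], levels = cls),
                       X[obs, -1, drop = FALSE], check.names = FALSE)
  fit <- suppressWarnings(
    nnet::multinom(.y ~ ., data = df_obs, trace = FALSE, maxit = 200))
  df_mis <- data.frame(X[mis, -1, drop = FALSE], check.names = FALSE)
  pr <- predict(fit, newdata = df_mis, type = "probs")
  if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)  # two-class case
  apply(pr, 1, function(p) sample(cls, 1L, prob = pmax(p, 1e-9)))
}

#' Multiple imputation by chained equations
#'
#' Produces `m` completed copies of `table`. Observed cells are identical
#' across all imputations; missing cells are filled by iterated conditional
#' draws. Variables scoped `within_cluster` are fitted separately per site;
#' `across_clusters` variables are fitted on the pooled data (with the site
#' factor excluded from their predictors). A within-cluster variable that is
#' 100% missing in some site is a hard error naming the variable and site —
#' such variables must be configured across clusters.
#'
#' @param table A tibble (harmonised, outlier-cleaned).
#' @param spec An [imputation_spec()].
#' @return List of `m` completed tibbles, with attribute `"spec"`.
#' @export
mice_impute <- function(table, spec) {
  assert_that(inherits(spec, "imputation_spec"), "spec must be an imputation_spec")
  vars <- names(spec$variables)
  missing_vars <- setdiff(vars, names(table))
  if (length(missing_vars))
    config_error(paste0("variables absent from table: ",
                        paste(missing_vars, collapse = ", ")))
  site <- as.character(col_or_null(table, spec$site_col) %||%
                         rep("all", nrow(table)))
  # predictors with missingness must themselves be imputed
  pred_only <- setdiff(spec$predictors, c(vars, spec$site_col))
  for (p in pred_only) {
    if (anyNA(table[[p]]))
      config_error(paste0("predictor ", p, " has missing values but is not ",
                          "in the imputation list"))
  }
  # within-cluster feasibility: no site may be 100% missing
  for (v in vars) {
    if (spec$variables[[v]]$scope != "within_cluster") next
    obs_by_site <- tapply(!is.na(table[[v]]), site, sum)
    dead <- names(obs_by_site)[obs_by_site == 0]
    if (length(dead))
      abort(paste0("variable ", v, " is completely missing in site(s) ",
                   paste(dead, collapse = ", "),
                   " and is scoped within_cluster; impute it across clusters"),
            class = c("eprlink_scope_error", "eprlink_error"))
  }
  mis_idx <- lapply(vars, function(v) which(is.na(table[[v]])))
  names(mis_idx) <- vars

  completed <- vector("list", spec$m)
  for (imp in seq_len(spec$m)) {
    cur <- table
    # initial fill: random draws from the observed margin — per site for
    # within-cluster variables, so sites never share a random stream
    for (v in vars) {
      mi <- mis_idx[[v]]
      if (!length(mi)) next
      if (!any(!is.na(cur[[v]])))
        config_error(paste0("variable ", v, " has no observed values at all"))
      e <- spec$variables[[v]]
      groups <- if (e$scope == "within_cluster")
        split(seq_len(nrow(cur)), site) else list(all = seq_len(nrow(cur)))
      for (gn in names(groups)) {
        g <- groups[[gn]]
        mig <- intersect(mi, g)
        if (!length(mig)) next
        obs_vals <- cur[[v]][setdiff(g, mi)]
        obs_vals <- obs_vals[!is.na(obs_vals)]
        set.seed(stream_seed(spec$seed, imp, 0L, v, gn))
        cur[[v]][mig] <- sample(obs_vals, length(mig), replace = TRUE)
      }
    }
    for (cycle in seq_len(spec$iterations)) {
      for (v in vars) {
        mi <- mis_idx[[v]]
        if (!length(mi)) next
        e <- spec$variables[[v]]
        preds <- setdiff(spec$predictors, v)
        if (e$scope == "across_clusters")
          preds <- setdiff(preds, spec$site_col)
        cur[[v]] <- impute_one(cur, v, preds, mi, e$family,
                               if (e$scope == "within_cluster") site else
                                 NULL, spec$pmm_k, table[[v]],
                               seed_base = c(spec$seed, imp, cycle, v))
      }
    }
    completed[[imp]] <- cur
  }
  attr(completed, "spec") <- spec
  completed
}

# deterministic per-(imputation, cycle, variable, group) seed so each site
# consumes an independent random stream
stream_seed <- function(seed, imp, cycle, v, group) {
  h <- strtoi(substr(as.character(openssl::md5(paste(seed, imp, cycle, v,
                                                     group, sep = "|"))),
                     1, 7), base = 16L)
  (as.integer(seed) + h) %% 2147483629L
}

# one conditional update of variable v; `truth_col` carries the original
# (with NAs) so observed cells are re-asserted, never drifting
impute_one <- function(cur, v, preds, mi, family, site, k, orig,
                       seed_base) {
  y <- cur[[v]]
  y[mi] <- NA
  groups <- if (is.null(site)) list(all = seq_len(nrow(cur))) else
    split(seq_len(nrow(cur)), site)
  for (gn in names(groups)) {
    g <- groups[[gn]]
    mig <- intersect(mi, g)
    if (!length(mig)) next
    set.seed(stream_seed(seed_base[1], seed_base[2], seed_base[3],
                         seed_base[4], gn))
    obs_g <- setdiff(g[!is.na(orig[g])], mig)
    Xg <- impute_design(cur[g, , drop = FALSE], preds)
    obs_p <- match(obs_g, g); mis_p <- match(mig, g)
    yg <- y[g]
    yg_obs_vals <- orig[g]
    drawn <- switch(family,
      pmm = ,
      pmm_round = {
        yv <- suppressWarnings(as.numeric(yg_obs_vals))
        pred <- fit_predict_lm(Xg, yv, obs_p)
        out <- pmm_draw(pred[obs_p], yv[obs_p], pred[mis_p], k)
        if (family == "pmm_round") pmax(round(out), 0) else out
      },
      logistic = fit_draw_logistic(Xg, yg_obs_vals, obs_p, mis_p),
      multinomial = fit_draw_multinomial(Xg, yg_obs_vals, obs_p, mis_p),
      config_error(paste0("unknown family: ", family)))
    y[mig] <- drawn
  }
  # observed cells are immutable
  keep <- !is.na(orig)
  y[keep] <- orig[keep]
  y
}

#' Compute the three-category primary-outcome variable from components
#'
#' `SGA_detected` — born small for gestational age (birthweight below the
#' centile function's cutoff for gestational age and sex) and suspected
#' antenatally on ultrasound; `SGA_not_detected` — born SGA, not suspected;
#' `not_SGA` otherwise. Missing where any component is missing.
#'
#' @param table Table with `mat_h_bwt`, `mat_h_ga`, `mat_h_sex` and
#'   `sga_detected_antenatal` (binary `"yes"`/`"no"`).
#' @param centile_fn Function `(ga_days, sex) -> cutoff in grams`; the
#'   bundled synthetic stand-in is [synthetic_sga_cutoff()].
#' @return Character vector of categories.
#' @export
compute_outcome_triple <- function(table, centile_fn = synthetic_sga_cutoff) {
  if (is.null(centile_fn)) config_error("a centile function is required")
  bwt <- suppressWarnings(as.numeric(col_or_null(table, "mat_h_bwt")))
  ga <- suppressWarnings(as.numeric(col_or_null(table, "mat_h_ga")))
  sex <- as.character(col_or_null(table, "mat_h_sex"))
  det <- as.character(col_or_null(table, "sga_detected_antenatal"))
  cutoff <- centile_fn(ga, sex)
  sga <- bwt < cutoff
  out <- ifelse(!sga, "not_SGA",
                ifelse(det == "yes", "SGA_detected", "SGA_not_detected"))
  out[is.na(bwt) | is.na(ga) | is.na(sex) | is.na(det)] <- NA_character_
  out
}

#' Impute with the outcome triple in the chains, then recompute it
#'
#' The three-category outcome participates in the chained equations as both
#' predictor and imputed variable (so other variables can borrow strength
#' from it), but the outcome finally used for analysis is recomputed in each
#' completed dataset from its imputed components via the pluggable centile
#' function, overwriting the chained draw.
#'
#' @param table Table containing the outcome components; the column
#'   `outcome_triple` is created from observed components if absent.
#' @param spec An [imputation_spec()] that includes `outcome_triple`
#'   (family `"multinomial"`) and its components.
#' @param centile_fn Centile cutoff function; required.
#' @return List of `m` completed tibbles, each with `outcome_triple`
#'   recomputed from components.
#' @export
impute_outcome_triple <- function(table, spec,
                                  centile_fn = synthetic_sga_cutoff) {
  if (is.null(centile_fn)) config_error("centile_fn must be supplied")
  if (!"outcome_triple" %in% names(table))
    table$outcome_triple <- compute_outcome_triple(table, centile_fn)
  completed <- mice_impute(table, spec)
  lapply(completed, function(tab) {
    recomputed <- compute_outcome_triple(tab, centile_fn)
    if (anyNA(recomputed))
      abort("outcome components still missing after imputation",
            class = "eprlink_error")
    tab$outcome_triple <- recomputed
    tab
  })
}

#' Floor imputed parity at one for women known to be multiparous
#'
#' At sites supplying parity only as a nulliparous/multiparous flag, an
#' imputed parity of zero contradicts known multiparity and is replaced with
#' the pre-specified value one. All other rows are untouched.
#'
#' @param completed_table One completed dataset.
#' @param known_multiparous Logical vector (or `"yes"`/`"no"`), one per row.
#' @param parity_col Parity column name (default `"mat_h_parity"`).
#' @return The corrected table.
#' @export
apply_parity_rule <- function(completed_table, known_multiparous,
                              parity_col = "mat_h_parity") {
  flag <- known_multiparous == TRUE | known_multiparous == "yes"
  flag[is.na(flag)] <- FALSE
  p <- completed_table[[parity_col]]
  fix <- flag & !is.na(p) & p == 0
  completed_table[[parity_col]][fix] <- 1
  completed_table
}

#' Compare observed and imputed summary statistics
#'
#' Per group, continuous variables are summarised as median \[IQR\] and
#' categorical variables as percentage per category, side by side for the
#' observed data and the imputed datasets (statistics averaged over the
#' imputations).
#'
#' @param observed The pre-imputation table.
#' @param completed_tables The list from [mice_impute()].
#' @param grouping Character vector of grouping columns (may be empty).
#' @param variables Variables to summarise (default: the imputed ones).
#' @return A tibble with one row per (group, variable\[, category\]).
#' @export
compare_observed_imputed <- function(observed, completed_tables,
                                     grouping = character(0),
                                     variables = NULL) {
  spec <- attr(completed_tables, "spec")
  variables <- variables %||% names(spec$variables)
  grp_key <- function(tab) {
    if (!length(grouping)) rep("all", nrow(tab)) else
      do.call(paste, c(tab[grouping], sep = " / "))
  }
  summarise_one <- function(tab, v) {
    key <- grp_key(tab)
    col <- tab[[v]]
    if (is.numeric(col)) {
      res <- tapply(col, key, function(x) {
        q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE,
                      type = 7)
        c(p25 = q[1], median = q[2], p75 = q[3])
      })
      bind_rows(lapply(names(res), function(k)
        tibble(group = k, variable = v, category = NA_character_,
               median = res[[k]]["median"], p25 = res[[k]]["p25"],
               p75 = res[[k]]["p75"], pct = NA_real_)))
    } else {
      tab2 <- tibble(key = key, val = as.character(col)) %>%
        filter(!is.na(.data$val))
      tot <- tab2 %>% dplyr::count(.data$key, name = "tot")
      tab2 %>%
        dplyr::count(.data$key, .data$val) %>%
        left_join(tot, by = "key") %>%
        mutate(pct = 100 * .data$n / .data$tot) %>%
        dplyr::transmute(group = .data$key, variable = v,
                         category = .data$val, median = NA_real_,
                         p25 = NA_real_, p75 = NA_real_, pct = .data$pct)
    }
  }
  obs <- bind_rows(lapply(variables, function(v) summarise_one(observed, v)))
  obs$source <- "observed"
  imp <- bind_rows(lapply(completed_tables, function(tab)
    bind_rows(lapply(variables, function(v) summarise_one(tab, v))))) %>%
    group_by(.data$group, .data$variable, .data$category) %>%
    summarise(across(c("median", "p25", "p75", "pct"),
                     ~ mean(.x)), .groups = "drop")
  imp$source <- "imputed"
  bind_rows(obs, imp) %>%
    arrange(.data$variable, .data$group, .data$category, .data$source)
}
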