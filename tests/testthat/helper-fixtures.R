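# Shared fixtures. Heavy objects are built once per test run and cached.

fixture_env <- new.env(parent = emptyenv())

# a small no-defect site in the given dialect, taken through
# pseudonymisation and harmonisation; cached per (dialect)
clean_site <- function(dialect = "alpha", n = 150, seed = 101) {
  key <- paste0("clean_", dialect, "_", n, "_", seed)
  if (!is.null(fixture_env[[key]])) return(fixture_env[[key]])
  cfg <- site_config(paste0("T", toupper(substr(dialect, 1, 1))), n,
                     dialect = dialect)
  g <- generate_bundle(cfg, seed = seed)
  ps <- pseudonymise_bundle(g$bundle, "fixture-salt")
  b <- drop_off_spine(ps$bundle)$bundle
  h <- harmonise_bundle(b, test_dictionary(), site = dialect)
  out <- list(config = cfg, truth = g$truth, raw = g$bundle,
              pseudonymised = b, harmonised = h$bundle, audit = h$audit,
              report = h$report)
  fixture_env[[key]] <- out
  out
}

test_dictionary <- function() {
  if (is.null(fixture_env$dict))
    fixture_env$dict <- load_dictionary(synthetic_dictionary_path())
  fixture_env$dict
}

# exact binomial central interval at the given confidence
binom_bounds <- function(n, p, conf = 0.99) {
  a <- (1 - conf) / 2
  c(qbinom(a, n, p), qbinom(1 - a, n, p))
}
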