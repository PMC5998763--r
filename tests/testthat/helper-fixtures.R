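# Shared fixtures, built lazily once per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_bundle <- function() {
  memo("tiny_bundle", generate_fixture(fixture_preset("tiny", rng_seed = 11L)))
}

tiny_features <- function() {
  memo("tiny_features", {
    b <- tiny_bundle()
    suppressWarnings(
      build_feature_matrix(b$drugs, b$metabolites, b$proteome, b$network)
    )
  })
}

tiny_universe <- function() {
  memo("tiny_universe", pair_universe(tiny_bundle()$labels))
}

# Mid-size world: enough positives (30) that binomial 3-sigma bands on
# positive-vs-background comparisons are satisfiable.
mid_bundle <- function() {
  memo("mid_bundle", generate_fixture(fixture_config(
    n_metabolites = 20L, n_natural_products = 6L, n_drugs = 30L,
    n_genes = 40L, n_phenotypes = 30L, n_positives = 30L,
    n_cooccurrence = 10L, rng_seed = 23L
  )))
}

mid_features <- function() {
  memo("mid_features", {
    b <- mid_bundle()
    suppressWarnings(
      build_feature_matrix(b$drugs, b$metabolites, b$proteome, b$network)
    )
  })
}

# Feature table with a planted Gaussian separation, for model-level tests
# that do not need the chemistry/network stack.
gaussian_features <- function(n_pos, n_neg, shift = 0.6, sd = 0.05,
                              seed = 1L) {
  withr::with_seed(seed, {
    n <- n_pos + n_neg
    lab <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
    mk <- function() {
      pmax(0, pmin(1, rnorm(n, ifelse(lab, 0.2 + shift, 0.2), sd)))
    }
    df <- data.frame(
      partner_id = sprintf("d%03d", seq_len(n)),
      metabolite_id = sprintf("m%03d", seq_len(n)),
      s_structure = mk(), s_target = mk(), s_phenotype = mk(),
      stringsAsFactors = FALSE
    )
    list(features = df, labels = lab)
  })
}

# Balanced training-set list pointing at rows of a gaussian_features table.
gaussian_training_sets <- function(gf, n_sets = 5L) {
  lapply(seq_len(n_sets), function(i) {
    data.frame(drug_id = gf$features$partner_id,
               metabolite_id = gf$features$metabolite_id,
               label = gf$labels, stringsAsFactors = FALSE)
  })
}
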