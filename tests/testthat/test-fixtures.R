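# Synthetic fixture generator.

test_that("fixture generation is reproducible and feasibility-checked", {
  cfg <- fixture_preset("tiny", rng_seed = 99L)
  b1 <- generate_fixture(cfg)
  b2 <- generate_fixture(cfg)
  expect_equal(b1$metabolites, b2$metabolites)
  expect_equal(b1$drugs, b2$drugs)
  expect_equal(as.character(b1$proteome), as.character(b2$proteome))
  expect_equal(b1$network, b2$network)
  expect_equal(b1$labels, b2$labels)
  expect_equal(b1$cooccurrence_method, b2$cooccurrence_method)

  # written twice, the bundles are byte-identical
  d1 <- tempfile(); d2 <- tempfile()
  write_fixture(b1, d1)
  write_fixture(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }

  expect_error(fixture_config(n_metabolites = 2, n_drugs = 3,
                              n_positives = 10),
               "more positives|n_positives")
})

test_that("default fixture parses cleanly through the readers", {
  b <- tiny_bundle()
  dir <- tempfile()
  write_fixture(b, dir)
  expect_no_warning(back <- read_fixture(dir))
  expect_equal(back$metabolites, b$metabolites)
  expect_equal(nrow(pair_universe(back$labels)),
               nrow(b$drugs) * nrow(b$metabolites))
})

test_that("empty-annotation config writes a header-only annotation file", {
  cfg <- fixture_config(n_metabolites = 4L, n_natural_products = 4L,
                        n_drugs = 6L, n_genes = 8L, n_phenotypes = 6L,
                        n_positives = 4L, terms_per_metabolite = 0L,
                        n_cooccurrence = 5L, rng_seed = 3L)
  b <- generate_fixture(cfg)
  expect_equal(nrow(b$annotations), 0)
  dir <- tempfile()
  write_fixture(b, dir)
  lines <- readLines(file.path(dir, "annotations.tsv"))
  expect_equal(lines, "compound_id\tphenotype_term")
})

test_that("planted positives have elevated feature values (3 sigma)", {
  fm <- mid_features()
  uni <- pair_universe(mid_bundle()$labels)
  pos <- uni$positive[match(paste(fm$partner_id, fm$metabolite_id),
                            paste(uni$drug_id, uni$metabolite_id))]
  for (col in c("s_structure", "s_target", "s_phenotype")) {
    x <- fm[[col]][pos]
    y <- fm[[col]][!pos]
    # positives should beat background well beyond binomial noise: compare
    # the fraction of positives above the background median to 1/2
    frac <- mean(x > median(y, na.rm = TRUE), na.rm = TRUE)
    se <- sqrt(0.25 / length(x))
    expect_gt(frac, 0.5 + 3 * se)
  }
})

test_that("null-signal fixtures carry no positive-pair elevation", {
  cfg <- fixture_config(n_metabolites = 10L, n_natural_products = 4L,
                        n_drugs = 16L, n_genes = 20L, n_phenotypes = 12L,
                        n_positives = 10L,
                        signal_shift = c(structure = 0, target = 0,
                                         phenotype = 0),
                        n_cooccurrence = 5L, rng_seed = 17L)
  b <- generate_fixture(cfg)
  # with no planting, positive drugs are built exactly like background ones:
  # scaffold and target assignments are exchangeable
  pos_drugs <- b$labels$positives$drug_id
  bg_drugs <- setdiff(b$drugs$id, pos_drugs)
  pos_scaf <- b$drugs$smiles[b$drugs$id %in% pos_drugs]
  bg_scaf <- b$drugs$smiles[b$drugs$id %in% bg_drugs]
  # same scaffold pool on both sides
  expect_true(all(pos_scaf %in% unlist(npmatch:::scaffold_pool())))
  expect_true(all(bg_scaf %in% unlist(npmatch:::scaffold_pool())))
  # and no metabolite-matched structure: the rate at which a positive drug
  # shares its paired metabolite's molecule is the background collision rate
  met_smiles <- b$metabolites$smiles[match(b$labels$positives$metabolite_id,
                                           b$metabolites$id)]
  drug_smiles <- b$drugs$smiles[match(pos_drugs, b$drugs$id)]
  expect_lt(mean(drug_smiles == met_smiles), 0.35)
})

test_that("fixture generation at default config is fast enough", {
  elapsed <- system.time(generate_fixture(fixture_preset("default",
                                                         rng_seed = 5L)))
  expect_lt(elapsed[["elapsed"]], 60)
})
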