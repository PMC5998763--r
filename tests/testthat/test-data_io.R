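# Readers, domain invariants and identifier hygiene.

write_lines <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

empty_targets <- function() {
  write_lines("compound_id\tgene_id")
}

test_that("read_compounds parses SMILES, aggregates targets, handles bad rows", {
  smi <- write_lines(c("C id1", "CCO id2"), ".smi")
  cs <- read_compounds(smi, empty_targets(), "metabolite")
  expect_s3_class(cs, "compound_set")
  expect_equal(nrow(cs), 2)
  expect_true(all(lengths(cs$targets) == 0))
  expect_false(anyNA(cs$smiles))

  # target rows aggregate with set semantics
  tgt <- write_lines(c("compound_id\tgene_id", "id1\tG1", "id1\tG1", "id1\tG2"))
  cs <- read_compounds(smi, tgt, "metabolite")
  expect_equal(cs$targets[[which(cs$id == "id1")]], c("G1", "G2"))

  # unparsable SMILES retained without structure, with a warning
  smi_bad <- write_lines(c("CCO id1", "not_a_molecule id3"), ".smi")
  expect_warning(cs <- read_compounds(smi_bad, empty_targets(), "drug"),
                 "did not parse")
  expect_true(is.na(cs$smiles[cs$id == "id3"]))
  expect_false(is.na(cs$smiles[cs$id == "id1"]))

  # conflicting duplicate structures are fatal, both values reported
  smi_dup <- write_lines(c("CCO idX", "CCC idX"), ".smi")
  expect_error(read_compounds(smi_dup, empty_targets(), "drug"),
               "conflicting structures.*CCO.*CCC")
  expect_error(read_compounds(tempfile(), empty_targets(), "drug"),
               "does not exist")
})

test_that("SMILES are canonicalized on load", {
  smi <- write_lines(c("OCC a", "CCO b"), ".smi")
  cs <- read_compounds(smi, empty_targets(), "metabolite")
  expect_equal(cs$smiles[cs$id == "a"], cs$smiles[cs$id == "b"])
})

test_that("read_network builds nodes/edges and enforces the contracts", {
  net_file <- write_lines(c(
    "source_id\ttarget_id\tsource_kind\ttarget_kind",
    "G1\tP1\tgene\tphenotype",
    "G2\tP1\tgene\tphenotype",
    "G1\tG2\tgene\tgene"
  ))
  net <- read_network(net_file)
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 3)
  expect_equal(net$n_self_loops_dropped, 0)

  self_file <- write_lines(c(
    "source_id\ttarget_id\tsource_kind\ttarget_kind",
    "G1\tG1\tgene\tgene",
    "G1\tP1\tgene\tphenotype"
  ))
  expect_warning(net <- read_network(self_file), "1 self-loop")
  expect_equal(net$n_self_loops_dropped, 1)
  expect_equal(nrow(net$edges), 1)

  neg_file <- write_lines(c(
    "source_id\ttarget_id\tsource_kind\ttarget_kind\tweight",
    "G1\tP1\tgene\tphenotype\t-1"
  ))
  expect_error(read_network(neg_file), "negative weight.*row 1")

  kind_file <- write_lines(c(
    "source_id\ttarget_id\tsource_kind\ttarget_kind",
    "G1\tP1\tgene\tsymptom"
  ))
  expect_error(read_network(kind_file), "undeclared node kind")
})

test_that("pair labels: Cartesian universe, dedup, unknown ids fatal", {
  pos <- write_lines(c("drug_id\tmetabolite_id", "d1\tm2"))
  labels <- read_pair_labels(pos, c("d1", "d2"), c("m1", "m2", "m3"))
  uni <- pair_universe(labels)
  expect_equal(nrow(uni), 6)
  expect_equal(sum(uni$positive), 1)

  # duplicates count once
  dup <- write_lines(c("drug_id\tmetabolite_id", "d1\tm2", "d1\tm2"))
  labels <- read_pair_labels(dup, c("d1", "d2"), c("m1", "m2", "m3"))
  expect_equal(nrow(labels$positives), 1)

  # empty positives load, but training refuses downstream
  none <- write_lines("drug_id\tmetabolite_id")
  labels <- read_pair_labels(none, c("d1", "d2"), c("m1", "m2"))
  expect_equal(nrow(labels$positives), 0)
  expect_error(sample_training_sets(labels, 2, 1), "no positive pairs")

  bad <- write_lines(c("drug_id\tmetabolite_id", "dZ\tm1"))
  expect_error(read_pair_labels(bad, c("d1"), c("m1")), "unknown compound")
})

test_that("co-occurrence invariants are enforced", {
  ok <- data.frame(term_a = "a", term_b = "b", n_c = 5, n_a = 10, n_b = 15,
                   N = 100)
  expect_silent(validate_cooccurrence(ok))
  bad <- ok
  bad$n_c <- 20 # exceeds min(n_a, n_b)
  expect_error(validate_cooccurrence(bad), "invalid co-occurrence")
  bad2 <- ok
  bad2$N <- 15 # n_a + n_b - n_c > N
  expect_error(validate_cooccurrence(bad2), "invalid co-occurrence")
})

test_that("loaded tables round-trip and loading is order-independent", {
  b <- tiny_bundle()
  dir <- tempfile()
  write_fixture(b, dir)
  b2 <- read_fixture(dir)
  expect_equal(b2$metabolites, b$metabolites)
  expect_equal(b2$drugs, b$drugs)
  expect_equal(b2$natural_products, b$natural_products)
  expect_equal(b2$network, b$network)
  expect_equal(b2$annotations, b$annotations)
  expect_equal(b2$labels, b$labels)
  expect_equal(b2$indications, b$indications)
  expect_equal(as.character(b2$proteome), as.character(b$proteome))
  expect_equal(b2$cooccurrence_method, b$cooccurrence_method)

  # permuting input rows yields identical in-memory datasets
  perm <- function(path, header = TRUE) {
    lines <- readLines(path)
    if (header) {
      body <- lines[-1]
      writeLines(c(lines[1], rev(body)), path)
    } else {
      writeLines(rev(lines), path)
    }
  }
  perm(file.path(dir, "metabolites.smi"), header = FALSE)
  perm(file.path(dir, "metabolites_targets.tsv"))
  perm(file.path(dir, "network.tsv"))
  perm(file.path(dir, "positives.tsv"))
  perm(file.path(dir, "annotations.tsv"))
  b3 <- read_fixture(dir)
  expect_equal(b3$metabolites, b2$metabolites)
  expect_equal(b3$network, b2$network)
  expect_equal(b3$labels, b2$labels)
  expect_equal(b3$annotations, b2$annotations)
})

test_that("proteome validation rejects bad alphabets and empty sequences", {
  expect_error(validate_proteome(c(g1 = "ACDEB")), "outside the 20-AA")
  expect_error(validate_proteome(c(g1 = "")), "empty protein")
  expect_silent(validate_proteome(c(g1 = "ACDX")))
})
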