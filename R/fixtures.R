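# Self-contained synthetic datasets with controllable planted signal.
# The generator emulates, at desk scale, the shape of the real corpora:
# small molecules with shared scaffolds, target proteins in homology
# families, a directed gene/phenotype network with modular wiring,
# metabolite phenotype annotations, silver-standard drug-metabolite
# positives, natural-product indications, and literature co-occurrence
# counts in an associated and an independent regime.

# Scaffold pool: 10 scaffold groups x 4 variants, RDKit-canonical SMILES.
# Within-group Tanimoto of hashed path fingerprints averages ~0.6 (some
# pairs exceed the 0.77 floor; identical assignments give 1.0); between
# groups it averages ~0.10.
scaffold_pool <- function() {
  list(
    c("O=C(O)c1ccccc1", "COC(=O)c1ccccc1", "Cc1ccccc1C(=O)O", "CCOC(=O)c1ccccc1"),
    c("Oc1ccccc1", "Cc1ccccc1O", "CCc1ccccc1O", "Cc1cccc(O)c1"),
    c("c1ccc2[nH]ccc2c1", "Cc1ccc2[nH]ccc2c1", "Cc1c[nH]c2ccccc12", "CCc1c[nH]c2ccccc12"),
    c("OCC1OC(O)C(O)C(O)C1O", "COC1OC(CO)C(O)C(O)C1O", "CC1OC(O)C(O)C(O)C1O", "OCC1OC(O)C(O)C1O"),
    c("CC(N)C(=O)O", "CCC(N)C(=O)O", "NC(CO)C(=O)O", "NC(CS)C(=O)O"),
    c("c1ncc2[nH]cnc2n1", "Cn1cnc2ncncc21", "Nc1ncnc2[nH]cnc12", "Cc1ncc2[nH]cnc2n1"),
    c("CC12CCC3CCCCC3C1CCC2O", "CC12CCC3CCCCC3C1CCC2=O",
      "CC12CCC3CCCC(O)C3C1CCC2O", "CC12CCC3CC(O)CCC3C1CCC2O"),
    c("CCCCCCCC(=O)O", "CCCCCCCCC(=O)O", "CCCCCCC(=O)O", "CCCCCCCCCC(=O)O"),
    c("c1ccncc1", "Cc1ccncc1", "CCc1ccncc1", "Cc1ccnc(C)c1"),
    c("Oc1ccccc1O", "Cc1ccc(O)c(O)c1", "CCc1ccc(O)c(O)c1", "O=C(O)c1ccc(O)c(O)c1")
  )
}

#' Fixture generator configuration
#'
#' Defaults describe the package's standard desk-scale world: a 60 x 40
#' drug-metabolite universe with 40 silver-standard positives, a network of
#' 80 genes (20 homology families) and 50 phenotypes (5 modules), and a
#' per-feature planted effect of 3 (the scale is pooled background standard
#' deviations; 3 means every positive pair is planted on that feature,
#' 0 means positives are drawn exactly like background).
#'
#' @param n_metabolites,n_natural_products,n_drugs compound counts.
#' @param n_genes,n_phenotypes network size.
#' @param edge_density density of random extra edges beyond the modular
#'   wiring, in \[0, 1\].
#' @param n_positives number of silver-standard (drug, metabolite) pairs;
#'   at most one per drug and at most `n_drugs * n_metabolites` total.
#' @param signal_shift named numeric vector with entries `structure`,
#'   `target`, `phenotype`; each >= 0.
#' @param terms_per_metabolite mean number of phenotype terms annotated per
#'   metabolite.
#' @param np_similar_fraction fraction of natural products planted to
#'   resemble a metabolite (these carry indications derived from that
#'   metabolite's terms).
#' @param n_cooccurrence co-occurrence records per regime.
#' @param mutation_rate per-site substitution rate within a homology family.
#' @param rng_seed integer seed; the full bundle is reproducible from it.
#' @return a `fixture_config`.
#' @export
fixture_config <- function(n_metabolites = 40L, n_natural_products = 40L,
                           n_drugs = 60L, n_genes = 80L, n_phenotypes = 50L,
                           edge_density = 0.03, n_positives = 40L,
                           signal_shift = c(structure = 3, target = 3,
                                            phenotype = 3),
                           terms_per_metabolite = 4L,
                           np_similar_fraction = 0.3,
                           n_cooccurrence = 30L,
                           mutation_rate = 0.05, rng_seed = 1L) {
  stopifnot(n_metabolites >= 1, n_natural_products >= 1, n_drugs >= 1,
            n_genes >= 1, n_phenotypes >= 1,
            edge_density >= 0, edge_density <= 1,
            all(signal_shift >= 0),
            all(c("structure", "target", "phenotype") %in% names(signal_shift)))
  if (n_positives > n_drugs * n_metabolites) {
    stop("more positives requested than drug x metabolite pairs", call. = FALSE)
  }
  if (n_positives > n_drugs) {
    stop("at most one positive pair per drug: n_positives must be <= n_drugs",
         call. = FALSE)
  }
  structure(list(n_metabolites = as.integer(n_metabolites),
                 n_natural_products = as.integer(n_natural_products),
                 n_drugs = as.integer(n_drugs), n_genes = as.integer(n_genes),
                 n_phenotypes = as.integer(n_phenotypes),
                 edge_density = edge_density,
                 n_positives = as.integer(n_positives),
                 signal_shift = signal_shift,
                 terms_per_metabolite = as.integer(terms_per_metabolite),
                 np_similar_fraction = np_similar_fraction,
                 n_cooccurrence = as.integer(n_cooccurrence),
                 mutation_rate = mutation_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "fixture_config")
}

#' Preset fixture configurations
#'
#' `tiny` (fast smoke runs), `default` (the standard world above) and
#' `stress` (larger universe for timing checks).
#'
#' @param preset preset name.
#' @param rng_seed seed passed through.
#' @return a `fixture_config`.
#' @export
fixture_preset <- function(preset = c("default", "tiny", "stress"),
                           rng_seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    tiny = fixture_config(n_metabolites = 8L, n_natural_products = 8L,
                          n_drugs = 12L, n_genes = 16L, n_phenotypes = 12L,
                          n_positives = 8L, terms_per_metabolite = 3L,
                          n_cooccurrence = 12L, rng_seed = rng_seed),
    default = fixture_config(rng_seed = rng_seed),
    stress = fixture_config(n_metabolites = 80L, n_natural_products = 120L,
                            n_drugs = 120L, n_genes = 160L,
                            n_phenotypes = 100L, n_positives = 80L,
                            rng_seed = rng_seed)
  )
}

random_aa_seq <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
        collapse = "")
}

mutate_seq <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                         sum(hit), replace = TRUE)
  }
  paste(chars, collapse = "")
}

make_compound_set <- function(ids, role, smiles, targets) {
  df <- data.frame(id = ids, role = role, smiles = smiles,
                   stringsAsFactors = FALSE)
  df$targets <- lapply(targets, function(t) sort(unique(t)))
  df <- df[order(df$id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("compound_set", "data.frame")
  df
}

#' Generate a synthetic dataset bundle
#'
#' Builds a complete, self-consistent world: molecules drawn from a
#' scaffold pool with controlled scaffold sharing, target proteins mutated
#' from family ancestors, a modular gene/phenotype network, metabolite
#' annotations taken from the phenotype module their targets feed,
#' silver-standard positives with per-feature planted signal, indications
#' for metabolite-like natural products, and co-occurrence counts in an
#' associated and an independent binomial regime.
#'
#' @param cfg a [fixture_config()].
#' @return an `np_fixture` bundle: `metabolites`, `natural_products`,
#'   `drugs` (compound sets), `proteome` (AAStringSet), `network`,
#'   `annotations`, `labels`, `indications`, `cooccurrence_method`,
#'   `cooccurrence_random`, `np_truth_pairs`, `config`.
#' @export
generate_fixture <- function(cfg = fixture_config()) {
  stopifnot(inherits(cfg, "fixture_config"))
  pool <- scaffold_pool()
  n_scaffolds <- length(pool)
  f_shift <- pmin(cfg$signal_shift / 3, 1)

  withr::with_seed(cfg$rng_seed, {
    # --- gene families and proteome ---------------------------------------
    n_fam <- max(2L, ceiling(cfg$n_genes / 4))
    fam_len <- sample(80:200, n_fam, replace = TRUE)
    fam_anc <- vapply(fam_len, random_aa_seq, "")
    gene_ids <- sprintf("g%03d", seq_len(cfg$n_genes))
    gene_fam <- ((seq_len(cfg$n_genes) - 1) %% n_fam) + 1
    proteome_chr <- vapply(seq_len(cfg$n_genes), function(i) {
      mutate_seq(fam_anc[gene_fam[i]], cfg$mutation_rate)
    }, "")
    names(proteome_chr) <- gene_ids

    # --- modular gene/phenotype network -----------------------------------
    n_mod <- max(2L, min(5L, cfg$n_phenotypes))
    phen_ids <- sprintf("p%03d", seq_len(cfg$n_phenotypes))
    phen_mod <- ((seq_len(cfg$n_phenotypes) - 1) %% n_mod) + 1
    fam_mod <- ((seq_len(n_fam) - 1) %% n_mod) + 1
    gene_mod <- fam_mod[gene_fam]
    edges_from <- character(0); edges_to <- character(0)
    for (i in seq_len(cfg$n_genes)) {
      module_phens <- phen_ids[phen_mod == gene_mod[i]]
      k <- min(3L, length(module_phens))
      edges_from <- c(edges_from, rep(gene_ids[i], k))
      edges_to <- c(edges_to, sample(module_phens, k))
    }
    # guarantee every phenotype is reachable
    orphan <- setdiff(phen_ids, edges_to)
    for (p in orphan) {
      cand <- gene_ids[gene_mod == phen_mod[match(p, phen_ids)]]
      if (length(cand) == 0) cand <- gene_ids
      edges_from <- c(edges_from, sample(cand, 1))
      edges_to <- c(edges_to, p)
    }
    n_gp <- round(cfg$edge_density * cfg$n_genes * cfg$n_phenotypes)
    if (n_gp > 0) {
      edges_from <- c(edges_from, sample(gene_ids, n_gp, replace = TRUE))
      edges_to <- c(edges_to, sample(phen_ids, n_gp, replace = TRUE))
    }
    n_gg <- round(cfg$edge_density * cfg$n_genes^2)
    if (n_gg > 0) {
      gg_from <- sample(gene_ids, n_gg, replace = TRUE)
      gg_to <- sample(gene_ids, n_gg, replace = TRUE)
      keep <- gg_from != gg_to
      edges_from <- c(edges_from, gg_from[keep])
      edges_to <- c(edges_to, gg_to[keep])
    }
    edges <- unique(data.frame(from = edges_from, to = edges_to,
                               weight = 1, stringsAsFactors = FALSE))
    nodes <- data.frame(id = c(gene_ids, phen_ids),
                        kind = rep(c("gene", "phenotype"),
                                   c(cfg$n_genes, cfg$n_phenotypes)),
                        stringsAsFactors = FALSE)
    network <- association_network(nodes, edges)

    # --- metabolites -------------------------------------------------------
    met_ids <- sprintf("m%03d", seq_len(cfg$n_metabolites))
    met_fam <- sample(n_fam, cfg$n_metabolites, replace = TRUE)
    met_scaffold <- sample(n_scaffolds, cfg$n_metabolites, replace = TRUE)
    met_smiles <- vapply(met_scaffold, function(s) sample(pool[[s]], 1), "")
    met_targets <- lapply(seq_len(cfg$n_metabolites), function(i) {
      fam_genes <- gene_ids[gene_fam == met_fam[i]]
      t <- sample(fam_genes, min(2, length(fam_genes)))
      if (runif(1) < 0.3) t <- c(t, sample(gene_ids, 1))
      t
    })
    metabolites <- make_compound_set(met_ids, "metabolite", met_smiles,
                                     met_targets)

    # --- annotations -------------------------------------------------------
    ann <- do.call(rbind, lapply(seq_len(cfg$n_metabolites), function(i) {
      if (cfg$terms_per_metabolite == 0) {
        return(data.frame(compound_id = character(0),
                          phenotype_term = character(0),
                          stringsAsFactors = FALSE))
      }
      module_phens <- phen_ids[phen_mod == fam_mod[met_fam[i]]]
      k <- min(cfg$terms_per_metabolite, length(module_phens))
      terms <- c(sample(module_phens, k),
                 sample(setdiff(phen_ids, module_phens), 1))
      data.frame(compound_id = met_ids[i], phenotype_term = terms,
                 stringsAsFactors = FALSE)
    }))
    ann <- unique(ann)
    ann <- ann[order(ann$compound_id, ann$phenotype_term), , drop = FALSE]
    rownames(ann) <- NULL

    # one planted partner: scaffold / family / module assignment vs its
    # metabolite, feature by feature
    plant_partner <- function(met_idx) {
      res <- list()
      res$scaffold <- if (runif(1) < f_shift["structure"]) {
        met_scaffold[met_idx]
      } else sample(n_scaffolds, 1)
      fam <- met_fam[met_idx]
      if (runif(1) < f_shift["target"]) {
        res$targets <- sample(gene_ids[gene_fam == fam],
                              min(2, sum(gene_fam == fam)))
      } else if (runif(1) < f_shift["phenotype"]) {
        sibling <- setdiff(which(fam_mod == fam_mod[fam]), fam)
        pick <- if (length(sibling) > 0) sample(sibling, 1) else fam
        res$targets <- sample(gene_ids[gene_fam == pick],
                              min(2, sum(gene_fam == pick)))
      } else {
        res$targets <- sample(gene_ids, 2)
      }
      res
    }

    # --- drugs and silver-standard positives -------------------------------
    drug_ids <- sprintf("d%03d", seq_len(cfg$n_drugs))
    drug_scaffold <- sample(n_scaffolds, cfg$n_drugs, replace = TRUE)
    drug_targets <- lapply(seq_len(cfg$n_drugs), function(i) sample(gene_ids, 2))
    pos_drugs <- sample(cfg$n_drugs, cfg$n_positives)
    pos_mets <- sample(cfg$n_metabolites, cfg$n_positives, replace = TRUE)
    for (k in seq_len(cfg$n_positives)) {
      planted <- plant_partner(pos_mets[k])
      drug_scaffold[pos_drugs[k]] <- planted$scaffold
      drug_targets[[pos_drugs[k]]] <- planted$targets
    }
    drug_smiles <- vapply(drug_scaffold, function(s) sample(pool[[s]], 1), "")
    drugs <- make_compound_set(drug_ids, "drug", drug_smiles, drug_targets)
    positives <- data.frame(drug_id = drug_ids[pos_drugs],
                            metabolite_id = met_ids[pos_mets],
                            stringsAsFactors = FALSE)
    labels <- pair_labels(positives, drug_ids, met_ids)

    # --- natural products --------------------------------------------------
    np_ids <- sprintf("n%03d", seq_len(cfg$n_natural_products))
    np_scaffold <- sample(n_scaffolds, cfg$n_natural_products, replace = TRUE)
    np_targets <- lapply(seq_len(cfg$n_natural_products),
                         function(i) sample(gene_ids, 2))
    n_sim <- round(cfg$np_similar_fraction * cfg$n_natural_products)
    sim_nps <- if (n_sim > 0) sample(cfg$n_natural_products, n_sim) else integer(0)
    sim_mets <- sample(cfg$n_metabolites, n_sim, replace = TRUE)
    for (k in seq_along(sim_nps)) {
      planted <- plant_partner(sim_mets[k])
      np_scaffold[sim_nps[k]] <- planted$scaffold
      np_targets[[sim_nps[k]]] <- planted$targets
    }
    np_smiles <- vapply(np_scaffold, function(s) sample(pool[[s]], 1), "")
    natural_products <- make_compound_set(np_ids, "natural_product",
                                          np_smiles, np_targets)
    np_truth_pairs <- data.frame(natural_product_id = np_ids[sim_nps],
                                 metabolite_id = met_ids[sim_mets],
                                 stringsAsFactors = FALSE)

    # --- indications for metabolite-like natural products ------------------
    indications <- if (nrow(np_truth_pairs) > 0) {
      do.call(rbind, lapply(seq_len(nrow(np_truth_pairs)), function(k) {
        terms <- ann$phenotype_term[ann$compound_id ==
                                      np_truth_pairs$metabolite_id[k]]
        terms <- c(sample(terms, min(3, length(terms))), sample(phen_ids, 1))
        data.frame(drug_id = np_truth_pairs$natural_product_id[k],
                   indication = unique(terms), stringsAsFactors = FALSE)
      }))
    } else {
      data.frame(drug_id = character(0), indication = character(0),
                 stringsAsFactors = FALSE)
    }
    indications <- unique(indications)
    indications <- indications[order(indications$drug_id,
                                     indications$indication), , drop = FALSE]
    rownames(indications) <- NULL

    # --- co-occurrence records --------------------------------------------
    make_cooc <- function(n, associated) {
      N <- 50000
      n_a <- sample(100:1000, n, replace = TRUE)
      n_b <- sample(100:1000, n, replace = TRUE)
      n_c <- if (associated) {
        rbinom(n, pmin(n_a, n_b), 0.2)
      } else {
        rbinom(n, n_b, n_a / N)
      }
      data.frame(term_a = sprintf("ta%03d", seq_len(n)),
                 term_b = sprintf("tb%03d", seq_len(n)),
                 n_c = pmin(n_c, pmin(n_a, n_b)),
                 n_a = n_a, n_b = n_b, N = N, stringsAsFactors = FALSE)
    }
    cooc_method <- make_cooc(cfg$n_cooccurrence, TRUE)
    cooc_random <- make_cooc(cfg$n_cooccurrence, FALSE)

    structure(
      list(metabolites = metabolites, natural_products = natural_products,
           drugs = drugs,
           proteome = Biostrings::AAStringSet(proteome_chr),
           network = network, annotations = ann, labels = labels,
           indications = indications,
           cooccurrence_method = cooc_method,
           cooccurrence_random = cooc_random,
           np_truth_pairs = np_truth_pairs,
           config = cfg),
      class = "np_fixture"
    )
  })
}

#' Write a fixture bundle to a directory
#'
#' Emits exactly the plain-text formats the readers consume (SMILES, FASTA,
#' TSV), so the bundle round-trips through the `read_*` functions without
#' loss.
#'
#' @param bundle an `np_fixture`.
#' @param directory output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_fixture <- function(bundle, directory) {
  stopifnot(inherits(bundle, "np_fixture"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(directory)) {
      stop("cannot create directory ", directory, call. = FALSE)
    }
  }
  p <- function(...) file.path(directory, ...)
  write_compounds(bundle$metabolites, p("metabolites"))
  write_compounds(bundle$natural_products, p("natural_products"))
  write_compounds(bundle$drugs, p("drugs"))
  Biostrings::writeXStringSet(bundle$proteome, p("proteome.fasta"))
  write_network(bundle$network, p("network.tsv"))
  write_tsv(bundle$annotations, p("annotations.tsv"))
  write_tsv(bundle$labels$positives, p("positives.tsv"))
  write_tsv(bundle$indications, p("indications.tsv"))
  write_tsv(bundle$cooccurrence_method, p("cooccurrence_method.tsv"))
  write_tsv(bundle$cooccurrence_random, p("cooccurrence_random.tsv"))
  invisible(directory)
}

#' Read a fixture directory back into a bundle
#'
#' @param directory a directory written by [write_fixture()].
#' @return an `np_fixture` (without the generator-only members
#'   `np_truth_pairs` and `config`).
#' @export
read_fixture <- function(directory) {
  p <- function(...) file.path(directory, ...)
  metabolites <- read_compounds(p("metabolites.smi"),
                                p("metabolites_targets.tsv"), "metabolite")
  natural_products <- read_compounds(p("natural_products.smi"),
                                     p("natural_products_targets.tsv"),
                                     "natural_product")
  drugs <- read_compounds(p("drugs.smi"), p("drugs_targets.tsv"), "drug")
  structure(
    list(metabolites = metabolites, natural_products = natural_products,
         drugs = drugs,
         proteome = read_proteome(p("proteome.fasta")),
         network = read_network(p("network.tsv")),
         annotations = read_annotations(p("annotations.tsv"), metabolites),
         labels = read_pair_labels(p("positives.tsv"), drugs, metabolites),
         indications = read_indications(p("indications.tsv")),
         cooccurrence_method = read_cooccurrence(p("cooccurrence_method.tsv")),
         cooccurrence_random = read_cooccurrence(p("cooccurrence_random.tsv")),
         np_truth_pairs = NULL, config = NULL),
    class = "np_fixture"
  )
}
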