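# Assembly of the per-pair score matrix: one (structure, target, phenotype)
# similarity triple per (partner, metabolite) pair.

#' Feature computation configuration
#'
#' @param fp_length fingerprint length in bits (default 1024).
#' @param top_fraction upper-tail fraction kept by the target-score filter
#'   (default 0.05, the top-5% rule).
#' @param restart restart probability of the random walk (default 0.7).
#' @param tol random-walk convergence tolerance (default 1e-5).
#' @param max_iter random-walk iteration cap.
#' @param alignment an [alignment_config()].
#' @return a `feature_config`.
#' @export
feature_config <- function(fp_length = 1024L, top_fraction = 0.05,
                           restart = 0.7, tol = 1e-5, max_iter = 1000L,
                           alignment = alignment_config()) {
  structure(list(fp_length = as.integer(fp_length),
                 top_fraction = top_fraction, restart = restart, tol = tol,
                 max_iter = as.integer(max_iter), alignment = alignment),
            class = "feature_config")
}

#' Build the pairwise similarity feature matrix
#'
#' Computes, for every (partner, metabolite) pair, the three similarity
#' features: Tanimoto of hashed path fingerprints, top-filtered mean
#' normalized Smith-Waterman similarity between target sequences, and
#' absolute Pearson correlation of random-walk phenotype profiles. The
#' target-score threshold is computed once over the pooled target-pair
#' scores of this matrix before per-pair averaging. Missing inputs (no
#' parseable structure, no scorable target, no seed gene in the network)
#' produce NA in the corresponding feature; nothing is imputed here.
#'
#' @param partners `compound_set` of natural products or drugs.
#' @param metabolites `compound_set` of human metabolites.
#' @param proteome named AAStringSet of target-gene sequences.
#' @param network an `association_network`.
#' @param config a [feature_config()].
#' @return data.frame with columns `partner_id`, `metabolite_id`,
#'   `s_structure`, `s_target`, `s_phenotype` (one row per pair), with the
#'   applied target threshold in attribute `target_threshold`.
#' @export
build_feature_matrix <- function(partners, metabolites, proteome, network,
                                 config = feature_config()) {
  if (nrow(partners) == 0 || nrow(metabolites) == 0) {
    out <- data.frame(partner_id = character(0), metabolite_id = character(0),
                      s_structure = numeric(0), s_target = numeric(0),
                      s_phenotype = numeric(0), stringsAsFactors = FALSE)
    return(out)
  }

  pairs <- expand.grid(metabolite_id = metabolites$id, partner_id = partners$id,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[, c("partner_id", "metabolite_id")]
  pi_idx <- match(pairs$partner_id, partners$id)
  mi_idx <- match(pairs$metabolite_id, metabolites$id)

  # -- structure ------------------------------------------------------------
  fp_p <- compute_fingerprint(partners$smiles, length = config$fp_length)
  fp_m <- compute_fingerprint(metabolites$smiles, length = config$fp_length)
  s_structure <- vapply(seq_len(nrow(pairs)), function(k) {
    fa <- fp_p[[pi_idx[k]]]
    fb <- fp_m[[mi_idx[k]]]
    if (!inherits(fa, "fingerprint") || !inherits(fb, "fingerprint")) {
      return(NA_real_)
    }
    tanimoto(fa, fb)
  }, 0)

  # -- target ---------------------------------------------------------------
  genes_used <- unique(c(unlist(partners$targets), unlist(metabolites$targets)))
  genes_known <- intersect(genes_used, names(proteome))
  if (length(setdiff(genes_used, genes_known)) > 0) {
    warning("target gene(s) without sequence skipped: ",
            paste(setdiff(genes_used, genes_known), collapse = ", "),
            call. = FALSE)
  }
  sim_mat <- if (length(genes_known) > 0) {
    normalized_sw_matrix(proteome[genes_known], config$alignment)
  } else NULL
  pair_score_list <- lapply(seq_len(nrow(pairs)), function(k) {
    ta <- intersect(partners$targets[[pi_idx[k]]], genes_known)
    tb <- intersect(metabolites$targets[[mi_idx[k]]], genes_known)
    if (length(ta) == 0 || length(tb) == 0) return(NULL)
    as.vector(sim_mat[ta, tb, drop = FALSE])
  })
  pooled <- unlist(pair_score_list, use.names = FALSE)
  pooled <- pooled[!is.na(pooled)]
  threshold <- if (length(pooled) > 0) {
    top_fraction_threshold(pooled, config$top_fraction)
  } else NA_real_
  s_target <- vapply(pair_score_list, target_similarity, 0,
                     threshold = threshold)

  # -- phenotype ------------------------------------------------------------
  gene_nodes <- network$nodes$id[network$nodes$kind == "gene"]
  profile_cache <- new.env(parent = emptyenv())
  profile_of <- function(compound_row) {
    seeds <- intersect(compound_row$targets[[1]], gene_nodes)
    if (length(seeds) == 0) return(NULL)
    key <- paste(seeds, collapse = "\r")
    if (!exists(key, envir = profile_cache)) {
      assign(key,
             phenotype_profile(compound_row, network,
                               restart = config$restart, tol = config$tol,
                               max_iter = config$max_iter),
             envir = profile_cache)
    }
    get(key, envir = profile_cache)
  }
  prof_p <- lapply(seq_len(nrow(partners)), function(i) profile_of(partners[i, ]))
  prof_m <- lapply(seq_len(nrow(metabolites)), function(i) profile_of(metabolites[i, ]))
  s_phenotype <- vapply(seq_len(nrow(pairs)), function(k) {
    suppressMessages(
      phenotype_similarity(prof_p[[pi_idx[k]]], prof_m[[mi_idx[k]]])
    )
  }, 0)

  out <- data.frame(pairs, s_structure = s_structure, s_target = s_target,
                    s_phenotype = s_phenotype, stringsAsFactors = FALSE)
  out <- out[order(out$partner_id, out$metabolite_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "target_threshold") <- threshold
  out
}

#' Write / read a feature matrix as TSV
#'
#' @param features feature matrix from [build_feature_matrix()].
#' @param path TSV path.
#' @export
write_features <- function(features, path) {
  write_tsv(features, path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read_tsv(path, c("partner_id", "metabolite_id",
                         "s_structure", "s_target", "s_phenotype"))
  for (col in c("s_structure", "s_target", "s_phenotype")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}
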