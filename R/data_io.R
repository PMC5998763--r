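# Domain types and readers. All tabular inputs use the package TSV dialect
# (tab-separated, UTF-8, header row, "." = missing); identifiers are
# whitespace-stripped and compared case-sensitively.

#' Read compounds from a structure file plus a target table
#'
#' Structures come either as a SMILES file (one molecule per line,
#' `SMILES<whitespace>id`) or an SDF/MOL file (detected by `.sdf`/`.mol`
#' extension; ids from the title line). SMILES are canonicalized through
#' RDKit at load time; strings that do not parse are retained with `smiles`
#' missing and a warning, because downstream target/phenotype features may
#' still exist for those compounds.
#'
#' @param structures_path path to the SMILES or SDF file.
#' @param targets_path path to a TSV with columns `compound_id`, `gene_id`.
#'   Rows are aggregated into a target set per compound (duplicates collapse).
#' @param role one of `"metabolite"`, `"natural_product"`, `"drug"`.
#' @return a `compound_set`: data.frame with columns `id`, `role`, `smiles`
#'   (canonical, NA when absent/unparsable) and list-column `targets`.
#' @export
read_compounds <- function(structures_path, targets_path, role) {
  role <- match.arg(role, c("metabolite", "natural_product", "drug"))
  if (!file.exists(structures_path)) {
    stop("structure file does not exist: ", structures_path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(structures_path))
  if (ext %in% c("sdf", "mol")) {
    raw <- read_sdf_smiles(structures_path)
    raw$id <- normalize_id(raw$id)
    canon <- raw$smiles # bridge already canonicalized; NA when unparsable
    ids <- raw$id
    orig <- raw$smiles
  } else {
    lines <- readLines(structures_path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    bad <- lengths(parts) < 2
    if (any(bad)) {
      stop("SMILES file line(s) without an id: ",
           paste(which(bad), collapse = ", "), call. = FALSE)
    }
    orig <- vapply(parts, `[[`, "", 1L)
    ids <- normalize_id(vapply(parts, `[[`, "", 2L))
    canon <- vapply(chem_lookup(orig), `[[`, NA_character_, "canonical")
  }
  unparsed <- !is.na(orig) & is.na(canon)
  if (any(unparsed)) {
    warning(sum(unparsed), " structure(s) did not parse and were retained ",
            "without SMILES: ", paste(ids[unparsed], collapse = ", "),
            call. = FALSE)
  }
  # duplicate ids: identical canonical SMILES collapse, conflicts are fatal
  by_id <- split(seq_along(ids), ids)
  for (id in names(by_id)) {
    vals <- unique(canon[by_id[[id]]])
    vals <- vals[!is.na(vals)]
    if (length(vals) > 1) {
      stop("compound id ", id, " has conflicting structures: ",
           paste(vals, collapse = " vs "), call. = FALSE)
    }
  }
  keep <- !duplicated(ids)
  compounds <- data.frame(id = ids[keep], role = role,
                          smiles = canon[keep], stringsAsFactors = FALSE)

  tgt <- read_tsv(targets_path, c("compound_id", "gene_id"))
  tgt$compound_id <- normalize_id(tgt$compound_id)
  tgt$gene_id <- normalize_id(tgt$gene_id)
  tgt <- tgt[!is.na(tgt$compound_id) & !is.na(tgt$gene_id), , drop = FALSE]
  unknown <- setdiff(tgt$compound_id, compounds$id)
  if (length(unknown) > 0) {
    warning("target rows for unknown compound id(s) ignored: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    tgt <- tgt[tgt$compound_id %in% compounds$id, , drop = FALSE]
  }
  tsets <- split(tgt$gene_id, tgt$compound_id)
  compounds$targets <- lapply(compounds$id, function(id) {
    sort(unique(tsets[[id]]))
  })
  compounds$targets[vapply(compounds$targets, is.null, NA)] <- list(character(0))
  compounds <- compounds[order(compounds$id), , drop = FALSE]
  rownames(compounds) <- NULL
  class(compounds) <- c("compound_set", "data.frame")
  compounds
}

#' Read a protein sequence set from FASTA
#'
#' @param path FASTA file; record names are gene identifiers.
#' @return named [Biostrings::AAStringSet]. Sequences must be non-empty and
#'   restricted to the 20 amino-acid letters plus X.
#' @export
read_proteome <- function(path) {
  if (!file.exists(path)) stop("FASTA file does not exist: ", path, call. = FALSE)
  seqs <- Biostrings::readAAStringSet(path)
  names(seqs) <- normalize_id(sub("\\s.*$", "", names(seqs)))
  validate_proteome(seqs)
}

#' Validate / coerce a proteome
#'
#' @param seqs named character vector or AAStringSet of amino-acid sequences.
#' @return named AAStringSet.
#' @export
validate_proteome <- function(seqs) {
  if (!methods::is(seqs, "AAStringSet")) {
    seqs <- Biostrings::AAStringSet(seqs)
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all protein records need a gene identifier", call. = FALSE)
  }
  if (any(Biostrings::width(seqs) == 0)) {
    stop("empty protein sequence for: ",
         paste(names(seqs)[Biostrings::width(seqs) == 0], collapse = ", "),
         call. = FALSE)
  }
  allowed <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]
  freq <- Biostrings::alphabetFrequency(seqs)
  extra <- freq[, setdiff(colnames(freq), allowed), drop = FALSE]
  if (any(rowSums(extra) > 0)) {
    stop("protein sequence(s) contain letters outside the 20-AA alphabet + X: ",
         paste(names(seqs)[rowSums(extra) > 0], collapse = ", "), call. = FALSE)
  }
  seqs
}

#' Read a directed gene/phenotype association network
#'
#' @param edges_path TSV with columns `source_id`, `target_id`,
#'   `source_kind`, `target_kind` (each `gene` or `phenotype`) and an
#'   optional non-negative `weight` (default 1). Self-loops are dropped with
#'   a warning and counted in the result.
#' @return an `association_network`: list with `nodes` (data.frame `id`,
#'   `kind`), `edges` (data.frame `from`, `to`, `weight`) and
#'   `n_self_loops_dropped`.
#' @export
read_network <- function(edges_path) {
  df <- read_tsv(edges_path, c("source_id", "target_id", "source_kind", "target_kind"))
  df$source_id <- normalize_id(df$source_id)
  df$target_id <- normalize_id(df$target_id)
  kinds_ok <- c("gene", "phenotype")
  bad_kind <- !(df$source_kind %in% kinds_ok) | !(df$target_kind %in% kinds_ok)
  if (any(bad_kind)) {
    stop("network row(s) with undeclared node kind: row ",
         paste(which(bad_kind), collapse = ", "), call. = FALSE)
  }
  if ("weight" %in% names(df)) {
    w <- as.numeric(df$weight)
    w[is.na(df$weight)] <- 1
    if (any(is.na(w))) {
      stop("non-numeric weight in network row ",
           paste(which(is.na(w)), collapse = ", "), call. = FALSE)
    }
    if (any(w < 0)) {
      stop("negative weight in network row ",
           paste(which(w < 0), collapse = ", "), call. = FALSE)
    }
  } else {
    w <- rep(1, nrow(df))
  }
  nodes <- unique(data.frame(
    id = c(df$source_id, df$target_id),
    kind = c(df$source_kind, df$target_kind),
    stringsAsFactors = FALSE
  ))
  dup <- nodes$id[duplicated(nodes$id)]
  if (length(dup) > 0) {
    stop("node(s) declared with conflicting kinds: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  self <- df$source_id == df$target_id
  n_self <- sum(self)
  if (n_self > 0) {
    warning("dropped ", n_self, " self-loop edge(s)", call. = FALSE)
  }
  edges <- data.frame(from = df$source_id[!self], to = df$target_id[!self],
                      weight = w[!self], stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(
    list(nodes = nodes, edges = edges, n_self_loops_dropped = n_self),
    class = "association_network"
  )
}

#' Construct an association network from in-memory tables
#'
#' @param nodes data.frame with `id`, `kind`.
#' @param edges data.frame with `from`, `to`, optional `weight`.
#' @return an `association_network` (self-loops dropped with a warning).
#' @export
association_network <- function(nodes, edges) {
  stopifnot(all(c("id", "kind") %in% names(nodes)),
            all(c("from", "to") %in% names(edges)))
  if (!all(nodes$kind %in% c("gene", "phenotype"))) {
    stop("node kind must be 'gene' or 'phenotype'", call. = FALSE)
  }
  if (anyDuplicated(nodes$id)) stop("duplicate node ids", call. = FALSE)
  missing <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(missing) > 0) {
    stop("edge endpoint(s) not declared as nodes: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(edges$weight)) edges$weight <- rep(1, nrow(edges))
  if (any(edges$weight < 0)) stop("negative edge weight", call. = FALSE)
  self <- edges$from == edges$to
  if (any(self)) warning("dropped ", sum(self), " self-loop edge(s)", call. = FALSE)
  nodes <- nodes[order(nodes$id), c("id", "kind"), drop = FALSE]
  rownames(nodes) <- NULL
  edges <- edges[!self, c("from", "to", "weight"), drop = FALSE]
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(nodes = nodes, edges = edges, n_self_loops_dropped = sum(self)),
    class = "association_network"
  )
}

#' @export
print.association_network <- function(x, ...) {
  cat("association_network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$kind == "gene"), "genes,",
      sum(x$nodes$kind == "phenotype"), "phenotypes ),",
      nrow(x$edges), "edges;", x$n_self_loops_dropped, "self-loops dropped\n")
  invisible(x)
}

#' Read drug-metabolite positive labels
#'
#' The labeled universe is the full Cartesian product of the supplied drugs
#' and metabolites (positive-unlabeled setting); positives are read from the
#' file and must resolve to known compounds.
#'
#' @param path TSV with columns `drug_id`, `metabolite_id`.
#' @param drugs,metabolites `compound_set`s (or character id vectors).
#' @return a `pair_label_set`: list with `positives` (data.frame `drug_id`,
#'   `metabolite_id`), `drug_ids`, `metabolite_ids`.
#' @export
read_pair_labels <- function(path, drugs, metabolites) {
  df <- read_tsv(path, c("drug_id", "metabolite_id"))
  pair_labels(df, drugs, metabolites)
}

#' @rdname read_pair_labels
#' @param positives data.frame with columns `drug_id`, `metabolite_id`.
#' @export
pair_labels <- function(positives, drugs, metabolites) {
  drug_ids <- if (is.data.frame(drugs)) drugs$id else as.character(drugs)
  met_ids <- if (is.data.frame(metabolites)) metabolites$id else as.character(metabolites)
  positives <- positives[, c("drug_id", "metabolite_id"), drop = FALSE]
  positives$drug_id <- normalize_id(positives$drug_id)
  positives$metabolite_id <- normalize_id(positives$metabolite_id)
  unknown_d <- setdiff(positives$drug_id, drug_ids)
  unknown_m <- setdiff(positives$metabolite_id, met_ids)
  if (length(unknown_d) > 0 || length(unknown_m) > 0) {
    stop("positive pair(s) reference unknown compound(s): ",
         paste(c(unknown_d, unknown_m), collapse = ", "), call. = FALSE)
  }
  positives <- unique(positives)
  positives <- positives[order(positives$drug_id, positives$metabolite_id), ,
                         drop = FALSE]
  rownames(positives) <- NULL
  structure(
    list(positives = positives,
         drug_ids = sort(unique(drug_ids)),
         metabolite_ids = sort(unique(met_ids))),
    class = "pair_label_set"
  )
}

#' Expand the candidate-pair universe of a label set
#'
#' @param labels a `pair_label_set`.
#' @return data.frame of all (drug_id, metabolite_id) pairs with a logical
#'   `positive` column; exactly |drugs| x |metabolites| rows.
#' @export
pair_universe <- function(labels) {
  stopifnot(inherits(labels, "pair_label_set"))
  uni <- expand.grid(metabolite_id = labels$metabolite_ids,
                     drug_id = labels$drug_ids,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  uni <- uni[, c("drug_id", "metabolite_id")]
  uni$positive <- pair_key(uni$drug_id, uni$metabolite_id) %in%
    pair_key(labels$positives$drug_id, labels$positives$metabolite_id)
  uni <- uni[order(uni$drug_id, uni$metabolite_id), , drop = FALSE]
  rownames(uni) <- NULL
  uni
}

#' Read metabolite phenotype annotations
#'
#' @param path TSV with columns `compound_id`, `phenotype_term`.
#' @param metabolites optional `compound_set`; when given, every annotated
#'   compound must be a known metabolite.
#' @return data.frame `compound_id`, `phenotype_term` (deduplicated,
#'   terms normalized with [normalize_term()]).
#' @export
read_annotations <- function(path, metabolites = NULL) {
  df <- read_tsv(path, c("compound_id", "phenotype_term"))
  df$compound_id <- normalize_id(df$compound_id)
  df$phenotype_term <- normalize_term(df$phenotype_term)
  df <- df[!is.na(df$compound_id) & nzchar(df$phenotype_term), , drop = FALSE]
  if (!is.null(metabolites)) {
    unknown <- setdiff(df$compound_id, metabolites$id)
    if (length(unknown) > 0) {
      stop("annotation(s) for unknown metabolite(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  df <- unique(df[, c("compound_id", "phenotype_term")])
  df <- df[order(df$compound_id, df$phenotype_term), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read drug indication sets
#'
#' @param path TSV with columns `drug_id`, `indication`.
#' @return data.frame `drug_id`, `indication` (terms normalized, dedup).
#' @export
read_indications <- function(path) {
  df <- read_tsv(path, c("drug_id", "indication"))
  df$drug_id <- normalize_id(df$drug_id)
  df$indication <- normalize_term(df$indication)
  df <- unique(df[nzchar(df$indication), c("drug_id", "indication"), drop = FALSE])
  df <- df[order(df$drug_id, df$indication), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read literature co-occurrence records
#'
#' Each row holds the abstract counts for one term pair: `n_c` abstracts
#' mentioning both, `n_a`/`n_b` mentioning each term, `N` total abstracts.
#'
#' @param path TSV with columns `term_a`, `term_b`, `n_c`, `n_a`, `n_b`, `N`.
#' @return validated data.frame of co-occurrence records.
#' @export
read_cooccurrence <- function(path) {
  df <- read_tsv(path, c("term_a", "term_b", "n_c", "n_a", "n_b", "N"))
  for (col in c("n_c", "n_a", "n_b", "N")) df[[col]] <- as.numeric(df[[col]])
  validate_cooccurrence(df)
}

#' @rdname read_cooccurrence
#' @param df data.frame of co-occurrence records.
#' @export
validate_cooccurrence <- function(df) {
  stopifnot(all(c("term_a", "term_b", "n_c", "n_a", "n_b", "N") %in% names(df)))
  bad <- df$n_c > pmin(df$n_a, df$n_b) | df$n_a + df$n_b - df$n_c > df$N |
    df$n_c < 0 | df$n_a < 0 | df$n_b < 0
  if (any(bad)) {
    stop("invalid co-occurrence record(s) at row ",
         paste(which(bad), collapse = ", "),
         " (need n_c <= min(n_a, n_b) and n_a + n_b - n_c <= N)", call. = FALSE)
  }
  df
}

#' Write a compound set back to disk
#'
#' Emits a SMILES file (`<stem>.smi`) and a target TSV (`<stem>_targets.tsv`)
#' that round-trip through [read_compounds()].
#'
#' @param compounds a `compound_set`.
#' @param stem path prefix without extension.
#' @return invisibly, the two paths written.
#' @export
write_compounds <- function(compounds, stem) {
  smi_path <- paste0(stem, ".smi")
  tgt_path <- paste0(stem, "_targets.tsv")
  with_smiles <- !is.na(compounds$smiles)
  writeLines(paste(compounds$smiles[with_smiles], compounds$id[with_smiles]),
             smi_path)
  n_t <- lengths(compounds$targets)
  tgt <- data.frame(compound_id = rep(compounds$id, n_t),
                    gene_id = unlist(compounds$targets, use.names = FALSE),
                    stringsAsFactors = FALSE)
  write_tsv(tgt, tgt_path)
  invisible(c(smi_path, tgt_path))
}

#' Write an association network as an edge-list TSV
#'
#' @param network an `association_network`.
#' @param path output TSV path.
#' @export
write_network <- function(network, path) {
  kind <- setNames(network$nodes$kind, network$nodes$id)
  df <- data.frame(source_id = network$edges$from,
                   target_id = network$edges$to,
                   source_kind = unname(kind[network$edges$from]),
                   target_kind = unname(kind[network$edges$to]),
                   weight = network$edges$weight,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}
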