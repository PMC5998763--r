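# Evaluation battery: rank-based AUROC, feature-ablation experiments with
# random or structure-filtered negatives, at-least-one-indication precision
# and recall against a random-pairing baseline, and literature co-occurrence
# statistics (Jaccard index, Fisher's exact test, Mann-Whitney U).

#' Area under the ROC curve
#'
#' Rank-sum (Mann-Whitney) formulation with midranks for ties: the
#' probability that a random positive outranks a random negative, counting
#' ties as one half.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) class labels; both classes required.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]
  labels <- labels[ok]
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop("AUROC needs both classes present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Ablation experiment specification
#'
#' @param feature_subsets list of feature subsets to train; each entry is a
#'   character vector over `"structure"`, `"target"`, `"phenotype"` or the
#'   string `"all"`.
#' @param test_mode `"random_negatives"` (negatives sampled to match the
#'   positive count) or `"structure_filtered"` (negatives restricted to
#'   pairs with structure similarity strictly above `tanimoto_floor`).
#' @param tanimoto_floor structure-similarity floor (default 0.77).
#' @param test_fraction fraction of positives held out for testing.
#' @param rng_seed seed for the split and negative sampling.
#' @return an `ablation_spec`.
#' @export
ablation_spec <- function(feature_subsets = list("structure", "target",
                                                 "phenotype", "all"),
                          test_mode = c("random_negatives", "structure_filtered"),
                          tanimoto_floor = 0.77, test_fraction = 0.3,
                          rng_seed = 1L) {
  stopifnot(tanimoto_floor >= 0, tanimoto_floor <= 1,
            test_fraction > 0, test_fraction < 1)
  structure(list(feature_subsets = feature_subsets,
                 test_mode = match.arg(test_mode),
                 tanimoto_floor = tanimoto_floor,
                 test_fraction = test_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "ablation_spec")
}

subset_feature_cols <- function(subset) {
  if (length(subset) == 1 && subset == "all") {
    c("s_structure", "s_target", "s_phenotype")
  } else {
    paste0("s_", subset)
  }
}

# Split positives into train/test and draw test negatives per test_mode.
ablation_split <- function(features, labels, spec) {
  uni <- pair_universe(labels)
  pos <- uni[uni$positive, , drop = FALSE]
  unl <- uni[!uni$positive, , drop = FALSE]
  n_test <- max(1L, round(spec$test_fraction * nrow(pos)))
  withr::with_seed(spec$rng_seed, {
    test_pos_idx <- sample.int(nrow(pos), n_test)
    test_pos <- pos[test_pos_idx, , drop = FALSE]
    train_pos <- pos[-test_pos_idx, , drop = FALSE]
    if (spec$test_mode == "structure_filtered") {
      fidx <- feature_rows(features, unl$drug_id, unl$metabolite_id)
      s <- features$s_structure[fidx]
      qualifying <- which(!is.na(s) & s > spec$tanimoto_floor)
      if (length(qualifying) < n_test) {
        stop("structure-filtered mode: only ", length(qualifying),
             " unlabeled pair(s) exceed the Tanimoto floor ",
             spec$tanimoto_floor, " (need ", n_test, ")", call. = FALSE)
      }
      test_neg <- unl[sample(qualifying, n_test), , drop = FALSE]
    } else {
      test_neg <- unl[sample.int(nrow(unl), n_test), , drop = FALSE]
    }
    list(train_pos = train_pos, test_pos = test_pos, test_neg = test_neg)
  })
}

#' Feature-ablation AUROC experiment
#'
#' For each feature subset, trains the positive-unlabeled ensemble on
#' training positives (test pairs excluded from the sampling universe) and
#' evaluates AUROC on held-out positives plus negatives built per the test
#' mode: random negatives matching the positive count, or negatives
#' restricted to structurally similar pairs (Tanimoto above the floor).
#'
#' @param features feature matrix over the labeled universe.
#' @param labels a `pair_label_set`.
#' @param spec an [ablation_spec()].
#' @param config a [training_config()].
#' @return data.frame `subset`, `test_mode`, `auroc`, `n_test`.
#' @export
run_ablation <- function(features, labels, spec = ablation_spec(),
                         config = training_config()) {
  split <- ablation_split(features, labels, spec)
  test_pairs <- rbind(split$test_pos, split$test_neg)
  test_keys <- pair_key(test_pairs$drug_id, test_pairs$metabolite_id)

  train_mets <- labels$metabolite_ids
  train_labels <- structure(
    list(positives = split$train_pos[, c("drug_id", "metabolite_id")],
         drug_ids = labels$drug_ids, metabolite_ids = train_mets),
    class = "pair_label_set"
  )
  # exclude every test pair from the member negative-sampling pool
  training_sets <- sample_training_sets(train_labels, config$n_resamples,
                                        config$rng_seed)
  training_sets <- lapply(training_sets, function(ts) {
    ts[!(pair_key(ts$drug_id, ts$metabolite_id) %in% test_keys), , drop = FALSE]
  })

  fidx <- feature_rows(features, test_pairs$drug_id, test_pairs$metabolite_id)
  results <- lapply(spec$feature_subsets, function(subset) {
    cols <- subset_feature_cols(subset)
    sub_features <- features[, c("partner_id", "metabolite_id", cols),
                             drop = FALSE]
    model <- train_ensemble(sub_features, training_sets, config)
    preds <- predict_pairs(model, sub_features[fidx, , drop = FALSE])
    data.frame(subset = paste(subset, collapse = "+"),
               test_mode = spec$test_mode,
               auroc = auroc(preds$ensemble_score, test_pairs$positive),
               n_test = nrow(test_pairs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, results)
  rownames(out) <- NULL
  out
}

#' At-least-one-indication precision and recall
#'
#' Compares transferred phenotype terms against known drug indications,
#' after identical term normalization on both sides. The per-pair variant
#' is primary: precision = fraction of predicted (drug, term) pairs that
#' are true indications; recall = fraction of true (drug, indication) pairs
#' predicted. The per-drug ("at least one indication") variant is also
#' reported. The random baseline redoes the transfer over uniformly random
#' partner-metabolite pairings of the same cardinality.
#'
#' @param transferred from [transfer_phenotypes()].
#' @param truth data.frame `drug_id`, `indication` ([read_indications()]);
#'   only partners present in `truth` enter the calculation.
#' @param baseline `"model"` or `"random"`.
#' @param rng_seed seed for the random baseline.
#' @param predictions required for `baseline = "random"`: the
#'   [predict_pairs()] table whose similar-pair count and id pools the
#'   random pairing reuses.
#' @param annotations required for `baseline = "random"`.
#' @return list with `precision`, `recall` (per-pair, primary) and
#'   `precision_per_drug`, `recall_per_drug` (at-least-one variant).
#'   Empty predictions give precision NA and recall 0.
#' @export
indication_precision_recall <- function(transferred, truth,
                                        baseline = c("model", "random"),
                                        rng_seed = 1L, predictions = NULL,
                                        annotations = NULL) {
  baseline <- match.arg(baseline)
  truth <- truth[, c("drug_id", "indication")]
  truth$indication <- normalize_term(truth$indication)
  truth <- unique(truth)
  if (baseline == "random") {
    if (is.null(predictions) || is.null(annotations)) {
      stop("baseline='random' needs `predictions` and `annotations`",
           call. = FALSE)
    }
    n_sim <- sum(predictions$is_similar)
    partners <- sort(unique(predictions$partner_id))
    mets <- sort(unique(predictions$metabolite_id))
    transferred <- withr::with_seed(rng_seed, {
      rnd <- data.frame(
        partner_id = sample(partners, n_sim, replace = TRUE),
        metabolite_id = sample(mets, n_sim, replace = TRUE),
        stringsAsFactors = FALSE
      )
      rnd$ensemble_score <- 1
      rnd$is_similar <- TRUE
      transfer_phenotypes(rnd, annotations)
    })
  }
  pred <- unique(data.frame(drug_id = transferred$natural_product_id,
                            term = normalize_term(transferred$phenotype_term),
                            stringsAsFactors = FALSE))
  pred <- pred[pred$drug_id %in% unique(truth$drug_id), , drop = FALSE]
  truth_key <- paste(truth$drug_id, truth$indication, sep = "\r")
  pred_key <- paste(pred$drug_id, pred$term, sep = "\r")
  hit <- pred_key %in% truth_key
  precision <- if (nrow(pred) == 0) NA_real_ else mean(hit)
  recall <- if (length(truth_key) == 0) NA_real_ else {
    mean(truth_key %in% pred_key)
  }
  drugs_pred <- unique(pred$drug_id)
  hit_drugs <- unique(pred$drug_id[hit])
  precision_pd <- if (length(drugs_pred) == 0) NA_real_ else {
    length(hit_drugs) / length(drugs_pred)
  }
  recall_pd <- length(hit_drugs) / length(unique(truth$drug_id))
  list(precision = precision, recall = if (is.na(recall)) 0 else recall,
       precision_per_drug = precision_pd, recall_per_drug = recall_pd)
}

#' Jaccard index of a co-occurrence record
#'
#' `JI = n_c / (n_a + n_b - n_c)` over literature abstract counts; the 0/0
#' case (neither term ever occurs) is defined as 0.
#'
#' @param rec data.frame of co-occurrence records (validated).
#' @return numeric vector of Jaccard indices in \[0, 1\].
#' @export
jaccard_index <- function(rec) {
  rec <- validate_cooccurrence(rec)
  denom <- rec$n_a + rec$n_b - rec$n_c
  ifelse(denom == 0, 0, rec$n_c / denom)
}

#' Two-sided Fisher's exact test for co-occurrence records
#'
#' Tests independence of the two terms over the 2x2 table
#' \[\[n_c, n_a - n_c\], \[n_b - n_c, N - n_a - n_b + n_c\]\]: the two-sided
#' hypergeometric p-value, summing the probabilities of all tables with the
#' same margins that are no more probable than the observed one (with the
#' conventional 1 + 1e-7 relative tolerance).
#'
#' @param rec data.frame of co-occurrence records.
#' @return numeric vector of two-sided p-values.
#' @export
fisher_exact <- function(rec) {
  rec <- validate_cooccurrence(rec)
  vapply(seq_len(nrow(rec)), function(i) {
    fisher_exact_1(rec$n_c[i], rec$n_a[i], rec$n_b[i], rec$N[i])
  }, 0)
}

fisher_exact_1 <- function(n_c, n_a, n_b, N) {
  cells <- c(n_c, n_a - n_c, n_b - n_c, N - n_a - n_b + n_c)
  if (any(cells < 0)) {
    stop("negative cell in 2x2 table: ", paste(cells, collapse = ", "),
         call. = FALSE)
  }
  # hypergeometric support for the top-left cell with fixed margins
  lo <- max(0, n_a + n_b - N)
  hi <- min(n_a, n_b)
  x <- lo:hi
  dens <- stats::dhyper(x, n_a, N - n_a, n_b)
  obs <- dens[x == n_c]
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# Mann-Whitney U, two-sided: exact distribution for small tie-free samples,
# normal approximation with tie correction otherwise.
mann_whitney_p <- function(x, y) {
  exact <- length(x) <= 20 && length(y) <= 20 &&
    !any(duplicated(c(x, y)))
  stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
}

#' Literature co-occurrence validation report
#'
#' Summarizes the method's term-pair co-occurrence records against a random
#' pairing's records: mean co-occurrence count, mean Jaccard index, the
#' number of Fisher-significant records at `alpha`, and two-sided
#' Mann-Whitney U p-values comparing the method and random distributions
#' (computed for the co-occurrence counts and the Jaccard indices
#' separately).
#'
#' @param records co-occurrence records of the method's pairs (non-empty).
#' @param random_records co-occurrence records of random pairs (non-empty).
#' @param alpha Fisher significance threshold (default 0.001).
#' @return a `literature_report` list: per-set summaries (`method`,
#'   `random`) and `mannwhitney` p-values.
#' @export
literature_report <- function(records, random_records, alpha = 0.001) {
  if (nrow(records) == 0 || nrow(random_records) == 0) {
    stop("both record lists must be non-empty", call. = FALSE)
  }
  summarize <- function(rec) {
    list(mean_cooccurrence = mean(rec$n_c),
         mean_jaccard = mean(jaccard_index(rec)),
         n_fisher_significant = sum(fisher_exact(rec) < alpha),
         n_records = nrow(rec))
  }
  structure(
    list(method = summarize(records),
         random = summarize(random_records),
         mannwhitney = list(
           cooccurrence_p = mann_whitney_p(records$n_c, random_records$n_c),
           jaccard_p = mann_whitney_p(jaccard_index(records),
                                      jaccard_index(random_records))
         ),
         alpha = alpha),
    class = "literature_report"
  )
}

#' @export
print.literature_report <- function(x, ...) {
  cat("literature_report (alpha =", x$alpha, ")\n")
  for (set in c("method", "random")) {
    s <- x[[set]]
    cat(sprintf("  %-7s n=%d  mean n_c=%.3f  mean JI=%.4g  n_fisher<%g: %d\n",
                set, s$n_records, s$mean_cooccurrence, s$mean_jaccard,
                x$alpha, s$n_fisher_significant))
  }
  cat(sprintf("  Mann-Whitney p: n_c %.4g, JI %.4g\n",
              x$mannwhitney$cooccurrence_p, x$mannwhitney$jaccard_p))
  invisible(x)
}
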