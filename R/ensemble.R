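# Positive-unlabeled ensemble: all positives + an equal-sized random sample
# of unlabeled pairs per member, one RBF SVM per member, mean member
# probability as the ensemble score.

#' Training configuration for the pairing ensemble
#'
#' @param n_resamples number of random balanced training sets (default 100).
#' @param cv_folds folds for the per-member cross-validation report
#'   (default 10).
#' @param rng_seed integer seed governing resampling and fold assignment.
#' @param decision_threshold ensemble-score threshold for the similar /
#'   not-similar call (default 0.5).
#' @param svm_cost soft-margin cost C (default 1).
#' @param svm_gamma RBF width; NULL = per-member median heuristic.
#' @param record_cv record per-member CV AUROC (costly: `cv_folds` extra
#'   fits per member; reporting only, default FALSE).
#' @param aggregate `"mean"` (smooth ensemble probability, default) or
#'   `"vote"` (majority vote fraction).
#' @return a `training_config`.
#' @export
training_config <- function(n_resamples = 100L, cv_folds = 10L, rng_seed = 1L,
                            decision_threshold = 0.5, svm_cost = 1,
                            svm_gamma = NULL, record_cv = FALSE,
                            aggregate = c("mean", "vote")) {
  stopifnot(n_resamples >= 1, cv_folds >= 2)
  structure(list(n_resamples = as.integer(n_resamples),
                 cv_folds = as.integer(cv_folds),
                 rng_seed = as.integer(rng_seed),
                 decision_threshold = decision_threshold,
                 svm_cost = svm_cost, svm_gamma = svm_gamma,
                 record_cv = isTRUE(record_cv),
                 aggregate = match.arg(aggregate)),
            class = "training_config")
}

feature_columns <- function(features) {
  intersect(c("s_structure", "s_target", "s_phenotype"), names(features))
}

#' Sample balanced positive-unlabeled training sets
#'
#' Each of the `n_resamples` sets contains every positive pair plus a fresh
#' uniform sample (without replacement within a set) of unlabeled pairs of
#' equal size.
#'
#' @param labels a `pair_label_set`.
#' @param n_resamples number of sets.
#' @param rng_seed seed; identical seeds give identical samples.
#' @return list of data.frames (`drug_id`, `metabolite_id`, `label` with
#'   TRUE = positive).
#' @export
sample_training_sets <- function(labels, n_resamples = 100L, rng_seed = 1L) {
  stopifnot(inherits(labels, "pair_label_set"))
  uni <- pair_universe(labels)
  pos <- uni[uni$positive, , drop = FALSE]
  unl <- uni[!uni$positive, , drop = FALSE]
  if (nrow(pos) == 0) {
    stop("no positive pairs; cannot build training sets", call. = FALSE)
  }
  if (nrow(unl) < nrow(pos)) {
    stop("not enough unlabeled pairs (", nrow(unl), ") to match ",
         nrow(pos), " positives", call. = FALSE)
  }
  withr::with_seed(rng_seed, {
    lapply(seq_len(n_resamples), function(m) {
      neg <- unl[sample.int(nrow(unl), nrow(pos)), , drop = FALSE]
      out <- rbind(
        data.frame(pos[, c("drug_id", "metabolite_id")], label = TRUE),
        data.frame(neg[, c("drug_id", "metabolite_id")], label = FALSE)
      )
      rownames(out) <- NULL
      out
    })
  })
}

# Look up the feature rows of a set of pairs; fatal if any pair lacks one.
feature_rows <- function(features, drug_id, metabolite_id) {
  idx <- match(pair_key(drug_id, metabolite_id),
               pair_key(features$partner_id, features$metabolite_id))
  if (anyNA(idx)) {
    stop(sum(is.na(idx)), " training pair(s) have no feature vector",
         call. = FALSE)
  }
  idx
}

fit_member <- function(X_raw, label, config, gamma_seed) {
  if (length(unique(label)) < 2) {
    stop("degenerate training member: a single class", call. = FALSE)
  }
  medians <- apply(X_raw, 2, median, na.rm = TRUE)
  medians[is.na(medians)] <- 0
  X <- X_raw
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- medians[j]
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0 | is.na(scale_)] <- 1
  Xs <- scale(X, center = center, scale = scale_)
  model <- svm_fit(Xs, ifelse(label, 1, -1),
                   cost = config$svm_cost, gamma = config$svm_gamma)
  list(svm = model, medians = medians, center = center, scale = scale_)
}

# Per-fold AUROC, averaged over folds that contain both classes. Averaging
# per fold (rather than pooling scores) avoids the pooling artifact where
# fold-specific score offsets fabricate ranking signal.
member_cv_auroc <- function(X_raw, label, config, fold_seed) {
  n <- length(label)
  folds <- withr::with_seed(fold_seed,
                            sample(rep_len(seq_len(config$cv_folds), n)))
  fold_auc <- rep(NA_real_, config$cv_folds)
  for (f in seq_len(config$cv_folds)) {
    test <- folds == f
    if (all(test) || !any(test)) next
    if (length(unique(label[!test])) < 2) next
    if (length(unique(label[test])) < 2) next
    m <- fit_member(X_raw[!test, , drop = FALSE], label[!test], config, fold_seed)
    fold_auc[f] <- auroc(predict_member(m, X_raw[test, , drop = FALSE]),
                         label[test])
  }
  if (all(is.na(fold_auc))) return(NA_real_)
  mean(fold_auc, na.rm = TRUE)
}

predict_member <- function(member, X_raw) {
  X <- X_raw
  for (j in seq_len(ncol(X))) {
    X[is.na(X[, j]), j] <- member$medians[j]
  }
  Xs <- scale(X, center = member$center, scale = member$scale)
  svm_decision(member$svm, Xs)$probability
}

#' Train the SVM ensemble
#'
#' One probability-producing RBF SVM per training set. Missing feature
#' values are imputed with that member's training-set median per feature;
#' features are then standardized with that member's training mean/sd.
#'
#' @param features feature matrix (from [build_feature_matrix()] or
#'   [read_features()]).
#' @param training_sets from [sample_training_sets()].
#' @param config a [training_config()].
#' @return an `np_ensemble` with one fitted member per training set and,
#'   when `config$record_cv`, a `cv_auroc` vector.
#' @export
train_ensemble <- function(features, training_sets, config = training_config()) {
  fcols <- feature_columns(features)
  if (length(fcols) == 0) stop("no feature columns found", call. = FALSE)
  members <- vector("list", length(training_sets))
  cv_auroc <- rep(NA_real_, length(training_sets))
  for (m in seq_along(training_sets)) {
    ts <- training_sets[[m]]
    idx <- feature_rows(features, ts$drug_id, ts$metabolite_id)
    X_raw <- as.matrix(features[idx, fcols, drop = FALSE])
    members[[m]] <- fit_member(X_raw, ts$label, config, config$rng_seed + m)
    if (config$record_cv) {
      cv_auroc[m] <- member_cv_auroc(X_raw, ts$label, config,
                                     config$rng_seed + m)
    }
  }
  structure(
    list(members = members, config = config, feature_cols = fcols,
         cv_auroc = if (config$record_cv) cv_auroc else NULL),
    class = "np_ensemble"
  )
}

#' @export
print.np_ensemble <- function(x, ...) {
  cat("np_ensemble:", length(x$members), "members on features",
      paste(x$feature_cols, collapse = ", "), "\n")
  if (!is.null(x$cv_auroc)) {
    cat("  mean member CV AUROC:", round(mean(x$cv_auroc, na.rm = TRUE), 3), "\n")
  }
  invisible(x)
}

#' Score candidate pairs with the ensemble
#'
#' The ensemble score of a pair is the arithmetic mean of the member
#' probabilities (or the member vote fraction under `aggregate = "vote"`);
#' a pair is called similar when the score reaches the decision threshold.
#'
#' @param model an `np_ensemble`.
#' @param features feature matrix with the same feature columns as training.
#' @return data.frame `partner_id`, `metabolite_id`, `ensemble_score`,
#'   `is_similar`.
#' @export
predict_pairs <- function(model, features) {
  stopifnot(inherits(model, "np_ensemble"))
  if (nrow(features) == 0) {
    return(data.frame(partner_id = character(0), metabolite_id = character(0),
                      ensemble_score = numeric(0), is_similar = logical(0),
                      stringsAsFactors = FALSE))
  }
  missing_cols <- setdiff(model$feature_cols, names(features))
  if (length(missing_cols) > 0) {
    stop("feature column(s) missing at prediction time: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  X_raw <- as.matrix(features[, model$feature_cols, drop = FALSE])
  probs <- vapply(model$members, predict_member, numeric(nrow(X_raw)),
                  X_raw = X_raw)
  if (nrow(X_raw) == 1) probs <- matrix(probs, nrow = 1)
  score <- if (model$config$aggregate == "vote") {
    rowMeans(probs >= model$config$decision_threshold)
  } else {
    rowMeans(probs)
  }
  data.frame(partner_id = features$partner_id,
             metabolite_id = features$metabolite_id,
             ensemble_score = score,
             is_similar = score >= model$config$decision_threshold,
             stringsAsFactors = FALSE)
}

#' Transfer metabolite phenotype terms to predicted-similar partners
#'
#' Every phenotype term of a metabolite predicted similar to a natural
#' product is assigned to that natural product; terms are deduplicated per
#' product with the contributing metabolites accumulated. Predicted-similar
#' metabolites without any annotation contribute nothing (logged).
#'
#' @param predictions from [predict_pairs()].
#' @param annotations data.frame `compound_id`, `phenotype_term`.
#' @return data.frame `natural_product_id`, `phenotype_term`,
#'   `source_metabolite_ids` (comma-joined, sorted).
#' @export
transfer_phenotypes <- function(predictions, annotations) {
  sim <- predictions[predictions$is_similar, , drop = FALSE]
  empty <- data.frame(natural_product_id = character(0),
                      phenotype_term = character(0),
                      source_metabolite_ids = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(sim) == 0) return(empty)
  unannotated <- setdiff(unique(sim$metabolite_id), annotations$compound_id)
  if (length(unannotated) > 0) {
    message("predicted-similar metabolite(s) without annotation: ",
            paste(unannotated, collapse = ", "))
  }
  joined <- merge(sim[, c("partner_id", "metabolite_id")], annotations,
                  by.x = "metabolite_id", by.y = "compound_id")
  if (nrow(joined) == 0) return(empty)
  key <- paste(joined$partner_id, joined$phenotype_term, sep = "\r")
  sources <- tapply(joined$metabolite_id, key, function(x) {
    paste(sort(unique(x)), collapse = ",")
  })
  parts <- strsplit(names(sources), "\r", fixed = TRUE)
  out <- data.frame(
    natural_product_id = vapply(parts, `[[`, "", 1L),
    phenotype_term = vapply(parts, `[[`, "", 2L),
    source_metabolite_ids = unname(as.character(sources)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$natural_product_id, out$phenotype_term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
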