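# Positive-unlabeled ensemble: sampling, training, prediction, transfer.

test_that("sample_training_sets: balance, reproducibility, preconditions", {
  labels <- pair_labels(
    data.frame(drug_id = sprintf("d%02d", 1:10),
               metabolite_id = rep("m01", 10), stringsAsFactors = FALSE),
    sprintf("d%02d", 1:40), sprintf("m%02d", 1:30)
  )
  sets <- sample_training_sets(labels, n_resamples = 20, rng_seed = 5)
  expect_length(sets, 20)
  expect_true(all(vapply(sets, nrow, 0L) == 20))
  expect_true(all(vapply(sets, function(s) sum(s$label), 0L) == 10))
  # the unlabeled sample is without replacement within a set
  expect_true(all(vapply(sets, function(s) {
    !anyDuplicated(paste(s$drug_id, s$metabolite_id))
  }, NA)))
  sets2 <- sample_training_sets(labels, n_resamples = 20, rng_seed = 5)
  expect_identical(sets, sets2)

  tight <- pair_labels(
    data.frame(drug_id = sprintf("d%d", 1:5), metabolite_id = rep("m1", 5),
               stringsAsFactors = FALSE),
    sprintf("d%d", 1:9), "m1" # 9 pairs total, 5 positive, 4 unlabeled
  )
  expect_error(sample_training_sets(tight, 2, 1), "not enough unlabeled")
})

test_that("ensemble separates planted Gaussian classes and not noise", {
  gf <- gaussian_features(30, 30, shift = 0.6, sd = 0.05, seed = 2)
  cfg <- training_config(n_resamples = 3, rng_seed = 2, record_cv = TRUE)
  model <- train_ensemble(gf$features, gaussian_training_sets(gf, 3), cfg)
  expect_length(model$members, 3)
  expect_true(all(model$cv_auroc > 0.95))
  preds <- predict_pairs(model, gf$features)
  expect_gt(auroc(preds$ensemble_score, gf$labels), 0.95)

  # identical features for every pair: no signal, CV AUROC near 1/2
  flat <- gf
  flat$features$s_structure <- 0.5
  flat$features$s_target <- 0.5
  flat$features$s_phenotype <- 0.5
  model0 <- train_ensemble(flat$features, gaussian_training_sets(flat, 3), cfg)
  expect_true(all(abs(model0$cv_auroc - 0.5) < 0.15))
})

test_that("train_ensemble contracts: member count, degenerate classes, NAs", {
  gf <- gaussian_features(10, 10, seed = 3)
  cfg <- training_config(n_resamples = 1, rng_seed = 3)
  model <- train_ensemble(gf$features, gaussian_training_sets(gf, 1), cfg)
  expect_length(model$members, 1)

  one_class <- gaussian_training_sets(gf, 1)
  one_class[[1]]$label <- TRUE
  expect_error(train_ensemble(gf$features, one_class, cfg), "single class")

  # missing feature values are imputed with the member's training median
  gf_na <- gf
  gf_na$features$s_target[c(1, 11)] <- NA
  model_na <- train_ensemble(gf_na$features, gaussian_training_sets(gf_na, 1), cfg)
  preds <- predict_pairs(model_na, gf_na$features)
  expect_false(anyNA(preds$ensemble_score))

  # pair at the positive centroid scores above threshold
  centroid <- gf$features[1, ]
  centroid$s_structure <- 0.8
  centroid$s_target <- 0.8
  centroid$s_phenotype <- 0.8
  expect_gt(predict_pairs(model, centroid)$ensemble_score, 0.5)
})

test_that("prediction is deterministic, mean-aggregated and empty-safe", {
  gf <- gaussian_features(15, 15, seed = 4)
  cfg <- training_config(n_resamples = 4, rng_seed = 4)
  model <- train_ensemble(gf$features, gaussian_training_sets(gf, 4), cfg)
  p1 <- predict_pairs(model, gf$features)
  p2 <- predict_pairs(model, gf$features)
  expect_identical(p1, p2)
  expect_identical(p1$is_similar, p1$ensemble_score >= 0.5)

  # the ensemble score is the arithmetic mean of member probabilities
  X <- as.matrix(gf$features[, model$feature_cols])
  member_probs <- vapply(model$members, npmatch:::predict_member,
                         numeric(nrow(X)), X_raw = X)
  expect_equal(p1$ensemble_score, rowMeans(member_probs), tolerance = 1e-12)

  expect_equal(nrow(predict_pairs(model, gf$features[0, ])), 0)
})

test_that("transfer_phenotypes unions terms and accumulates sources", {
  preds <- data.frame(
    partner_id = c("NP1", "NP1", "NP2"),
    metabolite_id = c("M1", "M2", "M1"),
    ensemble_score = c(0.9, 0.8, 0.2),
    is_similar = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  ann <- data.frame(
    compound_id = c("M1", "M1", "M2", "M2"),
    phenotype_term = c("t1", "t2", "t2", "t3"),
    stringsAsFactors = FALSE
  )
  tr <- transfer_phenotypes(preds, ann)
  np1 <- tr[tr$natural_product_id == "NP1", ]
  expect_setequal(np1$phenotype_term, c("t1", "t2", "t3"))
  expect_equal(np1$source_metabolite_ids[np1$phenotype_term == "t2"], "M1,M2")
  # NP2's only pair is below threshold
  expect_false("NP2" %in% tr$natural_product_id)

  # no similar pair -> empty result
  none <- preds
  none$is_similar <- FALSE
  expect_equal(nrow(transfer_phenotypes(none, ann)), 0)

  # similar pair with unannotated metabolite: nothing transferred, logged
  lone <- data.frame(partner_id = "NP9", metabolite_id = "M9",
                     ensemble_score = 1, is_similar = TRUE,
                     stringsAsFactors = FALSE)
  expect_message(out <- transfer_phenotypes(lone, ann), "without annotation")
  expect_equal(nrow(out), 0)
})

test_that("phenotype transfer never invents terms", {
  b <- tiny_bundle()
  fm <- tiny_features()
  ts <- sample_training_sets(b$labels, 5, rng_seed = 9)
  model <- train_ensemble(fm, ts, training_config(n_resamples = 5, rng_seed = 9))
  npfm <- suppressWarnings(build_feature_matrix(
    b$natural_products, b$metabolites, b$proteome, b$network
  ))
  preds <- predict_pairs(model, npfm)
  tr <- suppressMessages(transfer_phenotypes(preds, b$annotations))
  if (nrow(tr) > 0) {
    known <- paste(b$annotations$compound_id, b$annotations$phenotype_term)
    for (i in seq_len(nrow(tr))) {
      sources <- strsplit(tr$source_metabolite_ids[i], ",")[[1]]
      expect_true(all(paste(sources, tr$phenotype_term[i]) %in% known))
      # every source is predicted-similar to the product
      expect_true(all(preds$is_similar[
        preds$partner_id == tr$natural_product_id[i] &
          preds$metabolite_id %in% sources
      ]))
    }
  } else {
    succeed("no similar pairs predicted on the tiny fixture")
  }
})
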