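# Evaluation battery: AUROC, ablation, precision/recall, literature stats.

test_that("auroc hand cases and error contract", {
  expect_equal(auroc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1.0)
  expect_equal(auroc(rep(0.5, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE)),
               oracle_auroc(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE)))
  expect_error(auroc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("auroc equals pair counting with heavy ties", {
  withr::with_seed(41, {
    for (i in 1:20) {
      n <- sample(10:60, 1)
      scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
      labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      expect_equal(auroc(scores, labels), oracle_auroc(scores, labels))
    }
  })
})

test_that("jaccard_index formula and symmetry", {
  rec <- data.frame(term_a = c("a", "b", "c"), term_b = c("x", "y", "z"),
                    n_c = c(7, 0, 5), n_a = c(7, 10, 10), n_b = c(7, 15, 15),
                    N = 1000)
  expect_equal(jaccard_index(rec), c(1.0, 0.0, 0.25))
  swapped <- rec
  names(swapped)[names(swapped) == "n_a"] <- "tmp"
  names(swapped)[names(swapped) == "n_b"] <- "n_a"
  names(swapped)[names(swapped) == "tmp"] <- "n_b"
  expect_equal(jaccard_index(swapped), jaccard_index(rec))
  # 0/0 case
  zero <- data.frame(term_a = "a", term_b = "b", n_c = 0, n_a = 0, n_b = 0,
                     N = 10)
  expect_equal(jaccard_index(zero), 0)
})

test_that("fisher_exact hand cases and oracle spot checks", {
  # [[5,0],[0,5]]: n_c=5, n_a=5, n_b=5, N=10; p = 2/choose(10,5)
  rec <- data.frame(term_a = "a", term_b = "b", n_c = 5, n_a = 5, n_b = 5,
                    N = 10)
  expect_equal(fisher_exact(rec), 2 / choose(10, 5))
  # independent table [[1,1],[1,1]]
  ind <- data.frame(term_a = "a", term_b = "b", n_c = 1, n_a = 2, n_b = 2,
                    N = 4)
  expect_equal(fisher_exact(ind), 1.0)
  # random tables match both the enumeration oracle and stats::fisher.test
  withr::with_seed(42, {
    for (i in 1:25) {
      N <- sample(10:60, 1)
      n_a <- sample(1:(N - 1), 1)
      n_b <- sample(1:(N - 1), 1)
      lo <- max(0, n_a + n_b - N)
      hi <- min(n_a, n_b)
      n_c <- sample(lo:hi, 1)
      rec <- data.frame(term_a = "a", term_b = "b", n_c = n_c, n_a = n_a,
                        n_b = n_b, N = N)
      p <- fisher_exact(rec)
      expect_equal(p, oracle_fisher(n_c, n_a, n_b, N), tolerance = 1e-12)
      tab <- matrix(c(n_c, n_b - n_c, n_a - n_c, N - n_a - n_b + n_c), 2)
      expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    }
  })
})

test_that("literature_report summarizes and compares distributions", {
  b <- tiny_bundle()
  # identical lists: Mann-Whitney cannot see a difference
  same <- literature_report(b$cooccurrence_method, b$cooccurrence_method)
  expect_gt(same$mannwhitney$cooccurrence_p, 0.9)
  # associated vs independent regimes: strong shift in counts
  rep <- literature_report(b$cooccurrence_method, b$cooccurrence_random)
  expect_lt(rep$mannwhitney$cooccurrence_p, 0.05)
  expect_gt(rep$method$mean_cooccurrence, rep$random$mean_cooccurrence)
  # vacuous alpha marks every record significant
  all_sig <- literature_report(b$cooccurrence_method, b$cooccurrence_random,
                               alpha = 1.0)
  expect_equal(all_sig$method$n_fisher_significant,
               nrow(b$cooccurrence_method))
  expect_error(literature_report(b$cooccurrence_method[0, ],
                                 b$cooccurrence_random), "non-empty")
})

test_that("indication precision/recall counts pairs correctly", {
  truth <- data.frame(drug_id = c("n1", "n1", "n2", "n3"),
                      indication = c("t1", "t2", "t3", "t4"),
                      stringsAsFactors = FALSE)
  # predictions exactly equal to the truth
  tr_exact <- data.frame(natural_product_id = truth$drug_id,
                         phenotype_term = truth$indication,
                         source_metabolite_ids = "m",
                         stringsAsFactors = FALSE)
  pr <- indication_precision_recall(tr_exact, truth)
  expect_equal(pr$precision, 1.0)
  expect_equal(pr$recall, 1.0)
  # disjoint predictions
  tr_miss <- data.frame(natural_product_id = c("n1", "n2"),
                        phenotype_term = c("zz", "yy"),
                        source_metabolite_ids = "m",
                        stringsAsFactors = FALSE)
  pr <- indication_precision_recall(tr_miss, truth)
  expect_equal(pr$precision, 0.0)
  expect_equal(pr$recall, 0.0)
  # 2 predicted pairs, 1 true, 4 true pairs total -> (0.5, 0.25)
  tr_half <- data.frame(natural_product_id = c("n1", "n2"),
                        phenotype_term = c("t1", "qq"),
                        source_metabolite_ids = "m",
                        stringsAsFactors = FALSE)
  pr <- indication_precision_recall(tr_half, truth)
  expect_equal(pr$precision, 0.5)
  expect_equal(pr$recall, 0.25)
  # empty predictions: precision missing, recall 0
  pr <- indication_precision_recall(tr_half[0, ], truth)
  expect_true(is.na(pr$precision))
  expect_equal(pr$recall, 0)
  # term matching is normalization-insensitive
  fancy <- truth
  fancy$indication <- toupper(fancy$indication)
  pr <- indication_precision_recall(tr_exact, fancy)
  expect_equal(pr$recall, 1.0)
})

test_that("random baseline approaches the analytic expectation", {
  # world: n_np products, each with 1 predicted metabolite; every metabolite
  # has exactly 1 term drawn uniformly from n_terms; truth gives each drug 1
  # uniform term. P(hit per predicted pair) = 1/n_terms.
  n_np <- 40L
  n_terms <- 8L
  reps <- 60L
  withr::with_seed(77, {
    terms <- sprintf("t%02d", seq_len(n_terms))
    truth <- data.frame(drug_id = sprintf("np%02d", seq_len(n_np)),
                        indication = sample(terms, n_np, replace = TRUE),
                        stringsAsFactors = FALSE)
    ann <- data.frame(compound_id = sprintf("m%02d", seq_len(n_np)),
                      phenotype_term = sample(terms, n_np, replace = TRUE),
                      stringsAsFactors = FALSE)
    preds <- data.frame(partner_id = sprintf("np%02d", seq_len(n_np)),
                        metabolite_id = sprintf("m%02d", seq_len(n_np)),
                        ensemble_score = 1, is_similar = TRUE,
                        stringsAsFactors = FALSE)
    hits <- 0
    pairs <- 0
    for (r in seq_len(reps)) {
      pr <- indication_precision_recall(
        transfer_phenotypes(preds, ann), truth, baseline = "random",
        rng_seed = r, predictions = preds, annotations = ann
      )
      if (!is.na(pr$precision)) {
        # precision is hit fraction over predicted pairs; recover counts
        # approximately by weighting with the number of predicted pairs
        hits <- hits + pr$precision
        pairs <- pairs + 1
      }
    }
    p_hat <- hits / pairs
    p0 <- 1 / n_terms
    # 3 sigma binomial band around the analytic expectation (n_np pairs/rep)
    se <- sqrt(p0 * (1 - p0) / (reps * n_np))
    expect_lt(abs(p_hat - p0), 3 * se + 0.02)
  })
})

test_that("run_ablation produces one row per subset and honors modes", {
  b <- tiny_bundle()
  fm <- tiny_features()
  cfg <- training_config(n_resamples = 3, rng_seed = 13)
  spec1 <- ablation_spec(feature_subsets = list("structure"),
                         test_mode = "random_negatives", rng_seed = 13)
  res <- run_ablation(fm, b$labels, spec1, cfg)
  expect_equal(nrow(res), 1)
  expect_equal(res$subset, "structure")
  expect_true(res$auroc >= 0 && res$auroc <= 1)

  # structure_filtered with an absurd floor: fatal with the count
  spec2 <- ablation_spec(feature_subsets = list("all"),
                         test_mode = "structure_filtered",
                         tanimoto_floor = 1, rng_seed = 13)
  expect_error(run_ablation(fm, b$labels, spec2, cfg),
               "structure-filtered mode")
})
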