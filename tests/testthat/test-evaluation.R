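test_that("negative sampling avoids positives, hits the count, and is seeded", {
  pos <- labeled_pairs(c(1, 2, 4), c(1, 3, 2), c(1, 1, 1))
  for (seed in 1:20) {
    neg <- sample_negatives(pos, 4, 4, ratio = 2, seed = seed)
    expect_identical(nrow(neg), 6L)
    expect_true(all(neg$label == 0))
    key <- paste(neg$drug, neg$disease)
    expect_identical(anyDuplicated(key), 0L)
    expect_length(intersect(key, paste(pos$drug, pos$disease)), 0L)
    expect_true(all(neg$drug %in% 1:4 & neg$disease %in% 1:4))
  }
  expect_identical(sample_negatives(pos, 4, 4, 2, seed = 3),
                   sample_negatives(pos, 4, 4, 2, seed = 3))
  expect_false(identical(sample_negatives(pos, 4, 4, 2, seed = 3),
                         sample_negatives(pos, 4, 4, 2, seed = 4)))
  # 13 non-positive cells exist; asking for 4x3=12 works, 5x3=15 cannot
  expect_silent(sample_negatives(pos, 4, 4, 4, seed = 1))
  expect_error(sample_negatives(pos, 4, 4, 5, seed = 1), "13")
})

test_that("pair folds are near-equal partitions; entity folds separate entities", {
  pos <- labeled_pairs(rep(1:10, 3), rep(1:6, 5), rep(1, 30))
  folds <- split_folds(pos, "pair", 10, seed = 2)
  sizes <- vapply(folds, function(f) nrow(f$test), integer(1L))
  expect_identical(sizes, rep(3L, 10))
  recon <- do.call(rbind, lapply(folds, `[[`, "test"))
  expect_identical(nrow(unique(recon)), 30L)  # disjoint cover

  dfolds <- split_folds(pos, "drug", 5, seed = 2)
  for (f in dfolds) {
    expect_length(intersect(unique(f$train$drug), unique(f$test$drug)), 0L)
    expect_identical(nrow(f$train) + nrow(f$test), 30L)
  }
  sfolds <- split_folds(pos, "disease", 3, seed = 2)
  test_union <- do.call(rbind, lapply(sfolds, `[[`, "test"))
  expect_identical(nrow(unique(test_union)), 30L)
  for (f in sfolds) {
    expect_length(intersect(unique(f$train$disease), unique(f$test$disease)),
                  0L)
  }
  expect_error(split_folds(pos, "disease", 7, seed = 1), "fewer distinct")
})

test_that("AUC equals exhaustive pair counting, including ties", {
  expect_identical(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_identical(roc_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  labels <- c(1, 0, 1, 0, 0, 1)
  scores <- c(0.9, 0.9, 0.3, 0.2, 0.3, 0.8)
  expect_identical(roc_auc(labels, scores), brute_auc(labels, scores))
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "at least one")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(4, {
    labels <- rbinom(40, 1, 0.4)
    labels[1:2] <- c(0, 1)
    scores <- round(rnorm(40), 1)
  })
  a_raw <- roc_auc(labels, scores)
  expect_identical(roc_auc(labels, 1 / (1 + exp(-scores))), a_raw)
  expect_identical(roc_auc(labels, 100 * scores - 3), a_raw)
})

test_that("repeated cross-validation is reproducible and well-formed", {
  ds <- small_dataset()
  cc <- cv_config(n_folds = 5, n_repeats = 2, k = 8, max_epochs = 20,
                  seed = 31)
  r1 <- cross_validate(ds$network, ds$drug_genes, ds$disease_genes,
                       ds$positives, cc)
  r2 <- cross_validate(ds$network, ds$drug_genes, ds$disease_genes,
                       ds$positives, cc)
  expect_identical(r1$folds, r2$folds)
  expect_identical(nrow(r1$folds), 10L)
  expect_true(all(r1$folds$auc >= 0 & r1$folds$auc <= 1))
  expect_equal(r1$mean_auc, mean(r1$folds$auc), tolerance = 1e-15)
  expect_equal(unname(r1$repeat_means),
               unname(tapply(r1$folds$auc, r1$folds$rep, mean)),
               tolerance = 1e-15)
})

test_that("cold-start training never touches latent rows of unseen entities", {
  ds <- small_dataset()
  cc <- cv_config(setting = "drug", n_folds = 4, n_repeats = 1, k = 8,
                  max_epochs = 15, seed = 7)
  spaces <- build_feature_spaces(ds$network, ds$drug_genes, ds$disease_genes,
                                 cc)
  pos <- positives_to_indices(ds$positives, ds$drug_genes$row_ids,
                              ds$disease_genes$row_ids)
  negs <- sample_negatives(pos, length(ds$drug_genes$row_ids),
                           length(ds$disease_genes$row_ids), 2, seed = 5)
  folds <- split_folds(rbind(pos, negs), "drug", 4, seed = 6)
  model0 <- init_model(spaces$drug_space, spaces$disease_space)
  for (f in folds) {
    trained <- mf_train(model0, f$train, max_epochs = 15, seed = 8)$model
    unseen <- setdiff(seq_len(nrow(model0$A)), unique(f$train$drug))
    expect_identical(trained$A[unseen, , drop = FALSE],
                     model0$A[unseen, , drop = FALSE])
    # every test drug is unseen by construction
    expect_true(all(unique(f$test$drug) %in% unseen))
  }
})

test_that("FV-mode AUC is identical for raw dot products and sigmoid scores", {
  ds <- small_dataset()
  cc <- cv_config(mode = "FV", n_folds = 5, n_repeats = 1, k = 8, seed = 13)
  spaces <- build_feature_spaces(ds$network, ds$drug_genes, ds$disease_genes,
                                 cc)
  m <- init_model(spaces$drug_space, spaces$disease_space)
  pos <- positives_to_indices(ds$positives, ds$drug_genes$row_ids,
                              ds$disease_genes$row_ids)
  negs <- sample_negatives(pos, length(ds$drug_genes$row_ids),
                           length(ds$disease_genes$row_ids), 2, seed = 2)
  s <- rbind(pos, negs)
  dots <- rowSums(m$A[s$drug, , drop = FALSE] * m$B[s$disease, , drop = FALSE])
  expect_identical(roc_auc(s$label, dots),
                   roc_auc(s$label, predict(m, s$drug, s$disease)))
})
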