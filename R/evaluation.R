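#' Cross-validation configuration
#'
#' Bundles the evaluation protocol and model hyperparameters.  Defaults
#' follow the reference protocol: 10 folds, 5 independent repeats, two
#' sampled negatives per positive, k = 32, lambda = 2^-7, eta = 2^-4,
#' closeness kernel a' = 10, b' = 0.25.
#'
#' @param setting prediction setting: `"pair"` (random pair folds),
#'   `"drug"` (folds partition drugs, so every test drug is unseen in
#'   training) or `"disease"` (symmetric over diseases).
#' @param mode `"full"` (warm start from genomic features, then SGD),
#'   `"FV"` (score directly by feature-vector dot products, no training)
#'   or `"MF"` (random initialization, then SGD; genomic space ignored).
#' @param n_folds number of folds (>= 2).
#' @param n_repeats number of independent repeats.
#' @param neg_ratio sampled negatives per positive (> 0).
#' @param k,lambda,eta model hyperparameters.
#' @param a_prime,b_prime closeness kernel parameters.
#' @param max_epochs,tol training schedule passed to [mf_train()].
#' @param init_scale half-width for random initialization / missing rows.
#' @param seed base seed; repeat r derives its own seed from it.
#' @return a list of class `cv_config`.
#' @export
cv_config <- function(setting = c("pair", "drug", "disease"),
                      mode = c("full", "FV", "MF"),
                      n_folds = 10L, n_repeats = 5L, neg_ratio = 2,
                      k = 32L, lambda = 2^-7, eta = 2^-4,
                      a_prime = 10, b_prime = 0.25,
                      max_epochs = 100L, tol = 1e-5,
                      init_scale = 0.1, seed = 1L) {
  setting <- match.arg(setting)
  mode <- match.arg(mode)
  n_folds <- check_count(n_folds, "n_folds", min = 2L)
  n_repeats <- check_count(n_repeats, "n_repeats")
  check_scalar(neg_ratio, "neg_ratio", positive = TRUE)
  structure(
    list(setting = setting, mode = mode, n_folds = n_folds,
         n_repeats = n_repeats, neg_ratio = neg_ratio,
         k = check_count(k, "k"), lambda = lambda, eta = eta,
         a_prime = a_prime, b_prime = b_prime,
         max_epochs = check_count(max_epochs, "max_epochs"), tol = tol,
         init_scale = init_scale, seed = as.integer(seed)),
    class = "cv_config"
  )
}

#' Sample negative drug-disease pairs
#'
#' Draws `round(ratio * nrow(positives))` distinct pairs uniformly without
#' replacement from the pairs of the drug x disease grid that are not in
#' the positive set, labeled 0.
#'
#' @param positives a [labeled_pairs()] data frame of positives (label 1).
#' @param n_drugs,n_diseases grid dimensions.
#' @param ratio negatives per positive.
#' @param seed integer seed; deterministic given the seed.
#' @return a [labeled_pairs()] data frame of negatives (label 0).
#' @export
sample_negatives <- function(positives, n_drugs, n_diseases, ratio = 2,
                             seed = 1L) {
  n_drugs <- check_count(n_drugs, "n_drugs")
  n_diseases <- check_count(n_diseases, "n_diseases")
  check_scalar(ratio, "ratio", positive = TRUE)
  n_pos <- nrow(positives)
  n_neg <- round(ratio * n_pos)
  pos_code <- (positives$drug - 1L) * n_diseases + positives$disease
  grid_size <- n_drugs * n_diseases
  n_free <- grid_size - length(unique(pos_code))
  if (n_neg > n_free) {
    stop(sprintf(
      "cannot sample %d negatives: only %d non-positive pairs exist",
      n_neg, n_free), call. = FALSE)
  }
  candidates <- setdiff(seq_len(grid_size), pos_code)
  chosen <- withr::with_seed(seed, sample(candidates, n_neg))
  labeled_pairs(drug = (chosen - 1L) %/% n_diseases + 1L,
                disease = (chosen - 1L) %% n_diseases + 1L,
                label = rep(0, n_neg))
}

#' Split labeled pairs into cross-validation folds
#'
#' Pair setting: the samples themselves are partitioned into `n_folds`
#' near-equal subsets.  Drug setting: the distinct drugs are partitioned,
#' and each fold's test set consists of every sample touching that fold's
#' drugs, so test drugs never occur in training.  Disease setting is
#' symmetric over diseases.  Folds are disjoint and cover all samples.
#'
#' @param samples a [labeled_pairs()] data frame.
#' @param setting `"pair"`, `"drug"` or `"disease"`.
#' @param n_folds number of folds.
#' @param seed integer seed for the random partition.
#' @return list of `n_folds` elements, each `list(train =, test =)`.
#' @export
split_folds <- function(samples, setting = c("pair", "drug", "disease"),
                        n_folds = 10L, seed = 1L) {
  setting <- match.arg(setting)
  n_folds <- check_count(n_folds, "n_folds", min = 2L)
  n <- nrow(samples)
  assign_folds <- function(m) {
    # random permutation, then round-robin: sizes differ by at most one
    withr::with_seed(seed, {
      fold <- integer(m)
      fold[sample.int(m)] <- rep_len(seq_len(n_folds), m)
      fold
    })
  }
  if (setting == "pair") {
    if (n < n_folds) {
      stop(sprintf("fewer samples (%d) than folds (%d)", n, n_folds),
           call. = FALSE)
    }
    fold_of <- assign_folds(n)
  } else {
    col <- if (setting == "drug") samples$drug else samples$disease
    entities <- sort(unique(col))
    if (length(entities) < n_folds) {
      stop(sprintf("fewer distinct %ss (%d) than folds (%d)",
                   setting, length(entities), n_folds), call. = FALSE)
    }
    entity_fold <- assign_folds(length(entities))
    fold_of <- entity_fold[match(col, entities)]
  }
  lapply(seq_len(n_folds), function(f) {
    list(train = samples[fold_of != f, , drop = FALSE],
         test = samples[fold_of == f, , drop = FALSE])
  })
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the fraction of
#' (positive, negative) score pairs in which the positive is ranked above
#' the negative, with ties counted one half (mid-ranks).
#'
#' @param labels binary 0/1 vector; both classes must be present.
#' @param scores numeric scores, higher = more likely positive.
#' @return a number in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.numeric(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC requires at least one positive and one negative label",
         call. = FALSE)
  }
  r <- rank(scores)  # mid-ranks handle ties as 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated cross-validation of the association model
#'
#' Builds the genomic feature spaces once (they depend only on the gene
#' network and the bipartite maps, never on the association labels, so
#' computing them outside the folds leaks nothing).  Then, per repeat:
#' samples fresh negatives, splits positives+negatives into folds, and per
#' fold fits the model on the training pairs according to `config$mode`
#' and scores the test pairs.
#'
#' Modes: `full` warm-starts A and B from the aggregated feature vectors
#' and trains; `MF` initializes A and B randomly and trains; `FV` uses the
#' warm-start vectors as-is and skips training (scores are the sigmoid of
#' the dot products — a monotone transform, so the AUC equals that of the
#' raw dot products).
#'
#' @param network a [gene_network].
#' @param drug_genes,disease_genes [bipartite_interactions] maps.
#' @param positives data frame of known associations with columns `drug`,
#'   `disease` holding entity IDs (matching the bipartite `row_ids`).
#' @param config a [cv_config()].
#' @return object of class `cv_result`: data frame `folds` (repeat, fold,
#'   auc), `mean_auc`, per-repeat means `repeat_means`, and the config.
#' @export
cross_validate <- function(network, drug_genes, disease_genes, positives,
                           config = cv_config()) {
  stopifnot(inherits(config, "cv_config"))
  spaces <- build_feature_spaces(network, drug_genes, disease_genes, config)
  drug_space <- spaces$drug_space
  disease_space <- spaces$disease_space
  pos <- positives_to_indices(positives, drug_genes$row_ids,
                              disease_genes$row_ids)
  nu <- length(drug_genes$row_ids)
  ns <- length(disease_genes$row_ids)

  rows <- vector("list", config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    rseed <- derive_seed(config$seed, r)
    negs <- sample_negatives(pos, nu, ns, config$neg_ratio, seed = rseed)
    samples <- rbind(pos, negs)
    folds <- split_folds(samples, config$setting, config$n_folds,
                         seed = derive_seed(rseed, 1L))
    aucs <- vapply(seq_along(folds), function(f) {
      fit <- fit_fold(drug_space, disease_space, folds[[f]]$train, config,
                      seed = derive_seed(rseed, 1L + f))
      test <- folds[[f]]$test
      roc_auc(test$label, predict(fit, test$drug, test$disease))
    }, numeric(1L))
    rows[[r]] <- data.frame(rep = r, fold = seq_along(folds), auc = aucs)
  }
  folds_df <- do.call(rbind, rows)
  structure(
    list(folds = folds_df,
         mean_auc = mean(folds_df$auc),
         repeat_means = tapply(folds_df$auc, folds_df$rep, mean),
         config = config),
    class = "cv_result"
  )
}

# fit one fold's model according to the evaluation mode
fit_fold <- function(drug_space, disease_space, train, config, seed) {
  model <- switch(config$mode,
    full = ,
    FV = init_model(drug_space, disease_space, config$lambda, config$eta),
    MF = init_model_random(drug_space$ids, disease_space$ids, config$k,
                           config$lambda, config$eta,
                           scale = config$init_scale, seed = seed)
  )
  if (config$mode == "FV") return(model)
  mf_train(model, train, max_epochs = config$max_epochs, tol = config$tol,
           seed = derive_seed(seed, 1L))$model
}

#' Build gene, drug and disease feature spaces from a dataset
#'
#' The genes of interest are those appearing in any drug-gene or
#' disease-gene interaction; shortest-path distances for them are computed
#' on the full network, turned into the closeness matrix, and
#' eigendecomposed at rank `config$k`.  Drug and disease vectors are the
#' means over interacting genes, with seeded random fill for entities
#' lacking interactors.
#'
#' @inheritParams cross_validate
#' @return list with `gene_space`, `drug_space`, `disease_space`.
#' @export
build_feature_spaces <- function(network, drug_genes, disease_genes,
                                 config = cv_config()) {
  genes <- sort(unique(c(drug_genes$pairs$gene, disease_genes$pairs$gene)))
  d <- shortest_path_distances(network, genes)
  relation <- gene_closeness(d, config$a_prime, config$b_prime)
  gene_space <- eigendecompose(relation, config$k)
  drug_space <- init_missing(aggregate_features(drug_genes, gene_space),
                             scale = config$init_scale,
                             seed = derive_seed(config$seed, 999L))
  disease_space <- init_missing(aggregate_features(disease_genes, gene_space),
                                scale = config$init_scale,
                                seed = derive_seed(config$seed, 998L))
  list(gene_space = gene_space, drug_space = drug_space,
       disease_space = disease_space)
}

#' Map ID-based associations to indexed labeled pairs
#'
#' Converts an association table of drug/disease IDs into the integer
#' index form used by the model, labeling every pair 1.
#'
#' @param positives data frame with `drug` and `disease` ID columns.
#' @param drug_ids,disease_ids ordered entity ID vectors defining the
#'   index space.
#' @return a [labeled_pairs()] data frame with label 1.
#' @export
positives_to_indices <- function(positives, drug_ids, disease_ids) {
  stopifnot(all(c("drug", "disease") %in% names(positives)))
  di <- match(as.character(positives$drug), drug_ids)
  si <- match(as.character(positives$disease), disease_ids)
  if (anyNA(di)) {
    stop(sprintf("association drug ID(s) not in the drug list: %s",
                 paste(utils::head(unique(positives$drug[is.na(di)]), 5L),
                       collapse = ", ")), call. = FALSE)
  }
  if (anyNA(si)) {
    stop(sprintf("association disease ID(s) not in the disease list: %s",
                 paste(utils::head(unique(positives$disease[is.na(si)]), 5L),
                       collapse = ", ")), call. = FALSE)
  }
  labeled_pairs(di, si, rep(1, length(di)))
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "cv_result: %s setting, %s mode | %d repeats x %d folds\n",
    x$config$setting, x$config$mode, x$config$n_repeats, x$config$n_folds))
  cat(sprintf("  mean AUC = %.4f (repeat means: %s)\n", x$mean_auc,
              paste(sprintf("%.4f", x$repeat_means), collapse = ", ")))
  invisible(x)
}
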