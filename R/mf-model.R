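#' Initialize a matrix-factorization model from feature spaces
#'
#' Warm start: the drug factor matrix A copies the drug feature vectors
#' row by row, and the disease factor matrix B copies the disease feature
#' vectors, so the genomic space sets the starting point of the
#' optimization.
#'
#' @param drug_space,disease_space complete `feature_space` objects (no
#'   undefined rows) sharing the same dimension k.
#' @param lambda_reg non-negative L2 regularization coefficient; default
#'   2^-7.
#' @param eta positive SGD learning rate; default 2^-4.
#' @return an object of class `mf_model`: `drug_ids`, `disease_ids`,
#'   factor matrices `A` (drugs x k) and `B` (diseases x k), `k`,
#'   `lambda_reg`, `eta`.
#' @export
init_model <- function(drug_space, disease_space, lambda_reg = 2^-7,
                       eta = 2^-4) {
  stopifnot(inherits(drug_space, "feature_space"),
            inherits(disease_space, "feature_space"))
  ku <- ncol(drug_space$P)
  ks <- ncol(disease_space$P)
  if (ku != ks) {
    stop(sprintf("feature dimension mismatch: drugs have k = %d, diseases k = %d",
                 ku, ks), call. = FALSE)
  }
  if (anyNA(drug_space$P) || anyNA(disease_space$P)) {
    stop("feature spaces contain undefined rows; run init_missing() first",
         call. = FALSE)
  }
  check_scalar(lambda_reg, "lambda_reg", non_negative = TRUE)
  check_scalar(eta, "eta", positive = TRUE)
  new_mf_model(drug_space$ids, disease_space$ids,
               drug_space$P, disease_space$P, lambda_reg, eta)
}

#' Randomly initialized model (genomic space ignored)
#'
#' Ablation counterpart of [init_model()]: both factor matrices are drawn
#' i.i.d. uniform on `[-scale, scale]`, discarding the network-derived
#' features, so training starts from an uninformative point.
#'
#' @param drug_ids,disease_ids ordered entity IDs.
#' @param k feature dimension.
#' @param lambda_reg,eta as in [init_model()].
#' @param scale half-width of the uniform initialization (default 0.1).
#' @param seed integer seed; deterministic given the seed.
#' @return an `mf_model`.
#' @export
init_model_random <- function(drug_ids, disease_ids, k, lambda_reg = 2^-7,
                              eta = 2^-4, scale = 0.1, seed = 1L) {
  k <- check_count(k, "k")
  check_scalar(scale, "scale", positive = TRUE)
  check_scalar(lambda_reg, "lambda_reg", non_negative = TRUE)
  check_scalar(eta, "eta", positive = TRUE)
  nu <- length(drug_ids)
  ns <- length(disease_ids)
  withr::with_seed(seed, {
    A <- matrix(stats::runif(nu * k, -scale, scale), nrow = nu)
    B <- matrix(stats::runif(ns * k, -scale, scale), nrow = ns)
  })
  new_mf_model(as.character(drug_ids), as.character(disease_ids),
               A, B, lambda_reg, eta)
}

new_mf_model <- function(drug_ids, disease_ids, A, B, lambda_reg, eta) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  dimnames(A) <- list(drug_ids, paste0("f", seq_len(ncol(A))))
  dimnames(B) <- list(disease_ids, paste0("f", seq_len(ncol(B))))
  if (!all(is.finite(A)) || !all(is.finite(B))) {
    stop("factor matrices must be finite", call. = FALSE)
  }
  structure(
    list(drug_ids = drug_ids, disease_ids = disease_ids, A = A, B = B,
         k = ncol(A), lambda_reg = lambda_reg, eta = eta),
    class = "mf_model"
  )
}

#' @export
print.mf_model <- function(x, ...) {
  cat(sprintf("mf_model: %d drugs x %d diseases, k = %d (lambda = %g, eta = %g)\n",
              nrow(x$A), nrow(x$B), x$k, x$lambda_reg, x$eta))
  invisible(x)
}

#' Labeled drug-disease pair set
#'
#' @param drug,disease integer indices into the model's drug and disease
#'   lists (1-based).
#' @param label 0/1 association labels.
#' @return a `data.frame` with columns `drug`, `disease`, `label`;
#'   duplicate (drug, disease) pairs are an error.
#' @export
labeled_pairs <- function(drug, disease, label) {
  drug <- as.integer(drug)
  disease <- as.integer(disease)
  label <- as.numeric(label)
  stopifnot(length(drug) == length(disease), length(drug) == length(label))
  if (!all(label %in% c(0, 1))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  if (anyDuplicated(cbind(drug, disease)) > 0L) {
    stop("duplicate (drug, disease) pairs are not allowed", call. = FALSE)
  }
  data.frame(drug = drug, disease = disease, label = label)
}

check_pairs <- function(model, samples) {
  stopifnot(is.data.frame(samples),
            all(c("drug", "disease", "label") %in% names(samples)))
  if (nrow(samples) > 0L &&
      (min(samples$drug) < 1L || max(samples$drug) > nrow(model$A) ||
       min(samples$disease) < 1L || max(samples$disease) > nrow(model$B))) {
    stop("sample indices out of model range", call. = FALSE)
  }
  invisible(samples)
}

#' Predict association scores for drug-disease pairs
#'
#' The score is the logistic function of the dot product of the drug and
#' disease factor rows, strictly inside (0, 1).
#'
#' @param object an `mf_model`.
#' @param drug,disease equal-length integer index vectors (1-based).
#' @param ... unused.
#' @return numeric vector of scores in (0, 1).
#' @export
predict.mf_model <- function(object, drug, disease, ...) {
  drug <- as.integer(drug)
  disease <- as.integer(disease)
  stopifnot(length(drug) == length(disease))
  if (length(drug) == 0L) return(numeric(0L))
  if (min(drug) < 1L || max(drug) > nrow(object$A) ||
      min(disease) < 1L || max(disease) > nrow(object$B)) {
    stop("drug or disease index out of range", call. = FALSE)
  }
  dots <- rowSums(object$A[drug, , drop = FALSE] *
                  object$B[disease, , drop = FALSE])
  unname(sigmoid(dots))
}

#' Full drug x disease score matrix
#'
#' @param model an `mf_model`.
#' @return numeric matrix (drugs x diseases) of sigmoid scores, with ID
#'   dimnames.
#' @export
score_grid <- function(model) {
  stopifnot(inherits(model, "mf_model"))
  S <- sigmoid(model$A %*% t(model$B))
  dimnames(S) <- list(model$drug_ids, model$disease_ids)
  S
}

#' Regularized squared-error objective
#'
#' Evaluates (1/2) * sum over samples of
#' `(y - F)^2 + lambda * (||a_i||^2 + ||b_j||^2)`.
#' The regularization terms accrue once per sample, exactly as the SGD
#' update applies decay at every sample visit, so rows that appear in many
#' pairs contribute (and decay) more.
#'
#' @param model an `mf_model`.
#' @param samples a [labeled_pairs()] data frame.
#' @return single non-negative number.
#' @export
mf_loss <- function(model, samples) {
  check_pairs(model, samples)
  if (nrow(samples) == 0L) return(0)
  f <- predict(model, samples$drug, samples$disease)
  reg <- rowSums(model$A[samples$drug, , drop = FALSE]^2) +
    rowSums(model$B[samples$disease, , drop = FALSE]^2)
  0.5 * sum((samples$label - f)^2 + model$lambda_reg * reg)
}

#' One epoch of stochastic gradient descent
#'
#' Visits every sample once in a seeded shuffled order.  For sample
#' (i, j): `F = sigmoid(a_i . b_j)`, `e = y - F`, and both rows are
#' updated simultaneously (b_j's rule uses the pre-update a_i):
#' `a_i <- a_i + eta * (e * F * (1 - F) * b_j - lambda * a_i)` and
#' symmetrically for `b_j`.
#'
#' @param model an `mf_model`.
#' @param samples a [labeled_pairs()] data frame.
#' @param seed integer seed for the visiting order.
#' @return the updated `mf_model`.
#' @export
sgd_epoch <- function(model, samples, seed = 1L) {
  fit <- mf_train(model, samples, max_epochs = 1L, tol = 0, seed = seed)
  fit$model
}

#' Train the factorization model by SGD
#'
#' Runs SGD epochs (each a seeded shuffle of the samples) until the
#' relative change of the objective between consecutive epochs falls below
#' `tol`, or `max_epochs` is reached.  The per-epoch objective values are
#' returned for auditing convergence.
#'
#' @param model an `mf_model` (warm-started or random).
#' @param samples a [labeled_pairs()] data frame; an empty set returns the
#'   model unchanged.
#' @param max_epochs maximum number of passes over the samples.
#' @param tol relative-change convergence threshold (>= 0).
#' @param seed integer seed controlling the per-epoch shuffles.
#' @return list with `model` (trained `mf_model`), `trace` (objective
#'   after each epoch run) and `epochs` (number of epochs run).
#' @export
mf_train <- function(model, samples, max_epochs = 500L, tol = 1e-5,
                     seed = 1L) {
  stopifnot(inherits(model, "mf_model"))
  check_pairs(model, samples)
  max_epochs <- check_count(max_epochs, "max_epochs")
  check_scalar(tol, "tol", non_negative = TRUE)
  n <- nrow(samples)
  if (n == 0L) {
    return(list(model = model, trace = numeric(0L), epochs = 0L))
  }
  orders <- withr::with_seed(seed, {
    vapply(seq_len(max_epochs), function(e) sample.int(n), integer(n))
  })
  orders <- matrix(orders, nrow = n)  # n x max_epochs, keep shape when n = 1
  res <- mf_sgd_core(model$A, model$B,
                     as.integer(samples$drug) - 1L,
                     as.integer(samples$disease) - 1L,
                     as.numeric(samples$label),
                     orders - 1L, model$eta, model$lambda_reg,
                     tol, max_epochs)
  if (!is.null(res$diverged)) {
    stop(sprintf("training diverged (non-finite objective) at epoch %d",
                 res$diverged), call. = FALSE)
  }
  trained <- new_mf_model(model$drug_ids, model$disease_ids, res$A, res$B,
                          model$lambda_reg, model$eta)
  list(model = trained, trace = as.numeric(res$trace),
       epochs = length(res$trace))
}
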