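# Independent brute-force reference implementations used as oracles.
# Deliberately naive (loops, queues) and kept free of any package internals.

# all-pairs hop distances by exhaustive breadth-first search
bfs_all_pairs <- function(edges, nodes) {
  adj <- lapply(stats::setNames(nm = nodes), function(x) character(0L))
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1L]
    b <- edges[r, 2L]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  for (s in nodes) {
    dist <- stats::setNames(rep(Inf, n), nodes)
    dist[s] <- 0
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1L]
      queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
      }
    }
    d[s, ] <- dist
  }
  d
}

# Mann-Whitney AUC by exhaustive pair counting, ties = 1/2
brute_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (if (p > q) 1 else if (p == q) 0.5 else 0)
    }
  }
  total / (length(pos) * length(neg))
}

# per-entity mean of interactor gene vectors by a double loop
naive_aggregate <- function(entity_ids, pairs, gene_P) {
  k <- ncol(gene_P)
  out <- matrix(NA_real_, length(entity_ids), k)
  for (i in seq_along(entity_ids)) {
    genes <- unique(pairs$gene[pairs$entity == entity_ids[i]])
    if (length(genes) == 0L) next
    acc <- numeric(k)
    for (g in genes) acc <- acc + gene_P[g, ]
    out[i, ] <- acc / length(genes)
  }
  out
}

# objective of Eq.-style regularized squared error, one sample at a time
naive_loss <- function(A, B, samples, lambda) {
  total <- 0
  for (s in seq_len(nrow(samples))) {
    i <- samples$drug[s]
    j <- samples$disease[s]
    f <- 1 / (1 + exp(-sum(A[i, ] * B[j, ])))
    total <- total + (samples$label[s] - f)^2 +
      lambda * (sum(A[i, ]^2) + sum(B[j, ]^2))
  }
  0.5 * total
}

# one SGD epoch in plain R, given an explicit visiting order
naive_sgd_epoch <- function(A, B, samples, ord, eta, lambda) {
  for (s in ord) {
    i <- samples$drug[s]
    j <- samples$disease[s]
    dot <- sum(A[i, ] * B[j, ])
    dot <- min(max(dot, -30), 30)
    f <- 1 / (1 + exp(-dot))
    g <- (samples$label[s] - f) * f * (1 - f)
    ai <- A[i, ]
    bj <- B[j, ]
    A[i, ] <- ai + eta * (g * bj - lambda * ai)
    B[j, ] <- bj + eta * (g * ai - lambda * bj)
  }
  list(A = A, B = B)
}

# small random symmetric positive-definite matrix wrapped as a relation
random_psd_relation <- function(n, seed) {
  X <- withr::with_seed(seed, matrix(stats::rnorm(n * n), n))
  C <- X %*% t(X) + diag(n) * 0.5
  ids <- sprintf("g%02d", seq_len(n))
  dimnames(C) <- list(ids, ids)
  structure(list(gene_ids = ids, C = C, a_prime = 10, b_prime = 0.25),
            class = "gene_relation")
}

# small random model + labeled samples for gradient/loss checks
random_model_and_samples <- function(n_u, n_s, k, n_samples, seed,
                                     lambda = 2^-7, eta = 2^-4) {
  withr::with_seed(seed, {
    A <- matrix(stats::rnorm(n_u * k, sd = 0.6), n_u)
    B <- matrix(stats::rnorm(n_s * k, sd = 0.6), n_s)
    grid <- expand.grid(drug = seq_len(n_u), disease = seq_len(n_s))
    pick <- sample(nrow(grid), n_samples)
    samples <- labeled_pairs(grid$drug[pick], grid$disease[pick],
                             stats::rbinom(n_samples, 1L, 0.5))
    drug_space <- feature_space(sprintf("D%02d", seq_len(n_u)), A)
    disease_space <- feature_space(sprintf("S%02d", seq_len(n_s)), B)
    list(model = init_model(drug_space, disease_space, lambda, eta),
         samples = samples)
  })
}

# tiny deterministic synthetic dataset for fast end-to-end tests
small_dataset <- function(seed = 3L, n_genes = 150L, n_drugs = 25L,
                          n_diseases = 12L, n_positives = 40L,
                          signal_strength = 0.9) {
  simulate_dataset(synth_config(
    n_genes = n_genes, n_drugs = n_drugs, n_diseases = n_diseases,
    n_positives = n_positives, signal_strength = signal_strength,
    seed = seed))
}
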