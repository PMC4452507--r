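#' Gene closeness matrix from shortest-path distances
#'
#' Transforms hop distances into a gene relation matrix through the
#' exponential closeness kernel c = a' * exp(-b' * d).  The diagonal
#' (distance zero) equals `a_prime` exactly, and unreachable pairs
#' (infinite distance) map to closeness zero, the limit of the kernel as
#' the distance grows, which keeps the matrix finite.
#'
#' The defaults a' = 10 and b' = 0.25 spread the closeness values fairly
#' evenly over the hop distances typically observed in protein-interaction
#' networks; the kernel is a monotone transform, so the precise values are
#' not critical.
#'
#' @param distances symmetric numeric matrix of hop counts with zero
#'   diagonal, as produced by [shortest_path_distances()].
#' @param a_prime positive kernel scale (closeness of a gene to itself).
#' @param b_prime positive kernel decay rate per hop.
#' @return an object of class `gene_relation`: list with `gene_ids`, the
#'   symmetric closeness matrix `C`, and the kernel parameters.
#' @export
gene_closeness <- function(distances, a_prime = 10, b_prime = 0.25) {
  check_scalar(a_prime, "a_prime", positive = TRUE)
  check_scalar(b_prime, "b_prime", positive = TRUE)
  distances <- as.matrix(distances)
  if (nrow(distances) != ncol(distances)) {
    stop("`distances` must be square", call. = FALSE)
  }
  if (any(diag(distances) != 0)) {
    stop("`distances` must have a zero diagonal", call. = FALSE)
  }
  finite <- distances[is.finite(distances)]
  if (any(finite < 0) || !isSymmetric(unname(distances))) {
    stop("`distances` must be symmetric and non-negative", call. = FALSE)
  }
  C <- a_prime * exp(-b_prime * distances)  # exp(-b' * Inf) = 0: unreachable -> 0
  structure(
    list(
      gene_ids = rownames(distances),
      C = C,
      a_prime = a_prime,
      b_prime = b_prime
    ),
    class = "gene_relation"
  )
}

#' @export
print.gene_relation <- function(x, ...) {
  cat(sprintf("gene_relation: %d x %d closeness matrix (a' = %g, b' = %g)\n",
              nrow(x$C), ncol(x$C), x$a_prime, x$b_prime))
  invisible(x)
}

#' Rank-k gene feature vectors by eigendecomposition
#'
#' Decomposes the gene relation matrix C into its eigenvalues (descending)
#' and eigenvectors, keeps the top k, and forms the feature matrix
#' P = Gamma * Lambda^(1/2) whose rows are the gene feature vectors, so
#' that P %*% t(P) reconstructs the projection of C onto its top-k
#' eigenspace.
#'
#' The closeness kernel is not guaranteed positive semidefinite, and the
#' square root of Lambda is undefined for negative eigenvalues, so the top
#' k eigenvalues are required to be strictly positive; otherwise an error
#' reports how many positive eigenvalues are available.  Eigenvectors are
#' sign-ambiguous; for reproducibility each is oriented so that its
#' largest-magnitude component is positive.  Downstream scores depend on P
#' only through dot products of its rows, which are invariant to this
#' orientation.
#'
#' @param relation a [gene_closeness()] result (or any object with a
#'   symmetric numeric matrix in `$C` and IDs in `$gene_ids`).
#' @param k number of feature dimensions to retain, `1 <= k <= nrow(C)`.
#' @return a `feature_space`: list with `ids`, the `N x k` matrix `P`
#'   (rows = feature vectors), and `eigenvalues` (length k, descending).
#' @export
eigendecompose <- function(relation, k) {
  C <- relation$C
  ids <- relation$gene_ids
  n <- nrow(C)
  k <- check_count(k, "k")
  if (k > n) {
    stop(sprintf("k = %d exceeds matrix size %d", k, n), call. = FALSE)
  }
  e <- eigen(C, symmetric = TRUE)          # eigenvalues already descending
  tol <- max(abs(e$values)) * 1e-12
  n_pos <- sum(e$values > tol)
  if (n_pos < k) {
    stop(sprintf(
      "only %d strictly positive eigenvalue(s) available but k = %d requested",
      n_pos, k), call. = FALSE)
  }
  values <- e$values[seq_len(k)]
  vectors <- e$vectors[, seq_len(k), drop = FALSE]
  # orient each eigenvector so its largest-magnitude entry is positive
  for (j in seq_len(k)) {
    v <- vectors[, j]
    s <- sign(v[which.max(abs(v))])
    if (s < 0) vectors[, j] <- -v
  }
  P <- vectors %*% diag(sqrt(values), nrow = k)
  feature_space(ids, P, eigenvalues = values)
}

#' Feature space container
#'
#' Holds one k-dimensional feature vector per entity (gene, drug, or
#' disease) as the rows of a matrix.  Rows that are entirely `NA` mark
#' entities whose vector is not yet defined (no interacting genes); see
#' [init_missing()].
#'
#' @param ids ordered character vector of entity IDs.
#' @param P numeric matrix with `length(ids)` rows.
#' @param eigenvalues optional descending eigenvalues retained when the
#'   space was built by [eigendecompose()]; `NULL` for aggregated spaces.
#' @return an object of class `feature_space`.
#' @export
feature_space <- function(ids, P, eigenvalues = NULL) {
  ids <- as.character(ids)
  P <- as.matrix(P)
  if (nrow(P) != length(ids)) {
    stop("row count of `P` must equal the number of IDs", call. = FALSE)
  }
  rownames(P) <- ids
  colnames(P) <- paste0("f", seq_len(ncol(P)))
  structure(
    list(ids = ids, P = P, eigenvalues = eigenvalues),
    class = "feature_space"
  )
}

#' @export
print.feature_space <- function(x, ...) {
  n_na <- sum(!stats::complete.cases(x$P))
  cat(sprintf("feature_space: %d entities x %d dimensions%s%s\n",
              nrow(x$P), ncol(x$P),
              if (!is.null(x$eigenvalues)) " (spectral)" else "",
              if (n_na > 0) sprintf(", %d undefined row(s)", n_na) else ""))
  invisible(x)
}
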