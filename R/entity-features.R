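#' Bipartite entity-gene interactions
#'
#' Binary interaction sets between entities (drugs or diseases) and genes.
#' Pairs have set semantics: duplicates are collapsed, absence means 0.
#'
#' @param pairs two-column `data.frame` (entity ID, gene ID), one
#'   interaction per row.
#' @param row_ids ordered entity IDs; defaults to the sorted unique
#'   entities in `pairs`.  Entities listed here but absent from `pairs`
#'   have no interactors.
#' @param col_ids ordered gene IDs; defaults to the sorted unique genes in
#'   `pairs`.
#' @return an object of class `bipartite_interactions` with elements
#'   `row_ids`, `col_ids` and `pairs` (deduplicated two-column
#'   data.frame).
#' @export
bipartite_interactions <- function(pairs, row_ids = NULL, col_ids = NULL) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2L) {
    stop("`pairs` must have two columns (entity ID, gene ID)", call. = FALSE)
  }
  pairs <- data.frame(
    entity = as.character(pairs[[1L]]),
    gene = as.character(pairs[[2L]]),
    stringsAsFactors = FALSE
  )
  pairs <- unique(pairs)
  if (is.null(row_ids)) row_ids <- sort(unique(pairs$entity))
  if (is.null(col_ids)) col_ids <- sort(unique(pairs$gene))
  row_ids <- as.character(row_ids)
  col_ids <- as.character(col_ids)
  bad_e <- setdiff(pairs$entity, row_ids)
  if (length(bad_e) > 0L) {
    stop(sprintf("interaction references undeclared entity ID(s): %s",
                 paste(utils::head(bad_e, 5L), collapse = ", ")),
         call. = FALSE)
  }
  bad_g <- setdiff(pairs$gene, col_ids)
  if (length(bad_g) > 0L) {
    stop(sprintf("interaction references undeclared gene ID(s): %s",
                 paste(utils::head(bad_g, 5L), collapse = ", ")),
         call. = FALSE)
  }
  structure(
    list(row_ids = row_ids, col_ids = col_ids, pairs = pairs),
    class = "bipartite_interactions"
  )
}

#' @export
print.bipartite_interactions <- function(x, ...) {
  cat(sprintf("bipartite_interactions: %d entities x %d genes, %d pairs\n",
              length(x$row_ids), length(x$col_ids), nrow(x$pairs)))
  invisible(x)
}

#' List interacting genes per entity
#'
#' @param interactions a [bipartite_interactions] object.
#' @return named list (one element per `row_ids` entry, in order) of
#'   character vectors of gene IDs.
#' @export
interactors <- function(interactions) {
  stopifnot(inherits(interactions, "bipartite_interactions"))
  out <- split(interactions$pairs$gene, factor(interactions$pairs$entity,
                                               levels = interactions$row_ids))
  out[lengths(out) == 0L] <- list(character(0L))
  out
}

#' Aggregate gene features into entity features
#'
#' Each entity's feature vector is the arithmetic mean of the feature
#' vectors of its distinct interacting genes.  Entities with no
#' interactors receive an all-`NA` row, to be filled by [init_missing()].
#'
#' @param interactions a [bipartite_interactions] (drug-gene or
#'   disease-gene).
#' @param gene_space a `feature_space` over genes; must contain every gene
#'   that appears in an interaction pair.
#' @return a `feature_space` whose rows follow `interactions$row_ids`
#'   (no eigenvalues: the rows are averages, not spectral vectors).
#' @export
aggregate_features <- function(interactions, gene_space) {
  stopifnot(inherits(interactions, "bipartite_interactions"),
            inherits(gene_space, "feature_space"))
  used_genes <- unique(interactions$pairs$gene)
  missing <- setdiff(used_genes, gene_space$ids)
  if (length(missing) > 0L) {
    stop(sprintf("gene(s) with interactions missing from the feature space: %s",
                 paste(utils::head(missing, 5L), collapse = ", ")),
         call. = FALSE)
  }
  k <- ncol(gene_space$P)
  by_entity <- interactors(interactions)
  P <- matrix(NA_real_, nrow = length(interactions$row_ids), ncol = k)
  for (i in seq_along(by_entity)) {
    genes <- by_entity[[i]]
    if (length(genes) > 0L) {
      P[i, ] <- colMeans(gene_space$P[genes, , drop = FALSE])
    }
  }
  feature_space(interactions$row_ids, P)
}

#' Fill undefined feature rows with small random vectors
#'
#' Entities without interacting genes carry no genomic information; their
#' rows are initialized i.i.d. uniform on `[-scale, scale]`.  The small
#' symmetric default keeps initial sigmoid outputs near 0.5.  Defined rows
#' are returned untouched, and a space with no undefined rows is returned
#' unchanged.
#'
#' @param space a `feature_space` possibly containing all-`NA` rows.
#' @param scale half-width of the uniform distribution (default 0.1).
#' @param seed integer seed; the fill is deterministic given the seed.
#' @return the completed `feature_space`.
#' @export
init_missing <- function(space, scale = 0.1, seed = 1L) {
  stopifnot(inherits(space, "feature_space"))
  check_scalar(scale, "scale", positive = TRUE)
  undef <- !stats::complete.cases(space$P)
  if (!any(undef)) return(space)
  k <- ncol(space$P)
  P <- space$P
  withr::with_seed(seed, {
    P[undef, ] <- matrix(stats::runif(sum(undef) * k, -scale, scale),
                         ncol = k)
  })
  feature_space(space$ids, P, eigenvalues = space$eigenvalues)
}
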