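#' Construct a gene interaction network
#'
#' Builds an undirected, unweighted gene network from an edge list of gene
#' identifier pairs.  Gene identifiers are opaque strings; no external
#' database validation is performed.  Self-loops and duplicate edges
#' (in either orientation) are removed, so every unordered pair is stored
#' once.
#'
#' @param edges a two-column `data.frame` or character matrix; each row is
#'   one undirected interaction between two gene IDs.
#' @param nodes optional character vector of additional isolated gene IDs
#'   to include as nodes.
#' @return an object of class `gene_network` with elements `graph` (an
#'   [igraph][igraph::graph_from_data_frame] graph) and `nodes` (character
#'   vector of gene IDs).
#' @export
#' @examples
#' net <- gene_network(data.frame(a = c("g1", "g2"), b = c("g2", "g3")))
#' network_nodes(net)
gene_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) {
    stop("`edges` must have two columns (gene ID pairs)", call. = FALSE)
  }
  edges <- data.frame(
    from = as.character(edges[[1L]]),
    to = as.character(edges[[2L]]),
    stringsAsFactors = FALSE
  )
  all_nodes <- unique(c(edges$from, edges$to, as.character(nodes)))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = all_nodes)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  structure(
    list(graph = g, nodes = igraph::V(g)$name),
    class = "gene_network"
  )
}

#' @rdname gene_network
#' @param network a `gene_network`.
#' @export
network_nodes <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  network$nodes
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d genes, %d interactions\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' All-pairs shortest-path hop distances for a gene subset
#'
#' Computes the minimum number of edges between every pair of genes in
#' `subset`, where paths may traverse any node of the full network (the
#' intermediate genes need not belong to the subset).  Unreachable pairs
#' get `Inf`.
#'
#' @param network a [gene_network].
#' @param subset ordered character vector of gene IDs of interest; every
#'   entry must be a node of `network`.
#' @return a symmetric numeric matrix (`length(subset)` square, dimnames =
#'   `subset`) of hop counts with zero diagonal; `Inf` marks disconnected
#'   pairs.
#' @export
shortest_path_distances <- function(network, subset) {
  stopifnot(inherits(network, "gene_network"))
  subset <- as.character(subset)
  if (length(subset) == 0L) stop("`subset` is empty", call. = FALSE)
  missing <- setdiff(subset, network$nodes)
  if (length(missing) > 0L) {
    stop(sprintf("gene(s) not present in the network: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  d <- igraph::distances(network$graph, v = subset, to = subset,
                         algorithm = "unweighted")
  dimnames(d) <- list(subset, subset)
  d
}
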