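# TSV readers/writers for every artifact the toolkit exchanges.
# All files are UTF-8, tab-separated, with '#' comment lines; IDs are
# opaque strings and never validated against external databases.

read_tsv_pairs <- function(path, n_cols = 2L, header = FALSE, what = "pair") {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (header && length(lines) > 0L) {
    lines <- lines[-1L]
    line_no <- line_no[-1L]
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != n_cols)
  if (length(bad) > 0L) {
    stop(sprintf("malformed %s line %d in %s: expected %d tab-separated fields",
                 what, line_no[bad[1L]], path, n_cols), call. = FALSE)
  }
  if (length(fields) == 0L) {
    return(as.data.frame(matrix(character(0L), ncol = n_cols),
                         stringsAsFactors = FALSE))
  }
  as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
}

#' Read a gene interaction network from a two-column edge TSV
#'
#' @param path TSV file, one undirected edge (two gene IDs) per line;
#'   lines starting with `#` are comments.
#' @param header set `TRUE` if the first non-comment line is a header.
#' @return a [gene_network].
#' @export
read_gene_network <- function(path, header = FALSE) {
  edges <- read_tsv_pairs(path, 2L, header, "network edge")
  if (nrow(edges) == 0L) {
    stop(sprintf("no edges in %s", path), call. = FALSE)
  }
  gene_network(edges)
}

#' Read a bipartite entity-gene interaction TSV
#'
#' @param path two-column TSV (entity ID, gene ID).
#' @param header first non-comment line is a header?
#' @return a [bipartite_interactions].
#' @export
read_bipartite <- function(path, header = FALSE) {
  pairs <- read_tsv_pairs(path, 2L, header, "interaction")
  if (nrow(pairs) == 0L) {
    stop(sprintf("no interactions in %s", path), call. = FALSE)
  }
  bipartite_interactions(pairs)
}

#' Read known drug-disease associations
#'
#' Duplicated associations raise a warning and are deduplicated.
#'
#' @param path two-column TSV (drug ID, disease ID).
#' @param header first non-comment line is a header?
#' @return data frame with columns `drug`, `disease`, `label` (= 1).
#' @export
read_associations <- function(path, header = FALSE) {
  pairs <- read_tsv_pairs(path, 2L, header, "association")
  if (nrow(pairs) == 0L) {
    stop(sprintf("no associations in %s", path), call. = FALSE)
  }
  names(pairs) <- c("drug", "disease")
  dup <- duplicated(pairs)
  if (any(dup)) {
    warning(sprintf("%d duplicate association(s) in %s removed", sum(dup),
                    path), call. = FALSE)
    pairs <- pairs[!dup, , drop = FALSE]
  }
  rownames(pairs) <- NULL
  pairs$label <- 1
  pairs
}

#' Load and filter a complete dataset
#'
#' Reads the network, the two bipartite maps and the association list,
#' then applies the interactor filter.  An entity "has interactors" when
#' at least one of its mapped genes is a node of the network.  In strict
#' mode an association is kept only when both its drug and its disease
#' have interactors; in relaxed mode, when at least one side does.  The
#' bipartite maps are restricted to network genes and to the entities of
#' the kept associations.
#'
#' @param network_path,drug_genes_path,disease_genes_path,associations_path
#'   input TSV paths.
#' @param strict logical: both-sides rule (`TRUE`, default) or
#'   either-side rule (`FALSE`).
#' @param header inputs carry header lines?
#' @return list of class `genomf_dataset` with `network`, `drug_genes`,
#'   `disease_genes`, `positives` and `provenance` (paths and kept/dropped
#'   counts).
#' @export
load_dataset <- function(network_path, drug_genes_path, disease_genes_path,
                         associations_path, strict = TRUE, header = FALSE) {
  network <- read_gene_network(network_path, header)
  drug_genes <- read_bipartite(drug_genes_path, header)
  disease_genes <- read_bipartite(disease_genes_path, header)
  positives <- read_associations(associations_path, header)
  filtered <- filter_dataset(network, drug_genes, disease_genes, positives,
                             strict = strict)
  filtered$provenance$paths <- c(
    network = network_path, drug_genes = drug_genes_path,
    disease_genes = disease_genes_path, associations = associations_path)
  filtered
}

#' Apply the interactor filter to an in-memory dataset
#'
#' @param network a [gene_network].
#' @param drug_genes,disease_genes [bipartite_interactions].
#' @param positives association data frame (`drug`, `disease` columns).
#' @param strict both-sides rule (`TRUE`) or either-side rule (`FALSE`).
#' @return a `genomf_dataset` (see [load_dataset()]).
#' @export
filter_dataset <- function(network, drug_genes, disease_genes, positives,
                           strict = TRUE) {
  nodes <- network$nodes
  has_interactor <- function(map) {
    ok <- map$pairs[map$pairs$gene %in% nodes, , drop = FALSE]
    unique(ok$entity)
  }
  drugs_ok <- has_interactor(drug_genes)
  diseases_ok <- has_interactor(disease_genes)
  drug_in <- positives$drug %in% drugs_ok
  disease_in <- positives$disease %in% diseases_ok
  keep <- if (strict) drug_in & disease_in else drug_in | disease_in
  kept <- positives[keep, , drop = FALSE]
  rownames(kept) <- NULL
  if (nrow(kept) == 0L) {
    stop("no associations survive the interactor filter", call. = FALSE)
  }
  restrict <- function(map, entities) {
    pairs <- map$pairs[map$pairs$entity %in% entities &
                       map$pairs$gene %in% nodes, , drop = FALSE]
    bipartite_interactions(pairs, row_ids = sort(unique(entities)),
                           col_ids = sort(unique(pairs$gene)))
  }
  drug_genes_f <- restrict(drug_genes, unique(kept$drug))
  disease_genes_f <- restrict(disease_genes, unique(kept$disease))
  structure(
    list(network = network,
         drug_genes = drug_genes_f,
         disease_genes = disease_genes_f,
         positives = kept,
         provenance = list(
           source = "files", strict = strict,
           n_associations_in = nrow(positives),
           n_associations_kept = nrow(kept),
           n_associations_dropped = nrow(positives) - nrow(kept))),
    class = "genomf_dataset"
  )
}

# ---- writers -----------------------------------------------------------

write_lines <- function(lines, path) {
  con <- file(path, open = "wb")  # binary mode: byte-identical across reruns
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

fmt_num <- function(x) sprintf("%.17g", x)  # shortest round-trip-exact form

#' Write a dataset's four TSV artifacts
#'
#' Creates `network.tsv`, `drug_genes.tsv`, `disease_genes.tsv` and
#' `associations.tsv` under `dir`.
#'
#' @param dataset a `genomf_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edges <- igraph::as_edgelist(dataset$network$graph, names = TRUE)
  write_lines(paste(edges[, 1L], edges[, 2L], sep = "\t"),
              file.path(dir, "network.tsv"))
  wb <- function(map, path) {
    write_lines(paste(map$pairs$entity, map$pairs$gene, sep = "\t"), path)
  }
  wb(dataset$drug_genes, file.path(dir, "drug_genes.tsv"))
  wb(dataset$disease_genes, file.path(dir, "disease_genes.tsv"))
  write_lines(paste(dataset$positives$drug, dataset$positives$disease,
                    sep = "\t"),
              file.path(dir, "associations.tsv"))
  invisible(dir)
}

#' Write / read a feature space as an ID-indexed TSV
#'
#' One row per entity: the ID followed by the k feature values; header
#' `id<TAB>f1..fk`.
#'
#' @param space a `feature_space`.
#' @param path TSV path.
#' @return `write_feature_space()` the path; `read_feature_space()` the
#'   `feature_space`.
#' @export
write_feature_space <- function(space, path) {
  stopifnot(inherits(space, "feature_space"))
  header <- paste(c("id", colnames(space$P)), collapse = "\t")
  body <- vapply(seq_len(nrow(space$P)), function(i) {
    paste(c(space$ids[i], fmt_num(space$P[i, ])), collapse = "\t")
  }, character(1L))
  write_lines(c(header, body), path)
}

#' @rdname write_feature_space
#' @export
read_feature_space <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = c("character"))
  P <- as.matrix(vapply(tab[-1L], as.numeric, numeric(nrow(tab))))
  P <- matrix(P, nrow = nrow(tab))
  feature_space(tab[[1L]], P)
}

#' Write / read a square relation matrix as TSV
#'
#' One header row of entity IDs followed by the numeric body.
#'
#' @param relation a `gene_relation` (for writing).
#' @param path TSV path.
#' @return `read_relation_matrix()` returns a `gene_relation`; the kernel
#'   parameters are stored on a comment line.
#' @export
write_relation_matrix <- function(relation, path) {
  stopifnot(inherits(relation, "gene_relation"))
  meta <- sprintf("# a_prime=%s b_prime=%s", fmt_num(relation$a_prime),
                  fmt_num(relation$b_prime))
  header <- paste(relation$gene_ids, collapse = "\t")
  body <- apply(relation$C, 1L, function(r) paste(fmt_num(r), collapse = "\t"))
  write_lines(c(meta, header, body), path)
}

#' @rdname write_relation_matrix
#' @export
read_relation_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_line <- grep("^# a_prime=", lines, value = TRUE)[1L]
  a_prime <- as.numeric(sub(".*a_prime=([^ ]+).*", "\\1", meta_line))
  b_prime <- as.numeric(sub(".*b_prime=([^ ]+).*", "\\1", meta_line))
  lines <- lines[!grepl("^\\s*#", lines)]
  ids <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  C <- do.call(rbind, lapply(lines[-1L], function(l) {
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1L]])
  }))
  dimnames(C) <- list(ids, ids)
  structure(list(gene_ids = ids, C = C, a_prime = a_prime,
                 b_prime = b_prime),
            class = "gene_relation")
}

#' Persist / restore a trained model
#'
#' Writes `A.tsv` and `B.tsv` (ID-indexed factor matrices) plus
#' `meta.txt`, a flat key=value file holding k, lambda, eta, the number of
#' epochs run and the final objective value.
#'
#' @param model an `mf_model`.
#' @param dir model directory.
#' @param epochs,final_loss optional training provenance for `meta.txt`.
#' @return `read_model()` returns the `mf_model`.
#' @export
write_model <- function(model, dir, epochs = NA, final_loss = NA) {
  stopifnot(inherits(model, "mf_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_space(feature_space(model$drug_ids, model$A),
                      file.path(dir, "A.tsv"))
  write_feature_space(feature_space(model$disease_ids, model$B),
                      file.path(dir, "B.tsv"))
  meta <- c(sprintf("k=%d", model$k),
            sprintf("lambda=%s", fmt_num(model$lambda_reg)),
            sprintf("eta=%s", fmt_num(model$eta)),
            sprintf("epochs=%s", ifelse(is.na(epochs), "NA", epochs)),
            sprintf("final_loss=%s",
                    ifelse(is.na(final_loss), "NA", fmt_num(final_loss))))
  write_lines(meta, file.path(dir, "meta.txt"))
  invisible(dir)
}

#' @rdname write_model
#' @export
read_model <- function(dir) {
  meta_lines <- readLines(file.path(dir, "meta.txt"), warn = FALSE)
  kv <- strsplit(meta_lines, "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, character(1L), 2L),
                          vapply(kv, `[`, character(1L), 1L))
  A <- read_feature_space(file.path(dir, "A.tsv"))
  B <- read_feature_space(file.path(dir, "B.tsv"))
  new_mf_model(A$ids, B$ids, A$P, B$P,
               as.numeric(meta[["lambda"]]), as.numeric(meta[["eta"]]))
}

#' Write prediction scores as a three-column TSV
#'
#' @param scores drugs x diseases matrix with ID dimnames (see
#'   [score_grid()]).
#' @param path output TSV (`drug`, `disease`, `score`).
#' @export
write_predictions <- function(scores, path) {
  rows <- expand.grid(drug = rownames(scores), disease = colnames(scores),
                      stringsAsFactors = FALSE)
  lines <- paste(rows$drug, rows$disease,
                 fmt_num(scores[cbind(rows$drug, rows$disease)]), sep = "\t")
  write_lines(c("drug\tdisease\tscore", lines), path)
}
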