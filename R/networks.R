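#' Build a binary entity-by-gene incidence matrix from an edge list
#'
#' Converts a two-column edge list (entity ID, gene ID) into the sparse binary
#' incidence matrix used to fill missing network entries from gene-association
#' evidence. Entities listed in `entity_ids` but absent from the edge list get
#' all-zero rows, so networks built from different sources can share one ID
#' registry.
#'
#' @param edges A data frame whose first two columns are entity ID and gene ID.
#' @param entity_ids Optional character vector fixing the row registry (order
#'   is preserved). Defaults to the sorted unique entity IDs in `edges`.
#' @param gene_ids Optional character vector fixing the column registry.
#' @return A binary matrix (entities x genes) with ID dimnames.
#' @examples
#' edges <- tibble::tibble(drug = c("d1", "d1", "d2"), gene = c("g1", "g2", "g2"))
#' incidence_matrix(edges)
#' @export
incidence_matrix <- function(edges, entity_ids = NULL, gene_ids = NULL) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  ent <- as.character(edges[[1]])
  gen <- as.character(edges[[2]])
  entity_ids <- entity_ids %||% sort(unique(ent))
  gene_ids <- gene_ids %||% sort(unique(gen))
  if (anyDuplicated(entity_ids)) abort("duplicate entity IDs in registry")
  if (anyDuplicated(gene_ids)) abort("duplicate gene IDs in registry")
  bad <- setdiff(ent, entity_ids)
  if (length(bad) > 0) {
    abort(sprintf("edge list mentions entities outside the registry: %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  bad_g <- setdiff(gen, gene_ids)
  if (length(bad_g) > 0) {
    abort(sprintf("edge list mentions genes outside the registry: %s",
                  paste(head(bad_g, 5), collapse = ", ")))
  }
  m <- matrix(0, length(entity_ids), length(gene_ids),
              dimnames = list(entity_ids, gene_ids))
  m[cbind(match(ent, entity_ids), match(gen, gene_ids))] <- 1
  m
}

#' Build a symmetric binary interaction matrix from a pair edge list
#'
#' Known drug-drug interactions arrive as unweighted pairs; they are binarized
#' and symmetrized into an adjacency matrix over the supplied drug registry.
#'
#' @param edges Data frame whose first two columns are the two interacting IDs.
#' @param entity_ids Character registry for both dimensions.
#' @return Symmetric 0/1 matrix with zero diagonal.
#' @export
interaction_matrix <- function(edges, entity_ids) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  bad <- setdiff(c(a, b), entity_ids)
  if (length(bad) > 0) {
    abort(sprintf("interaction list mentions IDs outside the registry: %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  m <- matrix(0, length(entity_ids), length(entity_ids),
              dimnames = list(entity_ids, entity_ids))
  ia <- match(a, entity_ids)
  ib <- match(b, entity_ids)
  keep <- ia != ib
  m[cbind(ia[keep], ib[keep])] <- 1
  m[cbind(ib[keep], ia[keep])] <- 1
  m
}

#' Jaccard similarity of two entities' gene sets
#'
#' The score used to fill missing drug-drug interaction entries: the size of
#' the intersection of the two gene sets divided by the size of their union,
#' with an empty union scoring 0.
#'
#' @param gene_map Binary entity x gene incidence matrix.
#' @param i,j Entity indices (1-based) or entity IDs.
#' @return A similarity in `[0, 1]`.
#' @export
jaccard_gene_similarity <- function(gene_map, i, j) {
  stopifnot(is.matrix(gene_map))
  idx <- function(x) {
    if (is.character(x)) x <- match(x, rownames(gene_map))
    if (is.na(x) || x < 1 || x > nrow(gene_map)) {
      abort("entity index out of range")
    }
    x
  }
  i <- idx(i); j <- idx(j)
  gi <- gene_map[i, ] != 0
  gj <- gene_map[j, ] != 0
  un <- sum(gi | gj)
  if (un == 0) return(0)
  sum(gi & gj) / un
}

# Full pairwise Jaccard over gene sets, vectorized via the co-membership
# product; pairs with empty unions score 0.
jaccard_matrix <- function(gene_map) {
  m <- (gene_map != 0) * 1
  shared <- m %*% t(m)
  sizes <- rowSums(m)
  union <- outer(sizes, sizes, "+") - shared
  out <- ifelse(union > 0, shared / union, 0)
  dimnames(out) <- list(rownames(gene_map), rownames(gene_map))
  out
}

#' Reconstruct the drug-drug interaction network from gene evidence
#'
#' Known interactions are kept (binarized to 1); every missing entry is filled
#' with the Jaccard similarity of the two drugs' gene sets, giving the
#' reconstructed drug-drug interaction (RDDI) network. Drugs without gene
#' annotations stay unconnected except through known interactions. The
#' diagonal is set to 1 (self-similarity); self-loops are never used as
#' neighbor candidates downstream.
#'
#' @param ddi Symmetric known-interaction matrix (drugs x drugs, same registry
#'   as `drug_gene`). Nonzero entries are treated as known interactions.
#' @param drug_gene Binary drug x gene incidence matrix.
#' @return Symmetric nonnegative matrix over the drug registry.
#' @export
reconstruct_ddi <- function(ddi, drug_gene) {
  check_square_named(ddi, "ddi")
  if (is.null(rownames(drug_gene))) abort("`drug_gene` needs row IDs")
  check_registry_match(rownames(ddi), rownames(drug_gene), "ddi", "drug_gene")
  known <- ddi != 0
  out <- jaccard_matrix(drug_gene)
  out[known] <- 1
  diag(out) <- 1
  stopifnot(max(abs(out - t(out))) < 1e-12)
  out
}

#' Reconstruct the disease similarity network from gene evidence
#'
#' Semantic similarities are kept where present; entries that are zero
#' (typically disease pairs from different vocabulary subtrees, for which no
#' semantic score exists) are filled from disease-gene evidence: the number of
#' shared genes divided by the product of the two diseases' gene counts
#' (`denominator = "product"`, the default), or by the geometric mean of the
#' counts (`denominator = "cosine"`). Pairs where either disease has no gene
#' annotation fill with 0.
#'
#' @param semantic Symmetric semantic similarity matrix (diseases x diseases).
#' @param dis_gene Binary disease x gene incidence matrix on the same registry.
#' @param denominator Normalization for the gene-evidence fill; see Details.
#' @return Symmetric nonnegative matrix over the disease registry, diagonal 1.
#' @export
reconstruct_disease_similarity <- function(semantic, dis_gene,
                                           denominator = c("product", "cosine")) {
  denominator <- match.arg(denominator)
  check_square_named(semantic, "semantic")
  if (is.null(rownames(dis_gene))) abort("`dis_gene` needs row IDs")
  check_registry_match(rownames(semantic), rownames(dis_gene),
                       "semantic", "dis_gene")
  m <- (dis_gene != 0) * 1
  shared <- m %*% t(m)
  counts <- rowSums(m)
  denom <- outer(counts, counts, "*")
  if (denominator == "cosine") denom <- sqrt(denom)
  fill <- ifelse(denom > 0, shared / denom, 0)
  out <- ifelse(semantic != 0, semantic, fill)
  diag(out) <- 1
  dimnames(out) <- dimnames(semantic)
  stopifnot(max(abs(out - t(out))) < 1e-12)
  out
}

#' Read/write helpers for network and table interchange
#'
#' Dense matrices travel as TSV with an ID header column; sparse copies can be
#' written as MatrixMarket. Edge lists are two-column TSVs.
#'
#' @param m Matrix with dimnames.
#' @param path File path.
#' @name network-io
NULL

#' @rdname network-io
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname network-io
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' @rdname network-io
#' @export
write_matrix_mtx <- function(m, path) {
  idx <- which(m != 0, arr.ind = TRUE)
  sm <- Matrix::sparseMatrix(i = idx[, 1], j = idx[, 2], x = m[idx],
                             dims = dim(m))
  Matrix::writeMM(sm, path)
  invisible(path)
}

#' @rdname network-io
#' @export
read_edges_tsv <- function(path) {
  tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE,
                               colClasses = "character"))
}

#' @rdname network-io
#' @param edges Data frame to write.
#' @export
write_edges_tsv <- function(edges, path) {
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
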