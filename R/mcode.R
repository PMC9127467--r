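# Seed-and-grow network clustering in the MCODE style: vertices are weighted
# by the density of the highest k-core of their closed neighborhood, then
# complexes grow outward from high-weight seeds. The factorization constraint
# needs a full disjoint partition, so nodes left out of every complex become
# singleton clusters.

# core-clustering-coefficient weight of every vertex
mcode_vertex_weights <- function(g, degree_cutoff) {
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  w <- numeric(n)
  for (v in seq_len(n)) {
    if (deg[v] < degree_cutoff) next
    nb <- c(v, as.integer(igraph::neighbors(g, v)))
    sub <- igraph::induced_subgraph(g, nb)
    cores <- igraph::coreness(sub)
    kmax <- max(cores)
    if (kmax == 0) next
    core_v <- which(cores >= kmax)
    sub2 <- igraph::induced_subgraph(sub, core_v)
    nv <- igraph::vcount(sub2)
    dens <- if (nv > 1) 2 * igraph::ecount(sub2) / (nv * (nv - 1)) else 0
    w[v] <- kmax * dens
  }
  w
}

#' Partition a similarity network into clusters (MCODE-style)
#'
#' Binarizes the network at `edge_threshold` (self-loops dropped), weights
#' each vertex by the product of the order and density of the highest k-core
#' of its closed neighborhood, then grows complexes from the highest-weight
#' unassigned seed: a breadth-first expansion that admits a neighbor whenever
#' its weight exceeds `(1 - node_score_cutoff)` times the seed's weight.
#' Post-processing optionally removes singly connected vertices (`haircut`)
#' and discards complexes lacking a `k_core`-core. Every node not in a
#' surviving complex becomes a singleton cluster, so the result is a full
#' disjoint partition. Ties in seed order and expansion are broken by
#' ascending node index, making the run deterministic.
#'
#' @param net Symmetric nonnegative similarity/interaction matrix with ID
#'   dimnames.
#' @param edge_threshold Edges with weight strictly above this survive
#'   binarization (default 0).
#' @param degree_cutoff Vertices with binarized degree below this get weight 0
#'   and cannot seed a complex (default 2).
#' @param node_score_cutoff Relative weight tolerance for expansion
#'   (default 0.2).
#' @param k_core Minimum core order a complex must contain (default 2).
#' @param haircut Remove singly connected vertices from complexes
#'   (default TRUE).
#' @param fluff Unused compatibility switch; fluff expansion produces
#'   overlapping complexes, which the disjoint partition cannot represent.
#' @return A tibble with columns `entity_id` and `cluster` (integer, 1-based);
#'   attribute `"sizes"` carries per-cluster sizes.
#' @export
cluster_network <- function(net, edge_threshold = 0, degree_cutoff = 2,
                            node_score_cutoff = 0.2, k_core = 2,
                            haircut = TRUE, fluff = FALSE) {
  if (length(net) == 0) abort("empty network")
  check_square_named(net, "net")
  if (isTRUE(fluff)) warn("fluff expansion is not supported; ignored")
  adj <- (net > edge_threshold) * 1
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  n <- nrow(net)
  w <- mcode_vertex_weights(g, degree_cutoff)
  nb_list <- lapply(seq_len(n), function(v) as.integer(igraph::neighbors(g, v)))

  assigned <- rep(FALSE, n)
  complexes <- list()
  # highest-weight unassigned vertex seeds next; ties by ascending index
  seed_order <- order(-w, seq_len(n))
  for (seed in seed_order) {
    if (assigned[seed] || w[seed] <= 0) next
    cutoff <- w[seed] * (1 - node_score_cutoff)
    members <- seed
    assigned[seed] <- TRUE
    frontier <- seed
    while (length(frontier) > 0) {
      cand <- sort(unique(unlist(nb_list[frontier])))
      cand <- cand[!assigned[cand] & w[cand] > cutoff]
      if (length(cand) == 0) break
      assigned[cand] <- TRUE
      members <- c(members, cand)
      frontier <- cand
    }
    if (haircut && length(members) > 1) {
      sub <- adj[members, members, drop = FALSE]
      keep <- rowSums(sub) >= 2
      dropped <- members[!keep]
      assigned[dropped] <- FALSE
      members <- members[keep]
    }
    if (length(members) > 0) {
      sub_g <- igraph::induced_subgraph(g, members)
      if (max(igraph::coreness(sub_g)) >= k_core) {
        complexes[[length(complexes) + 1]] <- sort(members)
      } else {
        assigned[members] <- FALSE
      }
    }
  }

  labels <- integer(n)
  for (ci in seq_along(complexes)) labels[complexes[[ci]]] <- ci
  nxt <- length(complexes)
  for (v in seq_len(n)) {
    if (labels[v] == 0) {
      nxt <- nxt + 1L
      labels[v] <- nxt
    }
  }
  out <- tibble::tibble(entity_id = rownames(net), cluster = as.integer(labels))
  attr(out, "sizes") <- as.integer(table(factor(labels, levels = seq_len(nxt))))
  out
}

#' Read or validate an externally supplied cluster assignment
#'
#' Clustering is pluggable: an assignment computed elsewhere can replace
#' [cluster_network()] as long as it is a full partition of the registry.
#'
#' @param assignment Data frame with columns `entity_id`, `cluster`.
#' @param entity_ids The registry the assignment must cover exactly.
#' @return The validated assignment tibble, clusters renumbered 1..c.
#' @export
as_cluster_assignment <- function(assignment, entity_ids) {
  stopifnot(is.data.frame(assignment),
            all(c("entity_id", "cluster") %in% names(assignment)))
  if (anyDuplicated(assignment$entity_id)) {
    abort("assignment labels some entity more than once")
  }
  check_registry_match(sort(as.character(assignment$entity_id)),
                       sort(entity_ids), "assignment", "registry")
  assignment <- assignment[match(entity_ids, assignment$entity_id), ]
  lab <- as.integer(factor(assignment$cluster))
  tibble::tibble(entity_id = entity_ids, cluster = lab)
}
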