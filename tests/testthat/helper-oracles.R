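# Independent oracles and tiny builders shared across tests.

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# brute-force AUC: concordant-pair fraction, ties counting one half
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# gene map from a named list of gene-ID character sets
gene_map_from_sets <- function(sets, gene_ids = NULL) {
  gene_ids <- gene_ids %||% sort(unique(unlist(sets)))
  m <- matrix(0, length(sets), length(gene_ids),
              dimnames = list(names(sets), gene_ids))
  for (i in seq_along(sets)) m[i, sets[[i]]] <- 1
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small symmetric named similarity matrix
named_symmetric <- function(m, ids) {
  m <- (m + t(m)) / 2
  dimnames(m) <- list(ids, ids)
  m
}

# random small labeled-pair problem for metric tests
random_scores_labels <- function(n, seed) {
  set.seed(seed)
  list(scores = round(runif(n), 2),  # rounding forces ties
       labels = c(0, 1, rbinom(n - 2, 1, 0.5)))
}

# loop-based per-cluster mean oracle
cluster_means_loop <- function(X, labels) {
  t(vapply(sort(unique(labels)), function(cl) {
    colMeans(X[labels == cl, , drop = FALSE])
  }, numeric(ncol(X))))
}

# tiny two-tower model on random networks/features for graphsage tests
tiny_model <- function(seed = 1, aggregator = "mean", n_d = 8, n_s = 6,
                       mode = "both") {
  set.seed(seed)
  dnet <- matrix(runif(n_d^2), n_d)
  dnet <- named_symmetric(dnet, sprintf("d%02d", seq_len(n_d)))
  diag(dnet) <- 1
  snet <- matrix(runif(n_s^2), n_s)
  snet <- named_symmetric(snet, sprintf("s%02d", seq_len(n_s)))
  diag(snet) <- 1
  feats <- list(
    drug_attr = matrix(rnorm(n_d * 5), n_d, 5, dimnames = list(rownames(dnet), NULL)),
    dis_attr = matrix(rnorm(n_s * 4), n_s, 4, dimnames = list(rownames(snet), NULL)),
    drug_clu = matrix(rnorm(n_d * 3), n_d, 3, dimnames = list(rownames(dnet), NULL)),
    dis_clu = matrix(rnorm(n_s * 3), n_s, 3, dimnames = list(rownames(snet), NULL))
  )
  drgcc_model(dnet, snet, feats, mode = mode, aggregator = aggregator,
              n_k = 3, dropout = 0, seed = seed)
}
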