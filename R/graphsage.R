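# Two-tower inductive graph neural network (GraphSAGE). One tower runs on the
# reconstructed drug-drug interaction network, the other on the reconstructed
# disease similarity network; each tower embeds two feature channels
# separately (attribute features from fingerprints/symptoms, clustering
# features from the constrained factorization) through L = 2 layers of
# neighbor sampling and aggregation. Pair probabilities come from a
# concatenated four-part embedding fed to a three-layer fully connected
# softmax head. Implemented directly in vectorized base R with hand-written
# reverse-mode gradients and adaptive-moment (Adam) updates.

CHANNEL_DIMS <- list(
  drug_attr = c(128L, 64L),
  drug_clu  = c(128L, 32L),
  dis_attr  = c(64L, 32L),
  dis_clu   = c(128L, 32L)
)

# concat order of the pair representation: z_drug^F, z_drug^U, z_dis^F, z_dis^V
channels_for_mode <- function(mode) {
  switch(mode,
    both      = c("drug_attr", "drug_clu", "dis_attr", "dis_clu"),
    attribute = c("drug_attr", "dis_attr"),
    cluster   = c("drug_clu", "dis_clu"),
    abort(sprintf("unknown feature mode '%s'", mode))
  )
}

channel_side <- function(ch) if (startsWith(ch, "drug")) "drug" else "dis"

#' Deterministic neighbor sampling from a weighted network
#'
#' Each node contributes its `n_k` highest-weight neighbors (edge weight as
#' the similarity), ties broken by ascending node index; nodes with fewer
#' than `n_k` neighbors contribute all of them, and isolated nodes contribute
#' none (they later aggregate over themselves alone). Self-loops are never
#' neighbor candidates.
#'
#' @param net Symmetric nonnegative network matrix.
#' @param n_k Neighbors sampled per node (default 5).
#' @return List of integer neighbor-index vectors, one per node.
#' @export
sample_neighbors <- function(net, n_k = 5) {
  check_square_named(net, "net")
  stopifnot(n_k >= 1)
  n <- nrow(net)
  lapply(seq_len(n), function(v) {
    w <- net[v, ]
    w[v] <- 0
    nb <- which(unname(w) > 0)
    if (length(nb) == 0) return(integer(0))
    unname(nb[order(-w[nb], nb)][seq_len(min(n_k, length(nb)))])
  })
}

#' Top-down minibatch neighborhood expansion
#'
#' Expands a batch node set through `L` sampling layers: the deepest set is
#' the batch itself and each shallower set adds every member's sampled
#' neighbors, yielding the node sets whose input features the forward pass
#' needs.
#'
#' @param batch Integer node indices (or IDs matching the network dimnames).
#' @param net Symmetric nonnegative network matrix.
#' @param L Number of layers (default 2).
#' @param n_k Neighbors sampled per node.
#' @return List with `sets` (length `L + 1`, from the batch down to the full
#'   support set) and `samples` (per-node sampled neighbors).
#' @export
sample_neighborhoods <- function(batch, net, L = 2, n_k = 5) {
  if (is.character(batch)) batch <- match(batch, rownames(net))
  stopifnot(!anyNA(batch), all(batch >= 1), all(batch <= nrow(net)))
  samples <- sample_neighbors(net, n_k)
  sets <- vector("list", L + 1)
  sets[[1]] <- sort(unique(as.integer(batch)))
  for (l in seq_len(L)) {
    cur <- sets[[l]]
    sets[[l + 1]] <- sort(unique(c(cur, unlist(samples[cur]))))
  }
  names(sets) <- paste0("B", seq(L, 0))
  list(sets = sets, samples = samples)
}

# Row-stochastic neighbor-mean operator (isolated nodes fall back to self)
# and its GCN variant averaging over self + neighbors.
neighbor_operators <- function(samples, n) {
  A <- matrix(0, n, n)
  Ag <- matrix(0, n, n)
  for (v in seq_len(n)) {
    s <- samples[[v]]
    if (length(s) == 0) {
      A[v, v] <- 1
      Ag[v, v] <- 1
    } else {
      A[v, s] <- 1 / length(s)
      Ag[v, c(v, s)] <- 1 / (length(s) + 1)
    }
  }
  list(A = A, Ag = Ag)
}

glorot <- function(fan_in, fan_out) {
  s <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -s, s), fan_in, fan_out)
}

init_channel_params <- function(prefix, in_dim, dims, aggregator) {
  p <- list()
  d_prev <- in_dim
  for (l in seq_along(dims)) {
    d_out <- dims[l]
    if (aggregator == "gcn") {
      p[[sprintf("%s.W%d", prefix, l)]] <- glorot(d_prev, d_out)
    } else {
      p[[sprintf("%s.W%d", prefix, l)]] <- glorot(2L * d_prev, d_out)
    }
    p[[sprintf("%s.b%d", prefix, l)]] <- numeric(d_out)
    if (aggregator %in% c("meanpool", "maxpool")) {
      p[[sprintf("%s.Wp%d", prefix, l)]] <- glorot(d_prev, d_prev)
      p[[sprintf("%s.bp%d", prefix, l)]] <- numeric(d_prev)
    }
    if (aggregator == "lstm") {
      for (g in c("i", "f", "o", "g")) {
        p[[sprintf("%s.lstmW%s%d", prefix, g, l)]] <- glorot(d_prev, d_prev)
        p[[sprintf("%s.lstmU%s%d", prefix, g, l)]] <- glorot(d_prev, d_prev)
        p[[sprintf("%s.lstmb%s%d", prefix, g, l)]] <- numeric(d_prev)
      }
    }
    d_prev <- d_out
  }
  p
}

init_head_params <- function(in_dim, dims = c(64L, 32L, 2L)) {
  p <- list()
  d_prev <- in_dim
  for (l in seq_along(dims)) {
    p[[sprintf("head.W%d", l)]] <- glorot(d_prev, dims[l])
    p[[sprintf("head.b%d", l)]] <- numeric(dims[l])
    d_prev <- dims[l]
  }
  p
}

relu <- function(x) pmax(x, 0)
add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Aggregate sampled neighbor representations into the next representation
#'
#' One aggregation step for a single node, exposing the five aggregator
#' kinds. `mean` averages the neighbor representations, concatenates with the
#' node's own representation and applies a linear map plus activation;
#' `meanpool`/`maxpool` first pass each neighbor through an inner transform
#' `sigma(h %*% Wp + bp)` and pool elementwise; `gcn` averages over the node
#' and its neighbors with no concatenation; `lstm` runs a recurrent cell over
#' a seeded random permutation of the neighbors (the one kind that is not
#' permutation-invariant). An empty neighbor set falls back to aggregating
#' over the node itself.
#'
#' @param kind Aggregator kind.
#' @param self_repr Numeric vector, the node's current representation.
#' @param neighbor_reprs Matrix with one neighbor representation per row (may
#'   have zero rows).
#' @param W,b Outer linear map (`2*d x d_out`, or `d x d_out` for `gcn`).
#' @param Wp,bp Inner pooling transform (meanpool/maxpool only).
#' @param lstm Named list of LSTM gate parameters (`Wi, Ui, bi, ...`).
#' @param sigma Outer activation function (default rectified linear).
#' @param sigma_inner Activation of the inner pooling transform (default
#'   rectified linear).
#' @param perm_seed Seed for the LSTM neighbor permutation.
#' @return List: `h` (the next representation) and `aggregated` (the pooled
#'   neighborhood vector before concatenation; for `gcn` the self-inclusive
#'   mean).
#' @export
sage_aggregate <- function(kind = c("mean", "meanpool", "maxpool", "gcn", "lstm"),
                           self_repr, neighbor_reprs, W, b, Wp = NULL, bp = NULL,
                           lstm = NULL, sigma = relu, sigma_inner = relu,
                           perm_seed = 1) {
  kind <- match.arg(kind)
  if (is.null(dim(neighbor_reprs))) {
    neighbor_reprs <- matrix(neighbor_reprs, nrow = 1)
  }
  if (nrow(neighbor_reprs) == 0) {
    neighbor_reprs <- matrix(self_repr, nrow = 1)  # self-only fallback
  }
  agg <- switch(kind,
    mean = colMeans(neighbor_reprs),
    meanpool = {
      G <- sigma_inner(add_bias(neighbor_reprs %*% Wp, bp))
      colMeans(G)
    },
    maxpool = {
      G <- sigma_inner(add_bias(neighbor_reprs %*% Wp, bp))
      apply(G, 2, max)
    },
    gcn = colMeans(rbind(self_repr, neighbor_reprs)),
    lstm = {
      ord <- with_seed(perm_seed, sample.int(nrow(neighbor_reprs)))
      hdim <- length(self_repr)
      h <- numeric(hdim); cc <- numeric(hdim)
      for (t in ord) {
        x <- neighbor_reprs[t, ]
        gi <- sigmoid(x %*% lstm$Wi + h %*% lstm$Ui + lstm$bi)
        gf <- sigmoid(x %*% lstm$Wf + h %*% lstm$Uf + lstm$bf)
        go <- sigmoid(x %*% lstm$Wo + h %*% lstm$Uo + lstm$bo)
        gg <- tanh(x %*% lstm$Wg + h %*% lstm$Ug + lstm$bg)
        cc <- as.numeric(gf) * cc + as.numeric(gi) * as.numeric(gg)
        h <- as.numeric(go) * tanh(cc)
      }
      h
    }
  )
  h_next <- if (kind == "gcn") {
    sigma(as.numeric(agg %*% W) + b)
  } else {
    sigma(as.numeric(c(self_repr, agg) %*% W) + b)
  }
  list(h = h_next, aggregated = agg)
}

# Vectorized channel forward over all nodes. mean/gcn/meanpool run as matrix
# products; maxpool/lstm loop over nodes (inference paths).
forward_channel <- function(params, prefix, ops, X, dims, aggregator,
                            training = FALSE, drop_rate = 0) {
  L <- length(dims)
  H <- X
  cache <- vector("list", L)
  for (l in seq_len(L)) {
    W <- params[[sprintf("%s.W%d", prefix, l)]]
    b <- params[[sprintf("%s.b%d", prefix, l)]]
    mask <- NULL
    Hin <- H
    if (training && drop_rate > 0) {
      mask <- matrix(rbinom(length(Hin), 1, 1 - drop_rate), nrow(Hin)) /
        (1 - drop_rate)
      Hin <- Hin * mask
    }
    st <- list(Hin = Hin, mask = mask)
    if (aggregator == "mean") {
      S <- cbind(Hin, ops$A %*% Hin)
      Z <- add_bias(S %*% W, b)
      st$S <- S
    } else if (aggregator == "gcn") {
      M <- ops$Ag %*% Hin
      Z <- add_bias(M %*% W, b)
      st$M <- M
    } else if (aggregator == "meanpool") {
      Wp <- params[[sprintf("%s.Wp%d", prefix, l)]]
      bp <- params[[sprintf("%s.bp%d", prefix, l)]]
      Zp <- add_bias(Hin %*% Wp, bp)
      G <- relu(Zp)
      S <- cbind(Hin, ops$A %*% G)
      Z <- add_bias(S %*% W, b)
      st$S <- S
      st$Zp <- Zp
    } else if (aggregator %in% c("maxpool", "lstm")) {
      extra <- if (aggregator == "maxpool") {
        list(Wp = params[[sprintf("%s.Wp%d", prefix, l)]],
             bp = params[[sprintf("%s.bp%d", prefix, l)]])
      } else {
        gates <- c("i", "f", "o", "g")
        lst <- c(
          setNames(lapply(gates, function(g)
            params[[sprintf("%s.lstmW%s%d", prefix, g, l)]]),
            paste0("W", gates)),
          setNames(lapply(gates, function(g)
            params[[sprintf("%s.lstmU%s%d", prefix, g, l)]]),
            paste0("U", gates)),
          setNames(lapply(gates, function(g)
            params[[sprintf("%s.lstmb%s%d", prefix, g, l)]]),
            paste0("b", gates))
        )
        list(lstm = lst)
      }
      Z <- t(vapply(seq_len(nrow(Hin)), function(v) {
        nb <- ops$samples[[v]]
        out <- sage_aggregate(
          aggregator, Hin[v, ], Hin[nb, , drop = FALSE], W, b,
          Wp = extra$Wp, bp = extra$bp, lstm = extra$lstm,
          sigma = identity, perm_seed = derive_seed(l * 1000 + v, "lstm-perm")
        )
        out$h
      }, numeric(length(b))))
    }
    st$Z <- Z
    H <- relu(Z)
    cache[[l]] <- st
  }
  list(H = H, cache = cache)
}

backward_channel <- function(params, prefix, ops, cache, dH, dims, aggregator) {
  grads <- list()
  L <- length(dims)
  for (l in rev(seq_len(L))) {
    st <- cache[[l]]
    W <- params[[sprintf("%s.W%d", prefix, l)]]
    dZ <- dH * (st$Z > 0)
    grads[[sprintf("%s.b%d", prefix, l)]] <- colSums(dZ)
    if (aggregator == "mean") {
      grads[[sprintf("%s.W%d", prefix, l)]] <- crossprod(st$S, dZ)
      dS <- tcrossprod(dZ, W)
      d_in <- ncol(st$Hin)
      dHin <- dS[, seq_len(d_in), drop = FALSE] +
        crossprod(ops$A, dS[, d_in + seq_len(d_in), drop = FALSE])
    } else if (aggregator == "gcn") {
      grads[[sprintf("%s.W%d", prefix, l)]] <- crossprod(st$M, dZ)
      dHin <- crossprod(ops$Ag, tcrossprod(dZ, W))
    } else if (aggregator == "meanpool") {
      Wp <- params[[sprintf("%s.Wp%d", prefix, l)]]
      grads[[sprintf("%s.W%d", prefix, l)]] <- crossprod(st$S, dZ)
      dS <- tcrossprod(dZ, W)
      d_in <- ncol(st$Hin)
      dHin <- dS[, seq_len(d_in), drop = FALSE]
      dG <- crossprod(ops$A, dS[, d_in + seq_len(d_in), drop = FALSE])
      dZp <- dG * (st$Zp > 0)
      grads[[sprintf("%s.Wp%d", prefix, l)]] <- crossprod(st$Hin, dZp)
      grads[[sprintf("%s.bp%d", prefix, l)]] <- colSums(dZp)
      dHin <- dHin + tcrossprod(dZp, Wp)
    } else {
      abort(sprintf("gradient-based training is not implemented for the '%s' aggregator; use mean, gcn or meanpool (maxpool and lstm towers support inference only)",
                    aggregator))
    }
    if (!is.null(st$mask)) dHin <- dHin * st$mask
    dH <- dHin
  }
  grads
}

head_forward <- function(params, X, training = FALSE, drop_rate = 0) {
  cache <- list()
  H <- X
  n_layers <- sum(grepl("^head\\.W", names(params)))
  for (l in seq_len(n_layers)) {
    W <- params[[sprintf("head.W%d", l)]]
    b <- params[[sprintf("head.b%d", l)]]
    mask <- NULL
    Hin <- H
    if (training && drop_rate > 0 && l > 1) {
      mask <- matrix(rbinom(length(Hin), 1, 1 - drop_rate), nrow(Hin)) /
        (1 - drop_rate)
      Hin <- Hin * mask
    }
    Z <- add_bias(Hin %*% W, b)
    H <- if (l < n_layers) relu(Z) else Z
    cache[[l]] <- list(Hin = Hin, Z = Z, mask = mask)
  }
  logits <- H
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  list(probs = probs, logits = logits, cache = cache)
}

head_backward <- function(params, cache, dlogits) {
  grads <- list()
  n_layers <- length(cache)
  dH <- dlogits
  for (l in rev(seq_len(n_layers))) {
    st <- cache[[l]]
    W <- params[[sprintf("head.W%d", l)]]
    dZ <- if (l < n_layers) dH * (st$Z > 0) else dH
    grads[[sprintf("head.W%d", l)]] <- crossprod(st$Hin, dZ)
    grads[[sprintf("head.b%d", l)]] <- colSums(dZ)
    dH <- tcrossprod(dZ, W)
    if (!is.null(st$mask)) dH <- dH * st$mask
  }
  grads$dX <- dH
  grads
}

#' Cross-entropy objective with L2 weight decay
#'
#' Cross-entropy summed over the labeled pairs plus `lambda / N` times the
#' sum of squared entries of every weight matrix (biases excluded), `N` being
#' the number of labeled pairs in the sum. Probabilities are clipped to
#' `[1e-10, 1 - 1e-10]`.
#'
#' @param prob Predicted probability of association per pair.
#' @param labels 0/1 labels.
#' @param params Named parameter list (entries named `*.W*` contribute to the
#'   penalty); may be empty.
#' @param lambda Regularization strength (default 0.01).
#' @return Scalar loss.
#' @export
sage_loss <- function(prob, labels, params = list(), lambda = 0.01) {
  p <- pmin(pmax(prob, 1e-10), 1 - 1e-10)
  ce <- -sum(labels * log(p) + (1 - labels) * log(1 - p))
  wsum <- 0
  wnames <- grep("\\.W", names(params), value = TRUE)
  for (nm in wnames) wsum <- wsum + sum(params[[nm]]^2)
  ce + lambda / max(length(labels), 1) * wsum
}

#' Assemble an untrained two-tower prediction model
#'
#' Wires the reconstructed networks, the four feature matrices and the
#' configured layer dimensions into one model object: per-network neighbor
#' samples and averaging operators, per-channel tower weights and the fully
#' connected head. Layer dimensions default to {128, 64} for drug attribute
#' features, {64, 32} for disease attribute features and {128, 32} for both
#' clustering channels; the head is {64, 32, 2}.
#'
#' @param drug_net,dis_net Reconstructed symmetric networks.
#' @param features Named list with entries `drug_attr` (drugs x d_drug),
#'   `dis_attr` (diseases x d_dis), `drug_clu` (drugs x k), `dis_clu`
#'   (diseases x k). Channels outside `mode` may be omitted.
#' @param mode `"both"` (default), `"attribute"`, or `"cluster"`.
#' @param aggregator Aggregator kind (default `"mean"`).
#' @param n_k Neighbors sampled per node (default 5).
#' @param lambda L2 strength (default 0.01).
#' @param dropout Dropout rate during training (default 0.5).
#' @param head_dims Fully connected head dimensions (default `c(64, 32, 2)`).
#' @param seed Seed for weight initialization.
#' @return An object of class `drgcc_model`.
#' @export
drgcc_model <- function(drug_net, dis_net, features, mode = "both",
                        aggregator = "mean", n_k = 5, lambda = 0.01,
                        dropout = 0.5, head_dims = c(64L, 32L, 2L), seed = 1) {
  check_square_named(drug_net, "drug_net")
  check_square_named(dis_net, "dis_net")
  chans <- channels_for_mode(mode)
  for (ch in chans) {
    if (is.null(features[[ch]])) abort(sprintf("feature channel '%s' missing", ch))
  }
  drug_ids <- rownames(drug_net)
  dis_ids <- rownames(dis_net)
  for (ch in chans) {
    ids <- if (channel_side(ch) == "drug") drug_ids else dis_ids
    if (nrow(features[[ch]]) != length(ids)) {
      abort(sprintf("feature channel '%s' has %d rows; expected %d",
                    ch, nrow(features[[ch]]), length(ids)))
    }
  }
  samples_drug <- sample_neighbors(drug_net, n_k)
  samples_dis <- sample_neighbors(dis_net, n_k)
  ops <- list(
    drug = c(neighbor_operators(samples_drug, length(drug_ids)),
             list(samples = samples_drug)),
    dis = c(neighbor_operators(samples_dis, length(dis_ids)),
            list(samples = samples_dis))
  )
  params <- with_seed(derive_seed(seed, "init"), {
    p <- list()
    for (ch in chans) {
      p <- c(p, init_channel_params(ch, ncol(features[[ch]]),
                                    CHANNEL_DIMS[[ch]], aggregator))
    }
    in_dim <- sum(vapply(chans, function(ch) {
      d <- CHANNEL_DIMS[[ch]]
      as.integer(d[length(d)])
    }, integer(1)))
    c(p, init_head_params(in_dim, as.integer(head_dims)))
  })
  structure(
    list(
      params = params, ops = ops, features = features[chans],
      drug_ids = drug_ids, dis_ids = dis_ids,
      drug_net = drug_net, dis_net = dis_net,
      config = list(mode = mode, channels = chans, aggregator = aggregator,
                    n_k = n_k, lambda = lambda, dropout = dropout,
                    head_dims = as.integer(head_dims)),
      loss_history = numeric(0), trained = FALSE, seed = seed
    ),
    class = "drgcc_model"
  )
}

# Eval-mode embeddings of every node for each active channel.
model_embeddings <- function(model, training = FALSE, drop_rate = 0,
                             with_cache = FALSE) {
  out <- lapply(model$config$channels, function(ch) {
    forward_channel(
      model$params, ch, model$ops[[channel_side(ch)]],
      model$features[[ch]], CHANNEL_DIMS[[ch]], model$config$aggregator,
      training = training, drop_rate = drop_rate
    )
  })
  names(out) <- model$config$channels
  if (with_cache) out else lapply(out, `[[`, "H")
}

#' Train the two-tower model on labeled pairs
#'
#' Minibatch gradient training of all tower and head weights against the
#' cross-entropy objective with L2 decay, using adaptive-moment updates.
#' Each step recomputes the tower embeddings in training mode (dropout on
#' layer inputs), scores the batch pairs, and backpropagates through the
#' head and both towers. Reproducible under a fixed seed.
#'
#' @param model An untrained (or previously trained) `drgcc_model`.
#' @param pairs Tibble with columns `drug_id`, `disease_id`, `label` (0/1).
#' @param epochs Training epochs (default 30).
#' @param lr Learning rate (default 0.001).
#' @param batch_size Pairs per minibatch (default 128).
#' @param seed Seed controlling shuffling and dropout.
#' @param verbose Print per-epoch loss.
#' @return The model with trained weights and a per-epoch `loss_history`.
#' @export
train_drgcc <- function(model, pairs, epochs = 30, lr = 0.001,
                        batch_size = 128, seed = 1, verbose = FALSE) {
  stopifnot(inherits(model, "drgcc_model"))
  if (model$config$aggregator %in% c("maxpool", "lstm")) {
    abort(sprintf("gradient-based training is not implemented for the '%s' aggregator; use mean, gcn or meanpool",
                  model$config$aggregator))
  }
  di <- match(pairs$drug_id, model$drug_ids)
  si <- match(pairs$disease_id, model$dis_ids)
  if (anyNA(di) || anyNA(si)) abort("pairs mention IDs outside the model registries")
  y <- as.integer(pairs$label)
  stopifnot(all(y %in% c(0L, 1L)))
  n_pairs <- length(y)
  lambda <- model$config$lambda
  chans <- model$config$channels
  final_dims <- vapply(chans, function(ch) {
    d <- CHANNEL_DIMS[[ch]]
    as.integer(d[length(d)])
  }, integer(1))
  col_end <- cumsum(final_dims)
  col_start <- col_end - final_dims + 1L

  adam_m <- list(); adam_v <- list(); adam_t <- 0L
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  loss_hist <- numeric(epochs)

  with_seed(derive_seed(seed, "train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n_pairs)
      ep_loss <- 0
      for (start in seq(1, n_pairs, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1, n_pairs)]
        nb <- length(idx)
        fwd <- model_embeddings(model, training = TRUE,
                                drop_rate = model$config$dropout,
                                with_cache = TRUE)
        Xh <- do.call(cbind, lapply(seq_along(chans), function(ci) {
          ch <- chans[ci]
          rows <- if (channel_side(ch) == "drug") di[idx] else si[idx]
          fwd[[ch]]$H[rows, , drop = FALSE]
        }))
        hf <- head_forward(model$params, Xh, training = TRUE,
                           drop_rate = model$config$dropout)
        p1 <- hf$probs[, 2]
        batch_loss <- sage_loss(p1, y[idx], model$params, lambda)
        if (!is.finite(batch_loss)) {
          abort(sprintf("non-finite loss at epoch %d; aborting", ep))
        }
        ep_loss <- ep_loss + batch_loss
        onehot <- cbind(1 - y[idx], y[idx])
        dlogits <- hf$probs - onehot
        hb <- head_backward(model$params, hf$cache, dlogits)
        dX <- hb$dX
        hb$dX <- NULL
        grads <- hb
        for (ci in seq_along(chans)) {
          ch <- chans[ci]
          rows <- if (channel_side(ch) == "drug") di[idx] else si[idx]
          dblock <- dX[, col_start[ci]:col_end[ci], drop = FALSE]
          n_nodes <- if (channel_side(ch) == "drug") length(model$drug_ids) else length(model$dis_ids)
          dH <- matrix(0, n_nodes, final_dims[ci])
          agg_rows <- rowsum(dblock, group = rows)
          dH[as.integer(rownames(agg_rows)), ] <- agg_rows
          grads <- c(grads, backward_channel(
            model$params, ch, model$ops[[channel_side(ch)]], fwd[[ch]]$cache,
            dH, CHANNEL_DIMS[[ch]], model$config$aggregator
          ))
        }
        # L2 decay on weight matrices
        for (nm in grep("\\.W", names(grads), value = TRUE)) {
          grads[[nm]] <- grads[[nm]] + 2 * lambda / nb * model$params[[nm]]
        }
        adam_t <- adam_t + 1L
        for (nm in names(grads)) {
          g <- grads[[nm]]
          if (is.null(adam_m[[nm]])) {
            adam_m[[nm]] <- g * 0
            adam_v[[nm]] <- g * 0
          }
          adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g
          adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g^2
          mhat <- adam_m[[nm]] / (1 - b1^adam_t)
          vhat <- adam_v[[nm]] / (1 - b2^adam_t)
          model$params[[nm]] <- model$params[[nm]] -
            lr * mhat / (sqrt(vhat) + adam_eps)
        }
      }
      loss_hist[ep] <- ep_loss
      if (verbose) message(sprintf("epoch %d: loss %.4f", ep, ep_loss))
    }
  })
  model$loss_history <- loss_hist
  model$trained <- TRUE
  model
}

#' Score drug-disease pairs with a trained model
#'
#' Computes eval-mode embeddings (no dropout, deterministic sampling) and the
#' softmax probability of association for each requested pair.
#'
#' @param object A `drgcc_model`.
#' @param pairs Tibble with `drug_id`, `disease_id`; defaults to all pairs.
#' @param ... Unused.
#' @return Tibble `drug_id`, `disease_id`, `probability`.
#' @export
predict.drgcc_model <- function(object, pairs = NULL, ...) {
  if (is.null(pairs)) {
    pairs <- tidyr::expand_grid(drug_id = object$drug_ids,
                                disease_id = object$dis_ids)
  }
  di <- match(pairs$drug_id, object$drug_ids)
  si <- match(pairs$disease_id, object$dis_ids)
  if (anyNA(di) || anyNA(si)) abort("pairs mention IDs outside the model registries")
  emb <- model_embeddings(object)
  chans <- object$config$channels
  Xh <- do.call(cbind, lapply(chans, function(ch) {
    rows <- if (channel_side(ch) == "drug") di else si
    emb[[ch]][rows, , drop = FALSE]
  }))
  hf <- head_forward(object$params, Xh)
  tibble::tibble(
    drug_id = pairs$drug_id, disease_id = pairs$disease_id,
    probability = hf$probs[, 2]
  )
}

#' Inductively embed a node unseen during training
#'
#' Computes the frozen-weight embedding of a new node attached to one of the
#' networks by the same similarity construction. Existing nodes keep their
#' training-time neighbor samples, so their embeddings are unchanged; the new
#' node aggregates from its own top-`n_k` neighbors among the existing nodes,
#' layer by layer. A node with no edges and an all-zero feature vector cannot
#' be embedded.
#'
#' @param model A trained `drgcc_model`.
#' @param side `"drug"` or `"disease"`.
#' @param channel `"attr"` or `"clu"` feature channel.
#' @param new_weights Similarity of the new node to every existing node on
#'   that side (named or in registry order).
#' @param new_features Feature vector of the new node in that channel's input
#'   space.
#' @return Numeric embedding vector (the channel's output dimension).
#' @export
embed_new_node <- function(model, side = c("drug", "disease"),
                           channel = c("attr", "clu"),
                           new_weights, new_features) {
  side <- match.arg(side)
  channel <- match.arg(channel)
  ch <- paste0(if (side == "drug") "drug" else "dis", "_", channel)
  if (!ch %in% model$config$channels) {
    abort(sprintf("channel '%s' is not part of this model (mode '%s')",
                  ch, model$config$mode))
  }
  ids <- if (side == "drug") model$drug_ids else model$dis_ids
  stopifnot(length(new_weights) == length(ids))
  if (all(new_weights <= 0) && all(new_features == 0)) {
    abort("new node has no edges and no features; cannot embed")
  }
  nb <- {
    w <- as.numeric(new_weights)
    cand <- which(w > 0)
    cand[order(-w[cand], cand)][seq_len(min(model$config$n_k, length(cand)))]
  }
  opsd <- model$ops[[if (side == "drug") "drug" else "dis"]]
  fwd <- forward_channel(model$params, ch, opsd, model$features[[ch]],
                         CHANNEL_DIMS[[ch]], model$config$aggregator)
  h_new <- as.numeric(new_features)
  dims <- CHANNEL_DIMS[[ch]]
  for (l in seq_along(dims)) {
    H_prev <- if (l == 1) model$features[[ch]] else relu(fwd$cache[[l - 1]]$Z)
    W <- model$params[[sprintf("%s.W%d", ch, l)]]
    b <- model$params[[sprintf("%s.b%d", ch, l)]]
    extra <- list(
      Wp = model$params[[sprintf("%s.Wp%d", ch, l)]],
      bp = model$params[[sprintf("%s.bp%d", ch, l)]]
    )
    lst <- NULL
    if (model$config$aggregator == "lstm") {
      gates <- c("i", "f", "o", "g")
      lst <- c(
        setNames(lapply(gates, function(g)
          model$params[[sprintf("%s.lstmW%s%d", ch, g, l)]]), paste0("W", gates)),
        setNames(lapply(gates, function(g)
          model$params[[sprintf("%s.lstmU%s%d", ch, g, l)]]), paste0("U", gates)),
        setNames(lapply(gates, function(g)
          model$params[[sprintf("%s.lstmb%s%d", ch, g, l)]]), paste0("b", gates))
      )
    }
    h_new <- sage_aggregate(
      model$config$aggregator, h_new, H_prev[nb, , drop = FALSE], W, b,
      Wp = extra$Wp, bp = extra$bp, lstm = lst,
      perm_seed = derive_seed(l, "lstm-perm-new")
    )$h
  }
  h_new
}

#' Rank all drugs against a newly added disease (or vice versa)
#'
#' Embeds the new node inductively in the attribute channel (and, when
#' supplied, the clustering channel; a brand-new node has no row in the
#' association matrix, so its clustering-channel input defaults to zeros) and
#' scores it against every node of the other side.
#'
#' @param model A trained `drgcc_model` (mode `"both"` or matching channels).
#' @param side Side of the new node, `"disease"` (default) or `"drug"`.
#' @param new_weights Similarity of the new node to existing same-side nodes.
#' @param new_attr Attribute feature vector of the new node (required when
#'   the model uses attribute channels).
#' @param new_cluster Optional clustering feature vector; defaults to zeros.
#' @return Tibble of the other side's IDs with association probabilities,
#'   ranked descending.
#' @export
score_new_node <- function(model, side = c("disease", "drug"), new_weights,
                           new_attr = NULL, new_cluster = NULL) {
  side <- match.arg(side)
  side_key <- if (side == "drug") "drug" else "dis"
  chans <- model$config$channels
  emb <- model_embeddings(model)
  new_emb <- list()
  for (ch in chans[startsWith(chans, side_key)]) {
    kind <- if (endsWith(ch, "attr")) "attr" else "clu"
    x <- if (kind == "attr") new_attr else new_cluster
    if (is.null(x)) {
      if (kind == "attr") abort("`new_attr` is required for attribute channels")
      x <- numeric(ncol(model$features[[ch]]))
      d <- CHANNEL_DIMS[[ch]]
      new_emb[[ch]] <- numeric(d[length(d)])  # clustering channel zeroed
      next
    }
    new_emb[[ch]] <- embed_new_node(model, if (side_key == "drug") "drug" else "disease",
                                    kind, new_weights, x)
  }
  other_ids <- if (side == "drug") model$dis_ids else model$drug_ids
  Xh <- do.call(cbind, lapply(chans, function(ch) {
    if (startsWith(ch, side_key)) {
      matrix(new_emb[[ch]], length(other_ids),
             length(new_emb[[ch]]), byrow = TRUE)
    } else {
      emb[[ch]]
    }
  }))
  hf <- head_forward(model$params, Xh)
  out <- tibble::tibble(id = other_ids, probability = hf$probs[, 2])
  names(out)[1] <- if (side == "drug") "disease_id" else "drug_id"
  dplyr::arrange(out, dplyr::desc(.data$probability))
}

#' @export
print.drgcc_model <- function(x, ...) {
  cat(sprintf("Two-tower GraphSAGE model (%s aggregator, mode '%s')\n",
              x$config$aggregator, x$config$mode))
  cat(sprintf("  %d drugs, %d diseases; channels: %s\n",
              length(x$drug_ids), length(x$dis_ids),
              paste(x$config$channels, collapse = ", ")))
  if (x$trained) {
    cat(sprintf("  trained %d epochs; loss %.4f -> %.4f\n",
                length(x$loss_history), x$loss_history[1],
                x$loss_history[length(x$loss_history)]))
  } else {
    cat("  untrained\n")
  }
  invisible(x)
}

#' @rdname train_drgcc
#' @param x A `drgcc_model`.
#' @param ... Unused.
#' @method tidy drgcc_model
#' @export
tidy.drgcc_model <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' @rdname train_drgcc
#' @param object A `drgcc_model`.
#' @method autoplot drgcc_model
#' @export
autoplot.drgcc_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training loss",
                  title = "Training loss history")
}
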