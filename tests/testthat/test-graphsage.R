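test_that("neighbor sampling takes highest-weight neighbors with index ties", {
  net <- named_symmetric(matrix(0, 5, 5), paste0("n", 1:5))
  net[1, 2] <- net[2, 1] <- 0.9
  net[1, 3] <- net[3, 1] <- 0.9
  net[1, 4] <- net[4, 1] <- 0.5
  diag(net) <- 1
  s <- sample_neighbors(net, n_k = 2)
  expect_equal(s[[1]], c(2L, 3L))              # tie 2 vs 3 broken by index
  expect_equal(s[[4]], 1L)                     # fewer neighbors than n_k
  expect_equal(s[[5]], integer(0))             # isolated
})

test_that("top-down expansion covers a two-hop path and star leaves", {
  # path a-b-c: two sampling layers from {a} must reach c (edge b-c is b's
  # strongest, so the single sampled neighbor of b is c)
  path <- named_symmetric(matrix(0, 3, 3), c("a", "b", "c"))
  path["a", "b"] <- path["b", "a"] <- 0.5
  path["b", "c"] <- path["c", "b"] <- 1
  nb <- sample_neighborhoods("a", path, L = 2, n_k = 1)
  expect_true(all(1:3 %in% nb$sets$B0))
  expect_equal(nb$sets$B2, 1L)
  # star: center with 3 leaves and n_k = 5 samples all leaves
  star <- named_symmetric(matrix(0, 4, 4), c("c", "l1", "l2", "l3"))
  star[1, 2:4] <- star[2:4, 1] <- 1
  nbs <- sample_neighborhoods("c", star, L = 1, n_k = 5)
  expect_equal(nbs$samples[[1]], 2:4)
})

test_that("aggregators match hand-computed values", {
  h_self <- c(1, 2)
  nb <- rbind(c(1, 5), c(3, 2))
  W <- diag(4)[, 1:2]                          # pass-through of concat halves
  # identical neighbor vectors: mean aggregation returns that vector
  same <- rbind(c(4, 7), c(4, 7), c(4, 7))
  out <- sage_aggregate("mean", h_self, same, W = diag(4), b = rep(0, 4),
                        sigma = identity)
  expect_equal(out$aggregated, c(4, 7))
  expect_equal(out$h, c(h_self, 4, 7))
  # maxpool with identity inner transform: elementwise maximum
  outm <- sage_aggregate("maxpool", h_self, nb, W = diag(4), b = rep(0, 4),
                         Wp = diag(2), bp = c(0, 0),
                         sigma = identity, sigma_inner = identity)
  expect_equal(outm$aggregated, c(3, 5))
  # gcn averages self with neighbors, no concatenation
  outg <- sage_aggregate("gcn", h_self, nb, W = diag(2), b = c(0, 0),
                         sigma = identity)
  expect_equal(outg$h, colMeans(rbind(h_self, nb)))
  # empty neighbor set aggregates over the node itself
  oute <- sage_aggregate("mean", h_self, matrix(0, 0, 2), W = diag(4),
                         b = rep(0, 4), sigma = identity)
  expect_equal(oute$aggregated, h_self)
})

test_that("non-recurrent aggregators are permutation invariant; lstm is not forced to be", {
  set.seed(79)
  h_self <- rnorm(4)
  nb <- matrix(rnorm(6 * 4), 6, 4)
  W <- matrix(rnorm(8 * 3), 8, 3)
  Wg <- matrix(rnorm(4 * 3), 4, 3)
  Wp <- matrix(rnorm(16), 4, 4)
  args <- list(b = rnorm(3), Wp = Wp, bp = rnorm(4))
  base <- lapply(c("mean", "meanpool", "maxpool", "gcn"), function(k) {
    Wk <- if (k == "gcn") Wg else W
    do.call(sage_aggregate, c(list(k, h_self, nb, W = Wk), args))$h
  })
  for (shuffle in 1:100) {
    ord <- sample(6)
    for (i in seq_along(base)) {
      k <- c("mean", "meanpool", "maxpool", "gcn")[i]
      Wk <- if (k == "gcn") Wg else W
      out <- do.call(sage_aggregate,
                     c(list(k, h_self, nb[ord, ], W = Wk), args))$h
      expect_equal(out, base[[i]], tolerance = 1e-12)
    }
  }
})

test_that("single-layer embedding matches a hand computation", {
  net <- named_symmetric(matrix(c(0, 1, 1, 0), 2, 2), c("a", "b"))
  x <- matrix(c(1, 3, 2, 4), 2, 2)             # rows: features of a, b
  feats <- list(drug_attr = x, dis_attr = x, drug_clu = x, dis_clu = x)
  m <- tiny_model(seed = 5)
  W <- matrix(rnorm(4 * 3), 4, 3)
  b <- rnorm(3)
  ops <- list(A = matrix(c(0, 1, 1, 0), 2, 2))
  fwd <- drgcc:::forward_channel(list(ch.W1 = W, ch.b1 = b), "ch", ops, x,
                                 dims = 3L, aggregator = "mean")
  by_hand <- pmax(cbind(x, x[2:1, ]) %*% W +
                    matrix(b, 2, 3, byrow = TRUE), 0)
  expect_equal(fwd$H, by_hand)
  # zero weights and bias with identity-like activation give zero embeddings
  fwd0 <- drgcc:::forward_channel(list(ch.W1 = W * 0, ch.b1 = b * 0), "ch",
                                  ops, x, dims = 3L, aggregator = "mean")
  expect_true(all(fwd0$H == 0))
})

test_that("analytic gradients agree with finite differences", {
  for (aggr in c("mean", "gcn", "meanpool")) {
    m <- tiny_model(seed = 3, aggregator = aggr)
    set.seed(4)
    pairs <- tibble::tibble(
      drug_id = sample(m$drug_ids, 8, TRUE),
      disease_id = sample(m$dis_ids, 8, TRUE),
      label = rbinom(8, 1, 0.5)
    )
    di <- match(pairs$drug_id, m$drug_ids)
    si <- match(pairs$disease_id, m$dis_ids)
    y <- pairs$label
    chans <- m$config$channels
    dims_final <- vapply(chans, function(ch) {
      d <- drgcc:::CHANNEL_DIMS[[ch]]
      as.integer(d[length(d)])
    }, integer(1))
    ce <- cumsum(dims_final); cs_ <- ce - dims_final + 1L
    loss_of <- function(params) {
      m2 <- m; m2$params <- params
      fwd <- drgcc:::model_embeddings(m2)
      Xh <- do.call(cbind, lapply(chans, function(ch) {
        rows <- if (drgcc:::channel_side(ch) == "drug") di else si
        fwd[[ch]][rows, , drop = FALSE]
      }))
      hf <- drgcc:::head_forward(params, Xh)
      sage_loss(hf$probs[, 2], y, params, lambda = 0.01)
    }
    fwd <- drgcc:::model_embeddings(m, with_cache = TRUE)
    Xh <- do.call(cbind, lapply(chans, function(ch) {
      rows <- if (drgcc:::channel_side(ch) == "drug") di else si
      fwd[[ch]]$H[rows, , drop = FALSE]
    }))
    hf <- drgcc:::head_forward(m$params, Xh)
    hb <- drgcc:::head_backward(m$params, hf$cache,
                                hf$probs - cbind(1 - y, y))
    dX <- hb$dX; hb$dX <- NULL
    grads <- hb
    for (ci in seq_along(chans)) {
      ch <- chans[ci]
      rows <- if (drgcc:::channel_side(ch) == "drug") di else si
      dH <- matrix(0, nrow(fwd[[ch]]$H), dims_final[ci])
      ar <- rowsum(dX[, cs_[ci]:ce[ci], drop = FALSE], group = rows)
      dH[as.integer(rownames(ar)), ] <- ar
      grads <- c(grads, drgcc:::backward_channel(
        m$params, ch, m$ops[[drgcc:::channel_side(ch)]], fwd[[ch]]$cache,
        dH, drgcc:::CHANNEL_DIMS[[ch]], aggr
      ))
    }
    for (nm in grep("\\.W", names(grads), value = TRUE)) {
      grads[[nm]] <- grads[[nm]] + 2 * 0.01 / length(y) * m$params[[nm]]
    }
    eps <- 1e-5
    for (nm in c("drug_attr.W1", "dis_clu.W2", "head.W1", "head.b3")) {
      for (i in seq_len(min(4, length(m$params[[nm]])))) {
        p_hi <- m$params; p_hi[[nm]][i] <- p_hi[[nm]][i] + eps
        p_lo <- m$params; p_lo[[nm]][i] <- p_lo[[nm]][i] - eps
        num <- (loss_of(p_hi) - loss_of(p_lo)) / (2 * eps)
        expect_equal(unname(grads[[nm]][i]), num, tolerance = 1e-4)
      }
    }
  }
})

test_that("pair scoring is deterministic, softmax-normalized and symmetric at equal logits", {
  m <- tiny_model(seed = 9)
  pairs <- tibble::tibble(drug_id = c("d01", "d01"), disease_id = c("s01", "s01"))
  p <- predict(m, pairs)
  expect_equal(p$probability[1], p$probability[2])
  # probabilities are a proper softmax: both classes sum to one
  emb <- drgcc:::model_embeddings(m)
  Xh <- cbind(emb$drug_attr[1, , drop = FALSE], emb$drug_clu[1, , drop = FALSE],
              emb$dis_attr[1, , drop = FALSE], emb$dis_clu[1, , drop = FALSE])
  hf <- drgcc:::head_forward(m$params, Xh)
  expect_equal(unname(rowSums(hf$probs)), 1)
  expect_true(all(hf$probs > 0 & hf$probs < 1))
  # equal logits give probability one half
  hf0 <- drgcc:::head_forward(list(head.W1 = matrix(0, 2, 2),
                                   head.b1 = c(0, 0)),
                              matrix(rnorm(2), 1, 2))
  expect_equal(hf0$probs[1, 2], 0.5)
  expect_error(predict(m, tibble::tibble(drug_id = "zz", disease_id = "s01")),
               "outside the model registries")
})

test_that("the loss matches hand evaluation and includes weight decay", {
  expect_equal(sage_loss(0.5, 1, lambda = 0), -log(0.5))
  expect_lt(sage_loss(c(1, 0), c(1, 0), lambda = 0), 1e-8)
  params <- list(x.W1 = matrix(2, 1, 1), x.b1 = 5)
  expect_equal(sage_loss(0.5, 1, params, lambda = 0.01),
               -log(0.5) + 0.01 * 4)            # bias excluded from penalty
})

test_that("training reduces the loss and is reproducible under a seed", {
  m <- tiny_model(seed = 13)
  set.seed(14)
  pairs <- tibble::tibble(
    drug_id = rep(m$drug_ids, each = 3),
    disease_id = sample(m$dis_ids, 24, TRUE),
    label = rbinom(24, 1, 0.5)
  )
  t1 <- train_drgcc(m, pairs, epochs = 8, batch_size = 8, seed = 15)
  expect_lt(t1$loss_history[8], t1$loss_history[1])
  t2 <- train_drgcc(m, pairs, epochs = 8, batch_size = 8, seed = 15)
  expect_identical(t1$params, t2$params)
  expect_equal(nrow(tidy(t1)), 8)
  expect_s3_class(autoplot(t1), "ggplot")
  m_lstm <- tiny_model(seed = 13, aggregator = "lstm")
  expect_error(train_drgcc(m_lstm, pairs), "not implemented")
})

test_that("inductive embedding reproduces duplicates and leaves others unchanged", {
  m <- tiny_model(seed = 17)
  set.seed(18)
  pairs <- tibble::tibble(
    drug_id = sample(m$drug_ids, 20, TRUE),
    disease_id = sample(m$dis_ids, 20, TRUE),
    label = rbinom(20, 1, 0.5)
  )
  tr <- train_drgcc(m, pairs, epochs = 3, batch_size = 8, seed = 19)
  before <- drgcc:::model_embeddings(tr)
  v <- 3
  w <- tr$dis_net[v, ]
  w[v] <- 0                                    # same edges as the original
  dup <- embed_new_node(tr, "disease", "attr", w, tr$features$dis_attr[v, ])
  expect_equal(dup, unname(before$dis_attr[v, ]), tolerance = 1e-12)
  after <- drgcc:::model_embeddings(tr)        # embedding a node is read-only
  expect_identical(before, after)
  expect_error(
    embed_new_node(tr, "disease", "attr", numeric(length(tr$dis_ids)),
                   numeric(4)),
    "no edges"
  )
  ranked <- score_new_node(tr, "disease", w,
                           new_attr = tr$features$dis_attr[v, ])
  expect_equal(nrow(ranked), length(tr$drug_ids))
  expect_true(all(diff(ranked$probability) <= 0))
})
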