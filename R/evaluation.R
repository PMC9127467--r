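# Cross-validation harness: stratified k-fold splits with re-randomized
# repeats, rank-based threshold-free metrics, and thresholded metrics at the
# F1-maximizing cut.

#' Stratified k-fold assignments for labeled pairs
#'
#' Positives and negatives are split into `k` near-equal folds separately, so
#' class balance is preserved in each fold; each repeat re-randomizes the
#' partition. Every pair is tested exactly once per repeat.
#'
#' @param pairs Tibble with a `label` column (0/1).
#' @param k Number of folds (default 5).
#' @param repeats Number of re-randomized repetitions (default 1).
#' @param seed RNG seed.
#' @return Tibble: `repeat_id`, `fold`, plus the columns of `pairs`.
#' @export
kfold_split <- function(pairs, k = 5, repeats = 1, seed = 1) {
  stopifnot(is.data.frame(pairs), "label" %in% names(pairs))
  if (k < 2) abort("k must be at least 2")
  if (nrow(pairs) < k) abort("fewer pairs than folds")
  purrr::map_dfr(seq_len(repeats), function(r) {
    fold <- integer(nrow(pairs))
    with_seed(derive_seed(seed, paste0("fold", r)), {
      for (cl in unique(pairs$label)) {
        idx <- which(pairs$label == cl)
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    })
    dplyr::bind_cols(tibble::tibble(repeat_id = r, fold = fold), pairs)
  })
}

#' Threshold-free and thresholded classification metrics
#'
#' AUC is the rank statistic (equal to the concordant-pair fraction, ties
#' counting one half); the precision-recall AUC is the trapezoidal area over
#' the precision-recall points at all observed thresholds. The remaining five
#' metrics are computed at the decision threshold that maximizes F1
#' (classifying `score >= threshold` as positive; ties resolved toward the
#' lowest threshold).
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return One-row tibble: `auc`, `prauc`, `f1_score`, `accuracy`,
#'   `specificity`, `precision`, `recall`, `threshold`.
#' @export
compute_metrics <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) abort("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)

  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & labels == 0), numeric(1))
  prec <- tp / pmax(tp + fp, 1)
  rec <- tp / npos
  # PR curve from recall 0 upward; anchor at (0, precision of first point)
  rec_c <- c(0, rec)
  prec_c <- c(prec[1], prec)
  prauc <- sum(diff(rec_c) * (utils::head(prec_c, -1) + prec_c[-1]) / 2)

  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  best <- which(f1 == max(f1))
  best <- best[which.min(thr[best])]
  t_star <- thr[best]
  pred <- as.integer(scores >= t_star)
  tp_b <- sum(pred == 1 & labels == 1)
  tn_b <- sum(pred == 0 & labels == 0)
  fp_b <- sum(pred == 1 & labels == 0)
  fn_b <- sum(pred == 0 & labels == 1)
  tibble::tibble(
    auc = auc, prauc = prauc, f1_score = f1[best],
    accuracy = (tp_b + tn_b) / length(labels),
    specificity = tn_b / (tn_b + fp_b),
    precision = if (tp_b + fp_b > 0) tp_b / (tp_b + fp_b) else 0,
    recall = tp_b / (tp_b + fn_b),
    threshold = t_star
  )
}

# Fit the fold-specific model (constrained factorization + tower training)
# and return the trained model.
fit_fold_model <- function(inputs, config, train_pairs, mode, seed) {
  feats <- list(drug_attr = inputs$F_drug, dis_attr = inputs$F_dis)
  if (mode %in% c("both", "cluster")) {
    P <- matrix(0, nrow(inputs$Y), ncol(inputs$Y), dimnames = dimnames(inputs$Y))
    P[cbind(match(train_pairs$drug_id, rownames(inputs$Y)),
            match(train_pairs$disease_id, colnames(inputs$Y)))] <- 1
    cmf <- fit_cmf(inputs$Y * P, P, inputs$assign_drug, inputs$assign_dis,
                   k = config$k, alpha = config$alpha, beta = config$beta,
                   max_iter = config$cmf_max_iter, tol = config$cmf_tol,
                   seed = derive_seed(seed, "cmf"))
    feats$drug_clu <- cmf$U
    feats$dis_clu <- t(cmf$V)
  }
  model <- drgcc_model(
    inputs$drug_net, inputs$dis_net, feats, mode = mode,
    aggregator = config$aggregator, n_k = config$n_k,
    lambda = config$lambda, dropout = config$dropout,
    head_dims = config$head_dims, seed = derive_seed(seed, "model")
  )
  train_drgcc(model, train_pairs, epochs = config$epochs, lr = config$lr,
              batch_size = config$batch_size, seed = derive_seed(seed, "sgd"))
}

#' Cross-validated evaluation of the full method
#'
#' Runs stratified k-fold cross-validation on the labeled pair set: per fold,
#' the clustering features are refit with the observation mask restricted to
#' the training pairs, the two-tower model is trained on the training pairs,
#' and the held-out pairs are scored. Metrics per fold come from
#' [compute_metrics()].
#'
#' @param inputs Prepared inputs from [prepare_inputs()].
#' @param config Configuration list from [drgcc_config()].
#' @param folds,repeats Cross-validation geometry (defaults 5 and 1).
#' @param seed Seed controlling splits, factorization and training.
#' @param mode Feature mode: `"both"`, `"attribute"`, or `"cluster"`.
#' @param max_eval_folds Optionally evaluate only the first few folds of each
#'   repeat (identical folds across modes for a given seed), bounding compute
#'   for ablation sweeps; default evaluates all folds.
#' @return An object of class `drgcc_eval` with per-fold metrics.
#' @export
evaluate_cv <- function(inputs, config = drgcc_config(), folds = 5,
                        repeats = 1, seed = 1, mode = "both",
                        max_eval_folds = folds) {
  splits <- kfold_split(inputs$pairs, k = folds, repeats = repeats, seed = seed)
  res <- list()
  for (r in seq_len(repeats)) {
    for (f in seq_len(min(folds, max_eval_folds))) {
      this <- splits[splits$repeat_id == r, ]
      train_pairs <- this[this$fold != f, c("drug_id", "disease_id", "label")]
      test_pairs <- this[this$fold == f, c("drug_id", "disease_id", "label")]
      model <- fit_fold_model(inputs, config, train_pairs, mode,
                              seed = derive_seed(seed, sprintf("r%df%d", r, f)))
      pred <- predict(model, test_pairs)
      met <- compute_metrics(pred$probability, test_pairs$label)
      res[[length(res) + 1]] <- dplyr::bind_cols(
        tibble::tibble(repeat_id = r, fold = f), met
      )
    }
  }
  structure(
    list(metrics = dplyr::bind_rows(res), mode = mode, folds = folds,
         repeats = repeats, seed = seed),
    class = "drgcc_eval"
  )
}

#' Ablation over feature channels
#'
#' Evaluates the combined model and the two single-channel variants
#' (attribute-only, clustering-only) on identical fold splits (same seed),
#' mirroring the question of whether network clustering features add
#' predictive value over attribute features alone.
#'
#' @inheritParams evaluate_cv
#' @return Tibble of per-fold metrics with a `mode` column.
#' @export
run_ablation <- function(inputs, config = drgcc_config(), folds = 5,
                         repeats = 1, seed = 1, max_eval_folds = folds) {
  purrr::map_dfr(c("both", "attribute", "cluster"), function(mode) {
    ev <- evaluate_cv(inputs, config, folds = folds, repeats = repeats,
                      seed = seed, mode = mode,
                      max_eval_folds = max_eval_folds)
    dplyr::mutate(ev$metrics, mode = mode, .before = 1)
  })
}

#' @export
print.drgcc_eval <- function(x, ...) {
  cat(sprintf("Cross-validation (%d-fold x %d repeats, mode '%s')\n",
              x$folds, x$repeats, x$mode))
  print(glance(x))
  invisible(x)
}

#' @rdname evaluate_cv
#' @param x A `drgcc_eval` object.
#' @param ... Unused.
#' @method tidy drgcc_eval
#' @export
tidy.drgcc_eval <- function(x, ...) x$metrics

#' @rdname evaluate_cv
#' @param object A `drgcc_eval` object.
#' @method glance drgcc_eval
#' @export
glance.drgcc_eval <- function(x, ...) {
  m <- x$metrics[, c("auc", "prauc", "f1_score", "accuracy", "specificity",
                     "precision", "recall")]
  out <- tibble::as_tibble(as.list(colMeans(m)))
  sds <- tibble::as_tibble(as.list(vapply(m, stats::sd, numeric(1))))
  names(sds) <- paste0(names(sds), "_sd")
  dplyr::bind_cols(out, sds, tibble::tibble(n_folds = nrow(x$metrics)))
}

#' @rdname evaluate_cv
#' @method autoplot drgcc_eval
#' @export
autoplot.drgcc_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$metrics,
    cols = c("auc", "prauc", "f1_score", "accuracy", "specificity",
             "precision", "recall"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "value",
                  title = sprintf("Cross-validated metrics (mode '%s')",
                                  object$mode)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
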