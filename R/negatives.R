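# Reliable-negative selection. Unknown drug-disease pairs are scored by an
# alternating (bi-) random walk over the two similarity networks; the
# lowest-scoring unknown pairs are the least supported by network proximity
# and serve as negative training examples, in place of uniform random
# negatives.

row_stochastic <- function(net) {
  rs <- rowSums(net)
  t_mat <- net / ifelse(rs > 0, rs, 1)
  # all-zero rows keep their prior score: lazy self-transition
  zero <- rs == 0
  if (any(zero)) t_mat[cbind(which(zero), which(zero))] <- 1
  t_mat
}

#' Bi-random-walk association scores
#'
#' Propagates the known association matrix through row-stochastic transition
#' matrices built from the drug and disease networks: at step `t` a left
#' (drug-side) walk `(1 - restart) * T_drug %*% R + restart * Y` and a right
#' (disease-side) walk `(1 - restart) * R %*% T_dis + restart * Y` are taken
#' while their step budgets last, and their results averaged. With zero steps
#' on both sides, or restart probability 1, the scores equal `Y`.
#'
#' @param Y Binary drug x disease association matrix with ID dimnames.
#' @param drug_net,dis_net Symmetric nonnegative networks over the matching
#'   registries.
#' @param left_steps,right_steps Walk lengths on each side (defaults 2).
#' @param restart Restart probability in `[0, 1]` (default 0.3).
#' @return Nonnegative score matrix shaped like `Y`.
#' @export
birw_scores <- function(Y, drug_net, dis_net, left_steps = 2, right_steps = 2,
                        restart = 0.3) {
  stopifnot(is.matrix(Y), restart >= 0, restart <= 1,
            left_steps >= 0, right_steps >= 0)
  check_registry_match(rownames(Y), rownames(drug_net), "Y rows", "drug_net")
  check_registry_match(colnames(Y), rownames(dis_net), "Y cols", "dis_net")
  td <- row_stochastic(drug_net)
  ts <- row_stochastic(dis_net)
  r <- Y
  for (t_step in seq_len(max(left_steps, right_steps))) {
    parts <- list()
    if (t_step <= left_steps) {
      parts <- c(parts, list((1 - restart) * (td %*% r) + restart * Y))
    }
    if (t_step <= right_steps) {
      parts <- c(parts, list((1 - restart) * (r %*% ts) + restart * Y))
    }
    r <- Reduce(`+`, parts) / length(parts)
  }
  dimnames(r) <- dimnames(Y)
  r
}

#' Select reliable negative pairs
#'
#' Returns the `count` unknown pairs (entries with `Y = 0`) with the smallest
#' walk scores. Ties are broken by a seeded shuffle, then by lexicographic
#' pair index, so the selection is deterministic given the seed and disjoint
#' from the positives by construction.
#'
#' @param scores Score matrix from [birw_scores()].
#' @param Y Binary association matrix of the same shape.
#' @param count Number of negatives; defaults to the number of positives.
#' @param seed Tie-break seed.
#' @return Tibble `drug_id`, `disease_id`, `score`, one row per negative.
#' @export
select_negatives <- function(scores, Y, count = NULL, seed = 1) {
  stopifnot(is.matrix(scores), all(dim(scores) == dim(Y)))
  count <- count %||% sum(Y == 1)
  unknown <- which(Y == 0)
  if (count > length(unknown)) {
    abort(sprintf("requested %d negatives but only %d unknown pairs exist",
                  count, length(unknown)))
  }
  shuffle <- with_seed(derive_seed(seed, "neg-ties"),
                       sample.int(length(unknown)))
  ord <- order(scores[unknown], shuffle, unknown)
  pick <- unknown[ord[seq_len(count)]]
  ij <- arrayInd(pick, dim(Y))
  tibble::tibble(
    drug_id = rownames(Y)[ij[, 1]],
    disease_id = colnames(Y)[ij[, 2]],
    score = scores[pick]
  )
}

#' Assemble the labeled pair set
#'
#' Positives are the known associations; negatives come from
#' [select_negatives()]. The two sets are disjoint by construction.
#'
#' @param Y Binary association matrix.
#' @param negatives Tibble from [select_negatives()].
#' @return Tibble `drug_id`, `disease_id`, `label`.
#' @export
labeled_pairs <- function(Y, negatives) {
  pos <- which(Y == 1)
  ij <- arrayInd(pos, dim(Y))
  dplyr::bind_rows(
    tibble::tibble(drug_id = rownames(Y)[ij[, 1]],
                   disease_id = colnames(Y)[ij[, 2]], label = 1L),
    tibble::tibble(drug_id = negatives$drug_id,
                   disease_id = negatives$disease_id, label = 0L)
  )
}
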