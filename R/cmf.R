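# Clustering-constrained nonnegative matrix factorization. The association
# matrix Y (drugs x diseases) is factorized as U V under an observation mask
# P (1 on labeled positive+negative pairs), with ridge shrinkage on both
# factors and a clustering reward that pushes per-cluster mean factor vectors
# away from the global mean, so entities from different network clusters get
# distinguishable latent features.

#' Cluster-averaging operators for the factorization constraint
#'
#' Builds the block-diagonal cluster-averaging operator `A_z` and the global-
#' averaging operator `B` for one side of the factorization. For the drug side
#' (row factors, drugs x k) both are `c x N`: `A_z %*% U` stacks the
#' per-cluster mean feature vectors and `B %*% U` repeats the global mean.
#' For the disease side (column factors, k x N) both are `N x c` and act on
#' the right: `V %*% A_z`, `V %*% B`.
#'
#' @param assignment Tibble with `entity_id`, `cluster` (as from
#'   [cluster_network()]).
#' @param side `"drug"` for row factors, `"disease"` for column factors.
#' @return List with `A_z`, `B`, `sizes`.
#' @export
build_averaging_operators <- function(assignment, side = c("drug", "disease")) {
  side <- match.arg(side)
  lab <- as.integer(assignment$cluster)
  n <- length(lab)
  c_n <- max(lab)
  sizes <- tabulate(lab, nbins = c_n)
  if (any(sizes == 0)) abort("empty cluster in assignment")
  a <- matrix(0, c_n, n)
  a[cbind(lab, seq_len(n))] <- 1 / sizes[lab]
  b <- matrix(1 / n, c_n, n)
  if (side == "disease") {
    a <- t(a)
    b <- t(b)
  }
  list(A_z = a, B = b, sizes = sizes)
}

check_cmf_params <- function(alpha, beta) {
  if (1 - 2 * alpha - 2 * beta <= 0) {
    abort("control parameters must satisfy 1 - 2*alpha - 2*beta > 0")
  }
  invisible(TRUE)
}

#' Objective of the clustering-constrained factorization
#'
#' Evaluates the objective either as the direct penalized sum of squares
#' (`form = "sum"`): masked reconstruction error, ridge terms, minus the
#' cluster-separation reward on each side; or via the algebraically equivalent
#' trace expansion (`form = "trace"`). The two forms agreeing is a correctness
#' check on the operator algebra.
#'
#' @param U,V Nonnegative factors, drugs x k and k x diseases.
#' @param Y Binary association matrix.
#' @param P Binary observation mask (1 on labeled pairs).
#' @param alpha,beta Control parameters, `1 - 2*alpha - 2*beta > 0`.
#' @param ops_drug,ops_dis Averaging operators from
#'   [build_averaging_operators()].
#' @param form `"sum"` or `"trace"`.
#' @return Scalar objective value.
#' @export
cmf_objective <- function(U, V, Y, P, alpha, beta, ops_drug, ops_dis,
                          form = c("sum", "trace")) {
  form <- match.arg(form)
  check_cmf_params(alpha, beta)
  g <- 1 - 2 * alpha - 2 * beta
  Ad <- ops_drug$A_z; Bd <- ops_drug$B
  As <- ops_dis$A_z; Bs <- ops_dis$B
  if (form == "sum") {
    resid <- P * (Y - U %*% V)
    du <- Ad %*% U - Bd %*% U           # per-cluster mean minus global mean
    dv <- V %*% As - V %*% Bs
    g / 2 * sum(resid^2) +
      alpha / 2 * sum(U^2) - beta / 2 * sum(du^2) +
      alpha / 2 * sum(V^2) - beta / 2 * sum(dv^2)
  } else {
    PY <- P * Y
    PUV <- P * (U %*% V)
    tr <- function(m) sum(diag(m))
    g / 2 * tr(t(PY) %*% PY) -
      g * tr(PUV %*% t(PY)) +
      g / 2 * tr(PUV %*% t(PUV)) +
      alpha / 2 * tr(U %*% t(U)) +
      alpha / 2 * tr(V %*% t(V)) -
      beta / 2 * tr(Ad %*% U %*% t(U) %*% t(Ad)) +
      beta * tr(Ad %*% U %*% t(U) %*% t(Bd)) -
      beta / 2 * tr(Bd %*% U %*% t(U) %*% t(Bd)) -
      beta / 2 * tr(t(As) %*% t(V) %*% V %*% As) +
      beta * tr(t(As) %*% t(V) %*% V %*% Bs) -
      beta / 2 * tr(t(Bs) %*% t(V) %*% V %*% Bs)
  }
}

#' One multiplicative update of the constrained factorization
#'
#' Applies the two multiplicative rules derived from the objective's partial
#' derivatives, with an epsilon-stabilized denominator. `V` is updated with
#' the refreshed `U` (standard alternating practice). Nonnegativity is
#' preserved because every factor in numerator and denominator is
#' nonnegative.
#'
#' @inheritParams cmf_objective
#' @param eps Denominator stabilizer (default 1e-12).
#' @return List with updated `U`, `V`.
#' @export
cmf_update <- function(U, V, Y, P, alpha, beta, ops_drug, ops_dis,
                       eps = 1e-12) {
  check_cmf_params(alpha, beta)
  g <- 1 - 2 * alpha - 2 * beta
  Ad <- ops_drug$A_z; Bd <- ops_drug$B
  As <- ops_dis$A_z; Bs <- ops_dis$B
  PY <- P * Y

  num_u <- g * (PY %*% t(V)) +
    beta * (t(Ad) %*% (Ad %*% U)) + beta * (t(Bd) %*% (Bd %*% U))
  den_u <- g * ((P * (U %*% V)) %*% t(V)) + alpha * U +
    beta * ((t(Bd) %*% Ad + t(Ad) %*% Bd) %*% U)
  U <- U * num_u / (den_u + eps)

  num_v <- g * (t(U) %*% PY) +
    beta * (V %*% As %*% t(As)) + beta * (V %*% Bs %*% t(Bs))
  den_v <- g * (t(U) %*% (P * (U %*% V))) + alpha * V +
    beta * (V %*% (Bs %*% t(As) + As %*% t(Bs)))
  V <- V * num_v / (den_v + eps)

  if (!all(is.finite(U)) || !all(is.finite(V))) {
    abort("non-finite factor entries produced by multiplicative update")
  }
  list(U = U, V = V)
}

#' Fit network clustering features by constrained factorization
#'
#' Initializes strictly positive factors and iterates the multiplicative
#' rules until the relative objective change falls below `tol` or `max_iter`
#' is reached. The rules are the printed fixed-point form of the gradient
#' and carry no monotonicity proof; the per-iteration objective trace is
#' returned so convergence can be inspected, and a warning is raised if the
#' objective increased anywhere along the run.
#'
#' @param Y Binary drug x disease association matrix (with ID dimnames).
#' @param P Binary observation mask of the same shape.
#' @param assign_drug,assign_dis Cluster assignments for each side.
#' @param k Latent feature dimension (default 200).
#' @param alpha,beta Control parameters (defaults 0.2, 0.1).
#' @param max_iter Iteration cap (default 1000).
#' @param tol Relative objective-change stopping tolerance (default 1e-6).
#' @param seed RNG seed for the uniform initialization.
#' @param eps Denominator stabilizer.
#' @return An object of class `cmf_fit`: factors `U` (drugs x k), `V`
#'   (k x diseases), the objective trace, iteration count and convergence
#'   flag.
#' @export
fit_cmf <- function(Y, P, assign_drug, assign_dis, k = 200, alpha = 0.2,
                    beta = 0.1, max_iter = 1000, tol = 1e-6, seed = 1,
                    eps = 1e-12) {
  stopifnot(is.matrix(Y), is.matrix(P), all(dim(Y) == dim(P)), k >= 1)
  check_cmf_params(alpha, beta)
  ops_drug <- build_averaging_operators(assign_drug, "drug")
  ops_dis <- build_averaging_operators(assign_dis, "disease")
  n <- nrow(Y); m <- ncol(Y)
  uv <- with_seed(seed, list(
    U = matrix(runif(n * k, 0.01, 1.01), n, k),
    V = matrix(runif(k * m, 0.01, 1.01), k, m)
  ))
  U <- uv$U; V <- uv$V
  obj <- numeric(max_iter + 1)
  obj[1] <- cmf_objective(U, V, Y, P, alpha, beta, ops_drug, ops_dis)
  it <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    upd <- cmf_update(U, V, Y, P, alpha, beta, ops_drug, ops_dis, eps = eps)
    U <- upd$U; V <- upd$V
    obj[it + 1] <- cmf_objective(U, V, Y, P, alpha, beta, ops_drug, ops_dis)
    if (!is.finite(obj[it + 1])) abort(sprintf("objective diverged at iteration %d", it))
    if (abs(obj[it + 1] - obj[it]) / max(abs(obj[it]), eps) < tol) {
      converged <- TRUE
      break
    }
  }
  obj <- obj[seq_len(it + 1)]
  if (any(diff(obj) > 1e-8 * max(abs(obj)))) {
    warn("objective increased during multiplicative updates; inspect the trace")
  }
  rownames(U) <- rownames(Y)
  colnames(V) <- colnames(Y)
  structure(
    list(U = U, V = V, objective = obj, iterations = it,
         converged = converged, k = k, alpha = alpha, beta = beta),
    class = "cmf_fit"
  )
}

#' @export
print.cmf_fit <- function(x, ...) {
  cat(sprintf(
    "Clustering-constrained factorization: %d drugs x %d diseases, k = %d\n",
    nrow(x$U), ncol(x$V), x$k
  ))
  cat(sprintf("  alpha = %g, beta = %g; %d iterations (%s)\n", x$alpha, x$beta,
              x$iterations, if (x$converged) "converged" else "iteration cap"))
  cat(sprintf("  objective: %.6g -> %.6g\n", x$objective[1],
              x$objective[length(x$objective)]))
  invisible(x)
}

#' @rdname fit_cmf
#' @param x A `cmf_fit` object.
#' @param ... Unused.
#' @method tidy cmf_fit
#' @export
tidy.cmf_fit <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$objective) - 1L, objective = x$objective)
}

#' @rdname fit_cmf
#' @method glance cmf_fit
#' @export
glance.cmf_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, alpha = x$alpha, beta = x$beta,
    iterations = x$iterations, converged = x$converged,
    initial_objective = x$objective[1],
    final_objective = x$objective[length(x$objective)]
  )
}

#' @rdname fit_cmf
#' @param object A `cmf_fit` object.
#' @method autoplot cmf_fit
#' @export
autoplot.cmf_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "objective",
                  title = "Constrained factorization objective trace")
}
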