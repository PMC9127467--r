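random_assignment <- function(ids, c_n) {
  lab <- rep_len(seq_len(c_n), length(ids))
  tibble::tibble(entity_id = ids, cluster = sample(lab))
}

test_that("averaging operators compute cluster and global means", {
  asg <- tibble::tibble(entity_id = c("a", "b", "c"), cluster = c(1, 1, 2))
  ops <- build_averaging_operators(asg, "drug")
  expect_equal(ops$A_z, matrix(c(0.5, 0, 0.5, 0, 0, 1), 2, 3))
  expect_equal(rowSums(ops$A_z), c(1, 1))
  expect_true(all(ops$B == 1 / 3))

  set.seed(31)
  U <- matrix(rnorm(24), 6, 4)
  asg6 <- random_assignment(paste0("d", 1:6), 3)
  opsd <- build_averaging_operators(asg6, "drug")
  expect_equal(opsd$A_z %*% U,
               unname(cluster_means_loop(U, asg6$cluster)))
  expect_equal(opsd$B %*% U,
               matrix(colMeans(U), 3, 4, byrow = TRUE))
  # disease side acts from the right on k x N factors
  V <- matrix(rnorm(20), 4, 5)
  asg5 <- random_assignment(paste0("s", 1:5), 2)
  opss <- build_averaging_operators(asg5, "disease")
  expect_equal(V %*% opss$A_z,
               unname(t(cluster_means_loop(t(V), asg5$cluster))))
  expect_error(
    build_averaging_operators(
      tibble::tibble(entity_id = "a", cluster = 2), "drug"
    ),
    "empty cluster"
  )
})

test_that("summation and trace forms of the objective agree", {
  set.seed(37)
  for (rep in 1:50) {
    n <- sample(4:9, 1); m <- sample(3:8, 1); k <- sample(2:4, 1)
    U <- matrix(runif(n * k), n, k)
    V <- matrix(runif(k * m), k, m)
    Y <- matrix(rbinom(n * m, 1, 0.4), n, m)
    P <- matrix(rbinom(n * m, 1, 0.6), n, m)
    od <- build_averaging_operators(random_assignment(paste0("d", 1:n), 2), "drug")
    os <- build_averaging_operators(random_assignment(paste0("s", 1:m), 2), "disease")
    j_sum <- cmf_objective(U, V, Y, P, 0.2, 0.1, od, os, form = "sum")
    j_tr <- cmf_objective(U, V, Y, P, 0.2, 0.1, od, os, form = "trace")
    expect_equal(j_sum, j_tr, tolerance = 1e-8)
  }
})

test_that("trace constraint equals loop-computed cluster-mean deviations", {
  set.seed(41)
  U <- matrix(runif(7 * 3), 7, 3)
  asg <- random_assignment(paste0("d", 1:7), 3)
  ops <- build_averaging_operators(asg, "drug")
  dev <- ops$A_z %*% U - ops$B %*% U
  trace_form <- sum(diag(dev %*% t(dev)))
  means <- cluster_means_loop(U, asg$cluster)
  loop_form <- sum(vapply(1:3, function(i) {
    sum((means[i, ] - colMeans(U))^2)
  }, numeric(1)))
  expect_equal(trace_form, loop_form, tolerance = 1e-10)
})

test_that("degenerate cases: zero residual and single-cluster constraint", {
  set.seed(43)
  U <- matrix(runif(12), 4, 3); V <- matrix(runif(9), 3, 3)
  od <- build_averaging_operators(random_assignment(paste0("d", 1:4), 2), "drug")
  os <- build_averaging_operators(random_assignment(paste0("s", 1:3), 2), "disease")
  # eps-free objective with alpha = beta = 0 vanishes at an exact factorization
  expect_equal(
    cmf_objective(U, V, U %*% V, matrix(1, 4, 3), 0, 0, od, os), 0,
    tolerance = 1e-12
  )
  # one cluster: per-cluster mean equals the global mean, constraint term 0
  od1 <- build_averaging_operators(
    tibble::tibble(entity_id = paste0("d", 1:4), cluster = 1), "drug")
  dev <- od1$A_z %*% U - od1$B %*% U
  expect_equal(sum(dev^2), 0, tolerance = 1e-20)
  expect_error(cmf_objective(U, V, U %*% V, matrix(1, 4, 3), 0.3, 0.3, od, os),
               "1 - 2\\*alpha")
})

test_that("multiplicative rule has exact factorizations as fixed points", {
  set.seed(47)
  U <- matrix(runif(10, 0.1, 1), 5, 2)
  V <- matrix(runif(8, 0.1, 1), 2, 4)
  od <- build_averaging_operators(random_assignment(paste0("d", 1:5), 2), "drug")
  os <- build_averaging_operators(random_assignment(paste0("s", 1:4), 2), "disease")
  up <- cmf_update(U, V, U %*% V, matrix(1, 5, 4), 0, 0, od, os)
  expect_equal(up$U, U, tolerance = 1e-9)
  expect_equal(up$V, V, tolerance = 1e-9)
})

test_that("a 1x1 update matches the hand-evaluated scalar rule", {
  od <- build_averaging_operators(tibble::tibble(entity_id = "d", cluster = 1), "drug")
  os <- build_averaging_operators(tibble::tibble(entity_id = "s", cluster = 1), "disease")
  u <- 0.5; v <- 0.4; y <- 1; alpha <- 0.2; beta <- 0.1
  g <- 1 - 2 * alpha - 2 * beta
  # A_z = B = [1] for a single entity, so the beta terms contribute
  # beta*(1+1)*u in the numerator and the same in the denominator
  num_u <- g * y * v + 2 * beta * u
  den_u <- g * (u * v) * v + alpha * u + 2 * beta * u
  u1 <- u * num_u / (den_u + 1e-12)
  num_v <- g * u1 * y + 2 * beta * v
  den_v <- g * u1 * (u1 * v) + alpha * v + 2 * beta * v
  v1 <- v * num_v / (den_v + 1e-12)
  up <- cmf_update(matrix(u), matrix(v), matrix(y), matrix(1),
                   alpha, beta, od, os)
  expect_equal(up$U[1, 1], u1, tolerance = 1e-12)
  expect_equal(up$V[1, 1], v1, tolerance = 1e-12)
})

test_that("nonnegativity is preserved across many iterations", {
  set.seed(53)
  n <- 8; m <- 6; k <- 3
  Y <- matrix(rbinom(n * m, 1, 0.4), n, m,
              dimnames = list(paste0("d", 1:n), paste0("s", 1:m)))
  P <- matrix(rbinom(n * m, 1, 0.7), n, m)
  ad <- random_assignment(rownames(Y), 2)
  as_ <- random_assignment(colnames(Y), 2)
  fit <- fit_cmf(Y, P, ad, as_, k = k, alpha = 0.2, beta = 0.1,
                 max_iter = 1000, tol = 0, seed = 59)
  expect_gte(min(fit$U), 0)
  expect_gte(min(fit$V), 0)
  expect_equal(fit$iterations, 1000L)
})

test_that("masked factorization recovers a planted low-rank product", {
  set.seed(61)
  U0 <- matrix(runif(12 * 2, 0.1, 1), 12, 2)
  V0 <- matrix(runif(2 * 10, 0.1, 1), 2, 10)
  Y <- U0 %*% V0
  dimnames(Y) <- list(paste0("d", 1:12), paste0("s", 1:10))
  P <- matrix(rbinom(120, 1, 0.8), 12, 10)
  ad <- random_assignment(rownames(Y), 2)
  as_ <- random_assignment(colnames(Y), 2)
  fit <- fit_cmf(Y, P, ad, as_, k = 2, alpha = 0, beta = 0,
                 max_iter = 2000, tol = 1e-12, seed = 67)
  # with alpha = beta = 0 the objective is half the masked squared error
  expect_lt(fit$objective[length(fit$objective)], 1e-3 * fit$objective[1])
})

test_that("fit accessors expose the objective trace and configuration", {
  set.seed(71)
  Y <- matrix(rbinom(20, 1, 0.5), 5, 4,
              dimnames = list(paste0("d", 1:5), paste0("s", 1:4)))
  fit <- fit_cmf(Y, matrix(1, 5, 4),
                 random_assignment(rownames(Y), 2),
                 random_assignment(colnames(Y), 2),
                 k = 2, max_iter = 50, seed = 73)
  td <- tidy(fit)
  expect_equal(td$iteration[1], 0L)
  expect_equal(nrow(td), fit$iterations + 1L)
  gl <- glance(fit)
  expect_equal(gl$k, 2)
  expect_equal(gl$final_objective, fit$objective[length(fit$objective)])
  expect_s3_class(autoplot(fit), "ggplot")
})
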