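test_that("fingerprint records decode per the stored byte layout", {
  zero <- c(as.raw(c(0, 0, 3, 113)), raw(111))  # 881 = 0x0371 big-endian
  bits <- decode_fingerprint(zero)
  expect_length(bits, 881)
  expect_true(all(bits == 0))
  one <- zero
  one[5] <- as.raw(0x80)                        # high bit of first payload byte
  bits1 <- decode_fingerprint(one)
  expect_equal(bits1[1], 1L)
  expect_true(all(bits1[-1] == 0))
  expect_error(decode_fingerprint(raw(10)), "115")
  bad <- zero
  bad[4] <- as.raw(0x70)
  expect_error(decode_fingerprint(bad), "expected 881")
})

test_that("encode/decode round trip is the identity and records are 115 bytes", {
  set.seed(7)
  for (i in 1:20) {
    bits <- rbinom(881, 1, runif(1, 0.05, 0.5))
    rec <- encode_fingerprint(bits)
    expect_length(rec, 115)                     # 4-byte prefix + 111 payload
    expect_identical(decode_fingerprint(rec), as.integer(bits))
  }
})

test_that("binary fingerprint files read back as incidence matrices", {
  set.seed(9)
  bits <- replicate(3, rbinom(881, 1, 0.2), simplify = FALSE)
  f <- withr::local_tempfile()
  writeBin(unlist(lapply(bits, encode_fingerprint)), f)
  m <- read_fingerprints(f, c("d1", "d2", "d3"))
  expect_equal(dim(m), c(3L, 881L))
  expect_equal(unname(m[2, ]), bits[[2]])
  expect_error(read_fingerprints(f, c("d1", "d2")), "3 records")
})

test_that("TF-IDF weighting matches hand evaluation and its invariants", {
  inc <- matrix(c(1, 1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE,
                dimnames = list(paste0("d", 1:3), paste0("s", 1:3)))
  w <- tfidf_weight(inc)
  # hand evaluation with natural log: tf rows 1/2 or 1; df = (2, 1, 1)
  expect_equal(w[1, 1], 0.5 * log(3 / 2))
  expect_equal(w[1, 2], 0.5 * log(3 / 1))
  expect_equal(w[2, 1], 1 * log(3 / 2))
  expect_equal(w[3, 3], 1 * log(3 / 1))
  expect_equal(w[2, 2], 0)

  set.seed(11)
  b <- matrix(rbinom(30 * 12, 1, 0.3), 30, 12)
  b[1, ] <- 0                                   # all-zero row passes through
  b[, 1] <- 1                                   # ubiquitous column zeroed
  ww <- tfidf_weight(b)
  expect_true(all(ww >= 0))
  expect_true(all(ww[1, ] == 0))
  expect_true(all(ww[, 1] == 0))
  # pre-idf term frequencies sum to 1 over present features
  tf_rows <- rowSums(b / pmax(rowSums(b), 1))
  expect_true(all(abs(tf_rows[rowSums(b) > 0] - 1) < 1e-12))
  # rarer columns never get smaller idf
  df <- colSums(b)
  idf <- ifelse(df > 0, log(nrow(b) / df), 0)
  ord <- order(df)
  expect_true(all(diff(idf[ord]) <= 1e-12))
})

test_that("SVD embedding satisfies exact-recovery and Eckart-Young checks", {
  set.seed(13)
  u <- runif(6); v <- runif(4)
  r1 <- outer(u, v)                             # rank-1 matrix
  emb <- svd_embed(r1, 1)
  right <- svd(r1)$v[, 1]
  if (max(abs(r1 %*% right)) > 0 && sum(emb[, 1] * (r1 %*% right)) < 0) right <- -right
  expect_equal(emb %*% t(right), r1, tolerance = 1e-10)

  m <- matrix(rnorm(48), 8, 6)
  full <- svd_embed(m, 6)
  expect_equal(qr.fitted(qr(full), m), m, tolerance = 1e-8)
  expect_equal(sum(full^2), sum(svd(m)$d^2), tolerance = 1e-8)
  d3 <- svd_embed(m, 3)
  sv <- svd(m)$d
  recon_err <- sqrt(sum(m^2) - sum(sv[1:3]^2))  # discarded spectrum
  # projecting onto the embedding's column space gives the best rank-3 fit
  proj <- qr.fitted(qr(d3), m)
  expect_equal(sqrt(sum((m - proj)^2)), recon_err, tolerance = 1e-8)
  expect_equal(sum(d3^2), sum(sv[1:3]^2), tolerance = 1e-8)
  expect_error(svd_embed(m, 7), "must be in")
})

test_that("SVD embedding is deterministic with a fixed sign convention", {
  set.seed(17)
  m <- matrix(rnorm(60), 10, 6)
  e1 <- svd_embed(m, 4)
  e2 <- svd_embed(m[, c(1:6)], 4)
  expect_identical(e1, e2)
  for (j in 1:4) {
    u <- e1[, j] / sqrt(sum(e1[, j]^2))
    expect_gt(u[which.max(abs(u))], 0)          # peak entry positive
  }
  # rank-deficient request zero-fills with a warning
  low <- outer(rnorm(5), rnorm(4))
  expect_warning(e3 <- svd_embed(low, 3), "rank")
  expect_true(all(e3[, 2:3] == 0))
})
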