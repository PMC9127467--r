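# Attribute features: substructure fingerprints for drugs, symptom profiles
# for diseases, TF-IDF weighting and truncated-SVD embedding.

FP_NBITS <- 881L    # substructure bits per compound
FP_PAYLOAD <- 111L  # ceil(881/8) bytes, 7 trailing pad bits
FP_RECORD <- 115L   # 4-byte big-endian bit-length prefix + payload

#' Decode a stored substructure fingerprint record
#'
#' PubChem-style substructure fingerprints are 881 ordered bits stored in
#' byte-packed form: a 4-byte big-endian prefix holding the bit length (881),
#' then 111 payload bytes (888 bits, the last 7 being padding). Bits are
#' packed most-significant-bit first, so bit 0 is the high bit of the first
#' payload byte.
#'
#' @param raw_record A raw vector of length 115.
#' @return Integer vector of 881 bits (0/1).
#' @export
decode_fingerprint <- function(raw_record) {
  if (!is.raw(raw_record) || length(raw_record) != FP_RECORD) {
    abort(sprintf("fingerprint record must be %d raw bytes", FP_RECORD))
  }
  prefix <- sum(as.integer(raw_record[1:4]) * 256^(3:0))
  if (prefix != FP_NBITS) {
    abort(sprintf("fingerprint prefix is %d, expected %d bits", prefix, FP_NBITS))
  }
  payload <- as.integer(raw_record[-(1:4)])
  j <- 0:(FP_NBITS - 1L)
  byte <- payload[j %/% 8L + 1L]
  bit <- bitwAnd(byte, bitwShiftL(1L, 7L - j %% 8L))
  as.integer(bit != 0L)
}

#' Encode 881 substructure bits into the stored record layout
#'
#' Inverse of [decode_fingerprint()]: writes the 4-byte big-endian bit-length
#' prefix (881) followed by the MSB-first byte-packed payload with 7 zero pad
#' bits, for a 115-byte record.
#'
#' @param bits Integer/logical vector of 881 bits.
#' @return Raw vector of length 115.
#' @export
encode_fingerprint <- function(bits) {
  bits <- as.integer(bits)
  if (length(bits) != FP_NBITS || any(!bits %in% c(0L, 1L))) {
    abort(sprintf("`bits` must be %d binary values", FP_NBITS))
  }
  prefix <- as.raw((FP_NBITS %/% 256^(3:0)) %% 256)
  padded <- c(bits, integer(FP_PAYLOAD * 8L - FP_NBITS))
  bytes <- vapply(seq_len(FP_PAYLOAD), function(b) {
    sum(padded[(b - 1L) * 8L + 1:8] * bitwShiftL(1L, 7:0))
  }, integer(1))
  c(prefix, as.raw(bytes))
}

#' Read concatenated binary fingerprint records
#'
#' Reads a file of back-to-back 115-byte fingerprint records into a binary
#' drug x substructure incidence matrix.
#'
#' @param path File of concatenated records.
#' @param drug_ids Character IDs, one per record, in file order.
#' @return Binary matrix (drugs x 881) with substructure columns `sub0001`...
#' @export
read_fingerprints <- function(path, drug_ids) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  if (length(raw_all) %% FP_RECORD != 0) {
    abort("file length is not a multiple of the 115-byte record size")
  }
  n <- length(raw_all) %/% FP_RECORD
  if (length(drug_ids) != n) {
    abort(sprintf("file holds %d records but %d drug IDs were given",
                  n, length(drug_ids)))
  }
  m <- t(vapply(seq_len(n), function(i) {
    decode_fingerprint(raw_all[((i - 1L) * FP_RECORD + 1L):(i * FP_RECORD)])
  }, integer(FP_NBITS)))
  dimnames(m) <- list(drug_ids, sprintf("sub%04d", seq_len(FP_NBITS)))
  m
}

#' TF-IDF weight a binary incidence table
#'
#' Term-frequency/inverse-document-frequency weighting of a binary entity x
#' feature incidence (drugs x substructures, or diseases x symptoms). For
#' entity i holding n_i features, each present feature gets tf = 1/n_i, so tf
#' rows sum to 1 over present features; the idf of feature j is
#' `log(N / df_j)` (natural log) with df_j the number of entities holding j.
#' Features held by every entity receive idf 0 and their column is zeroed;
#' features held by none stay all-zero. All-zero rows pass through as zeros.
#'
#' @param incidence Binary matrix with entity rows and feature columns.
#' @return Nonnegative weighted matrix of the same shape.
#' @export
tfidf_weight <- function(incidence) {
  stopifnot(is.matrix(incidence))
  b <- (incidence != 0) * 1
  n_feat <- rowSums(b)
  tf <- b / ifelse(n_feat > 0, n_feat, 1)
  df <- colSums(b)
  idf <- ifelse(df > 0, log(nrow(b) / df), 0)
  out <- sweep(tf, 2, idf, "*")
  dimnames(out) <- dimnames(incidence)
  out
}

#' Embed a weighted incidence table by truncated SVD
#'
#' Latent-semantic-analysis style embedding: the table is decomposed by SVD
#' and each entity is represented by its loadings on the top `d` singular
#' directions scaled by the singular values (`U_d %*% diag(sigma_d)`), ordered
#' by descending singular value. Each singular vector's sign is fixed so that
#' its largest-magnitude entry is positive, making the embedding reproducible.
#' If `d` exceeds the numerical rank the trailing components are zero-filled
#' with a warning.
#'
#' @param weighted Real matrix (entities x features).
#' @param d Embedding dimension, `d <= min(dim(weighted))`.
#' @return Matrix (entities x d) carrying the entity row names.
#' @export
svd_embed <- function(weighted, d) {
  stopifnot(is.matrix(weighted))
  d <- as.integer(d)
  if (d < 1 || d > min(dim(weighted))) {
    abort(sprintf("`d` must be in [1, %d]", min(dim(weighted))))
  }
  dec <- svd(weighted, nu = d, nv = 0)
  sigma <- dec$d[seq_len(d)]
  u <- dec$u
  # deterministic sign: largest-|entry| of each left singular vector positive
  for (c_i in seq_len(d)) {
    peak <- which.max(abs(u[, c_i]))
    if (u[peak, c_i] < 0) u[, c_i] <- -u[, c_i]
  }
  rank_tol <- max(dim(weighted)) * .Machine$double.eps * max(dec$d, 0)
  low <- sigma <= rank_tol
  if (any(low)) {
    warn(sprintf("requested d=%d exceeds numerical rank %d; trailing components zero-filled",
                 d, sum(!low)))
    sigma[low] <- 0
    u[, low] <- 0
  }
  out <- u %*% diag(sigma, nrow = d)
  rownames(out) <- rownames(weighted)
  colnames(out) <- sprintf("dim%03d", seq_len(d))
  out
}

#' Attribute feature matrices for drugs and diseases
#'
#' Convenience wrapper running the full attribute pipeline: TF-IDF weighting
#' (skipped when the table already carries weights) followed by truncated-SVD
#' embedding.
#'
#' @param incidence Entity x feature table, binary or pre-weighted.
#' @param d Embedding dimension.
#' @param weighting `"tfidf"` to weight a binary table, `"given"` to embed the
#'   table as supplied (e.g. a published pre-weighted symptom table).
#' @return Matrix (entities x d).
#' @export
attribute_features <- function(incidence, d, weighting = c("tfidf", "given")) {
  weighting <- match.arg(weighting)
  w <- if (weighting == "tfidf") tfidf_weight(incidence) else incidence
  svd_embed(w, d)
}
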