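# Internal helpers shared across modules.

# Derive a bounded child seed from a master seed and a stage label, so one
# user-facing seed fans out reproducibly to every stochastic stage.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Run an expression under a local RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

check_square_named <- function(m, what) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort(sprintf("`%s` must be a square matrix.", what))
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort(sprintf("`%s` must carry entity IDs as dimnames.", what))
  }
  if (!identical(rownames(m), colnames(m))) {
    abort(sprintf("`%s` row and column IDs differ.", what))
  }
  invisible(m)
}

check_registry_match <- function(ids_a, ids_b, what_a, what_b) {
  if (!identical(ids_a, ids_b)) {
    only_a <- setdiff(ids_a, ids_b)
    only_b <- setdiff(ids_b, ids_a)
    abort(sprintf(
      "ID registries of %s and %s differ (only in %s: %s; only in %s: %s).",
      what_a, what_b,
      what_a, paste(head(only_a, 5), collapse = ", "),
      what_b, paste(head(only_b, 5), collapse = ", ")
    ))
  }
  invisible(TRUE)
}

symmetrize <- function(m) (m + t(m)) / 2
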