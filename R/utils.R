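## Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Coerce landmark input (K x 2 matrix or data.frame) to a numeric matrix.
as_landmarks <- function(config) {
  m <- as.matrix(config)
  storage.mode(m) <- "double"
  if (ncol(m) != 2L) stop("landmark configuration must have 2 columns (x, y)")
  if (nrow(m) < 3L) stop("landmark configuration must have K >= 3 landmarks")
  if (!all(is.finite(m))) stop("landmark coordinates must be finite")
  dimnames(m) <- NULL
  m
}

# Coerce a list of configurations to a common K x 2 x n array.
as_landmark_array <- function(configs) {
  if (is.array(configs) && length(dim(configs)) == 3L) {
    stopifnot(dim(configs)[2] == 2L)
    return(configs)
  }
  mats <- lapply(configs, as_landmarks)
  K <- nrow(mats[[1]])
  if (!all(vapply(mats, nrow, 1L) == K)) {
    stop("all configurations must have the same number of landmarks")
  }
  arr <- array(0, dim = c(K, 2L, length(mats)))
  for (i in seq_along(mats)) arr[, , i] <- mats[[i]]
  arr
}

# Row-wise lexicographic order of a coordinate matrix (first column primary).
lex_order <- function(X) {
  X <- as.matrix(X)
  do.call(order, c(lapply(seq_len(ncol(X)), function(j) X[, j]),
                   list(method = "radix")))
}

# Index of the lexicographically smallest row among `idx` rows of X.
lex_min_index <- function(X, idx) {
  if (length(idx) == 1L) return(idx)
  sub <- X[idx, , drop = FALSE]
  idx[lex_order(sub)[1L]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
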