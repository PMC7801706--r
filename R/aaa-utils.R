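#' @keywords internal
"_PACKAGE"

MS_CLASSES <- c("A", "B", "C", "D")

# Ordered non-self class pairs, fixed feature order: A->B, A->C, ..., D->C.
ordered_pairs <- function(classes = MS_CLASSES) {
  out <- list()
  for (x in classes) for (y in classes) if (x != y) out[[length(out) + 1L]] <- c(x, y)
  out
}

# Unordered pairs in fixed order (A,B),(A,C),(A,D),(B,C),(B,D),(C,D).
unordered_pairs <- function(classes = MS_CLASSES) {
  out <- list()
  n <- length(classes)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    out[[length(out) + 1L]] <- c(classes[i], classes[j])
  }
  out
}

# Evaluate expr with a temporary RNG state; NULL seed leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation, kept within 32-bit integer range.
derive_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483647)
}

# Remove the per-column (per-sample) mean across channels.
demean_channels <- function(mat) {
  sweep(mat, 2L, colMeans(mat), "-")
}

# Normalize columns to unit Euclidean norm; all-zero columns left at zero.
unit_norm_cols <- function(mat) {
  nrm <- sqrt(colSums(mat^2))
  nrm[nrm == 0] <- 1
  sweep(mat, 2L, nrm, "/")
}

# All permutations of 1..n (small n only).
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Stratified fold assignment: each class split as evenly as possible.
stratified_folds <- function(y, k, seed = NULL) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}
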