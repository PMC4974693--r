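# Internal geometry and table helpers shared across modules.

# Squared Euclidean cross-distance matrix between rows of a (n x 3) and b (m x 3).
dist2_cross <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}

# Minimum distance from each row of a to any row of b.
min_dist_to <- function(a, b) {
  d2 <- dist2_cross(a, b)
  sqrt(pmax(apply(d2, 1L, min), 0))
}

xyz_mat <- function(atoms) {
  m <- as.matrix(atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run expr with a private RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards so generators never perturb user code.
with_private_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == floor(x)
}
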