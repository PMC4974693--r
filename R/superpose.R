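#' Rigid-body least-squares superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the root mean
#' square deviation
#' \deqn{RMSD = \sqrt{\frac{1}{N}\sum_i \chi_i^2}}
#' between `fixed` and the transformed `moving` set (`x -> R x + t`), where
#' \eqn{\chi_i} is the distance between the i-th matched pair and N the number
#' of pairs. Solved by SVD of the cross-covariance with a determinant
#' correction, so the result is always a proper rotation (det +1), never a
#' reflection.
#'
#' @param moving,fixed Numeric matrices of matched coordinates, one row per
#'   atom, 3 columns; equal row counts, at least 3 non-collinear points.
#' @return An object of class `superposition`: list with `rotation` (3x3),
#'   `translation` (length 3), `rmsd`, `n_pairs`, and `residuals` (the
#'   per-pair distances \eqn{\chi_i} after the optimal transform).
#' @examples
#' p <- matrix(rnorm(15), ncol = 3)
#' s <- superpose_kabsch(p, p)
#' s$rmsd  # 0
#' @export
superpose_kabsch <- function(moving, fixed) {
  moving <- as.matrix(moving)
  fixed <- as.matrix(fixed)
  if (!is.numeric(moving) || !is.numeric(fixed) ||
      ncol(moving) != 3L || ncol(fixed) != 3L) {
    stop("coordinate sets must be numeric n x 3 matrices")
  }
  if (nrow(moving) != nrow(fixed)) {
    stop("length mismatch: ", nrow(moving), " moving vs ", nrow(fixed), " fixed points")
  }
  n <- nrow(moving)
  if (n < 3L) stop("underdetermined superposition: need at least 3 points")

  cm <- colMeans(moving)
  cf <- colMeans(fixed)
  p <- sweep(moving, 2L, cm)
  q <- sweep(fixed, 2L, cf)

  # Unique rotation requires non-collinear points in both sets.
  scale <- max(sqrt(rowSums(p^2)), sqrt(rowSums(q^2)), 1e-8)
  if (svd(p)$d[2L] < 1e-8 * scale || svd(q)$d[2L] < 1e-8 * scale) {
    stop("underdetermined superposition: points are collinear or coincident")
  }

  h <- crossprod(p, q)                      # 3x3 cross-covariance
  s <- svd(h)
  d <- sign(det(tcrossprod(s$v, s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- as.numeric(cf - rot %*% cm)

  moved <- tcrossprod(moving, rot) + matrix(trans, n, 3L, byrow = TRUE)
  chi <- sqrt(rowSums((fixed - moved)^2))
  structure(
    list(rotation = rot,
         translation = trans,
         rmsd = sqrt(mean(chi^2)),
         n_pairs = n,
         residuals = chi),
    class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> rmsd = ", format(x$rmsd, digits = 6),
      " A over ", x$n_pairs, " atom pairs\n", sep = "")
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param sup A `superposition`.
#' @param xyz n x 3 matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(sup, xyz) {
  stopifnot(inherits(sup, "superposition"))
  xyz <- as.matrix(xyz)
  tcrossprod(xyz, sup$rotation) +
    matrix(sup$translation, nrow(xyz), 3L, byrow = TRUE)
}

#' Number of unordered unit pairs
#'
#' All-pairs comparison of `n` units visits `n(n-1)/2` combinations
#' (147 units give 10,731).
#'
#' @param n_units Non-negative integer count.
#' @return `n_units * (n_units - 1) / 2`.
#' @examples
#' pair_combinations(147)
#' @export
pair_combinations <- function(n_units) {
  if (!is_count(n_units)) stop("n_units must be a single non-negative integer")
  n_units * (n_units - 1) / 2
}
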