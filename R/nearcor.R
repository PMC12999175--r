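#' Nearest correlation matrix by alternating projections
#'
#' Projects a symmetric matrix onto the set of correlation matrices
#' (symmetric, unit diagonal, positive semi-definite) with Higham's
#' alternating-projections algorithm with Dykstra correction. Used to
#' repair hand-built connectivity templates whose block structure makes
#' them slightly indefinite.
#'
#' @param mat symmetric numeric matrix with unit diagonal (small
#'   asymmetries are symmetrized first).
#' @param tol convergence tolerance on the relative Frobenius change
#'   between iterates (default 1e-10).
#' @param max_iter iteration cap (default 500).
#' @return the repaired matrix, with attributes `distance` (Frobenius
#'   distance from the input) and `iterations`.
#' @examples
#' m <- matrix(c(1, .9, .7, .9, 1, .9, .7, .9, 1), 3)
#' r <- nearest_correlation(m)
#' min(eigen(r, symmetric = TRUE, only.values = TRUE)$values) >= -1e-8
#' @export
nearest_correlation <- function(mat, tol = 1e-10, max_iter = 500L) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat)) {
    stop("`mat` must be a square matrix")
  }
  x <- (mat + t(mat)) / 2
  ds <- matrix(0, nrow(x), ncol(x))
  y <- x
  for (it in seq_len(max_iter)) {
    r <- y - ds
    # project onto PSD cone
    e <- eigen(r, symmetric = TRUE)
    ev <- pmax(e$values, 0)
    x_new <- e$vectors %*% (ev * t(e$vectors))
    x_new <- (x_new + t(x_new)) / 2
    ds <- x_new - r
    # project onto unit-diagonal affine set
    y_new <- x_new
    diag(y_new) <- 1
    delta <- norm(y_new - y, "F") / max(norm(y_new, "F"), 1e-300)
    y <- y_new
    if (delta < tol) break
  }
  out <- y
  dimnames(out) <- dimnames(mat)
  attr(out, "distance") <- norm(out - (mat + t(mat)) / 2, "F")
  attr(out, "iterations") <- it
  out
}

# TRUE if already a valid correlation matrix (within eigenvalue slack)
is_psd_correlation <- function(mat, eig_tol = 1e-8) {
  isSymmetric(mat, tol = 1e-12) &&
    all(abs(diag(mat) - 1) < 1e-12) &&
    min(eigen(mat, symmetric = TRUE, only.values = TRUE)$values) > -eig_tol
}
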