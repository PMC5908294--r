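#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' coordinate sets with known atom correspondence, via singular value
#' decomposition of the cross-covariance matrix. Reflections are excluded:
#' the returned rotation always has determinant +1.
#'
#' @param mobile numeric `N x 3` matrix to be moved.
#' @param reference numeric `N x 3` matrix kept fixed.
#' @return list with `rotation` (3x3 matrix), `translation` (length-3
#'   vector) and `rmsd` (Angstrom). The fitted coordinates are
#'   `mobile %*% rotation + translation` (row-wise).
#' @examples
#' ref <- matrix(rnorm(12), 4, 3)
#' th <- pi / 3
#' R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
#' fit <- kabschSuperpose(ref %*% R + 2, ref)
#' fit$rmsd   # ~0
#' @export
kabschSuperpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)))
    stop("mobile and reference must have identical dimensions")
  if (ncol(mobile) != 3L)
    stop("coordinates must be N x 3 matrices")
  n <- nrow(mobile)
  if (n < 3L)
    stop("superposition is degenerate: need at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  X <- sweep(mobile, 2, cm); Y <- sweep(reference, 2, cr)
  # collinear (rank < 2) reference leaves the rotation under-determined
  if (sum(svd(Y, nu = 0, nv = 0)$d > 1e-8 * max(1, max(abs(Y)))) < 2L)
    stop("superposition is degenerate: reference points are collinear")
  s <- svd(crossprod(X, Y))
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- X %*% R
  msd <- sum((fitted - Y)^2) / n
  list(rotation = R,
       translation = as.numeric(cr - cm %*% R),
       rmsd = sqrt(max(msd, 0)))
}

#' Apply a rigid transform to coordinates
#'
#' @param coords numeric `N x 3` matrix.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric vector.
#' @return transformed `N x 3` matrix (`coords %*% rotation + translation`).
#' @export
applyTransform <- function(coords, rotation, translation = c(0, 0, 0)) {
  sweep(as.matrix(coords) %*% rotation, 2, -translation)
}

# RMSD of mobile vs reference after optimal superposition
.fitRmsd <- function(mobile, reference) kabschSuperpose(mobile, reference)$rmsd

# squared distances between one point and rows of a matrix
.dist2 <- function(p, m) colSums((t(m) - p)^2)
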