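# Rigid-body superposition and coordinate RMSD primitives.

#' Optimal rigid superposition (Kabsch) and minimum RMSD
#'
#' Finds the proper rotation and translation minimising the least-squares
#' Calpha deviation of `coords_b` onto `coords_a`, via singular value
#' decomposition of the covariance matrix with the standard reflection
#' correction, and returns the minimised RMSD.
#'
#' @param coords_a,coords_b N x 3 numeric matrices of matched points
#'   (N >= 3, finite).
#' @return List with `rotation` (3 x 3, determinant +1), `translation`
#'   (length-3; the fit is `coords_b %*% t(rotation) + translation`) and
#'   `rmsd` in the coordinate units (angstroms).
#' @export
superpose_rmsd <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a)
  coords_b <- as.matrix(coords_b)
  if (!identical(dim(coords_a), dim(coords_b)) || ncol(coords_a) != 3L) {
    stop("coordinate sets must be N x 3 matrices of equal size")
  }
  if (nrow(coords_a) < 3L) stop("need at least 3 points")
  if (!all(is.finite(coords_a)) || !all(is.finite(coords_b))) {
    stop("coordinates must be finite")
  }
  ca <- colMeans(coords_a)
  cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca)
  B <- sweep(coords_b, 2, cb)
  H <- crossprod(B, A)            # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)     # maps centred B onto centred A
  fit <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((fit - A)^2)))
  translation <- as.numeric(ca - cb %*% t(R))
  list(rotation = R, translation = translation, rmsd = rmsd)
}

#' Plain coordinate RMSD (no re-superposition)
#'
#' Root-mean-square deviation between two coordinate sets already expressed
#' in a common frame.
#'
#' @param coords_a,coords_b N x 3 numeric matrices.
#' @return RMSD in angstroms.
#' @export
coord_rmsd <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a)
  coords_b <- as.matrix(coords_b)
  if (!identical(dim(coords_a), dim(coords_b))) {
    stop("coordinate sets must have identical dimensions")
  }
  sqrt(mean(rowSums((coords_a - coords_b)^2)))
}
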