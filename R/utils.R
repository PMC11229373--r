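# Shared geometry helpers. Coordinates are N x 3 matrices (Angstrom).

#' Optimal rigid-body superposition (Kabsch)
#'
#' Computes the proper rotation and translation that best superposes `mobile`
#' onto `fixed` in the least-squares sense. Reflections are never returned:
#' the smallest singular direction is flipped when the optimal orthogonal
#' transform would be improper, so chirality is preserved.
#'
#' @param mobile,fixed N x 3 coordinate matrices with matched rows.
#' @return List with `rotation` (3 x 3), `translation` (length 3) such that
#'   `mobile %*% rotation + translation` superposes onto `fixed`, the
#'   transformed coordinates `xyz`, and the residual `rmsd` in Angstrom.
#' @export
#' @examples
#' p <- matrix(rnorm(30), 10, 3)
#' rot <- rotationMatrix(c(0, 0, 1), pi / 5)
#' q <- p %*% rot
#' kabsch(q, p)$rmsd
kabsch <- function(mobile, fixed) {
  stopifnot(is.matrix(mobile), is.matrix(fixed),
            ncol(mobile) == 3L, ncol(fixed) == 3L,
            nrow(mobile) == nrow(fixed))
  cm <- colMeans(mobile)
  cf <- colMeans(fixed)
  a <- sweep(mobile, 2, cm)
  b <- sweep(fixed, 2, cf)
  h <- crossprod(a, b)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  xyz <- sweep(a %*% rot, 2, cf, `+`)
  list(rotation = rot,
       translation = as.numeric(cf - cm %*% rot),
       xyz = xyz,
       rmsd = sqrt(mean(rowSums((xyz - fixed)^2))))
}

#' Rotation matrix about an axis
#'
#' @param axis Length-3 axis vector (normalized internally).
#' @param angle Rotation angle in radians.
#' @return 3 x 3 rotation matrix (acts on row vectors via `x %*% R`).
#' @export
rotationMatrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c0 <- cos(angle); s0 <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2],
                 u[3], 0, -u[1],
                 -u[2], u[1], 0), 3, 3, byrow = TRUE)
  c0 * diag(3) + s0 * t(ux) + (1 - c0) * tcrossprod(u)
}

vecNorm <- function(v) sqrt(sum(v^2))

unitVec <- function(v) v / sqrt(sum(v^2))

# Interior angle at vertex b of the triplet (a, b, c), radians in [0, pi].
tripletAngle <- function(a, b, c) {
  u <- a - b; v <- c - b
  ct <- sum(u * v) / (vecNorm(u) * vecNorm(v))
  acos(max(-1, min(1, ct)))
}

# Random proper rotation (uniform via QR of a Gaussian matrix).
randomRotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

`%||%` <- function(a, b) if (is.null(a)) b else a
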