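# 2D rigid transformations: rotation by theta about the coordinate origin
# followed by a translation (tx, ty), i.e. p' = R(theta) p + t.  Rigid
# means distance-preserving with no reflection: det(R) = +1.

#' Construct a 2D rigid transformation
#'
#' Represents `p' = R(theta) %*% p + c(tx, ty)` with `R(theta)` the
#' counter-clockwise rotation about the origin.
#'
#' @param theta rotation angle in radians.
#' @param tx,ty translation in nm, applied after the rotation.
#' @return An object of class `rigid_transform`.
#' @examples
#' t1 <- rigid_transform(0.01, 500, -300)
#' transform_points(t1, cbind(0, 0))
#' @export
rigid_transform <- function(theta = 0, tx = 0, ty = 0) {
  stopifnot(is.finite(theta), is.finite(tx), is.finite(ty))
  structure(list(theta = theta, tx = tx, ty = ty), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("Rigid transform: theta = %.6g rad, t = (%.4g, %.4g) nm\n",
              x$theta, x$tx, x$ty))
  invisible(x)
}

#' @rdname rigid_transform
#' @param transform a `rigid_transform`.
#' @return `rotation_matrix()`: the 2x2 rotation matrix (orthogonal,
#'   determinant +1).
#' @export
rotation_matrix <- function(transform) {
  th <- transform$theta
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Apply a rigid transformation to points
#'
#' @param transform a [rigid_transform()].
#' @param points numeric matrix (or 2-column data.frame) with columns x, y
#'   in nm.
#' @return Matrix of the same shape with transformed coordinates.
#' @export
transform_points <- function(transform, points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  out <- points %*% t(rotation_matrix(transform))
  out[, 1] <- out[, 1] + transform$tx
  out[, 2] <- out[, 2] + transform$ty
  colnames(out) <- c("x", "y")
  out
}

#' Compose and invert rigid transformations
#'
#' `compose_transforms(b, a)` is the transform applying `a` first, then
#' `b`; `invert_transform(t)` satisfies
#' `compose_transforms(invert_transform(t), t) = identity`.
#'
#' @param a,b,transform [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transforms <- function(b, a) {
  Rb <- rotation_matrix(b)
  t_new <- Rb %*% c(a$tx, a$ty) + c(b$tx, b$ty)
  rigid_transform(a$theta + b$theta, t_new[1], t_new[2])
}

#' @rdname compose_transforms
#' @export
invert_transform <- function(transform) {
  Ri <- t(rotation_matrix(transform))
  t_new <- -Ri %*% c(transform$tx, transform$ty)
  rigid_transform(-transform$theta, t_new[1], t_new[2])
}

#' Least-squares rigid fit between matched point sets
#'
#' Closed-form estimate of the rigid transformation (rotation +
#' translation, determinant +1) minimizing the sum of squared distances
#' `sum(||T(m_i) - r_i||^2)` over matched pairs: centroids are subtracted,
#' the rotation comes from the SVD of the 2x2 cross-covariance with the
#' reflection branch corrected, and the translation maps the rotated
#' moving centroid onto the reference centroid.
#'
#' @param moving,reference numeric matrices of matched points (equal row
#'   counts, >= 2 rows), columns x, y in nm.
#' @return A [rigid_transform()] mapping `moving` onto `reference`.
#' @export
estimate_rigid <- function(moving, reference) {
  moving <- as.matrix(moving); reference <- as.matrix(reference)
  if (nrow(moving) != nrow(reference))
    stop("matched point sets must have equal length")
  if (nrow(moving) < 2L)
    stop("rigid estimation needs at least 2 point pairs")
  cm <- colMeans(moving)
  cr <- colMeans(reference)
  M <- sweep(moving, 2, cm)
  R <- sweep(reference, 2, cr)
  if (all(abs(M) < .Machine$double.eps * 1e3))
    stop("degenerate configuration: all moving points coincide, ",
         "rotation is unidentifiable")
  H <- t(M) %*% R  # cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  theta <- atan2(rot[2, 1], rot[1, 1])
  t_vec <- cr - rot %*% cm
  rigid_transform(theta, t_vec[1], t_vec[2])
}

#' Apply a rigid transformation to a localization table
#'
#' Maps every localization's coordinates; frame, intensity and any other
#' columns are unchanged and row order is preserved.
#'
#' @param table a [loc_table].
#' @param transform a [rigid_transform()].
#' @return A [loc_table] with transformed x, y.
#' @export
apply_transform <- function(table, transform) {
  stopifnot(inherits(table, "loc_table"), inherits(transform, "rigid_transform"))
  if (nrow(table) == 0L) return(table)
  xy <- transform_points(transform, cbind(table$x, table$y))
  out <- as.data.frame(table)
  out$x <- xy[, 1]
  out$y <- xy[, 2]
  relabel_table(out, table)
}
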