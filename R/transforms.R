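#' Rigid-body (SE(3)) transforms
#'
#' A rigid transform maps CT-frame coordinates to world (standing)
#' coordinates as `x -> R x + t`, with `R` a 3x3 special-orthogonal matrix
#' and `t` a translation in millimetres.
#'
#' @param rotation 3x3 rotation matrix (special orthogonal).
#' @param translation length-3 numeric translation (mm).
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @examples
#' tr <- rigid_transform(rot_x(10), c(1, 2, 3))
#' compose_transforms(tr, invert_transform(tr))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (abs(det(rotation) - 1) > 1e-9 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation must be special orthogonal (det 1, R'R = I within 1e-9)")
  }
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$R)
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

#' @rdname rigid_transform
#' @export
transform_identity <- function() rigid_transform()

#' Elementary rotation matrices
#'
#' Rotations about the world x (patient-left), y (anterior) and z (cranial)
#' axes, and about an arbitrary axis. Angles in degrees.
#'
#' @param angle_deg rotation angle in degrees.
#' @param axis length-3 axis (need not be unit length).
#' @return 3x3 rotation matrix.
#' @export
rot_x <- function(angle_deg) {
  a <- .deg2rad(angle_deg); c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' @rdname rot_x
#' @export
rot_y <- function(angle_deg) {
  a <- .deg2rad(angle_deg); c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

#' @rdname rot_x
#' @export
rot_z <- function(angle_deg) {
  a <- .deg2rad(angle_deg); c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' @rdname rot_x
#' @export
rot_axis <- function(axis, angle_deg) {
  axis_angle_matrix(axis / sqrt(sum(axis^2)) * .deg2rad(angle_deg))
}

# Rodrigues formula; omega is an axis-angle 3-vector in radians.
axis_angle_matrix <- function(omega) {
  th <- sqrt(sum(omega^2))
  if (th < 1e-12) return(diag(3) + skew(omega))
  k <- omega / th
  K <- skew(k)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

skew <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

# Total rotation angle of R in degrees.
rotation_angle_deg <- function(R) {
  .rad2deg(acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))))
}

#' Project a near-rotation matrix onto SO(3)
#'
#' SVD polar projection, used to remove numerical drift after iterative
#' optimizer updates.
#'
#' @param R 3x3 matrix close to a rotation.
#' @return The nearest (Frobenius) rotation matrix.
#' @export
project_so3 <- function(R) {
  s <- svd(R)
  d <- diag(c(1, 1, det(s$u %*% t(s$v))))
  s$u %*% d %*% t(s$v)
}

#' Compose, invert and apply rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform that applies `b` first
#' and then `a`. `apply_transform` maps 3D points (n x 3 matrix), a
#' `triangle_mesh`, a `projection_view` or a `biplanar_environment`.
#'
#' @param a,b,transform `rigid_transform` objects.
#' @param x points matrix, mesh, view or environment to transform.
#' @return The composed/inverted transform, or the transformed object.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(project_so3(a$R %*% b$R), as.numeric(a$R %*% b$t) + a$t)
}

#' @rdname compose_transforms
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$R)
  rigid_transform(Rt, as.numeric(-Rt %*% transform$t))
}

#' @rdname compose_transforms
#' @export
apply_transform <- function(transform, x) UseMethod("apply_transform", x)

#' @export
apply_transform.default <- function(transform, x) {
  x <- rbind(x)  # accept a bare length-3 vector
  stopifnot(ncol(x) == 3L)
  sweep(x %*% t(transform$R), 2, transform$t, "+")
}

#' @export
apply_transform.triangle_mesh <- function(transform, x) {
  x$vertices <- apply_transform.default(transform, x$vertices)
  x
}

#' Serialize a rigid transform to/from JSON
#'
#' The on-disk format is a JSON object with `rotation` (9 entries,
#' row-major) and `translation` (3 entries, mm).
#'
#' @param transform a `rigid_transform`.
#' @param path file path.
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(
    list(rotation = as.numeric(t(transform$R)),
         translation = as.numeric(transform$t)),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(obj$rotation, 3, 3, byrow = TRUE), obj$translation)
}
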