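# Core 3-D primitives: vectors, planes, rigid transforms, rotations.
# Coordinates are millimetres in a right-handed frame with X positive to the
# subject's right, Y positive forward, Z positive up.

DEG <- 180 / pi

as_vec3 <- function(v, what = "vector") {
  v <- as.numeric(v)
  if (length(v) != 3L || !all(is.finite(v)))
    stop(what, " must be a finite numeric vector of length 3", call. = FALSE)
  v
}

vnorm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v, what = "vector") {
  v <- as_vec3(v, what)
  n <- vnorm(v)
  if (n < 1e-12) stop(what, " has zero length", call. = FALSE)
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

clamp1 <- function(x) pmin(1, pmax(-1, x))

# Coerce points to an n x 3 matrix.
as_points <- function(x) {
  if (inherits(x, "trimesh")) return(x$vertices)
  if (inherits(x, "corresponded_shape")) return(x$points)
  if (is.null(dim(x))) {
    if (length(x) %% 3L != 0L) stop("points must have 3 columns", call. = FALSE)
    x <- matrix(x, ncol = 3L, byrow = TRUE)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("points must have 3 columns", call. = FALSE)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' Construct a plane from a normal vector and offset
#'
#' A plane is stored in Hessian form `A x + B y + C z + D = 0`, with
#' `normal = c(A, B, C)` a unit vector and `offset = D` in millimetres.
#'
#' @param normal numeric length-3 normal direction (normalized internally).
#' @param offset scalar plane offset `D`.
#' @return an object of class `"plane"` with elements `normal` and `offset`.
#' @seealso [fit_plane()], [orient_plane()], [reference_plane_angles()]
#' @export
plane <- function(normal, offset = 0) {
  n <- unit_vec(normal, "plane normal")
  # offset scales with the normalization so the point set is unchanged
  offset <- as.numeric(offset) / vnorm(as_vec3(normal))
  structure(list(normal = n, offset = offset), class = "plane")
}

#' @export
print.plane <- function(x, ...) {
  cat(sprintf("Plane: %.4f x + %.4f y + %.4f z + %.4f = 0\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset))
  invisible(x)
}

plane_from_point_normal <- function(point, normal) {
  n <- unit_vec(normal, "plane normal")
  plane(n, -sum(n * as_vec3(point)))
}

#' Total-least-squares plane fit
#'
#' Fits the plane minimizing the sum of squared orthogonal distances to the
#' points: the normal is the eigenvector of the centered scatter matrix with
#' the smallest eigenvalue, and the centroid lies on the plane. The sign of
#' the normal is arbitrary at this level; use [orient_plane()] to enforce an
#' anatomical sign convention.
#'
#' @param points an n x 3 matrix (n >= 3, not all collinear) of positions, mm.
#' @return a [plane()].
#' @export
fit_plane <- function(points) {
  p <- as_points(points)
  if (nrow(p) < 3L)
    stop("plane fit needs at least 3 points, got ", nrow(p), call. = FALSE)
  ctr <- colMeans(p)
  q <- sweep(p, 2L, ctr)
  s <- crossprod(q)
  e <- eigen(s, symmetric = TRUE)
  rank <- sum(e$values > max(e$values[1], 1e-300) * 1e-10)
  if (rank < 2L)
    stop("degenerate input for plane fit: centered points have rank ", rank,
         " (collinear or coincident)", call. = FALSE)
  n <- e$vectors[, 3L]
  plane_from_point_normal(ctr, n)
}

#' Enforce a sign convention on a plane normal
#'
#' Flips the plane's normal (and offset) if needed so that
#' `normal . reference_direction > 0`. This is how anatomical conventions
#' (e.g. lateral-canal normal pointing downward) are imposed on the
#' sign-agnostic total-least-squares fit.
#'
#' @param p a [plane()].
#' @param reference_direction nonzero length-3 direction.
#' @return the plane, flipped if necessary.
#' @export
orient_plane <- function(p, reference_direction) {
  stopifnot(inherits(p, "plane"))
  r <- unit_vec(reference_direction, "reference direction")
  d <- sum(p$normal * r)
  if (abs(d) < 1e-9)
    stop("ambiguous orientation: reference direction is orthogonal to the ",
         "plane normal", call. = FALSE)
  if (d < 0) structure(list(normal = -p$normal, offset = -p$offset),
                       class = "plane")
  else p
}

plane_normal <- function(x) {
  if (inherits(x, "plane")) x$normal else as_vec3(x, "normal")
}

#' Angles of a plane to the sagittal, coronal and horizontal reference planes
#'
#' Returns the dihedral angle between the oriented plane normal and the
#' normal of each reference plane of the standardized head frame (sagittal:
#' X axis; coronal: Y axis; horizontal: Z axis), i.e. the arc-cosines of the
#' normal's direction cosines, in degrees in `[0, 180]`. Angles are *not*
#' folded to the acute range, so an inward-pointing normal reports an obtuse
#' sagittal angle.
#'
#' The components are used exactly as given (only clamped to `[-1, 1]`), not
#' renormalized: published normals quoted to a few decimals are therefore
#' reproduced at their printed precision.
#'
#' @param x a [plane()] or a length-3 unit normal.
#' @return named numeric: `sagittal`, `coronal`, `horizontal` (degrees).
#' @export
reference_plane_angles <- function(x) {
  n <- plane_normal(x)
  a <- acos(clamp1(n)) * DEG
  names(a) <- c("sagittal", "coronal", "horizontal")
  a
}

#' Dihedral angle between two planes
#'
#' `acos(n1 . n2)` in degrees, in `[0, 180]`, between the oriented normals;
#' by default obtuse values are kept (not folded to `[0, 90]`), so the
#' result depends on the sign conventions imposed by [orient_plane()].
#' `folded = TRUE` returns the acute angle between the planes regardless of
#' normal signs. Symmetric in its arguments.
#'
#' @param p1,p2 planes or length-3 normals.
#' @param folded fold to the acute range `[0, 90]`.
#' @return angle in degrees.
#' @export
angle_between_planes <- function(p1, p2, folded = FALSE) {
  n1 <- unit_vec(plane_normal(p1), "normal")
  n2 <- unit_vec(plane_normal(p2), "normal")
  a <- acos(clamp1(sum(n1 * n2))) * DEG
  if (folded && a > 90) 180 - a else a
}

#' Rotation matrix about an arbitrary axis (Rodrigues)
#'
#' @param axis length-3 rotation axis (normalized internally).
#' @param angle rotation angle in degrees, right-hand rule.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  a <- unit_vec(axis, "axis")
  th <- angle / DEG
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3L, 3L)
  diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotate vectors about an axis
#'
#' @param v length-3 vector or n x 3 matrix of vectors/points.
#' @param axis rotation axis.
#' @param angle degrees, right-hand rule.
#' @return rotated vector(s), same shape as `v`.
#' @export
rotate_about_axis <- function(v, axis, angle) {
  R <- rotation_about_axis(axis, angle)
  if (is.null(dim(v))) as.numeric(R %*% as_vec3(v))
  else t(R %*% t(as_points(v)))
}

#' Rigid (or similarity) spatial transform
#'
#' Represents `x -> scale * R %*% M %*% x + translation` where `M` negates the
#' X coordinate when `mirrored` is `TRUE`. The rotation must be proper
#' (orthonormal, determinant +1): reflections are expressed through the
#' `mirrored` flag, never through an improper rotation matrix.
#'
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation length-3 translation, mm.
#' @param scale positive isotropic scale factor.
#' @param mirrored logical; reflect through the X = 0 sagittal plane first.
#' @return object of class `"rigid_transform"`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            scale = 1, mirrored = FALSE) {
  R <- as.matrix(rotation)
  if (!all(dim(R) == c(3L, 3L)) ||
      max(abs(crossprod(R) - diag(3))) > 1e-8)
    stop("rotation must be a 3 x 3 orthonormal matrix", call. = FALSE)
  if (det(R) < 0)
    stop("rotation has determinant -1; use mirrored = TRUE for reflections",
         call. = FALSE)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("scale must be a positive scalar", call. = FALSE)
  structure(list(rotation = R, translation = as_vec3(translation),
                 scale = as.numeric(scale), mirrored = isTRUE(mirrored)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(clamp1((sum(diag(x$rotation)) - 1) / 2)) * DEG
  cat(sprintf(
    "Rigid transform: rotation %.2f deg, translation (%.2f, %.2f, %.2f) mm%s%s\n",
    ang, x$translation[1], x$translation[2], x$translation[3],
    if (x$scale != 1) sprintf(", scale %.4f", x$scale) else "",
    if (x$mirrored) ", mirrored" else ""))
  invisible(x)
}

mirror_matrix <- diag(c(-1, 1, 1))

#' Apply a rigid transform to points, meshes or planes
#'
#' @param x an n x 3 matrix of points, a `trimesh`, a `corresponded_shape`,
#'   or a `plane`.
#' @param t a [rigid_transform()].
#' @return the transformed object, same class as `x`.
#' @export
apply_transform <- function(x, t) {
  stopifnot(inherits(t, "rigid_transform"))
  if (inherits(x, "plane")) {
    # planes are unaffected by scale; for x' = sRM x + t the normal maps by
    # R M and the offset follows from a transformed on-plane point
    n2 <- as.numeric(t$rotation %*% (if (t$mirrored) mirror_matrix %*% x$normal
                                     else x$normal))
    p0 <- -x$offset * x$normal                # a point on the plane
    p2 <- apply_transform(rbind(p0), t)[1, ]
    return(plane_from_point_normal(p2, n2))
  }
  if (inherits(x, "trimesh")) {
    v <- apply_transform(x$vertices, t)
    f <- x$faces
    if (t$mirrored) f <- f[, c(1L, 3L, 2L), drop = FALSE]  # keep orientation
    return(trimesh(v, f))
  }
  if (inherits(x, "corresponded_shape")) {
    return(corresponded_shape(apply_transform(x$points, t), x$labels))
  }
  p <- as_points(x)
  if (t$mirrored) p[, 1] <- -p[, 1]
  sweep(t$scale * p %*% t(t$rotation), 2L, t$translation, `+`)
}

#' Compose two transforms
#'
#' `compose_transform(a, b)` applies `b` first, then `a`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return the composed [rigid_transform()].
#' @export
compose_transform <- function(a, b) {
  # a(b(x)) = sa Ra Ma (sb Rb Mb x + tb) + ta; using Ma Rb = (Ma Rb Ma) Ma
  # the two mirrors collapse into a single xor'ed flag
  Rb <- b$rotation
  tb <- b$translation
  if (a$mirrored) {
    Rb <- mirror_matrix %*% Rb %*% mirror_matrix
    tb <- as.numeric(mirror_matrix %*% tb)
  }
  rigid_transform(a$rotation %*% Rb,
                  a$scale * as.numeric(a$rotation %*% tb) + a$translation,
                  scale = a$scale * b$scale,
                  mirrored = xor(a$mirrored, b$mirrored))
}

#' Invert a transform
#'
#' @param t a [rigid_transform()].
#' @return the inverse [rigid_transform()].
#' @export
invert_transform <- function(t) {
  # x = (1/s) M R' (y - tr); M R' = (M R' M) M keeps the mirror-first form
  Rt <- t(t$rotation)
  R <- if (t$mirrored) mirror_matrix %*% Rt %*% mirror_matrix else Rt
  tr <- -(1 / t$scale) * (if (t$mirrored) mirror_matrix %*% Rt else Rt) %*% t$translation
  rigid_transform(R, as.numeric(tr), scale = 1 / t$scale, mirrored = t$mirrored)
}

#' Reflect through the sagittal plane
#'
#' Negates the X coordinate (the sagittal plane of the standardized head
#' frame is X = 0). For meshes the face winding is flipped so outward
#' orientation is preserved; for planes the normal's X component is negated
#' and the offset kept, so a plane with reference-plane angles
#' `(s, c, h)` maps to `(180 - s, c, h)`.
#'
#' @param x points, `trimesh`, `corresponded_shape` or `plane`.
#' @return the mirrored object.
#' @export
mirror_sagittal <- function(x) {
  apply_transform(x, rigid_transform(mirrored = TRUE))
}

# Distance of points from plane (signed), mm.
plane_distance <- function(p, points) {
  as.numeric(as_points(points) %*% p$normal + p$offset)
}
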