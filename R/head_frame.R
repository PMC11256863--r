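# Standardized head coordinate frame: X to the subject's right (sagittal
# normal), Y forward, Z up. The frame is anchored on the mean model by (i)
# the bilateral symmetry plane of the two labyrinths and (ii) the horizontal
# plane through the tops of the common crura and the bottoms of the eyeballs.

required_landmarks <- c("common_crus_top_left", "common_crus_top_right",
                        "eyeball_bottom_left", "eyeball_bottom_right")

#' Estimate the bilateral symmetry (sagittal) plane
#'
#' Finds the plane P minimizing the mismatch between the left-side points
#' and the reflection of the right-side points through P. When the two sides
#' have equal point counts they are treated as mirror-corresponded (point i
#' left matches point i right) and the plane follows in closed form: the
#' left-right difference vectors are all parallel to the plane normal and
#' the midpoints lie on the plane. With unequal counts an
#' iterative-closest-point matching loop wraps the closed form.
#'
#' @param left_points,right_points point matrices, mm.
#' @param max_iter,tol ICP loop controls (uncorresponded case).
#' @return a [plane()] with the normal pointing to the subject's right;
#'   attribute `"residual"` is the RMS left-vs-mirrored-right distance, mm.
#' @export
estimate_symmetry_plane <- function(left_points, right_points,
                                    max_iter = 50L, tol = 1e-9) {
  L <- as_points(left_points); R <- as_points(right_points)
  if (nrow(L) == 0L || nrow(R) == 0L)
    stop("both sides must be non-empty", call. = FALSE)

  fit_from_pairs <- function(L, R) {
    d <- L - R
    m <- (L + R) / 2
    # normal = dominant direction of the difference vectors
    e <- eigen(crossprod(d), symmetric = TRUE)
    n <- e$vectors[, 1L]
    pl <- plane_from_point_normal(colMeans(m), n)
    # orient toward the right side
    to_right <- colMeans(R) - colMeans(L)
    if (sum(pl$normal * to_right) < 0)
      pl <- plane(-pl$normal, -pl$offset)
    pl
  }

  reflect <- function(p, pl) {
    d <- plane_distance(pl, p)
    p - 2 * outer(d, pl$normal)
  }

  if (nrow(L) == nrow(R)) {
    pl <- fit_from_pairs(L, R)
    resid <- sqrt(mean(rowSums((L - reflect(R, pl))^2)))
    return(structure(pl, residual = resid))
  }

  # unequal counts: alternate closed-form fit with nearest-point matching
  pl <- plane_from_point_normal((colMeans(L) + colMeans(R)) / 2,
                                colMeans(R) - colMeans(L))
  prev <- Inf
  for (it in seq_len(max_iter)) {
    Rm <- reflect(R, pl)
    idx <- nearest_neighbor(L, Rm)
    pl <- fit_from_pairs(L, R[idx, , drop = FALSE])
    resid <- sqrt(mean(rowSums((L - reflect(R[idx, , drop = FALSE], pl))^2)))
    if (abs(prev - resid) < tol) break
    prev <- resid
  }
  structure(pl, residual = resid)
}

#' Build the standardized head frame from landmarks and the symmetry plane
#'
#' The X axis is the symmetry-plane normal (to the subject's right). The Z
#' (up) axis is the component, orthogonal to X, of the total-least-squares
#' plane normal through the four defining landmarks (left/right common-crus
#' tops and eyeball bottoms); its sign is chosen so that Y = Z x X points
#' forward, i.e. from the common crura toward the eyeballs. The origin is
#' the midpoint of the left/right labyrinth centroids (landmarks
#' `labyrinth_centroid_left/right` when present, otherwise the common-crus
#' tops) projected onto the symmetry plane.
#'
#' @param landmarks named list of length-3 points, mm. Required names:
#'   `common_crus_top_left`, `common_crus_top_right`, `eyeball_bottom_left`,
#'   `eyeball_bottom_right`.
#' @param symmetry a [plane()] from [estimate_symmetry_plane()].
#' @return object of class `"frame_calibration"`: `transform` (world-to-head
#'   [rigid_transform()]), `sagittal_residual` and `horizontal_residual`
#'   (mm), and the `axes` (rows X, Y, Z in world coordinates).
#' @export
build_head_frame <- function(landmarks, symmetry) {
  stopifnot(inherits(symmetry, "plane"))
  miss <- setdiff(required_landmarks, names(landmarks))
  if (length(miss))
    stop("missing required landmarks: ", paste(miss, collapse = ", "),
         call. = FALSE)
  lm4 <- do.call(rbind, lapply(required_landmarks, function(nm)
    as_vec3(landmarks[[nm]], nm)))
  X <- symmetry$normal
  hp <- fit_plane(lm4)
  nz <- hp$normal - sum(hp$normal * X) * X
  if (vnorm(nz) < 1e-6)
    stop("degenerate frame: landmark-plane normal is parallel to the ",
         "symmetry axis", call. = FALSE)
  Z <- nz / vnorm(nz)
  cc_mid <- (lm4[1, ] + lm4[2, ]) / 2
  eye_mid <- (lm4[3, ] + lm4[4, ]) / 2
  Y <- vcross(Z, X)
  if (sum(Y * (eye_mid - cc_mid)) < 0) {   # eyes are anterior
    Z <- -Z
    Y <- vcross(Z, X)
  }
  ctr_names <- c("labyrinth_centroid_left", "labyrinth_centroid_right")
  ctrs <- if (all(ctr_names %in% names(landmarks))) {
    rbind(as_vec3(landmarks[[ctr_names[1]]]), as_vec3(landmarks[[ctr_names[2]]]))
  } else lm4[1:2, ]
  origin <- colMeans(ctrs)
  origin <- origin - plane_distance(symmetry, rbind(origin)) * X
  Rwh <- rbind(X, Y, Z)                     # world -> head rotation (rows)
  transform <- rigid_transform(Rwh, -as.numeric(Rwh %*% origin))
  hres <- sqrt(mean(plane_distance(hp, lm4)^2))
  structure(list(transform = transform,
                 sagittal_residual = attr(symmetry, "residual") %||% NA_real_,
                 horizontal_residual = hres,
                 axes = Rwh),
            class = "frame_calibration")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.frame_calibration <- function(x, ...) {
  cat(sprintf(
    "Head-frame calibration: sagittal residual %.4g mm, horizontal residual %.4g mm\n",
    x$sagittal_residual, x$horizontal_residual))
  invisible(x)
}

#' Calibrate a specimen into the standard model's frame
#'
#' Rigid-only (no scale) registration of a specimen point set onto the
#' standard mean model. The returned transform is meant to be *transferred*:
#' applying the same transform to sibling structures segmented from the same
#' scan (membranous labyrinth, crista patches, centerlines) carries them
#' into the standard frame exactly, without re-estimation.
#'
#' @param specimen_points matrix or [corresponded_shape()]; if corresponded
#'   with the standard layout the alignment is direct, otherwise
#'   label-constrained ICP correspondence is established first.
#' @param standard a [build_mean_model()] result (in the head frame) or a
#'   [corresponded_shape()].
#' @param max_residual registration residual (RMS mm) above which an error
#'   is raised.
#' @return a [rigid_transform()]; attribute `"rmsd"` is the residual.
#' @export
calibrate_specimen <- function(specimen_points, standard,
                               max_residual = Inf) {
  std <- if (inherits(standard, "mean_shape_model")) standard$mean
         else standard
  stopifnot(inherits(std, "corresponded_shape"))
  p <- as_points(specimen_points)
  if (nrow(p) == nrow(std$points)) {
    tf <- procrustes_align(p, std$points, allow_scale = FALSE)
  } else {
    corr <- establish_correspondence(specimen_points, std)
    # corr holds specimen points ordered like the standard layout
    tf <- procrustes_align(corr$points, std$points, allow_scale = FALSE)
  }
  if (attr(tf, "rmsd") > max_residual)
    stop("calibration residual ", formatC(attr(tf, "rmsd"), digits = 4),
         " mm exceeds limit ", max_residual, " mm", call. = FALSE)
  tf
}

#' Extreme vertex along a direction
#'
#' Deterministic helper for operationalizing landmarks such as the top of
#' the common crus or the bottom of an eyeball: the vertex maximizing the
#' dot product with `direction`; exact ties are broken toward the lowest
#' vertex index.
#'
#' @param mesh a [trimesh()] or point matrix.
#' @param direction length-3 direction (unit not required).
#' @return the length-3 extreme vertex.
#' @export
pick_extreme_landmark <- function(mesh, direction) {
  p <- as_points(mesh)
  if (nrow(p) == 0L) stop("empty mesh", call. = FALSE)
  d <- unit_vec(direction, "direction")
  s <- as.numeric(p %*% d)
  p[which.max(s), ]
}
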