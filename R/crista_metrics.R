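# Plane extraction for the crista ampullaris and the semicircular canals in
# the standardized head frame, and the angle tables that summarize them.
#
# Anatomical sign conventions (left ear, head frame): the superior
# (anterior) canal-plane normal points outward (-X), the posterior canal
# normal points inward (+X), and the lateral canal normal points downward
# (-Z). Right-ear structures are measured after reflection through the
# sagittal plane and obey the 180 - sagittal mirror relation.

canal_ids <- c("LAC", "LPC", "LHC", "RAC", "RPC", "RHC")

# reference directions enforcing the canal-normal conventions above
canal_reference_direction <- function(canal) {
  switch(canal,
    LAC = c(-1, 0, 0), LPC = c(1, 0, 0), LHC = c(0, 0, -1),
    RAC = c(1, 0, 0), RPC = c(-1, 0, 0), RHC = c(0, 0, -1),
    stop("unknown canal ID: ", canal, call. = FALSE))
}

# canonical crista-normal hemisphere per canal, taken from the published
# left-ear measurements (see reference_normals()); used as the sign
# reference for crista planes measured in the head frame
crista_reference_direction <- function(canal) {
  ref <- switch(canal,
    LPC = c(-1, 0, -1), LHC = c(1, 0, 0), LAC = c(1, 0, -1),
    RPC = c(1, 0, -1), RHC = c(-1, 0, 0), RAC = c(-1, 0, -1),
    stop("unknown canal ID: ", canal, call. = FALSE))
  ref / vnorm(ref)
}

#' Crista ampullaris surface patch
#'
#' A point sample of the saddle-shaped crista surface together with its
#' parent canal and the centroid of the housing ampulla. When the points
#' come from a structured u-v grid, pass `grid_dim = c(nu, nv)` (row-major
#' over v fastest) to enable triangulation by [extrude_cupula()].
#'
#' @param points n x 3 matrix (n >= 3, non-collinear), mm.
#' @param canal canal ID, one of LAC/LPC/LHC/RAC/RPC/RHC.
#' @param ampulla_centroid length-3 centroid of the ampulla, mm.
#' @param grid_dim optional `c(nu, nv)` grid dimensions.
#' @return object of class `"crista_patch"`.
#' @export
crista_patch <- function(points, canal, ampulla_centroid = NULL,
                         grid_dim = NULL) {
  p <- as_points(points)
  if (nrow(p) < 3L) stop("crista patch needs >= 3 points", call. = FALSE)
  if (!canal %in% canal_ids)
    stop("canal must be one of ", paste(canal_ids, collapse = "/"),
         call. = FALSE)
  if (!is.null(grid_dim) && prod(grid_dim) != nrow(p))
    stop("grid_dim inconsistent with point count", call. = FALSE)
  structure(list(points = p, canal = canal,
                 ampulla_centroid = if (is.null(ampulla_centroid)) NULL
                                    else as_vec3(ampulla_centroid),
                 grid_dim = grid_dim),
            class = "crista_patch")
}

#' Best-fit plane of a semicircular-canal centerline
#'
#' Total-least-squares plane through the centerline points, oriented by the
#' per-canal anatomical convention (superior outward, posterior inward,
#' lateral downward) when `canal` is given and orientation is requested.
#'
#' @param centerline_points n x 3 matrix spanning the canal loop, mm.
#' @param canal optional canal ID for sign orientation.
#' @param orient apply the anatomical sign convention.
#' @return a [plane()].
#' @export
canal_plane <- function(centerline_points, canal = NULL, orient = TRUE) {
  pl <- fit_plane(centerline_points)
  if (orient && !is.null(canal))
    pl <- orient_plane(pl, canal_reference_direction(canal))
  pl
}

#' Best-fit plane of a crista ampullaris patch
#'
#' The crista is a saddle, not a plane; its orientation is summarized by the
#' total-least-squares plane of the full surface patch (rather than a line
#' through two endpoints, which ignores most of the saddle). The normal sign
#' is fixed per canal by orienting into the canonical crista hemisphere of
#' the standardized frame (see `reference_normals()`), so left/right and
#' repeat measurements are comparable.
#'
#' @param patch a [crista_patch()].
#' @param orient apply the per-canal sign convention.
#' @return a [plane()].
#' @export
crista_plane <- function(patch, orient = TRUE) {
  stopifnot(inherits(patch, "crista_patch"))
  pl <- fit_plane(patch$points)
  if (orient)
    pl <- orient_plane(pl, crista_reference_direction(patch$canal))
  pl
}

#' Extrude a crista patch into a cupula model
#'
#' Sweeps the patch surface along a direction by a given height, producing a
#' closed prismatic mesh (bottom = patch, top = patch shifted, side walls on
#' the boundary): the crista shape extruded toward the roof of the ampulla
#' is the classical stand-in for the cupula. Requires a grid-structured
#' patch (`grid_dim` set).
#'
#' @param patch a [crista_patch()] with `grid_dim`.
#' @param direction extrusion direction (normalized internally).
#' @param height extrusion height, mm (> 0).
#' @return a watertight [trimesh()].
#' @export
extrude_cupula <- function(patch, direction, height) {
  stopifnot(inherits(patch, "crista_patch"))
  if (is.null(patch$grid_dim))
    stop("extrusion requires a grid-structured patch (grid_dim)",
         call. = FALSE)
  if (!is.finite(height) || height <= 0)
    stop("height must be a positive finite number", call. = FALSE)
  d <- unit_vec(direction, "direction")
  nu <- patch$grid_dim[1]; nv <- patch$grid_dim[2]
  bot <- patch$points
  top <- sweep(bot, 2L, height * d, `+`)
  v <- rbind(bot, top)
  nb <- nrow(bot)
  id <- function(i, j) (i - 1L) * nv + j          # row-major, v fastest
  fb <- list(); ft <- list()
  for (i in seq_len(nu - 1L)) for (j in seq_len(nv - 1L)) {
    a <- id(i, j); b <- id(i + 1L, j); cc <- id(i + 1L, j + 1L); e <- id(i, j + 1L)
    # bottom faces wound downward (outward = away from the solid)
    fb[[length(fb) + 1L]] <- rbind(c(a, cc, b), c(a, e, cc))
    ft[[length(ft) + 1L]] <- rbind(c(a, b, cc) + nb, c(a, cc, e) + nb)
  }
  # boundary loop of the grid, in the rotational direction of the bottom
  # winding; side faces traverse it reversed so half-edges pair up
  loop <- c(id(1L, seq_len(nv)),
            id(seq(2L, nu), nv),
            id(nu, rev(seq_len(nv - 1L))),
            if (nu > 2L) id(rev(seq(2L, nu - 1L)), 1L))
  fs <- list()
  for (k in seq_along(loop)) {
    a <- loop[k]; b <- loop[if (k == length(loop)) 1L else k + 1L]
    fs[[length(fs) + 1L]] <- rbind(c(b, a, a + nb), c(b, a + nb, b + nb))
  }
  m <- trimesh(v, do.call(rbind, c(fb, ft, fs)))
  if (mesh_volume(m) < 0)  # flip winding if the sweep direction was inward
    m <- trimesh(m$vertices, m$faces[, c(1L, 3L, 2L)])
  m
}

# Table 2-style default pair list: each crista against its own membranous
# and bony canal, membranous vs bony per canal, and the crista pairs.
default_pair_list <- function(labels) {
  pairs <- rbind(
    c("LPC_CA", "LPC_MEM"), c("LPC_CA", "LPC_BONY"), c("LPC_MEM", "LPC_BONY"),
    c("LHC_CA", "LHC_MEM"), c("LHC_CA", "LHC_BONY"), c("LHC_MEM", "LHC_BONY"),
    c("LAC_CA", "LAC_MEM"), c("LAC_CA", "LAC_BONY"), c("LAC_MEM", "LAC_BONY"),
    c("LPC_CA", "LHC_CA"), c("LPC_CA", "LAC_CA"), c("LHC_CA", "LAC_CA"))
  pairs[pairs[, 1] %in% labels & pairs[, 2] %in% labels, , drop = FALSE]
}

#' Angle tables for a set of labeled planes
#'
#' Produces the two standard summaries: the spatial-attitude table (per
#' plane: normal components and angles to the sagittal, coronal and
#' horizontal reference planes) and the pairwise-angle table for a
#' configured list of plane pairs. Values are kept at full precision;
#' rounding to 2 decimals happens only in [write_angle_tables()].
#'
#' @param planes named list of [plane()]s (unique labels).
#' @param pairs 2-column character matrix of label pairs; defaults to the
#'   standard 12-row list restricted to the labels present.
#' @return list of two data frames: `attitude` (label, A, B, C, sagittal,
#'   coronal, horizontal) and `pairwise` (label1, label2, angle).
#' @export
build_angle_tables <- function(planes, pairs = NULL) {
  labels <- names(planes)
  if (is.null(labels) || anyDuplicated(labels) || any(labels == ""))
    stop("planes must be a uniquely named list", call. = FALSE)
  att <- do.call(rbind, lapply(labels, function(lb) {
    n <- plane_normal(planes[[lb]])
    a <- reference_plane_angles(planes[[lb]])
    data.frame(label = lb, A = n[1], B = n[2], C = n[3],
               sagittal = a[["sagittal"]], coronal = a[["coronal"]],
               horizontal = a[["horizontal"]])
  }))
  if (is.null(pairs)) pairs <- default_pair_list(labels)
  pairs <- matrix(as.character(pairs), ncol = 2L)
  pw <- if (nrow(pairs)) {
    data.frame(label1 = pairs[, 1], label2 = pairs[, 2],
               angle = vapply(seq_len(nrow(pairs)), function(i)
                 angle_between_planes(planes[[pairs[i, 1]]],
                                      planes[[pairs[i, 2]]]), 0))
  } else data.frame(label1 = character(0), label2 = character(0),
                    angle = numeric(0))
  rownames(att) <- NULL
  list(attitude = att, pairwise = pw)
}

#' Write angle tables to CSV
#'
#' Serializes the output of [build_angle_tables()], with angles rounded to
#' 2 decimals and normal components to 4, matching the conventional printed
#' precision.
#'
#' @param tables list from [build_angle_tables()].
#' @param attitude_path,pairwise_path output CSV paths (`NULL` to skip).
#' @return `tables`, invisibly.
#' @export
write_angle_tables <- function(tables, attitude_path = NULL,
                               pairwise_path = NULL) {
  if (!is.null(attitude_path)) {
    att <- tables$attitude
    att[c("A", "B", "C")] <- lapply(att[c("A", "B", "C")], round, 4L)
    att[c("sagittal", "coronal", "horizontal")] <-
      lapply(att[c("sagittal", "coronal", "horizontal")], round, 2L)
    utils::write.csv(att, attitude_path, row.names = FALSE)
  }
  if (!is.null(pairwise_path)) {
    pw <- tables$pairwise
    pw$angle <- round(pw$angle, 2L)
    utils::write.csv(pw, pairwise_path, row.names = FALSE)
  }
  invisible(tables)
}
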