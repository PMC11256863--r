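# Synthetic labyrinth generator. Stands in for clinical MRI cohorts and
# micro-CT membranous-labyrinth models, which are not publicly deposited:
# every specimen carries a known ground truth (true crista/canal planes,
# landmarks, applied pose), so the full calibrate-and-measure pipeline can
# be validated by parameter recovery.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed",
                                            envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Parameters of the synthetic labyrinth
#'
#' Defaults describe a stylized bilateral inner-ear phantom in the
#' standardized head frame (mm): three mutually near-orthogonal
#' semicircular-canal circles per side with an ampulla at the utricular end
#' of each, a saddle-shaped crista patch inside each ampulla, a common
#' crus, and two eyeball spheres. Crista and canal plane normals default to
#' the published left-ear values of [reference_normals()] (a fixture
#' choice, so end-to-end runs reproduce the published angle tables, not an
#' anatomical claim); radii are plausible human scales.
#'
#' @param canal_radius named canal-circle radii, mm.
#' @param tube_radius canal duct tube radius, mm (< min canal radius).
#' @param ampulla_axes ellipsoid semi-axes of each ampulla, mm.
#' @param crista_extent half-extents `c(u, v)` of the crista patch, mm.
#' @param saddle_coeff saddle curvature coefficient c in
#'   `w = c (u^2 - v^2)`, 1/mm.
#' @param crista_grid patch grid resolution `c(nu, nv)`.
#' @param labyrinth_center center of the left labyrinth, mm (right side is
#'   the sagittal mirror).
#' @param eyeball_center,eyeball_radius left eyeball sphere, mm.
#' @param common_crus_top top of the left common crus, mm; its height
#'   matches the eyeball bottom so the four defining landmarks are coplanar
#'   in the canonical horizontal plane.
#' @param canal_normals,crista_normals named lists of left-side plane
#'   normals (membranous); bony canal normals are tilted from the
#'   membranous ones by `bony_tilt_deg`.
#' @param bony_tilt_deg angle between bony and membranous canal planes of
#'   the same canal, degrees.
#' @param rot_jitter_deg per-structure rotation jitter s.d. across a
#'   population, degrees.
#' @param size_jitter fractional isotropic size jitter s.d.
#' @param noise_sd isotropic surface-point noise s.d., mm.
#' @return list of class `"labyrinth_params"`.
#' @export
labyrinth_params <- function(
    canal_radius = c(AC = 3.2, PC = 3.1, HC = 2.9),
    tube_radius = 0.45,
    ampulla_axes = c(1.1, 0.9, 0.9),
    crista_extent = c(0.75, 0.5),
    saddle_coeff = 0.5,
    crista_grid = c(13L, 9L),
    labyrinth_center = c(-35, 0, 0),
    eyeball_center = c(-31, 62, 21),
    eyeball_radius = 11,
    common_crus_top = c(-33, -2, 10),
    canal_normals = list(AC = reference_normal("LAC_MEM"),
                         PC = reference_normal("LPC_MEM"),
                         HC = reference_normal("LHC_MEM")),
    crista_normals = list(AC = reference_normal("LAC_CA"),
                          PC = reference_normal("LPC_CA"),
                          HC = reference_normal("LHC_CA")),
    bony_tilt_deg = 1.5,
    rot_jitter_deg = 0,
    size_jitter = 0,
    noise_sd = 0) {
  if (tube_radius >= min(canal_radius))
    stop("tube radius must be smaller than every canal radius",
         call. = FALSE)
  if (any(canal_radius <= 0) || tube_radius <= 0 || any(ampulla_axes <= 0) ||
      eyeball_radius <= 0)
    stop("radii must be positive", call. = FALSE)
  if (rot_jitter_deg < 0 || size_jitter < 0 || noise_sd < 0)
    stop("jitter parameters must be non-negative", call. = FALSE)
  p <- list(canal_radius = canal_radius, tube_radius = tube_radius,
            ampulla_axes = ampulla_axes, crista_extent = crista_extent,
            saddle_coeff = saddle_coeff, crista_grid = as.integer(crista_grid),
            labyrinth_center = labyrinth_center,
            eyeball_center = eyeball_center, eyeball_radius = eyeball_radius,
            common_crus_top = common_crus_top,
            canal_normals = lapply(canal_normals, unit_vec),
            crista_normals = lapply(crista_normals, unit_vec),
            bony_tilt_deg = bony_tilt_deg, rot_jitter_deg = rot_jitter_deg,
            size_jitter = size_jitter, noise_sd = noise_sd)
  class(p) <- "labyrinth_params"
  p
}

# small random rotation with axis uniform on the sphere, angle N(0, sd_deg)
random_small_rotation <- function(sd_deg) {
  if (sd_deg == 0) return(diag(3))
  ax <- stats::rnorm(3)
  rotation_about_axis(ax, stats::rnorm(1, 0, sd_deg))
}

random_rigid_pose <- function(max_translation = 20) {
  ax <- stats::rnorm(3)
  rigid_transform(rotation_about_axis(ax, stats::runif(1, 0, 360)),
                  stats::runif(3, -max_translation, max_translation))
}

# orthonormal in-plane basis for a unit normal
plane_basis <- function(n) {
  h <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit_vec(vcross(n, h))
  e2 <- vcross(n, e1)
  list(e1 = e1, e2 = e2)
}

circle_points <- function(center, normal, radius, n) {
  b <- plane_basis(unit_vec(normal))
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  sweep(radius * (outer(cos(th), b$e1) + outer(sin(th), b$e2)), 2L, center,
        `+`)
}

# UV ellipsoid mesh (watertight, outward-wound)
make_ellipsoid <- function(center, axes, n_lat = 8L, n_lon = 12L) {
  lat <- seq(0, pi, length.out = n_lat + 1L)[-c(1L, n_lat + 1L)]
  lon <- seq(0, 2 * pi, length.out = n_lon + 1L)[-(n_lon + 1L)]
  ring <- function(phi)
    cbind(axes[1] * sin(phi) * cos(lon), axes[2] * sin(phi) * sin(lon),
          axes[3] * cos(phi))
  v <- rbind(c(0, 0, axes[3]), do.call(rbind, lapply(lat, ring)),
             c(0, 0, -axes[3]))
  v <- sweep(v, 2L, center, `+`)
  nr <- length(lat); np <- n_lon
  idx <- function(r, k) 1L + (r - 1L) * np + ((k - 1L) %% np) + 1L
  f <- list()
  for (k in seq_len(np))                       # top cap
    f[[length(f) + 1L]] <- c(1L, idx(1L, k), idx(1L, k + 1L))
  for (r in seq_len(nr - 1L)) for (k in seq_len(np)) {
    f[[length(f) + 1L]] <- c(idx(r, k), idx(r + 1L, k), idx(r + 1L, k + 1L))
    f[[length(f) + 1L]] <- c(idx(r, k), idx(r + 1L, k + 1L), idx(r, k + 1L))
  }
  bot <- nrow(v)
  for (k in seq_len(np))                       # bottom cap
    f[[length(f) + 1L]] <- c(bot, idx(nr, k + 1L), idx(nr, k))
  m <- trimesh(v, do.call(rbind, f))
  if (mesh_volume(m) < 0) m <- trimesh(m$vertices, m$faces[, c(1L, 3L, 2L)])
  m
}

# torus mesh around a circle of radius R with tube radius r (watertight)
make_torus <- function(center, normal, R, r, n_u = 24L, n_v = 8L) {
  b <- plane_basis(unit_vec(normal))
  n <- unit_vec(normal)
  u <- seq(0, 2 * pi, length.out = n_u + 1L)[-(n_u + 1L)]
  v <- seq(0, 2 * pi, length.out = n_v + 1L)[-(n_v + 1L)]
  verts <- matrix(0, n_u * n_v, 3L)
  for (i in seq_len(n_u)) {
    radial <- cos(u[i]) * b$e1 + sin(u[i]) * b$e2
    for (j in seq_len(n_v)) {
      verts[(i - 1L) * n_v + j, ] <- center + (R + r * cos(v[j])) * radial +
        r * sin(v[j]) * n
    }
  }
  idx <- function(i, j) ((i - 1L) %% n_u) * n_v + ((j - 1L) %% n_v) + 1L
  f <- list()
  for (i in seq_len(n_u)) for (j in seq_len(n_v)) {
    f[[length(f) + 1L]] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
    f[[length(f) + 1L]] <- c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  }
  m <- trimesh(verts, do.call(rbind, f))
  if (mesh_volume(m) < 0) m <- trimesh(m$vertices, m$faces[, c(1L, 3L, 2L)])
  m
}

# tapered tube for the common crus, closed at both ends; the apex is a
# single vertex (cone tip) so extreme-vertex landmarking finds it uniquely
make_capped_cylinder <- function(base, apex, radius, n_u = 10L, n_h = 4L) {
  axis <- unit_vec(apex - base)
  b <- plane_basis(axis)
  u <- seq(0, 2 * pi, length.out = n_u + 1L)[-(n_u + 1L)]
  hs <- seq(0, 0.85, length.out = n_h + 1L)
  L <- vnorm(apex - base)
  v <- do.call(rbind, lapply(hs, function(h) {
    ctr <- base + h * L * axis
    sweep(radius * (outer(cos(u), b$e1) + outer(sin(u), b$e2)), 2L, ctr, `+`)
  }))
  v <- rbind(v, base, apex)
  i_base <- nrow(v) - 1L; i_apex <- nrow(v)
  idx <- function(r, k) (r - 1L) * n_u + ((k - 1L) %% n_u) + 1L
  f <- list()
  for (r in seq_len(n_h)) for (k in seq_len(n_u)) {
    f[[length(f) + 1L]] <- c(idx(r, k), idx(r + 1L, k), idx(r + 1L, k + 1L))
    f[[length(f) + 1L]] <- c(idx(r, k), idx(r + 1L, k + 1L), idx(r, k + 1L))
  }
  for (k in seq_len(n_u)) {
    f[[length(f) + 1L]] <- c(i_base, idx(1L, k), idx(1L, k + 1L))
    f[[length(f) + 1L]] <- c(i_apex, idx(n_h + 1L, k + 1L), idx(n_h + 1L, k))
  }
  m <- trimesh(v, do.call(rbind, f))
  if (mesh_volume(m) < 0) m <- trimesh(m$vertices, m$faces[, c(1L, 3L, 2L)])
  m
}

# deterministic Fibonacci sphere sample
fib_sphere <- function(center, radius, n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  sweep(radius * cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi)),
        2L, center, `+`)
}

canal_keys <- c("AC", "PC", "HC")

# Build one side of the canonical anatomy from (possibly jittered) params.
# Returns clouds (points+labels), patches, centerlines, landmarks, meshes,
# and the true planes.
build_side <- function(p, side, with_meshes = TRUE) {
  mirror_if_right <- function(x) if (side == "R") {
    if (is.matrix(x)) { x[, 1] <- -x[, 1]; x } else { x[1] <- -x[1]; x }
  } else x
  lab_ctr <- mirror_if_right(p$labyrinth_center)
  pts <- list(); labs <- list()
  patches <- list(); centerlines <- list(); meshes <- list()
  true_planes <- list()
  canal_offsets <- list(AC = c(0.5, 1.5, 1.5), PC = c(0.5, -1.5, 1.5),
                        HC = c(0, 0, -0.5))
  for (ck in canal_keys) {
    id <- paste0(side, ck)
    n_mem <- mirror_if_right(p$canal_normals[[ck]])
    # bony canal: tilted from the membranous plane by a fixed small angle
    tilt_axis <- plane_basis(n_mem)$e1
    n_bony <- as.numeric(rotation_about_axis(tilt_axis, p$bony_tilt_deg) %*%
                           n_mem)
    ctr <- lab_ctr + mirror_if_right(canal_offsets[[ck]])
    R <- p$canal_radius[[ck]]
    cl_mem <- circle_points(ctr, n_mem, R, 36L)
    cl_bony <- circle_points(ctr, n_bony, R * 1.05, 36L)
    centerlines[[paste0(id, "_MEM")]] <- cl_mem
    centerlines[[paste0(id, "_BONY")]] <- cl_bony
    # ampulla at the first centerline point (the canal's utricular end)
    amp_ctr <- cl_mem[1L, ]
    amp <- fib_sphere(amp_ctr, 1, 30L)
    amp <- sweep(sweep(amp, 2L, amp_ctr) %*% diag(p$ampulla_axes), 2L,
                 amp_ctr, `+`)
    # saddle crista patch centered in the ampulla with the true normal
    n_ca <- mirror_if_right(p$crista_normals[[ck]])
    bb <- plane_basis(n_ca)
    nu <- p$crista_grid[1]; nv <- p$crista_grid[2]
    us <- seq(-p$crista_extent[1], p$crista_extent[1], length.out = nu)
    vs <- seq(-p$crista_extent[2], p$crista_extent[2], length.out = nv)
    gr <- expand.grid(v = vs, u = us)            # v fastest (row-major grid)
    patch_pts <- sweep(outer(gr$u, bb$e1) + outer(gr$v, bb$e2) +
                         outer(p$saddle_coeff * (gr$u^2 - gr$v^2), n_ca),
                       2L, amp_ctr, `+`)
    patches[[paste0(id, "_CA")]] <-
      crista_patch(patch_pts, id, amp_ctr, grid_dim = c(nu, nv))
    true_planes[[paste0(id, "_CA")]] <- plane_from_point_normal(amp_ctr, n_ca)
    true_planes[[paste0(id, "_MEM")]] <- plane_from_point_normal(ctr, n_mem)
    true_planes[[paste0(id, "_BONY")]] <- plane_from_point_normal(ctr, n_bony)
    pts <- c(pts, list(cl_mem, cl_bony, amp, patch_pts))
    labs <- c(labs, list(rep(paste0(id, "_MEM"), nrow(cl_mem)),
                         rep(paste0(id, "_BONY"), nrow(cl_bony)),
                         rep(paste0(id, "_AMP"), nrow(amp)),
                         rep(paste0(id, "_CA"), nrow(patch_pts))))
    if (with_meshes) {
      meshes[[paste0(id, "_duct")]] <- make_torus(ctr, n_mem, R,
                                                  p$tube_radius)
      meshes[[paste0(id, "_ampulla")]] <-
        make_ellipsoid(amp_ctr, p$ampulla_axes)
    }
  }
  # common crus and eyeball
  cc_top <- mirror_if_right(p$common_crus_top)
  cc_base <- cc_top - c(0, 0, 6)
  eye_ctr <- mirror_if_right(p$eyeball_center)
  eye <- fib_sphere(eye_ctr, p$eyeball_radius, 42L)
  cc <- circle_points(cc_base + c(0, 0, 1), c(0, 0, 1), 0.6, 10L)
  cc <- rbind(cc, circle_points(cc_top - c(0, 0, 0.5), c(0, 0, 1), 0.4, 10L),
              cc_top)
  pts <- c(pts, list(cc, eye))
  labs <- c(labs, list(rep(paste0("CC_", side), nrow(cc)),
                       rep(paste0("EYE_", side), nrow(eye))))
  if (with_meshes) {
    meshes[[paste0("CC_", side)]] <- make_capped_cylinder(cc_base, cc_top, 0.5)
    meshes[[paste0("EYE_", side)]] <- make_ellipsoid(eye_ctr,
                                                     rep(p$eyeball_radius, 3L),
                                                     n_lat = 10L, n_lon = 14L)
  }
  landmarks <- list()
  landmarks[[paste0("common_crus_top_", tolower_side(side))]] <- cc_top
  landmarks[[paste0("eyeball_bottom_", tolower_side(side))]] <-
    eye_ctr - c(0, 0, p$eyeball_radius)
  landmarks[[paste0("labyrinth_centroid_", tolower_side(side))]] <- lab_ctr
  lm_pts <- do.call(rbind, landmarks)
  pts <- c(pts, list(lm_pts))
  labs <- c(labs, list(paste0("LM_", names(landmarks))))
  list(points = do.call(rbind, pts), labels = unlist(labs),
       patches = patches, centerlines = centerlines, landmarks = landmarks,
       meshes = meshes, true_planes = true_planes)
}

tolower_side <- function(side) if (side == "L") "left" else "right"

# exact sagittal mirror of a built side: guarantees pointwise left/right
# mirror correspondence in the cloud layout
mirror_side <- function(side) {
  ren <- function(x) { names(x) <- mirror_label(names(x)); x }
  list(
    points = mirror_sagittal(side$points),
    labels = mirror_label(side$labels),
    patches = ren(lapply(side$patches, function(pa)
      crista_patch(mirror_sagittal(pa$points), mirror_label(pa$canal),
                   { a <- pa$ampulla_centroid; a[1] <- -a[1]; a },
                   grid_dim = pa$grid_dim))),
    centerlines = ren(lapply(side$centerlines, mirror_sagittal)),
    landmarks = ren(lapply(side$landmarks,
                           function(v) { v[1] <- -v[1]; v })),
    meshes = ren(lapply(side$meshes, mirror_sagittal)),
    true_planes = ren(lapply(side$true_planes, mirror_sagittal)))
}

#' Generate one synthetic labyrinth specimen
#'
#' Builds the bilateral canonical anatomy from `params`, optionally
#' perturbs it (per-canal rotation jitter, isotropic size jitter, surface
#' noise) and applies a rigid pose. The ground truth (true planes,
#' landmarks, and the applied pose) refers to the specimen's own, possibly
#' jittered, anatomy and is recorded so that recovery after calibration can
#' be checked exactly.
#'
#' @param params a [labyrinth_params()].
#' @param seed RNG seed (noise/jitter/pose); generation is deterministic
#'   given `params`, `seed` and `pose`.
#' @param pose `NULL` (canonical), `"random"`, or a [rigid_transform()].
#' @param with_meshes also build the surface meshes (slower).
#' @return object of class `"labyrinth_specimen"`: `cloud`
#'   ([corresponded_shape()]), `patches`, `centerlines`, `landmarks`,
#'   `meshes`, `ground_truth` (list with `true_planes`, `landmarks`,
#'   `pose`), and `params`.
#' @export
generate_specimen <- function(params = labyrinth_params(), seed = 1L,
                              pose = NULL, with_meshes = TRUE) {
  stopifnot(inherits(params, "labyrinth_params"))
  with_seed(seed, {
    p <- params
    # parameter-level shape jitter keeps every representation consistent
    if (p$rot_jitter_deg > 0) {
      for (ck in canal_keys) {
        Rj <- random_small_rotation(p$rot_jitter_deg)
        p$canal_normals[[ck]] <- as.numeric(Rj %*% p$canal_normals[[ck]])
        p$crista_normals[[ck]] <- as.numeric(Rj %*% p$crista_normals[[ck]])
      }
    }
    if (p$size_jitter > 0) {
      s <- exp(stats::rnorm(1, 0, p$size_jitter))
      p$canal_radius <- p$canal_radius * s
      p$tube_radius <- p$tube_radius * s
      p$ampulla_axes <- p$ampulla_axes * s
      p$crista_extent <- p$crista_extent * s
      p$eyeball_radius <- p$eyeball_radius * s
      p$labyrinth_center <- p$labyrinth_center * s
      p$eyeball_center <- p$eyeball_center * s
      p$common_crus_top <- p$common_crus_top * s
    }
    left <- build_side(p, "L", with_meshes)
    right <- mirror_side(left)
    points <- rbind(left$points, right$points)
    labels <- c(left$labels, right$labels)
    if (p$noise_sd > 0)
      points <- points + matrix(stats::rnorm(length(points), 0, p$noise_sd),
                                ncol = 3L)
    tf <- if (is.null(pose)) rigid_transform()
          else if (identical(pose, "random")) random_rigid_pose()
          else pose
    cloud <- corresponded_shape(apply_transform(points, tf), labels)
    # patches and centerlines are re-extracted from the noised, posed cloud
    # so every representation of a structure is identical
    pick <- function(lb) cloud$points[cloud$labels == lb, , drop = FALSE]
    patches0 <- c(left$patches, right$patches)
    patches <- lapply(names(patches0), function(lb) {
      pa <- patches0[[lb]]
      crista_patch(pick(lb), pa$canal,
                   apply_transform(rbind(pa$ampulla_centroid), tf)[1L, ],
                   grid_dim = pa$grid_dim)
    })
    names(patches) <- names(patches0)
    centerlines0 <- c(left$centerlines, right$centerlines)
    centerlines <- lapply(names(centerlines0), pick)
    names(centerlines) <- names(centerlines0)
    landmarks0 <- c(left$landmarks, right$landmarks)
    landmarks <- lapply(names(landmarks0), function(nm)
      cloud$points[cloud$labels == paste0("LM_", nm), , drop = FALSE][1L, ])
    names(landmarks) <- names(landmarks0)
    specimen <- list(
      cloud = cloud,
      patches = patches,
      centerlines = centerlines,
      landmarks = landmarks,
      meshes = lapply(c(left$meshes, right$meshes), apply_transform, t = tf),
      ground_truth = list(true_planes = c(left$true_planes,
                                          right$true_planes),
                          landmarks = c(left$landmarks, right$landmarks),
                          pose = tf),
      params = p)
    class(specimen) <- "labyrinth_specimen"
    specimen
  })
}

#' @export
print.labyrinth_specimen <- function(x, ...) {
  cat(sprintf("Synthetic labyrinth specimen: %d cloud points, %d meshes\n",
              nrow(x$cloud$points), length(x$meshes)))
  invisible(x)
}

#' Generate a synthetic population
#'
#' Each specimen shares the canonical anatomy of `params` plus its own
#' shape jitter, surface noise and random rigid pose. The canonical
#' (unjittered, unposed) specimen is returned alongside as the recovery
#' target for the mean-model and head-frame pipeline.
#'
#' @param n number of specimens (>= 2).
#' @param params a [labyrinth_params()] (its jitter/noise fields set the
#'   population variability).
#' @param seed RNG seed.
#' @param with_meshes build meshes for each specimen (slow; default off).
#' @return list of class `"labyrinth_population"`: `specimens` (list),
#'   `canonical` (zero-jitter specimen in canonical pose), `params`.
#' @export
generate_population <- function(n, params = labyrinth_params(), seed = 1L,
                                with_meshes = FALSE) {
  if (n < 2L) stop("a population needs n >= 2", call. = FALSE)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n + 1L))
  canon_params <- params
  canon_params$rot_jitter_deg <- 0
  canon_params$size_jitter <- 0
  canon_params$noise_sd <- 0
  canonical <- generate_specimen(canon_params, seed = seeds[n + 1L],
                                 pose = NULL, with_meshes = FALSE)
  specimens <- lapply(seq_len(n), function(i)
    generate_specimen(params, seed = seeds[i], pose = "random",
                      with_meshes = with_meshes))
  structure(list(specimens = specimens, canonical = canonical,
                 params = params), class = "labyrinth_population")
}

#' @export
print.labyrinth_population <- function(x, ...) {
  cat(sprintf("Synthetic labyrinth population: %d specimens\n",
              length(x$specimens)))
  invisible(x)
}

# side of each label: canal labels start L../R.., others end _L/_R or name
# a left/right landmark
label_side <- function(labels) {
  side <- rep(NA_character_, length(labels))
  side[grepl("^L(AC|PC|HC)", labels)] <- "left"
  side[grepl("^R(AC|PC|HC)", labels)] <- "right"
  side[grepl("_L$|_left$", labels)] <- "left"
  side[grepl("_R$|_right$", labels)] <- "right"
  side
}

# mirror counterpart of each label (LPC_MEM <-> RPC_MEM, CC_L <-> CC_R, ...)
mirror_label <- function(labels) {
  out <- labels
  out <- sub("^L(AC|PC|HC)", "X\\1", out)
  out <- sub("^R(AC|PC|HC)", "L\\1", out)
  out <- sub("^X(AC|PC|HC)", "R\\1", out)
  swap <- function(x, a, b) {
    x <- sub(paste0(a, "$"), "@@", x)
    x <- sub(paste0(b, "$"), a, x)
    sub("@@$", b, x)
  }
  out <- swap(out, "_L", "_R")
  swap(out, "_left", "_right")
}

# split a corresponded shape into mirror-ordered left/right point blocks
split_sides <- function(shape) {
  stopifnot(inherits(shape, "corresponded_shape"))
  side <- label_side(shape$labels)
  li <- which(side == "left")
  key <- paste(shape$labels, stats::ave(seq_along(shape$labels),
                                        shape$labels, FUN = seq_along))
  mkey <- paste(mirror_label(shape$labels[li]),
                stats::ave(seq_along(li), shape$labels[li], FUN = seq_along))
  ri <- match(mkey, key)
  if (anyNA(ri))
    stop("left and right structures are not mirror-labelled", call. = FALSE)
  list(left = shape$points[li, , drop = FALSE],
       right = shape$points[ri, , drop = FALSE])
}
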