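# Triangle mesh container and validity checks. Vertices are stored as an
# n x 3 double matrix (mm); faces as an m x 3 integer matrix of 1-based
# vertex indices with counter-clockwise (outward) winding.

#' Triangle mesh
#'
#' @param vertices n x 3 numeric matrix of vertex positions, mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return object of class `"trimesh"`.
#' @export
trimesh <- function(vertices, faces) {
  v <- as_points(vertices)
  f <- as.matrix(faces)
  if (nrow(v) == 0L) stop("mesh has no vertices", call. = FALSE)
  if (ncol(f) != 3L) stop("faces must have 3 columns", call. = FALSE)
  storage.mode(f) <- "integer"
  dimnames(f) <- NULL
  if (nrow(f) > 0L && (min(f) < 1L || max(f) > nrow(v)))
    stop("face indices out of range", call. = FALSE)
  structure(list(vertices = v, faces = f), class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("Triangle mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Surface area of a triangle mesh
#' @param mesh a [trimesh()].
#' @return total area, mm^2.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Enclosed volume of a closed triangle mesh
#'
#' Signed volume by the divergence theorem; positive for outward-oriented
#' watertight meshes.
#' @param mesh a [trimesh()].
#' @return volume, mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) +
      p1[, 2] * (p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

#' Watertightness and orientation check
#'
#' A mesh is watertight and consistently oriented when every undirected edge
#' is shared by exactly two faces and every directed half-edge appears
#' exactly once.
#' @param mesh a [trimesh()].
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(FALSE)
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  directed <- paste(he[, 1], he[, 2])
  if (anyDuplicated(directed)) return(FALSE)
  und <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  all(table(und) == 2L)
}

# --- minimal ASCII mesh I/O (PLY / OBJ / STL) --------------------------------

#' Read a triangle mesh from file
#'
#' Supports ASCII PLY, OBJ and STL, selected by file extension. Point-cloud
#' PLY files (no faces) are returned as meshes with zero faces.
#'
#' @param path file path ending in `.ply`, `.obj` or `.stl`.
#' @return a [trimesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    ply = read_ply(path),
    obj = read_obj(path),
    stl = read_stl(path),
    stop("unsupported mesh format '.", ext,
         "'; supported formats: .ply, .obj, .stl", call. = FALSE))
  if (nrow(m$vertices) == 0L) stop("empty mesh in ", path, call. = FALSE)
  m
}

#' Write a triangle mesh to file
#'
#' Format chosen by extension (`.ply`, `.obj` or `.stl`), always ASCII.
#' Round-tripping preserves vertex coordinates to full double precision for
#' PLY/OBJ and to the printed precision for STL.
#'
#' @param mesh a [trimesh()] (or bare point matrix, written as vertices only).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  if (!inherits(mesh, "trimesh"))
    mesh <- trimesh(mesh, matrix(integer(0), 0L, 3L))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = write_ply(mesh, path),
    obj = write_obj(mesh, path),
    stl = write_stl(mesh, path),
    stop("unsupported mesh format '.", ext,
         "'; supported formats: .ply, .obj, .stl", call. = FALSE))
  invisible(path)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || lines[1] != "ply")
    stop("not a PLY file: ", path, call. = FALSE)
  end <- match("end_header", lines)
  if (is.na(end)) stop("PLY header not terminated in ", path, call. = FALSE)
  header <- lines[seq_len(end)]
  if (!any(grepl("^format ascii", header)))
    stop("only ASCII PLY is supported: ", path, call. = FALSE)
  nv <- as.integer(sub("^element vertex\\s+", "",
                       grep("^element vertex", header, value = TRUE)[1]))
  nfl <- grep("^element face", header, value = TRUE)
  nf <- if (length(nfl)) as.integer(sub("^element face\\s+", "", nfl[1])) else 0L
  body <- lines[-seq_len(end)]
  vt <- utils::read.table(text = body[seq_len(nv)], colClasses = "numeric")
  v <- as.matrix(vt[, 1:3])
  f <- matrix(integer(0), 0L, 3L)
  if (nf > 0L) {
    ft <- utils::read.table(text = body[nv + seq_len(nf)])
    if (any(ft[, 1] != 3L))
      stop("non-triangular faces in ", path, call. = FALSE)
    f <- as.matrix(ft[, 2:4]) + 1L  # PLY is 0-based
  }
  trimesh(v, f)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nv),
               "property double x", "property double y", "property double z",
               paste("element face", nf),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(paste(fmt_num(mesh$vertices[, 1]), fmt_num(mesh$vertices[, 2]),
                   fmt_num(mesh$vertices[, 3])), con)
  if (nf > 0L)
    writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  v <- as.matrix(utils::read.table(text = vl)[, 2:4])
  f <- matrix(integer(0), 0L, 3L)
  if (length(fl)) {
    toks <- strsplit(sub("^f\\s+", "", fl), "\\s+")
    idx <- lapply(toks, function(tk) as.integer(sub("/.*$", "", tk)))
    if (any(lengths(idx) != 3L))
      stop("non-triangular faces in ", path, call. = FALSE)
    f <- do.call(rbind, idx)
  }
  trimesh(v, f)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("v", fmt_num(mesh$vertices[, 1]),
                   fmt_num(mesh$vertices[, 2]), fmt_num(mesh$vertices[, 3])),
             con)
  if (nrow(mesh$faces) > 0L)
    writeLines(paste("f", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]),
               con)
}

read_stl <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  if (!grepl("^solid", lines[1]))
    stop("only ASCII STL is supported: ", path, call. = FALSE)
  vl <- grep("^vertex ", lines, value = TRUE)
  if (length(vl) %% 3L != 0L)
    stop("malformed STL (vertex count not a multiple of 3): ", path,
         call. = FALSE)
  coords <- as.matrix(utils::read.table(text = vl)[, 2:4])
  # merge exactly coincident vertices so shared edges are recognized
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  uk <- !duplicated(key)
  id <- match(key, key[uk])
  v <- coords[uk, , drop = FALSE]
  f <- matrix(id, ncol = 3L, byrow = TRUE)
  trimesh(v, f)
}

write_stl <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  if (nrow(f) > 0L) {
    a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
    len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
    n <- n / len
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        paste("facet normal", fmt_num(n[i, 1]), fmt_num(n[i, 2]),
              fmt_num(n[i, 3])),
        "  outer loop",
        paste("    vertex", fmt_num(v[f[i, 1], 1]), fmt_num(v[f[i, 1], 2]),
              fmt_num(v[f[i, 1], 3])),
        paste("    vertex", fmt_num(v[f[i, 2], 1]), fmt_num(v[f[i, 2], 2]),
              fmt_num(v[f[i, 2], 3])),
        paste("    vertex", fmt_num(v[f[i, 3], 1]), fmt_num(v[f[i, 3], 2]),
              fmt_num(v[f[i, 3], 3])),
        "  endloop", "endfacet"), con)
    }
  }
  writeLines("endsolid mesh", con)
}
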