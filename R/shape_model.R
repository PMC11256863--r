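# Population shape modelling: point correspondence, Procrustes alignment and
# iterative averaging into a standard (mean) inner-ear model. The averaging
# loop re-references on the running mean so the converged model does not
# depend on which specimen was picked first.

#' Corresponded shape
#'
#' An ordered point set with one structure label per point. All shapes of a
#' population share the same point count and label layout, so point `i` of
#' one specimen corresponds anatomically to point `i` of every other.
#'
#' @param points K x 3 matrix, mm.
#' @param labels character/factor vector of length K (structure IDs).
#' @return object of class `"corresponded_shape"`.
#' @export
corresponded_shape <- function(points, labels = NULL) {
  p <- as_points(points)
  if (is.null(labels)) labels <- rep("all", nrow(p))
  labels <- as.character(labels)
  if (length(labels) != nrow(p))
    stop("one label per point required", call. = FALSE)
  structure(list(points = p, labels = labels), class = "corresponded_shape")
}

#' @export
print.corresponded_shape <- function(x, ...) {
  cat(sprintf("Corresponded shape: %d points, %d structures\n",
              nrow(x$points), length(unique(x$labels))))
  invisible(x)
}

centroid_size <- function(p) {
  p <- as_points(p)
  sqrt(sum(sweep(p, 2L, colMeans(p))^2))
}

#' Least-squares rigid / similarity alignment (Procrustes)
#'
#' Finds the proper rotation, translation and (optionally) isotropic scale
#' minimizing the summed squared distances between corresponded point sets,
#' by the SVD solution of the cross-covariance with the determinant
#' constrained to +1 (no reflections).
#'
#' @param moving,fixed corresponded point sets (equal K x 3).
#' @param allow_scale estimate an isotropic scale factor as well.
#' @return a [rigid_transform()] mapping `moving` onto `fixed`; attribute
#'   `"rmsd"` holds the post-alignment root-mean-square distance, mm.
#' @export
procrustes_align <- function(moving, fixed, allow_scale = FALSE) {
  X <- as_points(moving); Y <- as_points(fixed)
  if (nrow(X) != nrow(Y))
    stop("point counts differ: ", nrow(X), " vs ", nrow(Y), call. = FALSE)
  if (nrow(X) < 3L) stop("need at least 3 points", call. = FALSE)
  cx <- colMeans(X); cy <- colMeans(Y)
  X0 <- sweep(X, 2L, cx); Y0 <- sweep(Y, 2L, cy)
  H <- crossprod(X0, Y0)           # 3x3 cross-covariance
  sv <- svd(H)
  if (sv$d[2] < max(sv$d[1], 1e-300) * 1e-12)
    stop("degenerate configuration (rank < 2); cannot align", call. = FALSE)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  s <- if (allow_scale) sum(sv$d * diag(D)) / sum(X0^2) else 1
  tr <- cy - s * as.numeric(R %*% cx)
  out <- rigid_transform(R, tr, scale = s)
  fit <- apply_transform(X, out)
  attr(out, "rmsd") <- sqrt(mean(rowSums((fit - Y)^2)))
  out
}

# Brute-force nearest neighbours of each query row in target; returns index
# vector. Chunked so the distance matrix stays modest.
nearest_neighbor <- function(query, target, chunk = 512L) {
  q <- as_points(query); tg <- as_points(target)
  t2 <- rowSums(tg^2)
  idx <- integer(nrow(q))
  for (st in seq(1L, nrow(q), by = chunk)) {
    en <- min(st + chunk - 1L, nrow(q))
    d <- outer(rowSums(q[st:en, , drop = FALSE]^2), t2, `+`) -
      2 * q[st:en, , drop = FALSE] %*% t(tg)
    idx[st:en] <- max.col(-d, ties.method = "first")
  }
  idx
}

#' Establish point correspondence with a reference shape
#'
#' Label-constrained iterative-closest-point matching: the reference is
#' rigidly registered to the input cloud, each reference point is matched to
#' the nearest input point carrying the same structure label, and
#' registration and matching alternate until the mean match distance
#' stabilizes. The returned shape consists of K input points (in the input's
#' coordinates), one per reference point.
#'
#' @param cloud input points: a matrix, `trimesh` or `corresponded_shape`.
#' @param cloud_labels structure label per input point (defaults to the
#'   cloud's own labels, or a single shared label).
#' @param reference a [corresponded_shape()] defining the layout.
#' @param init optional [rigid_transform()] pre-alignment of the reference
#'   into the cloud's frame; defaults to centroid translation.
#' @param max_iter,tol iteration cap and convergence tolerance on the change
#'   in mean match distance, mm.
#' @return a [corresponded_shape()]; attributes `"residual"` (final mean
#'   match distance, mm) and `"iterations"`.
#' @export
establish_correspondence <- function(cloud, reference, cloud_labels = NULL,
                                     init = NULL, max_iter = 100L,
                                     tol = 1e-3) {
  stopifnot(inherits(reference, "corresponded_shape"))
  p <- as_points(cloud)
  if (nrow(p) == 0L) stop("empty input cloud", call. = FALSE)
  if (is.null(cloud_labels)) {
    cloud_labels <- if (inherits(cloud, "corresponded_shape")) cloud$labels
                    else rep("all", nrow(p))
  }
  ref <- reference$points
  rlab <- reference$labels
  if (all(rlab %in% unique(cloud_labels))) {
    groups <- lapply(split(seq_len(nrow(p)), cloud_labels), identity)
  } else {
    # no usable labels on the cloud: match globally
    rlab <- rep("all", nrow(ref))
    cloud_labels <- rep("all", nrow(p))
    groups <- list(all = seq_len(nrow(p)))
  }
  cur <- if (is.null(init)) {
    rigid_transform(translation = colMeans(p) - colMeans(ref))
  } else init
  moved <- apply_transform(ref, cur)
  prev <- Inf
  match_idx <- integer(nrow(ref))
  for (it in seq_len(max_iter)) {
    for (lb in unique(rlab)) {
      ri <- which(rlab == lb)
      ci <- groups[[lb]]
      match_idx[ri] <- ci[nearest_neighbor(moved[ri, , drop = FALSE],
                                           p[ci, , drop = FALSE])]
    }
    matched <- p[match_idx, , drop = FALSE]
    resid <- mean(sqrt(rowSums((moved - matched)^2)))
    if (is.finite(prev) && abs(prev - resid) < tol) {
      return(structure(corresponded_shape(matched, rlab),
                       residual = resid, iterations = it))
    }
    prev <- resid
    cur <- procrustes_align(ref, matched)
    moved <- apply_transform(ref, cur)
  }
  stop("correspondence did not converge after ", max_iter,
       " iterations (last mean match distance ",
       formatC(prev, format = "g", digits = 4), " mm)", call. = FALSE)
}

#' Build the mean (standard) shape model of a population
#'
#' Generalized-Procrustes-style averaging: all shapes are aligned to the
#' current reference, averaged pointwise, and the average becomes the new
#' reference, iterating until the mean point displacement between successive
#' averages drops below `tol`. Re-referencing on the running mean removes
#' the dependence on the initial reference choice. With `allow_scale` the
#' alignment uses similarity transforms and the mean is rescaled to the mean
#' centroid size of the population so sizes do not drift.
#'
#' @param population list of [corresponded_shape()]s with identical layout.
#' @param tol convergence tolerance on mean point displacement, mm.
#' @param max_iter iteration cap.
#' @param allow_scale use similarity (not rigid) alignment; default `TRUE`
#'   because inner-ear size varies across subjects.
#' @return object of class `"mean_shape_model"`: `mean` (corresponded
#'   shape), `history` (mean displacement per iteration, mm), `n`.
#' @export
build_mean_model <- function(population, tol = 1e-3, max_iter = 100L,
                             allow_scale = TRUE) {
  if (length(population) < 2L) stop("need at least 2 shapes", call. = FALSE)
  stopifnot(all(vapply(population, inherits, TRUE, "corresponded_shape")))
  K <- nrow(population[[1]]$points)
  labs <- population[[1]]$labels
  for (s in population)
    if (nrow(s$points) != K || !identical(s$labels, labs))
      stop("all shapes must share point count and label layout",
           call. = FALSE)
  target_size <- mean(vapply(population, function(s)
    centroid_size(s$points), 0))
  ref <- population[[1]]$points
  history <- numeric(0)
  for (it in seq_len(max_iter)) {
    aligned <- lapply(population, function(s)
      apply_transform(s$points,
                      procrustes_align(s$points, ref,
                                       allow_scale = allow_scale)))
    m <- Reduce(`+`, aligned) / length(aligned)
    if (allow_scale) {
      m <- sweep(m, 2L, colMeans(m))
      m <- m * (target_size / centroid_size(m))
      m <- sweep(m, 2L, colMeans(ref), `+`)
    }
    delta <- mean(sqrt(rowSums((m - ref)^2)))
    history <- c(history, delta)
    ref <- m
    if (delta < tol) break
  }
  if (delta >= tol)
    stop("mean model did not stabilize within ", max_iter,
         " iterations; displacement history: ",
         paste(formatC(history, format = "g", digits = 3), collapse = ", "),
         call. = FALSE)
  structure(list(mean = corresponded_shape(ref, labs),
                 history = history, n = length(population)),
            class = "mean_shape_model")
}

#' @export
print.mean_shape_model <- function(x, ...) {
  cat(sprintf(
    "Mean shape model of %d specimens: %d points, converged in %d iterations\n",
    x$n, nrow(x$mean$points), length(x$history)))
  invisible(x)
}

#' Principal modes of shape variation
#'
#' PCA of the population residuals about the mean after alignment; provided
#' for population description, the downstream plane measurements use only
#' the mean geometry.
#'
#' @param model a [build_mean_model()] result.
#' @param population the population it was built from.
#' @param n_modes number of modes to keep.
#' @return list with `modes` (3K x n matrix) and `variances`.
#' @export
shape_modes <- function(model, population, n_modes = 3L) {
  ref <- model$mean$points
  resid <- vapply(population, function(s) {
    a <- apply_transform(s$points, procrustes_align(s$points, ref,
                                                    allow_scale = TRUE))
    as.numeric(a - ref)
  }, numeric(length(ref)))
  pc <- stats::prcomp(t(resid), center = TRUE)
  k <- min(n_modes, ncol(pc$rotation))
  list(modes = pc$rotation[, seq_len(k), drop = FALSE],
       variances = pc$sdev[seq_len(k)]^2)
}
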