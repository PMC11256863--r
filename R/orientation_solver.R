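# Closed-form solvers for head rotations that bring a crista plane parallel
# or perpendicular to gravity.
#
# Axis and label conventions (right-hand rule, head frame):
#   X (interaural, +right):      theta > 0 "tilted back", theta < 0 "anterior pitch"
#   Y (anteroposterior, +fwd):   theta > 0 "tilt right",  theta < 0 "tilt left"
#   Z (craniocaudal, +up):       theta > 0 "tilt left",   theta < 0 "tilt right"

#' Head position with its gravity direction
#'
#' Gravity is expressed in the head frame: upright `(0, 0, -1)`, supine
#' `(0, -1, 0)` (gravity through the back of the head), prone `(0, 1, 0)`.
#'
#' @param name `"upright"`, `"supine"`, `"prone"` or `"custom"`.
#' @param gravity length-3 gravity direction, required for `"custom"`.
#' @return object of class `"head_position"`.
#' @export
head_position <- function(name = c("upright", "supine", "prone", "custom"),
                          gravity = NULL) {
  name <- match.arg(name)
  g <- switch(name,
    upright = c(0, 0, -1),
    supine = c(0, -1, 0),
    prone = c(0, 1, 0),
    custom = {
      if (is.null(gravity)) stop("custom position needs a gravity direction",
                                 call. = FALSE)
      unit_vec(gravity, "gravity")
    })
  structure(list(name = name, gravity = g), class = "head_position")
}

principal_axis_names <- rbind(X = c(1, 0, 0), Y = c(0, 1, 0), Z = c(0, 0, 1))

direction_label <- function(axis, angle) {
  if (abs(angle) < 1e-9) return("none")
  a <- unit_vec(axis, "axis")
  dots <- as.numeric(principal_axis_names %*% a)
  k <- which.max(abs(dots))
  if (abs(dots[k]) < 1 - 1e-6) return("rotation about oblique axis")
  signed <- angle * sign(dots[k])
  switch(rownames(principal_axis_names)[k],
    X = if (signed > 0) "tilted back" else "anterior pitch",
    Y = if (signed > 0) "tilt right" else "tilt left",
    Z = if (signed > 0) "tilt left" else "tilt right")
}

alignment_solution <- function(axis, angle, residual) {
  structure(list(axis = unit_vec(axis, "axis"), angle = angle,
                 label = direction_label(axis, angle), residual = residual),
            class = "alignment_solution")
}

#' @export
print.alignment_solution <- function(x, ...) {
  cat(sprintf("Rotate %.2f deg about (%.3g, %.3g, %.3g): %s (residual %.2g)\n",
              x$angle, x$axis[1], x$axis[2], x$axis[3], x$label, x$residual))
  invisible(x)
}

wrap_angle <- function(deg) {
  w <- (deg + 180) %% 360 - 180
  ifelse(w <= -180, w + 360, w)
}

#' Single-axis gravity-alignment solver
#'
#' Finds all rotations about a fixed axis that place the plane parallel to
#' gravity (the rotated plane contains the gravity direction, i.e.
#' `(R(theta) n) . g = 0`) or perpendicular to it (the rotated normal is
#' parallel to gravity). Writing the Rodrigues expansion of the rotated
#' normal dotted with gravity gives `A cos(theta) + B sin(theta) + C` with
#' `A = n.g - (a.n)(a.g)`, `B = (a x n).g`, `C = (a.n)(a.g)`, solved in
#' closed form.
#'
#' @param p a [plane()] (unit normal `n`).
#' @param position a [head_position()] (gravity `g`).
#' @param axis rotation axis `a` in the head frame.
#' @param mode `"parallel"` or `"perpendicular"`.
#' @param tol feasibility/residual tolerance.
#' @return list of `alignment_solution`s sorted by `|theta|` (ties toward
#'   positive theta).
#' @export
solve_single_axis <- function(p, position, axis,
                              mode = c("parallel", "perpendicular"),
                              tol = 1e-9) {
  mode <- match.arg(mode)
  stopifnot(inherits(p, "plane"), inherits(position, "head_position"))
  n <- p$normal
  g <- position$gravity
  a <- unit_vec(axis, "axis")
  A <- sum(n * g) - sum(a * n) * sum(a * g)
  B <- sum(vcross(a, n) * g)
  C <- sum(a * n) * sum(a * g)
  Rm <- sqrt(A^2 + B^2)
  targets <- if (mode == "parallel") 0 else c(-1, 1)
  thetas <- numeric(0)
  for (tgt in targets) {
    # A cos + B sin = tgt - C  =>  Rm cos(theta - phi) = tgt - C
    rhs <- tgt - C
    if (Rm < tol) {
      if (abs(rhs) < tol) thetas <- c(thetas, 0)  # any angle works; report 0
      next
    }
    if (abs(rhs) > Rm + tol) next
    phi <- atan2(B, A)
    dd <- acos(clamp1(rhs / Rm))
    thetas <- c(thetas, wrap_angle((phi + c(dd, -dd)) * DEG))
  }
  if (!length(thetas)) {
    extremes <- C + c(-Rm, Rm)
    if (mode == "parallel") {
      best <- extremes[which.min(abs(extremes))]
      stop(sprintf(paste0(
        "infeasible about this axis: |(R(theta) n).g| has minimum %.4g ",
        "(need 0); no single-axis solution"), abs(best)), call. = FALSE)
    }
    best <- extremes[which.max(abs(extremes))]
    stop(sprintf(paste0(
      "infeasible about this axis: |(R(theta) n).g| reaches at most %.4g ",
      "(need 1, i.e. misalignment >= %.2f deg); use solve_two_step_horizontal"),
      abs(best), acos(clamp1(abs(best))) * DEG), call. = FALSE)
  }
  thetas <- unique(round(thetas, 12))
  thetas <- thetas[order(abs(thetas), -sign(thetas))]
  lapply(thetas, function(th) {
    n2 <- rotate_about_axis(n, a, th)
    resid <- if (mode == "parallel") abs(sum(n2 * g))
             else acos(clamp1(abs(sum(n2 * g)))) * DEG
    alignment_solution(a, th, resid)
  })
}

#' Two-step horizontalization of a crista plane
#'
#' Brings the plane horizontal (normal along gravity in the upright
#' position, i.e. along the Z axis) by a pitch about the interaural X axis
#' that nulls the normal's Y component, followed by a roll about the
#' anteroposterior Y axis that nulls the remaining X component. The
#' minimal-magnitude branch of each rotation is taken.
#'
#' @param p a [plane()].
#' @return list with `pitch` and `roll` `alignment_solution`s; the roll's
#'   `residual` is the final angular misalignment (degrees) between the
#'   rotated normal and the vertical.
#' @export
solve_two_step_horizontal <- function(p) {
  stopifnot(inherits(p, "plane"))
  n <- p$normal
  # pitch about X: y' = y cos - z sin = 0
  th1 <- if (abs(n[2]) < 1e-15 && abs(n[3]) < 1e-15) 0 else atan2(n[2], n[3])
  if (th1 > pi / 2) th1 <- th1 - pi
  if (th1 <= -pi / 2) th1 <- th1 + pi
  th1 <- th1 * DEG
  n1 <- rotate_about_axis(n, c(1, 0, 0), th1)
  # roll about Y: x' = x cos + z sin = 0
  th2 <- if (abs(n1[1]) < 1e-15 && abs(n1[3]) < 1e-15) 0 else atan2(-n1[1], n1[3])
  if (th2 > pi / 2) th2 <- th2 - pi
  if (th2 <= -pi / 2) th2 <- th2 + pi
  th2 <- th2 * DEG
  n2 <- rotate_about_axis(n1, c(0, 1, 0), th2)
  resid <- acos(clamp1(abs(n2[3]))) * DEG
  list(pitch = alignment_solution(c(1, 0, 0), th1, abs(n1[2])),
       roll = alignment_solution(c(0, 1, 0), th2, resid))
}

#' Zero-point orientations of a crista plane
#'
#' The zero-point plane is the head orientation placing the crista in a
#' minimally stimulated configuration with respect to gravity. Both
#' published conventions are exposed: `"parallel"` (the crista plane
#' contains the gravity direction) solves about the clinically standard
#' single axis for the position (supine: craniocaudal Z roll; upright:
#' interaural X pitch); `"perpendicular"` (the crista plane horizontal,
#' normal along gravity) uses the two-step pitch-then-roll maneuver and is
#' defined for the upright position.
#'
#' @param p a [plane()].
#' @param position a [head_position()].
#' @param convention `"parallel"` or `"perpendicular"`.
#' @return for `"parallel"`: list of `alignment_solution`s (minimal first);
#'   for `"perpendicular"`: the `solve_two_step_horizontal()` pair.
#' @export
zero_point_orientations <- function(p, position,
                                    convention = c("parallel",
                                                   "perpendicular")) {
  convention <- match.arg(convention)
  stopifnot(inherits(position, "head_position"))
  if (convention == "parallel") {
    axis <- switch(position$name,
      supine = c(0, 0, 1),
      prone = c(0, 0, 1),
      upright = c(1, 0, 0),
      custom = c(1, 0, 0))
    solve_single_axis(p, position, axis, mode = "parallel")
  } else {
    if (abs(clamp1(sum(p$normal * position$gravity))) > 1 - 1e-12)
      return(list())                      # already perpendicular to gravity
    solve_two_step_horizontal(p)
  }
}
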