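# End-to-end pipeline: simulate or load a population, build the mean model,
# establish the head frame, calibrate a measurement specimen into it,
# extract crista/canal planes, tabulate angles and solve zero-point
# orientations. All randomness flows from the single config seed; no global
# state is touched.

#' Read / write landmarks as JSON
#'
#' Landmark files map names to `[x, y, z]` positions in millimetres.
#'
#' @param path JSON file path.
#' @return named list of length-3 numeric vectors.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path))
    stop("landmark file not found: ", path, call. = FALSE)
  lst <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lapply(lst, function(v) as_vec3(v, "landmark"))
}

#' @rdname read_landmarks
#' @param landmarks named list of length-3 positions.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(lapply(landmarks, function(v) unname(as.numeric(v))),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Write / read a specimen as plain files
#'
#' A specimen directory holds `cloud.ply` (corresponded points),
#' `labels.json`, and `landmarks.json`.
#'
#' @param specimen a `labyrinth_specimen` or [corresponded_shape()] plus
#'   landmarks.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_specimen <- function(specimen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cloud <- if (inherits(specimen, "labyrinth_specimen")) specimen$cloud
           else specimen
  write_mesh(cloud$points, file.path(dir, "cloud.ply"))
  jsonlite::write_json(cloud$labels, file.path(dir, "labels.json"))
  lms <- if (inherits(specimen, "labyrinth_specimen")) specimen$landmarks
         else list()
  write_landmarks(lms, file.path(dir, "landmarks.json"))
  invisible(dir)
}

#' @rdname write_specimen
#' @export
read_specimen <- function(dir) {
  cloud <- read_mesh(file.path(dir, "cloud.ply"))
  labels <- jsonlite::fromJSON(file.path(dir, "labels.json"))
  lms <- read_landmarks(file.path(dir, "landmarks.json"))
  structure(list(cloud = corresponded_shape(cloud$vertices, labels),
                 landmarks = lms),
            class = "labyrinth_specimen")
}

#' Read a population manifest
#'
#' A manifest is a plain-text file listing one specimen directory per line
#' (relative paths resolved against the manifest's location).
#'
#' @param path manifest file.
#' @return list of specimens (see [read_specimen()]).
#' @export
read_population_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  dirs <- trimws(readLines(path, warn = FALSE))
  dirs <- dirs[nzchar(dirs) & !startsWith(dirs, "#")]
  base <- dirname(normalizePath(path))
  lapply(dirs, function(d) {
    if (!grepl("^(/|[A-Za-z]:)", d)) d <- file.path(base, d)
    read_specimen(d)
  })
}

#' Pipeline configuration
#'
#' @param n_population number of (simulated) specimens for the mean model.
#' @param seed master seed for all randomness.
#' @param params a [labyrinth_params()] describing the simulated anatomy
#'   and its population variability.
#' @param manifest optional path to a population manifest; when given the
#'   population is loaded instead of simulated.
#' @param out_dir optional output directory for CSV/JSON/PLY artifacts.
#' @param zero_point_convention `"parallel"` or `"perpendicular"`.
#' @param zero_point_canal crista to solve for, e.g. `"LHC"`.
#' @param zero_point_position `"supine"` or `"upright"`.
#' @param mean_tol,mean_max_iter mean-model convergence controls, mm.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(n_population = 8L, seed = 1L,
                            params = labyrinth_params(rot_jitter_deg = 2,
                                                      size_jitter = 0.03,
                                                      noise_sd = 0.02),
                            manifest = NULL, out_dir = NULL,
                            zero_point_convention = "parallel",
                            zero_point_canal = "LHC",
                            zero_point_position = "supine",
                            mean_tol = 1e-3, mean_max_iter = 100L) {
  if (mean_tol <= 0) stop("tolerances must be positive", call. = FALSE)
  structure(list(n_population = n_population, seed = seed, params = params,
                 manifest = manifest, out_dir = out_dir,
                 zero_point_convention = zero_point_convention,
                 zero_point_canal = zero_point_canal,
                 zero_point_position = zero_point_position,
                 mean_tol = mean_tol, mean_max_iter = mean_max_iter),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the arguments of [pipeline_config()]; unknown
#' keys under `params` are passed to [labyrinth_params()].
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pargs <- y$params %||% list()
  y$params <- do.call(labyrinth_params, pargs)
  do.call(pipeline_config, y)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full calibration-and-measurement pipeline
#'
#' Stages: simulate (or load) the population; build the mean shape model;
#' estimate the bilateral symmetry plane and the head frame on the mean;
#' calibrate a measurement specimen into the standard frame and transfer
#' the transform to its crista patches and canal centerlines; fit all
#' planes; build the angle tables; solve the configured zero-point
#' orientation. Residuals of every stage are collected in the returned
#' bundle; when `out_dir` is set, tables (CSV), solutions and calibration
#' report (JSON) and the mean model (PLY + JSON) are written.
#'
#' @param config a [pipeline_config()].
#' @return list with `mean_model`, `frame`, `calibration`, `planes`,
#'   `tables`, `zero_point`, `residuals`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- with_seed(config$seed, sample.int(2^31 - 2L, 3L))

  pop_clouds <- stage("population", {
    if (!is.null(config$manifest)) {
      lapply(read_population_manifest(config$manifest), `[[`, "cloud")
    } else {
      pop <- generate_population(config$n_population, config$params,
                                 seed = seeds[1])
      lapply(pop$specimens, `[[`, "cloud")
    }
  })

  model <- stage("mean_model",
    build_mean_model(pop_clouds, tol = config$mean_tol,
                     max_iter = config$mean_max_iter))

  sides <- stage("symmetry", split_sides(model$mean))
  symmetry <- stage("symmetry",
    estimate_symmetry_plane(sides$left, sides$right))

  frame <- stage("head_frame", {
    labs <- model$mean$labels
    lm_labels <- grep("^LM_", labs, value = TRUE)
    lms <- lapply(lm_labels, function(lb)
      model$mean$points[labs == lb, , drop = FALSE][1L, ])
    names(lms) <- sub("^LM_", "", lm_labels)
    build_head_frame(lms, symmetry)
  })
  mean_head <- corresponded_shape(
    apply_transform(model$mean$points, frame$transform), model$mean$labels)

  # measurement specimen: fresh anatomy in an arbitrary pose whose crista
  # patches and centerlines ride along with the cloud's calibration
  specimen <- stage("specimen", {
    if (!is.null(config$manifest)) NULL
    else generate_specimen(config$params, seed = seeds[2], pose = "random")
  })

  calib <- NULL
  planes <- NULL
  if (!is.null(specimen)) {
    calib <- stage("calibration",
      calibrate_specimen(specimen$cloud$points, mean_head))
    planes <- stage("plane_fitting", {
      pl <- list()
      for (lb in names(specimen$patches)) {
        pa <- specimen$patches[[lb]]
        pa2 <- crista_patch(apply_transform(pa$points, calib), pa$canal,
                            apply_transform(rbind(pa$ampulla_centroid),
                                            calib)[1L, ],
                            grid_dim = pa$grid_dim)
        pl[[lb]] <- crista_plane(pa2)
      }
      for (lb in names(specimen$centerlines)) {
        canal <- substr(lb, 1L, 3L)
        pl[[lb]] <- canal_plane(
          apply_transform(specimen$centerlines[[lb]], calib), canal)
      }
      pl
    })
  }

  tables <- NULL
  zero_point <- NULL
  if (!is.null(planes)) {
    left_planes <- planes[grepl("^L", names(planes))]
    tables <- stage("angle_tables", build_angle_tables(left_planes))
    zp_label <- paste0(config$zero_point_canal, "_CA")
    zero_point <- stage("zero_point",
      zero_point_orientations(planes[[zp_label]],
                              head_position(config$zero_point_position),
                              config$zero_point_convention))
  }

  residuals <- list(
    mean_model_final_change = utils::tail(model$history, 1L),
    sagittal_symmetry = frame$sagittal_residual,
    horizontal_plane = frame$horizontal_residual,
    calibration_rmsd = if (!is.null(calib)) attr(calib, "rmsd") else NA_real_)

  bundle <- list(mean_model = model, frame = frame, calibration = calib,
                 planes = planes, tables = tables, zero_point = zero_point,
                 residuals = residuals, config = config)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    if (!is.null(tables))
      write_angle_tables(tables, file.path(od, "attitude.csv"),
                         file.path(od, "pairwise.csv"))
    write_mesh(mean_head$points, file.path(od, "mean_model.ply"))
    jsonlite::write_json(list(labels = mean_head$labels,
                              history = model$history),
                         file.path(od, "mean_model.json"), digits = NA)
    jsonlite::write_json(
      list(residuals = residuals,
           zero_point = lapply(unclass_solutions(zero_point), identity)),
      file.path(od, "report.json"), digits = NA, auto_unbox = TRUE,
      force = TRUE)
  }
  bundle
}

unclass_solutions <- function(x) {
  if (inherits(x, "alignment_solution")) {
    return(list(axis = x$axis, angle = x$angle, label = x$label,
                residual = x$residual))
  }
  lapply(x, unclass_solutions)
}
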