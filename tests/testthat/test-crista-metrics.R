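test_that("canal planes recover the generator's ground truth", {
  s <- canonical_specimen
  for (lb in names(s$centerlines)) {
    canal <- substr(lb, 1, 3)
    pl <- canal_plane(s$centerlines[[lb]], canal)
    truth <- s$ground_truth$true_planes[[lb]]
    expect_lt(angle_between_planes(pl, truth), 0.1)
  }
  # orientation conventions: posterior inward, superior outward, lateral down
  expect_gt(canal_plane(s$centerlines$LPC_MEM, "LPC")$normal[1], 0)
  expect_lt(canal_plane(s$centerlines$LAC_MEM, "LAC")$normal[1], 0)
  expect_lt(canal_plane(s$centerlines$LHC_MEM, "LHC")$normal[3], 0)
})

test_that("bony and membranous canal planes are nearly coplanar", {
  s <- canonical_specimen
  for (ck in c("LPC", "LHC", "LAC")) {
    a <- canal_plane(s$centerlines[[paste0(ck, "_MEM")]], ck)
    b <- canal_plane(s$centerlines[[paste0(ck, "_BONY")]], ck)
    expect_lt(angle_between_planes(a, b), 2.5)
  }
})

test_that("canal planes are equivariant under rigid motion", {
  s <- canonical_specimen
  set.seed(41)
  cl <- s$centerlines$LPC_MEM
  n0 <- canal_plane(cl, orient = FALSE)$normal
  for (rep in 1:5) {
    R <- random_rotation()
    n1 <- canal_plane(cl %*% t(R), orient = FALSE)$normal
    expect_lt(angle_between_dirs(n1, as.numeric(R %*% n0)), 1e-9)
  }
})

test_that("crista planes recover ground truth and the saddle is handled", {
  s <- canonical_specimen
  for (lb in names(s$patches)) {
    pl <- crista_plane(s$patches[[lb]])
    truth <- s$ground_truth$true_planes[[lb]]
    expect_lt(angle_between_planes(pl, truth), 0.05)
  }
  # flat disc: the fit is the disc plane, exactly
  g <- expand.grid(v = seq(-1, 1, length.out = 5),
                   u = seq(-1, 1, length.out = 5))
  disc <- crista_patch(cbind(g$u, g$v, 2), "LHC", grid_dim = c(5, 5))
  pl <- fit_plane(disc$points)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-12)
})

test_that("noisy saddle patches still recover the plane within half a degree", {
  set.seed(42)
  params <- labyrinth_params(noise_sd = 0.01)
  errs <- replicate(10, {
    sp <- generate_specimen(params, seed = sample.int(1e6, 1),
                            with_meshes = FALSE)
    max(vapply(names(sp$patches), function(lb)
      angle_between_planes(crista_plane(sp$patches[[lb]]),
                           sp$ground_truth$true_planes[[lb]]), 0))
  })
  expect_lt(mean(errs), 0.5)
})

test_that("each crista is nearly perpendicular to its own canal", {
  s <- canonical_specimen
  for (ck in c("LPC", "LHC", "LAC")) {
    ca <- crista_plane(s$patches[[paste0(ck, "_CA")]])
    mem <- canal_plane(s$centerlines[[paste0(ck, "_MEM")]], ck)
    acute <- angle_between_planes(ca, mem, folded = TRUE)
    expect_gte(acute, 80)
    expect_lte(acute, 90)
    # the published acute range for these angles
    expect_gte(acute, 80.6 - 0.2)
    expect_lte(acute, 86.2 + 0.2)
  }
})

test_that("cupula extrusion produces a watertight prism of the right volume", {
  g <- expand.grid(v = seq(-0.5, 0.5, length.out = 6),
                   u = seq(-0.5, 0.5, length.out = 6))
  square <- crista_patch(cbind(g$u, g$v, 0), "LHC", grid_dim = c(6, 6))
  cup <- extrude_cupula(square, c(0, 0, 1), 1)
  expect_true(is_watertight(cup))
  expect_equal(mesh_volume(cup), 1, tolerance = 1e-9)
  expect_equal(mesh_area(cup), 6, tolerance = 1e-9)
  # mid-plane of a symmetric extrusion keeps the crista normal
  mid <- (cup$vertices[1:36, ] + cup$vertices[37:72, ]) / 2
  expect_lt(angle_between_dirs(fit_plane(mid)$normal,
                               crista_plane(square, orient = FALSE)$normal),
            1e-6)
  # saddle patch extrusion stays watertight
  s <- canonical_specimen
  pa <- s$patches$LAC_CA
  cup2 <- extrude_cupula(pa, crista_plane(pa)$normal, 0.4)
  expect_true(is_watertight(cup2))
  expect_error(extrude_cupula(square, c(0, 0, 1), -1), "positive")
  expect_error(extrude_cupula(square, c(0, 0, 0), 1), "zero length")
})

test_that("angle tables reproduce the published values from their normals", {
  normals <- reference_normals()
  planes <- lapply(seq_len(nrow(normals)), function(i)
    as.numeric(normals[i, c("A", "B", "C")]))
  names(planes) <- normals$label
  # raw direction cosines feed the attitude table unrenormalized
  att <- do.call(rbind, lapply(normals$label, function(lb)
    round(reference_plane_angles(planes[[lb]]), 2)))
  expect_equal(att[, "sagittal"], published_attitude$sagittal,
               ignore_attr = TRUE)
  expect_equal(att[, "coronal"], published_attitude$coronal,
               ignore_attr = TRUE)
  expect_equal(att[, "horizontal"], published_attitude$horizontal,
               ignore_attr = TRUE)
  tabs <- build_angle_tables(lapply(planes, plane))
  expect_equal(nrow(tabs$attitude), 9L)
  expect_equal(nrow(tabs$pairwise), 12L)
  cr <- tabs$pairwise[tabs$pairwise$label1 == "LPC_CA" &
                        tabs$pairwise$label2 == "LHC_CA", "angle"]
  expect_equal(cr, 125.30, tolerance = 0.1)
  # every row satisfies the direction-cosine identity before rounding
  for (i in seq_len(nrow(tabs$attitude))) {
    a <- as.numeric(tabs$attitude[i, c("sagittal", "coronal",
                                       "horizontal")]) * pi / 180
    expect_equal(sum(cos(a)^2), 1, tolerance = 1e-6)
  }
})

test_that("angle tables handle single planes and serialize rounded CSVs", {
  tabs <- build_angle_tables(list(up = plane(c(0, 0, 1))))
  expect_equal(as.numeric(tabs$attitude[1, c("sagittal", "coronal",
                                             "horizontal")]),
               c(90, 90, 0))
  expect_equal(nrow(tabs$pairwise), 0L)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  normals <- reference_normals()
  planes <- lapply(seq_len(nrow(normals)), function(i)
    plane(as.numeric(normals[i, c("A", "B", "C")])))
  names(planes) <- normals$label
  write_angle_tables(build_angle_tables(planes), f1, f2)
  att <- utils::read.csv(f1)
  expect_equal(att$horizontal, round(att$horizontal, 2))
  pw <- utils::read.csv(f2)
  expect_equal(nrow(pw), 12L)
  expect_error(build_angle_tables(list(plane(c(0, 0, 1)))), "named")
})
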