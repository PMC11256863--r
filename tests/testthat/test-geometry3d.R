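test_that("fit_plane recovers exact and symmetric configurations", {
  set.seed(1)
  # coplanar points on z = 0
  pts <- cbind(runif(40, -2, 2), runif(40, -2, 2), 0)
  pl <- fit_plane(pts)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-12)
  expect_equal(pl$offset, 0, tolerance = 1e-12)
  # symmetric saddle z = x^2 - y^2: least-variance direction is Z
  g <- expand.grid(x = seq(-1, 1, length.out = 9),
                   y = seq(-1, 1, length.out = 9))
  saddle <- cbind(g$x, g$y, g$x^2 - g$y^2)
  pls <- fit_plane(saddle)
  expect_equal(abs(pls$normal[3]), 1, tolerance = 1e-9)
})

test_that("fit_plane matches the brute-force scatter-matrix oracle", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(10:500, 1)
    nrm <- random_unit()
    b <- vestigeom:::plane_basis(nrm)
    u <- runif(n, -3, 3); v <- runif(n, -2, 2)
    pts <- outer(u, b$e1) + outer(v, b$e2) +
      matrix(rnorm(3 * n, 0, 0.01), ncol = 3)
    pts <- sweep(pts, 2, rnorm(3, 0, 5), `+`)
    fitted <- fit_plane(pts)$normal
    expect_lt(angle_between_dirs(fitted, oracle_tls_normal(pts)), 1e-6)
    expect_lt(angle_between_dirs(fitted, nrm), 0.5)
  }
})

test_that("fit_plane is equivariant under rigid motion", {
  set.seed(2)
  pts <- cbind(runif(50), runif(50), 0.3 * runif(50))
  n0 <- fit_plane(pts)$normal
  for (rep in 1:5) {
    R <- random_rotation()
    n1 <- fit_plane(pts %*% t(R))$normal
    expect_lt(angle_between_dirs(n1, as.numeric(R %*% n0)), 1e-9)
  }
})

test_that("fit_plane rejects degenerate input and names the rank", {
  expect_error(fit_plane(rbind(c(0, 0, 0), c(1, 1, 1))), "at least 3")
  line <- cbind(seq_len(5), seq_len(5) * 2, seq_len(5) * -1)
  expect_error(fit_plane(line), "rank 1")
  expect_error(fit_plane(matrix(1, 4, 3)), "rank 0")
})

test_that("orient_plane enforces the requested hemisphere", {
  p <- plane(c(0, 0, 1), 2)
  flipped <- orient_plane(p, c(0, 0, -1))
  expect_equal(flipped$normal, c(0, 0, -1))
  expect_equal(flipped$offset, -2)
  expect_identical(orient_plane(p, c(0, 0, 1)), p)
  expect_identical(orient_plane(plane(c(0.6, 0, 0.8)), c(1, 0, 0)),
                   plane(c(0.6, 0, 0.8)))
  expect_error(orient_plane(p, c(1, 0, 0)), "ambiguous")
})

test_that("reference-plane angles reproduce the published attitude table", {
  for (i in seq_len(nrow(published_attitude))) {
    a <- reference_plane_angles(reference_normal(published_attitude$label[i]))
    expect_equal(round(unname(a), 2),
                 unlist(published_attitude[i, c("sagittal", "coronal",
                                                "horizontal")],
                        use.names = FALSE),
                 tolerance = 1e-8)
  }
  expect_equal(unname(reference_plane_angles(c(0, 0, 1))), c(90, 90, 0))
})

test_that("direction cosines of any unit normal satisfy the identity", {
  set.seed(3)
  for (rep in 1:25) {
    a <- reference_plane_angles(random_unit()) / (180 / pi)
    expect_equal(sum(cos(a)^2), 1, tolerance = 1e-9)
  }
  # published rows satisfy it within print rounding
  for (lb in published_attitude$label) {
    expect_equal(sum(reference_normal(lb)^2), 1, tolerance = 1e-3)
  }
})

test_that("angle_between_planes is unfolded, symmetric, and flip-covariant", {
  lpc <- reference_normal("LPC_CA"); lhc <- reference_normal("LHC_CA")
  lac <- reference_normal("LAC_CA")
  expect_equal(angle_between_planes(lpc, lhc), 125.30, tolerance = 0.1)
  expect_equal(angle_between_planes(lpc, lac), 80.83, tolerance = 0.1)
  expect_equal(angle_between_planes(lhc, lac), 45.11, tolerance = 0.1)
  expect_equal(angle_between_planes(lpc, lpc), 0)
  set.seed(4)
  for (rep in 1:10) {
    p <- random_unit(); q <- random_unit()
    expect_equal(angle_between_planes(p, q), angle_between_planes(q, p))
    expect_equal(angle_between_planes(p, -q),
                 180 - angle_between_planes(p, q), tolerance = 1e-9)
    expect_lte(angle_between_planes(p, q, folded = TRUE), 90)
  }
})

test_that("rotation about an axis follows the right-hand rule", {
  expect_equal(rotate_about_axis(c(1, 0, 0), c(0, 0, 1), 90), c(0, 1, 0),
               tolerance = 1e-12)
  set.seed(5)
  for (rep in 1:10) {
    v <- rnorm(3); a <- random_unit(); th <- runif(1, -360, 360)
    expect_equal(rotate_about_axis(v, a, 0), v)
    expect_equal(rotate_about_axis(v, a, 360), v, tolerance = 1e-12)
    expect_equal(sqrt(sum(rotate_about_axis(v, a, th)^2)), sqrt(sum(v^2)),
                 tolerance = 1e-12)
  }
})

test_that("transforms compose, invert and validate", {
  set.seed(6)
  pts <- matrix(rnorm(90), 30)
  for (rep in 1:5) {
    tf <- rigid_transform(random_rotation(), rnorm(3),
                          scale = exp(rnorm(1, 0, 0.2)),
                          mirrored = rep %% 2 == 0)
    rt <- compose_transform(invert_transform(tf), tf)
    expect_equal(apply_transform(pts, rt), pts, tolerance = 1e-9)
    rt2 <- compose_transform(tf, invert_transform(tf))
    expect_equal(apply_transform(pts, rt2), pts, tolerance = 1e-9)
  }
  expect_equal(apply_transform(pts, rigid_transform()), pts)
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  expect_error(rigid_transform(diag(c(-1, 1, 1))), "determinant")
  expect_error(rigid_transform(scale = -2), "positive")
})

test_that("sagittal mirroring obeys the 180 - angle relation", {
  lpc <- plane(reference_normal("LPC_CA"))
  m <- mirror_sagittal(lpc)
  expect_equal(m$normal[1], -lpc$normal[1])
  expect_equal(m$normal[2:3], lpc$normal[2:3])
  a0 <- reference_plane_angles(lpc); a1 <- reference_plane_angles(m)
  expect_equal(unname(a1["sagittal"]), 180 - unname(a0["sagittal"]),
               tolerance = 1e-9)
  expect_equal(a1[c("coronal", "horizontal")], a0[c("coronal", "horizontal")])
  # mirror of the published row: 180 - 138.33 = 41.7 (printed to 1 decimal)
  expect_equal(round(unname(a1["sagittal"]), 1), 41.7, tolerance = 0.051)
  # points: X negated, twice = identity
  pts <- matrix(rnorm(30), 10)
  expect_equal(mirror_sagittal(pts)[, 1], -pts[, 1])
  expect_equal(mirror_sagittal(mirror_sagittal(pts)), pts)
})
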