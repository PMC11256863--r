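test_that("procrustes_align recovers known rigid and similarity motions", {
  set.seed(21)
  X <- matrix(rnorm(60, sd = 3), 20)
  tf0 <- procrustes_align(X, X)
  expect_equal(tf0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(attr(tf0, "rmsd"), 0, tolerance = 1e-9)
  for (rep in 1:5) {
    R <- random_rotation(); tr <- rnorm(3, 0, 10)
    Y <- X %*% t(R) + matrix(tr, 20, 3, byrow = TRUE)
    tf <- procrustes_align(X, Y)
    expect_equal(tf$rotation, R, tolerance = 1e-6)
    expect_equal(tf$translation, tr, tolerance = 1e-6)
    s <- exp(rnorm(1, 0, 0.3))
    tfs <- procrustes_align(X, s * Y, allow_scale = TRUE)
    expect_equal(tfs$scale, s, tolerance = 1e-6)
  }
})

test_that("procrustes_align never produces a reflection and bounds noise", {
  set.seed(22)
  X <- matrix(rnorm(90), 30)
  # target is a mirrored copy: best proper rotation still has det +1
  Y <- X %*% diag(c(-1, 1, 1))
  tf <- procrustes_align(X, Y)
  expect_equal(det(tf$rotation), 1, tolerance = 1e-9)
  # noisy copy: post-alignment RMSD stays within 3 sigma
  sigma <- 0.05
  for (rep in 1:5) {
    R <- random_rotation()
    Y <- (X + matrix(rnorm(90, 0, sigma), 30)) %*% t(R)
    expect_lt(attr(procrustes_align(X, Y), "rmsd"), 3 * sigma)
  }
})

test_that("procrustes_align agrees with the vegan oracle", {
  skip_if_not_installed("vegan")
  set.seed(23)
  X <- matrix(rnorm(75), 25)
  Y <- X %*% t(random_rotation()) + matrix(rnorm(75, 0, 0.1), 25)
  ours <- apply_transform(X, procrustes_align(X, Y, allow_scale = TRUE))
  veg <- vegan::procrustes(Y, X)   # rotates X onto Y, reports centered coords
  expect_equal(sweep(ours, 2, colMeans(ours)),
               sweep(unclass(veg$Yrot), 2, colMeans(veg$Yrot)),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("correspondence recovers identity and known motions", {
  set.seed(24)
  ref <- corresponded_shape(matrix(rnorm(300, sd = 2), 100),
                            rep(c("a", "b"), each = 50))
  same <- establish_correspondence(ref, ref)
  expect_equal(same$points, ref$points)
  expect_lt(attr(same, "residual"), 1e-9)
  tf <- rigid_transform(random_rotation(), rnorm(3, 0, 5))
  moved <- corresponded_shape(apply_transform(ref$points, tf), ref$labels)
  corr <- establish_correspondence(moved, ref)
  expect_equal(corr$points, moved$points, tolerance = 1e-6)
  expect_lt(attr(corr, "residual"), 1e-6)
})

test_that("correspondence residual stays near the noise scale", {
  set.seed(25)
  sigma <- 0.05
  ref <- corresponded_shape(matrix(rnorm(450, sd = 3), 150),
                            rep(c("a", "b", "c"), each = 50))
  noisy <- corresponded_shape(
    apply_transform(ref$points + matrix(rnorm(450, 0, sigma), 150),
                    rigid_transform(rotation_about_axis(c(1, 1, 0), 5),
                                    c(1, 0, -1))),
    ref$labels)
  corr <- establish_correspondence(noisy, ref)
  expect_lt(attr(corr, "residual"), 2 * sigma * sqrt(3))
})

test_that("mean model of identical shapes is that shape, immediately", {
  set.seed(26)
  base <- corresponded_shape(matrix(rnorm(150), 50), rep("s", 50))
  pop <- replicate(4, base, simplify = FALSE)
  m <- build_mean_model(pop)
  expect_equal(m$mean$points, base$points, tolerance = 1e-9)
  expect_equal(length(m$history), 1L)
})

test_that("mean model of rigidly moved copies is congruent to the base", {
  set.seed(27)
  base <- matrix(rnorm(240, sd = 4), 80)
  pop <- lapply(1:6, function(i)
    corresponded_shape(
      apply_transform(base, rigid_transform(random_rotation(),
                                            rnorm(3, 0, 10))),
      rep("s", 80)))
  m <- build_mean_model(pop, allow_scale = FALSE)
  tf <- procrustes_align(m$mean$points, base)
  expect_lt(attr(tf, "rmsd"), 1e-6)
})

test_that("mean model averages noise down as sigma over sqrt(n)", {
  set.seed(28)
  n <- 20L; sigma <- 0.1
  base <- matrix(rnorm(150, sd = 3), 50)
  pop <- lapply(seq_len(n), function(i)
    corresponded_shape(base + matrix(rnorm(150, 0, sigma), 50), rep("s", 50)))
  m <- build_mean_model(pop, allow_scale = FALSE)
  per_point <- sqrt(rowSums((m$mean$points - base)^2))
  # mean per-point error ~ sigma * sqrt(3) / sqrt(n); allow factor 2
  expect_lt(mean(per_point), 2 * sigma * sqrt(3) / sqrt(n))
})

test_that("mean model is invariant to population order and reference choice", {
  set.seed(29)
  base <- matrix(rnorm(180, sd = 3), 60)
  pop <- lapply(1:5, function(i)
    corresponded_shape(
      apply_transform(base + matrix(rnorm(180, 0, 0.05), 60),
                      rigid_transform(random_rotation(), rnorm(3, 0, 5))),
      rep("s", 60)))
  tol <- 1e-3
  m1 <- build_mean_model(pop, tol = tol)
  m2 <- build_mean_model(rev(pop), tol = tol)
  m3 <- build_mean_model(pop[c(3, 1, 2, 5, 4)], tol = tol)
  d12 <- attr(procrustes_align(m2$mean$points, m1$mean$points,
                               allow_scale = TRUE), "rmsd")
  d13 <- attr(procrustes_align(m3$mean$points, m1$mean$points,
                               allow_scale = TRUE), "rmsd")
  expect_lt(d12, 10 * tol)
  expect_lt(d13, 10 * tol)
  # convergence history non-increasing after the first two iterations
  h <- m1$history
  if (length(h) > 2) expect_true(all(diff(h[-1]) <= 1e-12))
})

test_that("mean model rejects inconsistent populations", {
  a <- corresponded_shape(matrix(rnorm(30), 10), rep("s", 10))
  b <- corresponded_shape(matrix(rnorm(36), 12), rep("s", 12))
  expect_error(build_mean_model(list(a)), "at least 2")
  expect_error(build_mean_model(list(a, b)), "share point count")
})
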