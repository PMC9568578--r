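test_that("terrain parameters enforce the angular tiling and radial band", {
  tp <- terrain_params()
  expect_equal(tp$n_spokes, 60L)
  expect_equal(tp$angular_step, 6)
  expect_equal(tp$n_radial, floor(140 / 3.2))
  expect_true(tp$n_radial %in% c(43L, 44L))
  expect_error(terrain_params(n_spokes = 60, angular_step = 7), "360")
  expect_error(terrain_params(max_radius = -1), "positive")
  expect_error(terrain_params(r_min = 100), "range")
})

test_that("terrain sampling reproduces a radial distance field", {
  # volume whose value is the distance from the axis of a straight fiber
  dims <- c(64L, 64L, 32L); voxel <- 1.6
  xs <- (1:64 - 0.5) * voxel
  dfield <- sqrt(outer((xs - 51.2)^2, (xs - 51.2)^2, "+"))
  vol <- array(rep(dfield, 32L), c(64L, 64L, 32L))
  v <- ft_volume(vol, voxel)
  cl <- straight_centerline(20, origin = c(51.2, 51.2, 8))
  tp <- terrain_params(n_spokes = 12, angular_step = 30, max_radius = 24,
                       radial_step = 1.6)
  terr <- sample_terrain(v, cl, params = tp)
  expect_equal(dim(terr$intensities), c(20L, 12L, 15L))
  rj <- (1:15) * 1.6
  for (k in c(1, 5, 9)) {
    got <- terr$intensities[10, k, ]
    expect_lt(max(abs(got - rj)), 0.5 * voxel)
  }
  # constant volume -> constant terrain
  vc <- ft_volume(array(7, c(16, 16, 16)), 2)
  clc <- straight_centerline(6, spacing = 2, origin = c(16, 16, 4))
  tc <- sample_terrain(vc, clc, params = terrain_params(n_spokes = 6,
    angular_step = 60, max_radius = 8, radial_step = 2))
  expect_true(all(abs(tc$intensities - 7) < 1e-9, na.rm = TRUE))
})

test_that("gradient cost implements central differences with one-sided ends", {
  tp <- terrain_params(n_spokes = 4, angular_step = 90, max_radius = 12,
                       radial_step = 2)
  # linear ramp of slope m along the radius
  m <- 3.5
  I <- array(0, c(2, 4, 6))
  for (j in 1:6) I[, , j] <- m * j * 2
  terr <- structure(list(intensities = I, params = tp), class = "ft_terrain")
  g <- gradient_cost(terr)
  expect_equal(g[1, 1, 2:5], rep(m, 4), tolerance = 1e-12)
  expect_equal(g[1, 1, 1], m, tolerance = 1e-12)   # one-sided
  expect_equal(g[1, 1, 6], m, tolerance = 1e-12)
  # step edge: most negative gradient at the transition
  I2 <- array(10, c(1, 4, 6)); I2[, , 4:6] <- 0
  terr2 <- structure(list(intensities = I2, params = tp), class = "ft_terrain")
  g2 <- gradient_cost(terr2)
  expect_true(which.min(g2[1, 1, ]) %in% 3:4)  # tie straddles the edge
  # constant -> zero gradients; NA samples -> +Inf cost
  I3 <- array(5, c(1, 4, 6)); I3[1, 1, 6] <- NA
  terr3 <- structure(list(intensities = I3, params = tp), class = "ft_terrain")
  g3 <- gradient_cost(terr3)
  expect_true(all(g3[1, 2:4, ] == 0))
  expect_true(is.infinite(g3[1, 1, 6]))
})

test_that("detect_surface finds per-column minima when constraints are loose", {
  tp <- terrain_params(n_spokes = 4, angular_step = 90, max_radius = 12,
                       radial_step = 2, delta_spoke = 5L, delta_slice = 5L,
                       r_min = 1L)
  set.seed(3)
  cost <- array(rnorm(3 * 4 * 6), c(3, 4, 6))
  s <- detect_surface(cost, tp)
  argmin <- apply(cost, c(1, 2), which.min)
  expect_equal(s$level, argmin)
})

test_that("detect_surface with zero smoothness returns the best constant radius", {
  tp <- terrain_params(n_spokes = 4, angular_step = 90, max_radius = 12,
                       radial_step = 2, delta_spoke = 0L, delta_slice = 0L,
                       r_min = 1L)
  set.seed(4)
  cost <- array(rnorm(3 * 4 * 6), c(3, 4, 6))
  s <- detect_surface(cost, tp)
  expect_equal(length(unique(as.vector(s$level))), 1L)
  totals <- vapply(1:6, function(j) sum(cost[, , j]), 0)
  expect_equal(unique(as.vector(s$level)), which.min(totals))
})

test_that("detect_surface matches exhaustive enumeration on random terrains", {
  set.seed(11)
  for (rep in 1:10) {
    dims <- c(sample(2:3, 1), sample(3:4, 1), sample(4:6, 1))
    cost <- array(rnorm(prod(dims)), dims)
    dsp <- sample(1:2, 1); dsl <- sample(1:2, 1)
    tp <- terrain_params(n_spokes = dims[2], angular_step = 360 / dims[2],
                         max_radius = dims[3] * 2, radial_step = 2,
                         delta_spoke = dsp, delta_slice = dsl, r_min = 1L)
    s <- detect_surface(cost, tp)
    bf <- brute_force_surface(cost, dsp, dsl, 1L)
    expect_equal(surface_cost_of(cost, s$level), bf$best, tolerance = 1e-9)
    # output respects the smoothness constraints exactly
    lv <- s$level
    expect_true(all(abs(lv[, -1] - lv[, -ncol(lv)]) <= dsp))
    expect_true(all(abs(lv[, 1] - lv[, ncol(lv)]) <= dsp))
    if (nrow(lv) > 1)
      expect_true(all(abs(lv[-1, ] - lv[-nrow(lv), ]) <= dsl))
  }
})

test_that("r_min forbids surface collapse", {
  tp <- terrain_params(n_spokes = 4, angular_step = 90, max_radius = 12,
                       radial_step = 2, r_min = 3L)
  cost <- array(1, c(2, 4, 6)); cost[, , 1] <- -100  # tempting inner minimum
  s <- detect_surface(cost, tp)
  expect_true(all(s$level >= 3L))
})

test_that("refinement recenters an offset centerline on a cylinder", {
  v <- make_cylinder_volume()
  tp <- terrain_params(n_spokes = 60, angular_step = 6, max_radius = 36,
                       radial_step = 1.6, refine_iters = 2L)
  cl <- straight_centerline(60, origin = c(67, 64, 0.8))   # 3 um off-axis
  vp <- pad_volume_z(v, 14L)
  seg <- segment_fiber(vp, cl, tp)
  dev <- sqrt((seg$centerline$points[, 1] - 64)^2 +
              (seg$centerline$points[, 2] - 64)^2)
  expect_lt(mean(dev), 0.5)
  # a perfectly centered centerline is (nearly) a fixed point
  cl0 <- straight_centerline(60, origin = c(64, 64, 0.8))
  fr <- frames(cl0)
  terr <- sample_terrain(vp, cl0, fr, tp)
  surf <- detect_surface(gradient_cost(terr), tp)
  ref <- refine_centerline(cl0, surf, fr)
  expect_lt(max(sqrt(rowSums((ref$points - cl0$points)^2))), 0.1)
})

test_that("rasterized cylinder matches the analytic mask and labels stay disjoint", {
  v <- make_cylinder_volume()
  tp <- terrain_params(n_spokes = 60, angular_step = 6, max_radius = 36,
                       radial_step = 1.6)
  cl <- straight_centerline(64, origin = c(64, 64, 0.8))
  seg <- segment_fibers(v, list("1" = cl), tp)
  lab <- seg$labels$data
  xs <- (1:80 - 0.5) * 1.6
  truth <- array(rep(outer((xs - 64)^2, (xs - 64)^2, "+") <= 16^2, 64),
                 dim(lab))
  dice <- 2 * sum(lab == 1L & truth) / (sum(lab == 1L) + sum(truth))
  expect_gt(dice, 0.97)
  # two separated fibers -> disjoint labels by construction
  v2dat <- array(20, c(96, 48, 48))
  xs2 <- (1:96 - 0.5) * 1.6; ys2 <- (1:48 - 0.5) * 1.6
  for (cx in c(38.4, 115.2)) {
    d2 <- outer((xs2 - cx)^2, (ys2 - 38.4)^2, "+")
    for (k in 1:48) v2dat[, , k][d2 <= 12^2] <- 100
  }
  v2 <- gaussian_blur(ft_volume(v2dat, 1.6), 1.6)
  cls <- list("a" = straight_centerline(48, origin = c(38.4, 38.4, 0.8)),
              "b" = straight_centerline(48, origin = c(115.2, 38.4, 0.8)))
  seg2 <- segment_fibers(v2, cls, tp)
  expect_setequal(sort(unique(as.vector(seg2$labels$data))), c(0L, 1L, 2L))
})

test_that("segmentation is deterministic given identical inputs", {
  v <- make_cylinder_volume(dims = c(48L, 48L, 32L), center = c(38.4, 38.4),
                            radius = 12)
  tp <- terrain_params(n_spokes = 30, angular_step = 12, max_radius = 28,
                       radial_step = 1.6)
  cl <- straight_centerline(32, origin = c(38.4, 38.4, 0.8))
  s1 <- segment_fibers(v, list("1" = cl), tp)
  s2 <- segment_fibers(v, list("1" = cl), tp)
  expect_identical(s1$seg, s2$seg)
  expect_identical(s1$labels$data, s2$labels$data)
  expect_identical(s1$segments[["1"]]$surface$radius,
                   s2$segments[["1"]]$surface$radius)
})
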