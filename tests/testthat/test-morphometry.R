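test_that("fiber length sums Euclidean steps and matches a brute-force oracle", {
  expect_equal(fiber_length(rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  line <- cbind(0, 0, seq(0, by = 1.32, length.out = 100))
  expect_equal(fiber_length(line), 99 * 1.32)
  set.seed(8)
  poly <- matrix(rnorm(3000), ncol = 3)
  manual <- 0
  for (i in 1:(nrow(poly) - 1))
    manual <- manual + sqrt(sum((poly[i + 1, ] - poly[i, ])^2))
  expect_equal(fiber_length(poly), manual, tolerance = 1e-9)
})

test_that("sinuosity is arc over chord, >= 1, and flags closed loops", {
  expect_equal(sinuosity(cbind(0, 0, seq(0, 10, by = 0.5))), 1)
  th <- seq(0, pi, length.out = 5000)
  semi <- cbind(7 * cos(th), 7 * sin(th), 0)
  expect_equal(sinuosity(semi), pi / 2, tolerance = 0.001 * pi / 2)
  set.seed(9)
  for (rep in 1:20) {
    pts <- matrix(cumsum(rnorm(60)), ncol = 3)
    expect_gte(sinuosity(pts), 1)
  }
  loop <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 0, 0))
  expect_warning(s <- sinuosity(loop), "loop")
  expect_true(is.infinite(s))
})

test_that("equivalent diameter and eccentricity follow their closed forms", {
  expect_equal(equivalent_diameter(pi), 2)
  expect_equal(equivalent_diameter(pi * 25^2), 50)
  expect_equal(eccentricity(3, 3), 0)
  expect_equal(eccentricity(2, 1), sqrt(3) / 2, tolerance = 1e-9)
  expect_equal(eccentricity(2, 1), 0.86603, tolerance = 1e-5)
  expect_error(equivalent_diameter(-1), "positive")
  expect_error(eccentricity(1, 2), "a >= b")
  # monotonicity: diameter in area; eccentricity decreasing in b/a
  A <- seq(10, 1000, length.out = 50)
  expect_true(all(diff(equivalent_diameter(A)) > 0))
  ba <- seq(0.1, 1, length.out = 50)
  expect_true(all(diff(eccentricity(1, ba)) < 0))
})

test_that("direct ellipse fit recovers exact ellipses to high precision", {
  th <- seq(0, 2 * pi, length.out = 40)[-40]
  for (par in list(c(30, 15, 0.3), c(10, 9.5, 2.1), c(50, 12, 0))) {
    a <- par[1]; b <- par[2]; phi <- par[3]
    x <- a * cos(th) * cos(phi) - b * sin(th) * sin(phi) + 5
    y <- a * cos(th) * sin(phi) + b * sin(th) * cos(phi) - 3
    fit <- fit_ellipse(cbind(x, y))
    expect_equal(fit$a, a, tolerance = 1e-6)
    expect_equal(fit$b, b, tolerance = 1e-6)
    expect_equal(fit$method, "direct")
  }
  expect_error(fit_ellipse(cbind(1:5, 1:5 * 2 + 1)), "6")
  expect_error(fit_ellipse(cbind(1:10, 1:10 * 2 + 1)), "collinear")
})

test_that("ellipse fit of a rasterized circle boundary matches its radius", {
  r <- 20
  img <- outer(-30:30, -30:30, function(i, j) i^2 + j^2 <= r^2)
  bnd <- which(img & !(outer(-30:30, -30:30, function(i, j)
    i^2 + j^2 <= (r - 1.5)^2)), arr.ind = TRUE)
  fit <- fit_ellipse(bnd)
  expect_equal(fit$a, r, tolerance = 0.02 * r)
  expect_equal(fit$b, r, tolerance = 0.02 * r)
})

test_that("cross-sections of a straight cylinder are congruent circles", {
  v <- make_cylinder_volume()
  tp <- terrain_params(n_spokes = 60, angular_step = 6, max_radius = 36,
                       radial_step = 1.6)
  cl <- straight_centerline(64, origin = c(64, 64, 0.8))
  seg <- segment_fibers(v, list("1" = cl), tp)
  s <- seg$segments[["1"]]
  secs <- extract_cross_sections(seg$labels, 1L, s$centerline, s$frames,
                                 spacing = 9.2, surface = s$surface,
                                 fiber_id = "1")
  d <- fiber_length(s$centerline)
  expect_equal(length(secs), floor(d / 9.2) + 1)
  dia <- vapply(secs, `[[`, 0, "diameter")
  ecc <- vapply(secs, `[[`, 0, "eccentricity")
  keep <- seq(2, length(secs) - 1)   # interior sections
  expect_lt(max(abs(dia[keep] - 32)) / 32, 0.05)
  expect_lt(max(ecc[keep]), 0.35)
  expect_lt(diff(range(dia[keep])) / 32, 0.06)  # congruent within tolerance
  # ellipse area and pixel-count area agree within 5%
  for (i in keep[1:3]) {
    px_area <- secs[[i]]$n_pixels * 1.6^2
    expect_lt(abs(secs[[i]]$area / px_area - 1), 0.05)
  }
})

test_that("FOV filter discards sections crossing the cylinder or the z faces", {
  secs <- list(
    list(arc_position = 0, xyz = cbind(50 + runif(9, -2, 2),
                                       50 + runif(9, -2, 2),
                                       runif(9, 40, 42)), empty = FALSE),
    list(arc_position = 1, xyz = cbind(seq(58, 66, by = 1), 50, 41),
         empty = FALSE),                                  # pokes out radially
    list(arc_position = 2, xyz = cbind(50, 50, c(0.5, 1.5, 2)),
         empty = FALSE),                                  # touches bottom
    list(arc_position = 3, xyz = NULL, empty = TRUE))
  cyl <- list(center = c(50, 50), radius = 12, zlim = c(1, 99))
  out <- fov_filter(secs, cyl)
  expect_equal(vapply(out, `[[`, TRUE, "kept"), c(TRUE, FALSE, FALSE, FALSE))
})

test_that("unfolded longitudinal sections mirror the local image structure", {
  vc <- ft_volume(array(4.2, c(32, 32, 32)), 2)
  cl <- straight_centerline(12, spacing = 2, origin = c(32, 32, 10))
  img <- unfold_longitudinal(vc, cl, width = 24, step = 2)
  expect_true(all(abs(img - 4.2) < 1e-9, na.rm = TRUE))
  expect_equal(ncol(img), round(24 / 2) + 1)
  # radial distance field: columns symmetric about the centerline
  dims <- c(64L, 64L, 32L); voxel <- 1.6
  xs <- (1:64 - 0.5) * voxel
  dfield <- sqrt(outer((xs - 51.2)^2, (xs - 51.2)^2, "+"))
  v <- ft_volume(array(rep(dfield, 32), dims), voxel)
  clf <- straight_centerline(16, origin = c(51.2, 51.2, 6))
  imf <- unfold_longitudinal(v, clf, width = 48, step = 1.6)
  mid <- (ncol(imf) + 1) / 2
  for (off in 1:10) {
    expect_equal(imf[8, mid + off], imf[8, mid - off], tolerance = 0.5 * voxel)
  }
})

test_that("morphometry is rotation invariant for diameter and eccentricity", {
  # one elliptic tube, axis along z, rotated by 30 degrees about z
  dims <- c(72L, 72L, 40L); voxel <- 1.6
  xs <- (1:72 - 0.5) * voxel
  ctr <- 57.6
  build <- function(phi) {
    a <- 18; b <- 13
    vol <- array(20, dims)
    co <- cos(phi); si <- sin(phi)
    for (k in 1:40) {
      u <- outer(xs - ctr, rep(1, 72)) * co + outer(rep(1, 72), xs - ctr) * si
      w <- -outer(xs - ctr, rep(1, 72)) * si + outer(rep(1, 72), xs - ctr) * co
      vol[, , k][(u / a)^2 + (w / b)^2 <= 1] <- 100
    }
    gaussian_blur(ft_volume(vol, voxel), 1.6)
  }
  tp <- terrain_params(n_spokes = 60, angular_step = 6, max_radius = 32,
                       radial_step = 1.6)
  med <- lapply(c(0, pi / 6), function(phi) {
    v <- build(phi)
    cl <- straight_centerline(40, origin = c(ctr, ctr, 0.8))
    seg <- segment_fibers(v, list("1" = cl), tp)
    s <- seg$segments[["1"]]
    secs <- extract_cross_sections(seg$labels, 1L, s$centerline, s$frames,
                                   spacing = 9.2, surface = s$surface)
    list(dia = median(vapply(secs, `[[`, 0, "diameter"), na.rm = TRUE),
         ecc = median(vapply(secs, `[[`, 0, "eccentricity"), na.rm = TRUE))
  })
  expect_lt(abs(med[[2]]$dia / med[[1]]$dia - 1), 0.02)
  expect_lt(abs(med[[2]]$ecc - med[[1]]$ecc), 0.05)
})
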