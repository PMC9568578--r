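test_that("phantom spec validates physical parameters", {
  expect_error(phantom_spec(voxel_size = 0), "voxel")
  expect_error(phantom_spec(sinuosity = c(0.9, 0.1)), "sinuosity")
  expect_error(phantom_spec(eccentricity_target = 1), "eccentricity")
  expect_error(phantom_spec(pathology = c(buckle = 0.8, split = 0.5)), "sum")
  expect_s3_class(phantom_spec(), "ft_phantom_spec")
})

test_that("generated centerlines hit their sinuosity targets", {
  # zero excess -> straight-dominated; target met within 5%
  spec0 <- phantom_spec(grid_shape = c(96, 96, 64), n_fibers = 2,
                        sinuosity = c(1.0, 0), shared_frac = 0,
                        packing_pct = 10, seed = 2)
  tr <- generate_centerline(spec0, 1)
  expect_equal(tr$analytic_sinuosity, 1.0, tolerance = 1e-3)
  spec1 <- phantom_spec(grid_shape = c(128, 128, 64), n_fibers = 2,
                        diameter_um = c(20, 0), sinuosity = c(1.08, 0),
                        shared_frac = 0, packing_pct = 10, seed = 2)
  tr1 <- generate_centerline(spec1, 1)
  expect_lt(abs(tr1$analytic_sinuosity / 1.08 - 1), 0.05)
})

test_that("a half-period bend can reach the semicircle-like sinuosity", {
  # single fiber, one half-period, amplitude solved for s = pi/2
  spec <- phantom_spec(grid_shape = c(256, 256, 48), voxel_size = 1.6,
                       n_fibers = 1, diameter_um = c(12, 0),
                       sinuosity = c(pi / 2, 0), shared_frac = 0,
                       wiggle_periods_range = 1L, packing_pct = 2, seed = 4)
  tr <- generate_centerline(spec, 1)
  expect_lt(abs(tr$analytic_sinuosity / (pi / 2) - 1), 0.05)
  # independent dense quadrature of the stored polyline
  pts <- tr$segments[[1]]
  arc <- sum(sqrt(rowSums(diff(pts)^2)))
  chord <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
  expect_equal(tr$analytic_sinuosity, arc / chord, tolerance = 1e-6)
})

test_that("unattainable sinuosity raises a parameter error", {
  spec <- phantom_spec(grid_shape = c(64, 64, 48), n_fibers = 1,
                       diameter_um = c(10, 0), sinuosity = c(30, 0),
                       shared_frac = 0, packing_pct = 5, seed = 1)
  expect_error(generate_centerline(spec, 1), "unattainable|too small")
})

test_that("generation is deterministic under a fixed seed", {
  spec <- tiny_phantom_spec(seed = 21, noise = 4)
  t1 <- generate_centerline(spec, 2)
  t2 <- generate_centerline(spec, 2)
  expect_identical(t1$segments, t2$segments)
  p1 <- generate_phantom(spec)
  p2 <- generate_phantom(spec)
  expect_identical(p1$volume$data, p2$volume$data)
  expect_identical(p1$labels$data, p2$labels$data)
  # different seed -> different noise field, same grid
  p3 <- generate_phantom(tiny_phantom_spec(seed = 22, noise = 4))
  expect_false(identical(p1$volume$data, p3$volume$data))
})

test_that("label count and packing agreement hold for clean phantoms", {
  spec <- phantom_spec(grid_shape = c(96, 96, 64), voxel_size = 1.6,
                       n_fibers = 5, diameter_um = c(26, 3),
                       sinuosity = c(1.03, 0.02), eccentricity_target = 0.45,
                       packing_pct = 25, noise_sigma = 0, seed = 31)
  ph <- generate_phantom(spec)
  ids <- sort(unique(as.vector(ph$labels$data)))
  expect_equal(ids, 0:length(ph$truths))
  expect_equal(length(ph$truths) + ph$n_rejected, 5L)
  # analytic vs voxelized packing within 3 percentage points
  expect_lt(abs(ph$analytic_packing_pct - ph$voxel_packing_pct), 3)
  # no overlap: each voxel carries at most one label by construction; seeds
  # lie inside their own fiber
  inside <- ph$labels$data[ph$seeds$data > 0L]
  expect_true(all(inside == ph$seeds$data[ph$seeds$data > 0L]))
})

test_that("a single straight cylinder voxelizes to its analytic volume", {
  spec <- phantom_spec(grid_shape = c(64, 64, 64), voxel_size = 1.6,
                       n_fibers = 1, diameter_um = c(32, 0),
                       sinuosity = c(1, 0), eccentricity_target = 0,
                       shared_frac = 0, packing_pct = 10,
                       blur_sigma = 0, noise_sigma = 0, seed = 5)
  ph <- generate_phantom(spec)
  vx <- sum(ph$labels$data > 0L) * 1.6^3
  tr <- ph$truths[[1]]
  analytic <- pi * 16^2 * tr$analytic_length
  expect_lt(abs(vx / analytic - 1), 0.02)
})

test_that("pathology phenotypes carry their structural signatures", {
  # break: two disjoint components under one label
  spb <- phantom_spec(grid_shape = c(96, 96, 64), n_fibers = 2,
                      diameter_um = c(24, 2), sinuosity = c(1.03, 0.01),
                      packing_pct = 12, pathology = c("break" = 1),
                      noise_sigma = 0, seed = 41)
  phb <- generate_phantom(spb)
  cc <- label_components(phb$labels$data == 1L, connectivity = 26)
  expect_gte(max(cc), 2)
  expect_equal(phb$truths[[1]]$phenotype, "break")
  # split: a branch point in the skeleton (one connected seed component)
  sps <- phantom_spec(grid_shape = c(128, 128, 64), n_fibers = 2,
                      diameter_um = c(24, 2), sinuosity = c(1.03, 0.01),
                      packing_pct = 4, pathology = c(split = 1),
                      noise_sigma = 0, seed = 42)
  phs <- generate_phantom(sps)
  sk <- skeletonize(phs$seeds, 1L)
  deg <- vapply(seq_len(nrow(sk)), function(i) {
    dd <- abs(sweep(sk, 2, sk[i, ])); sum(apply(dd, 1, max) == 1)
  }, 0)
  expect_gte(sum(deg >= 3), 1)
  # swell: radius profile bulges along the fiber
  spw <- phantom_spec(grid_shape = c(96, 96, 64), n_fibers = 1,
                      diameter_um = c(20, 0), sinuosity = c(1.01, 0),
                      packing_pct = 3, pathology = c(swell = 1),
                      noise_sigma = 0, seed = 43)
  phw <- generate_phantom(spw)
  prof <- phw$truths[[1]]$a_profile[[1]]
  expect_gt(max(prof) / min(prof), 1.3)
})

test_that("truth morphometry reports the analytic per-fiber metrics", {
  spec <- phantom_spec(grid_shape = c(96, 96, 64), voxel_size = 1.32,
                       n_fibers = 2, diameter_um = c(50, 0),
                       sinuosity = c(1, 0), eccentricity_target = 0,
                       shared_frac = 0, packing_pct = 25, seed = 6)
  ph <- generate_phantom(spec)
  tm <- truth_morphometry(ph$truths, spacing = 9.2)
  expect_equal(tm$per_fiber$diameter_um, rep(50, length(ph$truths)),
               tolerance = 1e-9)
  expect_equal(tm$per_fiber$eccentricity, rep(0, length(ph$truths)))
  expect_equal(tm$per_fiber$sinuosity, rep(1, length(ph$truths)),
               tolerance = 1e-6)
  # elliptic 2:1 semi-axes -> e = 0.8660
  e <- sqrt(1 - 0.25)
  spec2 <- phantom_spec(grid_shape = c(128, 128, 64), n_fibers = 1,
                        diameter_um = c(28, 0), eccentricity_target = e,
                        sinuosity = c(1, 0), shared_frac = 0,
                        packing_pct = 2, seed = 7)
  ph2 <- generate_phantom(spec2)
  tm2 <- truth_morphometry(ph2$truths)
  expect_equal(tm2$per_fiber$eccentricity[1], 0.8660, tolerance = 1e-4)
  # straight fiber: length equals point spacing times interval count
  pts <- ph$truths[[1]]$segments[[1]]
  expect_equal(ph$truths[[1]]$analytic_length,
               sum(sqrt(rowSums(diff(pts)^2))), tolerance = 1e-6)
})

test_that("truth geometry statistics are seed-stable but noise differs", {
  s1 <- tiny_phantom_spec(seed = 50, noise = 5)
  s2 <- tiny_phantom_spec(seed = 51, noise = 5)
  p1 <- generate_phantom(s1); p2 <- generate_phantom(s2)
  # same generative distribution: mean diameters within a broad band
  d1 <- mean(vapply(p1$truths, `[[`, 0, "diameter_um"))
  d2 <- mean(vapply(p2$truths, `[[`, 0, "diameter_um"))
  expect_lt(abs(d1 - d2) / 24, 0.5)
  expect_false(identical(p1$volume$data, p2$volume$data))
})
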