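test_that("thinning reduces a digital cylinder to a near-axial curve", {
  dims <- c(15L, 15L, 100L)
  mask <- digital_tube(dims, c(8, 8, 1), c(8, 8, 100), radius = 5)
  lab <- ft_labels(array(as.integer(mask), dims), 1)
  sk <- skeletonize(lab, 1L)
  expect_gt(nrow(sk), 50)
  # every skeleton voxel within 1.5 voxels of the true axis (x = y = 8)
  off_axis <- sqrt((sk[, 1] - 8)^2 + (sk[, 2] - 8)^2)
  expect_lt(max(off_axis), 1.5)
  # thin: no voxel has a 3x3x3 neighbourhood fully foreground
  expect_lt(max(table(sk[, 3])), 4)
})

test_that("a single voxel mask skeletonizes to itself and empties error", {
  lab <- ft_labels(array(c(rep(0L, 13), 1L, rep(0L, 13)), c(3, 3, 3)), 1)
  sk <- skeletonize(lab, 1L)
  expect_equal(nrow(sk), 1L)
  expect_equal(unname(sk[1, ]), c(2L, 2L, 2L))
  expect_error(skeletonize(lab, 9L), "empty")
})

test_that("skeleton of a Y-shaped tube contains exactly one branch voxel", {
  dims <- c(40L, 40L, 40L)
  m <- digital_tube(dims, c(20, 20, 2), c(20, 20, 20), 2.2) |
       digital_tube(dims, c(20, 20, 20), c(8, 20, 38), 2.2) |
       digital_tube(dims, c(20, 20, 20), c(32, 20, 38), 2.2)
  lab <- ft_labels(array(as.integer(m), dims), 1)
  sk <- skeletonize(lab, 1L)
  # degree >= 3 voxels in the 26-connectivity skeleton graph
  key <- sk[, 1] + 100 * sk[, 2] + 10000 * sk[, 3]
  deg <- vapply(seq_len(nrow(sk)), function(i) {
    dd <- abs(sweep(sk, 2, sk[i, ]))
    sum(apply(dd, 1, max) == 1 & apply(dd, 1, max) <= 1) }, 0)
  expect_gte(sum(deg >= 3), 1)
  expect_lte(sum(deg >= 3), 3)  # one branch point, possibly thick
})

test_that("longest path equals the chain on a linear skeleton", {
  chain <- cbind(5L, 5L, 1:10)
  p <- longest_path(chain)
  expect_equal(nrow(p), 10L)
  expect_true(all(diff(p[, 3]) == 1) || all(diff(p[, 3]) == -1))
})

test_that("longest path on a Y keeps the two longest arms", {
  # arms along +z (length 30), +x (40), -x (50) from a hub
  hub <- c(60L, 5L, 5L)
  vox <- rbind(t(vapply(0:30, function(i) c(hub[1], hub[2], hub[3] + i), integer(3))),
               t(vapply(1:40, function(i) c(hub[1] + i, hub[2], hub[3]), integer(3))),
               t(vapply(1:50, function(i) c(hub[1] - i, hub[2], hub[3]), integer(3))))
  p <- longest_path(vox)
  len <- sum(sqrt(rowSums(diff(p)^2)))
  expect_equal(len, 90)
  # ends are the tips of the 40 and 50 arms
  ends <- rbind(p[1, ], p[nrow(p), ])
  expect_setequal(ends[, 1], c(hub[1] + 40L, hub[1] - 50L))
})

test_that("longest path equals brute force on small random skeletons", {
  set.seed(42)
  for (rep in 1:12) {
    # random connected voxel blob of <= 15 voxels
    vox <- matrix(c(5L, 5L, 5L), 1)
    while (nrow(vox) < sample(6:15, 1)) {
      base <- vox[sample(nrow(vox), 1), ]
      cand <- base + sample(c(-1L, 0L, 1L), 3, TRUE)
      if (all(cand >= 1) && !any(apply(vox, 1, function(r) all(r == cand))))
        vox <- rbind(vox, cand)
    }
    got <- longest_path(vox)
    expect_equal(sum(sqrt(rowSums(diff(got)^2))),
                 brute_force_longest(vox), tolerance = 1e-9)
    # always a simple path
    expect_equal(nrow(unique(got)), nrow(got))
  }
})

test_that("resampling yields equidistant points and preserves endpoints", {
  seg <- rbind(c(0, 0, 0), c(0, 0, 13.2))
  cl <- resample_centerline(seg, 1.32)
  expect_equal(nrow(cl$points), 11L)
  expect_equal(cl$points[1, ], c(0, 0, 0))
  expect_equal(cl$points[11, ], c(0, 0, 13.2))
  gaps <- sqrt(rowSums(diff(cl$points)^2))
  expect_lt(max(abs(gaps - 1.32)) / 1.32, 0.01)
  # curved path: dense semicircle of radius 10
  th <- seq(0, pi, length.out = 4000)
  semi <- cbind(10 * cos(th), 10 * sin(th), 0)
  cls <- resample_centerline(semi, 0.05)
  expect_equal(fiber_length(cls), pi * 10, tolerance = 0.005 * pi * 10)
  expect_error(resample_centerline(seg, 20), "shorter")
})

test_that("frames are orthonormal, rotation-minimizing and match plane geometry", {
  # straight line: constant frames
  cl <- straight_centerline(20)
  fr <- frames(cl)
  expect_equal(max(abs(fr$tangent %*% c(0, 0, 1) - 1)), 0, tolerance = 1e-12)
  expect_lt(max(abs(diff(fr$normal))), 1e-12)
  for (i in c(1, 10, 20)) {
    expect_equal(sum(fr$tangent[i, ] * fr$normal[i, ]), 0, tolerance = 1e-9)
    expect_equal(sum(fr$normal[i, ]^2), 1, tolerance = 1e-9)
    expect_equal(sum(fr$binormal[i, ]^2), 1, tolerance = 1e-9)
  }
  # planar arc: binormal equals the plane normal throughout
  th <- seq(0, pi / 2, length.out = 80)
  arc <- cbind(20 * cos(th), 20 * sin(th), 0)
  fra <- frames(structure(list(points = arc, spacing = 1, fiber_id = "a"),
                          class = "ft_centerline"))
  # the plane normal (z) keeps fixed coordinates in the transported frame
  c1 <- fra$normal[, 3]; c2 <- fra$binormal[, 3]
  expect_lt(max(abs(c1 - c1[1])), 1e-6)
  expect_lt(max(abs(c2 - c2[1])), 1e-6)
  expect_equal(c1[1]^2 + c2[1]^2, 1, tolerance = 1e-9)
  # helix: rotation-minimizing frames twist less than Frenet frames
  t <- seq(0, 4 * pi, length.out = 300)
  helix <- cbind(10 * cos(t), 10 * sin(t), 2 * t)
  frh <- frames(structure(list(points = helix, spacing = 1, fiber_id = "h"),
                          class = "ft_centerline"))
  twist <- sum(abs(asin(pmin(pmax(rowSums(
    frh$normal[-1, ] * frh$binormal[-nrow(helix), ]), -1), 1))))
  # Frenet normal rotates with the full torsion: tau * arclen
  tau <- 2 / (10^2 + 2^2)
  arclen <- sum(sqrt(rowSums(diff(helix)^2)))
  expect_lt(twist, tau * arclen)
  expect_error(frames(structure(list(points = rbind(c(0, 0, 0), c(0, 0, 0),
                                                    c(0, 0, 1)),
                                     spacing = 1, fiber_id = "d"),
                                class = "ft_centerline")), "duplicate")
})

test_that("centerline CSV round-trips", {
  dir <- withr::local_tempdir()
  cl1 <- straight_centerline(10)
  cl2 <- straight_centerline(8, origin = c(10, 10, 0.8))
  cl2$fiber_id <- "2"
  p <- file.path(dir, "cl.csv")
  write_centerlines(list("t" = cl1, "2" = cl2), p)
  back <- read_centerlines(p)
  expect_equal(length(back), 2L)
  expect_equal(unname(back[["t"]]$points), unname(cl1$points))
  expect_equal(back[["2"]]$spacing, cl2$spacing)
})

test_that("phantom centerline recovery: position, length, and id splitting", {
  spec <- tiny_phantom_spec()
  ph <- generate_phantom(spec)
  cls <- extract_centerlines(ph$seeds, spacing = 1.6)
  expect_equal(length(cls), length(ph$truths))
  for (fid in names(cls)) {
    tru <- ph$truths[[as.integer(fid)]]$segments[[1]]
    pts <- cls[[fid]]$points
    mx <- approx(tru[, 3], tru[, 1], xout = pts[, 3], rule = 2)$y
    my <- approx(tru[, 3], tru[, 2], xout = pts[, 3], rule = 2)$y
    dev <- sqrt((pts[, 1] - mx)^2 + (pts[, 2] - my)^2)
    expect_lt(mean(dev), 1.6)  # within one voxel on average
    expect_lt(abs(fiber_length(cls[[fid]]) /
                  ph$truths[[as.integer(fid)]]$analytic_length - 1), 0.02)
  }
})
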