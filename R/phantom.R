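#' Specification of a synthetic fiber-population phantom
#'
#' Defines the conditions of a synthetic muscle sample: grid and voxel size,
#' fiber diameter distribution (median and IQR, micrometers), sinuosity
#' distribution (median and IQR), cross-sectional eccentricity, target
#' packing fraction, pathology phenotype probabilities, and the two-level
#' intensity model (foreground/background intensity, Gaussian blur emulating
#' partial-volume effects, additive Gaussian noise). Identical spec and seed
#' give bit-identical phantoms.
#'
#' Geometry model: fibers span the z extent of the grid from transverse
#' positions on a jittered hexagonal lattice (muscle fibers are densely
#' packed and share a main direction). Bending is the sum of a coherent
#' displacement field shared by all fibers (amplitude set by
#' \code{shared_frac} of the median sinuosity excess) and a per-fiber
#' short-wavelength sinusoidal component, both vanishing at the fiber ends;
#' the per-fiber amplitude is solved numerically so the analytic sinuosity
#' matches a per-fiber target drawn from the stated distribution. Phenotypes
#' modify the geometry: \code{buckle} inserts a localized fold-back loop,
#' \code{split} adds a branch sharing the first portion of the trunk,
#' \code{break} removes a mid-fiber window leaving two disjoint segments,
#' \code{swell} inflates the radius profile locally.
#'
#' @param grid_shape integer vector of 3 voxel counts.
#' @param voxel_size isotropic voxel size, micrometers.
#' @param n_fibers requested number of fibers.
#' @param diameter_um c(median, IQR) of the equivalent-diameter distribution.
#' @param sinuosity c(median, IQR) of the per-fiber sinuosity distribution.
#' @param eccentricity_target cross-sectional ellipse eccentricity in [0, 1).
#' @param packing_pct target packing fraction of the usable cross-section, %.
#' @param pathology named per-fiber probabilities for \code{buckle},
#'   \code{split}, \code{break}, \code{swell} (at most one phenotype per
#'   fiber).
#' @param fg_intensity,bg_intensity intensity of fiber interior / background.
#' @param blur_sigma Gaussian partial-volume blur, micrometers.
#' @param noise_sigma additive Gaussian noise std, intensity units.
#' @param shared_frac fraction of the median sinuosity excess carried by the
#'   coherent shared bending field (default 0.5).
#' @param wiggle_periods_range integer range of half-periods for the
#'   per-fiber component (default 5:7; short wavelengths let small, packing
#'   compatible amplitudes produce realistic sinuosity).
#' @param seed integer RNG seed.
#' @return validated spec (class \code{ft_phantom_spec}).
#' @export
phantom_spec <- function(grid_shape = c(144, 144, 96), voxel_size = 1.6,
                         n_fibers = 10,
                         diameter_um = c(35, 5), sinuosity = c(1.05, 0.04),
                         eccentricity_target = 0.55, packing_pct = 35,
                         pathology = c(buckle = 0, split = 0, "break" = 0,
                                       swell = 0),
                         fg_intensity = 100, bg_intensity = 20,
                         blur_sigma = 1.6, noise_sigma = 0,
                         shared_frac = 0.5, wiggle_periods_range = 5:7,
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8))
  if (voxel_size <= 0) stop("voxel_size must be > 0")
  if (diameter_um[1] <= 0 || diameter_um[2] < 0)
    stop("diameter median must be > 0 and IQR >= 0")
  if (sinuosity[1] < 1) stop("sinuosity target must be >= 1")
  if (eccentricity_target < 0 || eccentricity_target >= 1)
    stop("eccentricity target must be in [0, 1)")
  if (packing_pct <= 0 || packing_pct > 90)
    stop("packing_pct must be in (0, 90]")
  if (noise_sigma < 0 || blur_sigma < 0) stop("noise/blur must be >= 0")
  path <- c(buckle = 0, split = 0, "break" = 0, swell = 0)
  path[names(pathology)] <- pathology
  if (any(path < 0) || sum(path) > 1)
    stop("pathology probabilities must be >= 0 and sum to <= 1")
  structure(list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
                 n_fibers = as.integer(n_fibers), diameter_um = diameter_um,
                 sinuosity = sinuosity,
                 eccentricity_target = eccentricity_target,
                 packing_pct = packing_pct, pathology = path,
                 fg_intensity = fg_intensity, bg_intensity = bg_intensity,
                 blur_sigma = blur_sigma, noise_sigma = noise_sigma,
                 shared_frac = shared_frac,
                 wiggle_periods_range = as.integer(wiggle_periods_range),
                 seed = as.integer(seed)),
            class = "ft_phantom_spec")
}

# deterministic derived seeds below 2^31
derive_seed <- function(seed, ...) {
  tags <- vapply(list(...), function(t) {
    if (is.character(t)) sum(utf8ToInt(t) * seq_along(utf8ToInt(t)))
    else as.numeric(t)
  }, 0)
  s <- (seed %% 1e6) * 2017
  for (t in tags) s <- (s * 193 + t * 7919 + 11) %% 2147483629
  as.integer(s)
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

# arc-length resampling of a bare polyline (n x 3), preserving endpoints
resample_polyline <- function(pts, step) {
  if (nrow(pts) < 2L) return(pts)
  seg <- sqrt(rowSums(diff(pts)^2))
  arc <- c(0, cumsum(seg))
  L <- arc[length(arc)]
  if (L < step) return(pts[c(1L, nrow(pts)), , drop = FALSE])
  targets <- seq(0, L, by = step)
  if (L - targets[length(targets)] > 1e-9) targets <- c(targets, L)
  vapply(1:3, function(a) approx(arc, pts[, a], xout = targets,
                                 ties = "ordered")$y,
         numeric(length(targets)))
}

# All random draws for one fiber, deterministic in (spec, index, retry).
# Placement retries redraw the wiggle and progressively damp diameter and
# sinuosity to ease packing.
fiber_params <- function(spec, fiber_index, retry = 0L) {
  with_seed(derive_seed(spec$seed, "fiber", fiber_index, retry), {
    shrink <- 0.93^max(0, retry - 2L)
    dia <- rnorm(1, spec$diameter_um[1], spec$diameter_um[2] / 1.349)
    dia <- min(max(dia, 0.5 * spec$diameter_um[1]),
               1.8 * spec$diameter_um[1]) * shrink
    s_t <- rnorm(1, spec$sinuosity[1], spec$sinuosity[2] / 1.349)
    s_t <- min(max(s_t, 1), spec$sinuosity[1] + 3.5 * spec$sinuosity[2] / 1.349)
    u <- runif(1)
    cum <- cumsum(spec$pathology)
    hit <- which(u < cum)
    ph <- if (length(hit) > 0L) names(cum)[hit[1]] else "none"
    list(dia = dia, s_t = s_t, phenotype = ph,
         k_ind = sample(spec$wiggle_periods_range, 1),
         ang_ind = runif(1, 0, 2 * pi),
         orientation = runif(1, 0, pi),
         t0_frac = runif(1, 0.35, 0.65),
         swell_frac = runif(1, 0.3, 0.7),
         ang_branch = runif(1, 0, 2 * pi))
  })
}

shared_sin <- function(spec) 1 + spec$shared_frac * (spec$sinuosity[1] - 1)

# Transverse allowance of one fiber: maximum radius (including swelling)
# plus the per-fiber wiggle amplitude. Buckle loops and split branches
# deliberately reserve no extra room: they point toward the domain center
# and displace their immediate neighbours through the collision check,
# emulating focal lesions.
fiber_allowance <- function(spec, par, L) {
  s_sh <- shared_sin(spec)
  A <- 2 * sqrt(max(par$s_t - s_sh, 0.002)) * L / (par$k_ind * pi)
  r <- par$dia / 2
  if (par$phenotype == "swell") r <- r * 1.45
  r + A
}

# Fiber positions by deterministic bottom-left first-fit disc packing: each
# fiber reserves a disc of radius (max radius + wiggle amplitude + one
# voxel), so heterogeneous diameters pack without systematically
# rejecting large fibers. The packing target is translated into a stretch
# factor applied to the contact spacing. Fibers that do not fit in the
# usable area stay unplaced (NA position).
phantom_lattice <- function(spec) {
  ext <- spec$grid_shape * spec$voxel_size
  L <- ext[3]
  vs <- spec$voxel_size
  pars <- lapply(seq_len(spec$n_fibers), function(i) fiber_params(spec, i))
  s_sh <- shared_sin(spec)
  A_sh <- 2 * sqrt(max(s_sh - 1, 0)) * L / (2 * pi)
  allow <- vapply(pars, function(p) fiber_allowance(spec, p, L), 0)
  q <- allow + vs      # placement reserve: one voxel between surfaces
  with_seed(derive_seed(spec$seed, "lattice"), {
    margin <- max(allow) + A_sh + 2 * vs
    x0 <- margin; x1 <- ext[1] - margin
    y0 <- margin; y1 <- ext[2] - margin
    if (x1 <= x0 || y1 <= y0)
      stop("grid too small for the requested fiber geometry")
    gx <- seq(x0, x1, by = vs)
    gy <- seq(y0, y1, by = vs)
    grid <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
    pos <- matrix(NA_real_, spec$n_fibers, 2L)
    placed_q <- numeric(0)
    pos_x <- numeric(0); pos_y <- numeric(0)
    for (i in seq_len(spec$n_fibers)) {
      ok <- rep(TRUE, nrow(grid))
      for (j in seq_along(placed_q)) {
        need2 <- (q[i] + placed_q[j])^2
        ok <- ok & ((grid[, 1] - pos_x[j])^2 + (grid[, 2] - pos_y[j])^2 >= need2)
      }
      hit <- which(ok)
      if (length(hit) == 0L) next
      p <- grid[hit[1], ] + runif(2, -0.15 * vs, 0.15 * vs)
      pos[i, ] <- p
      pos_x <- c(pos_x, p[1]); pos_y <- c(pos_y, p[2])
      placed_q <- c(placed_q, q[i])
    }
    # recenter the contact-packed configuration in the usable rectangle,
    # then expand it about the center toward the target density (expansion
    # capped where fibers would leave the usable area)
    okr <- !is.na(pos[, 1])
    if (sum(okr) > 1L) {
      ctr_conf <- c(mean(range(pos[okr, 1])), mean(range(pos[okr, 2])))
      ctr_use <- c((x0 + x1) / 2, (y0 + y1) / 2)
      pos[okr, ] <- sweep(pos[okr, , drop = FALSE], 2L, ctr_use - ctr_conf, "+")
      dx <- pos[okr, 1] - ctr_use[1]
      dy <- pos[okr, 2] - ctr_use[2]
      qv <- q[okr]
      conf_area <- (diff(range(pos[okr, 1])) + 2 * mean(qv)) *
                   (diff(range(pos[okr, 2])) + 2 * mean(qv))
      dens_conf <- 100 * sum(pi * vapply(pars[okr], function(p) (p$dia / 2)^2, 0)) /
        conf_area
      g_target <- sqrt(max(dens_conf / spec$packing_pct, 1))
      gcap <- suppressWarnings(min(
        ifelse(dx > 0, (x1 - ctr_use[1]) / dx, Inf),
        ifelse(dx < 0, (x0 - ctr_use[1]) / dx, Inf),
        ifelse(dy > 0, (y1 - ctr_use[2]) / dy, Inf),
        ifelse(dy < 0, (y0 - ctr_use[2]) / dy, Inf)))
      g <- max(1, min(g_target, gcap))
      pos[okr, 1] <- ctr_use[1] + g * dx
      pos[okr, 2] <- ctr_use[2] + g * dy
    }
    ang <- runif(1, 0, 2 * pi)
    list(pos = pos, margin = margin, L = L, allow = q,
         usable_area = (x1 - x0) * (y1 - y0),
         shared = list(k = 2L, A = A_sh, dir = c(cos(ang), sin(ang))))
  })
}

# continuous transverse displacement (n x 2) of the shared field
shared_disp <- function(lat, t) {
  w <- lat$shared$A * sin(lat$shared$k * pi * t / lat$L)
  cbind(w * lat$shared$dir[1], w * lat$shared$dir[2])
}

#' Generate the ground-truth geometry of one phantom fiber
#'
#' Draws the fiber's diameter, eccentricity, sinuosity target and phenotype,
#' builds the continuous centerline (shared bending plus per-fiber
#' sinusoidal component whose amplitude is solved numerically for the
#' sinuosity target, within 5 percent), applies the phenotype modification,
#' and returns the sampled geometry with analytic length and sinuosity
#' (dense quadrature). Deterministic in (spec, fiber_index, retry).
#'
#' @param spec \code{\link{phantom_spec}}.
#' @param fiber_index 1-based fiber index (<= n_fibers).
#' @param lattice precomputed lattice (internal reuse).
#' @param retry internal retry counter used to redraw on placement
#'   collisions.
#' @return \code{ft_fiber_truth}: list with \code{fiber_id},
#'   \code{segments} (list of point matrices, um), \code{a_profile},
#'   \code{b_profile} (per segment, per point), \code{phenotype},
#'   \code{analytic_length}, \code{analytic_sinuosity},
#'   \code{diameter_um}, \code{eccentricity}, \code{site}.
#' @export
generate_centerline <- function(spec, fiber_index, lattice = NULL, retry = 0L) {
  stopifnot(inherits(spec, "ft_phantom_spec"))
  if (fiber_index < 1L || fiber_index > spec$n_fibers)
    stop("fiber_index out of range")
  lat <- if (is.null(lattice)) phantom_lattice(spec) else lattice
  par <- fiber_params(spec, fiber_index, retry)
  site <- lat$pos[fiber_index, ]
  if (any(is.na(site)))
    stop("fiber ", fiber_index, " was not placed: no room in the usable ",
         "cross-section at packing ", spec$packing_pct, "%")
  {
    L <- lat$L
    vs <- spec$voxel_size
    dia <- par$dia
    ecc <- spec$eccentricity_target
    a0 <- (dia / 2) / (1 - ecc^2)^(1 / 4)
    b0 <- (dia / 2) * (1 - ecc^2)^(1 / 4)
    s_t <- par$s_t
    ph <- par$phenotype
    k_ind <- par$k_ind
    u_ind <- c(cos(par$ang_ind), sin(par$ang_ind))
    tfine <- seq(0.5 * vs, L - 0.5 * vs, by = vs)
    shape_ind <- sin(k_ind * pi * tfine / L)
    base <- cbind(site[1] + shared_disp(lat, tfine)[, 1],
                  site[2] + shared_disp(lat, tfine)[, 2],
                  tfine)
    curve_at <- function(A) {
      p <- base
      p[, 1] <- p[, 1] + A * shape_ind * u_ind[1]
      p[, 2] <- p[, 2] + A * shape_ind * u_ind[2]
      p
    }
    sin_of <- function(p) {
      arc <- sum(sqrt(rowSums(diff(p)^2)))
      arc / sqrt(sum((p[nrow(p), ] - p[1, ])^2))
    }
    A_hi <- 3 * sqrt(max(s_t - 1, 1e-4)) * L / (k_ind * pi)
    A <- 0
    if (s_t > sin_of(base) + 1e-6) {
      f <- function(A) sin_of(curve_at(A)) - s_t
      if (f(A_hi) < 0) stop("sinuosity target ", signif(s_t, 4),
                            " unattainable for this grid size")
      A <- uniroot(f, c(0, A_hi), tol = 1e-6)$root
    }
    pts <- curve_at(A)

    segments <- list(pts)
    branch_from <- NA_integer_
    if (ph == "buckle") {
      ctr <- colMeans(lat$pos[!is.na(lat$pos[, 1]), , drop = FALSE])
      dirc <- ctr - site
      nd <- sqrt(sum(dirc^2))
      dirc <- if (nd < 1e-9) c(1, 0) else dirc / nd
      wd <- min(1.6 * dia, 0.2 * L)
      R <- 0.9 * wd
      t0 <- par$t0_frac * L
      psi <- 2 * pi * smoothstep((tfine - (t0 - wd)) / (2 * wd))
      # helical fold-back loop: the in-plane perpendicular component keeps
      # the outgoing and returning passes apart, so a single 2D slice
      # through the loop shows multiple disconnected profiles of one fiber
      perp <- c(-dirc[2], dirc[1])
      pts[, 1] <- pts[, 1] + R * (1 - cos(psi)) * dirc[1] +
        0.8 * R * sin(psi) * perp[1]
      pts[, 2] <- pts[, 2] + R * (1 - cos(psi)) * dirc[2] +
        0.8 * R * sin(psi) * perp[2]
      pts[, 3] <- pts[, 3] - 0.8 * R * sin(psi)
      segments <- list(pts)
    } else if (ph == "break") {
      gap <- max(0.1 * L, 8 * vs)
      t0 <- par$t0_frac * L
      keep1 <- tfine < t0 - gap / 2
      keep2 <- tfine > t0 + gap / 2
      segments <- list(pts[keep1, , drop = FALSE], pts[keep2, , drop = FALSE])
    } else if (ph == "split") {
      ts <- 0.45 * L
      after <- tfine > ts
      delta <- 1.6 * dia * smoothstep((tfine[after] - ts) / (L - ts))
      # branch diverges inward (within +/- 60 degrees of the center
      # direction) so it cannot leave the grid
      ctr <- colMeans(lat$pos[!is.na(lat$pos[, 1]), , drop = FALSE])
      dirc <- ctr - site
      base_ang <- atan2(dirc[2], dirc[1])
      angb <- base_ang + (par$ang_branch / (2 * pi) - 0.5) * (2 * pi / 3)
      ub <- c(cos(angb), sin(angb))
      br <- pts[after, , drop = FALSE]
      br[, 1] <- br[, 1] + delta * ub[1]
      br[, 2] <- br[, 2] + delta * ub[2]
      segments <- list(pts, br)
      branch_from <- sum(!after) + 1L
    }

    # resample every segment to uniform arc-length steps (the fold of a
    # buckle compresses the z parameterization, which would otherwise leave
    # gaps in the rasterized tube), tracking each segment's t range for the
    # radius profiles
    tranges <- switch(ph,
      "break" = list(range(tfine[keep1]), range(tfine[keep2])),
      "split" = list(range(tfine), range(tfine[after])),
      list(range(tfine)))
    segments <- lapply(segments, resample_polyline, step = vs)
    swell_profile <- function(tseg) rep(1, length(tseg))
    if (ph == "swell") {
      t0 <- par$swell_frac * L
      swell_profile <- function(tseg) 1 + 0.45 * exp(-((tseg - t0) / (0.12 * L))^2)
    }
    a_profile <- list(); b_profile <- list()
    for (si in seq_along(segments)) {
      tpar <- seq(tranges[[si]][1], tranges[[si]][2],
                  length.out = nrow(segments[[si]]))
      sw <- swell_profile(tpar)
      if (ph == "split") {
        # the trunk keeps its size until the split, then both branches shrink
        ts <- 0.45 * L
        sw <- sw * (1 - 0.22 * smoothstep((tpar - ts) / (0.15 * L)))
      }
      a_profile[[si]] <- a0 * sw
      b_profile[[si]] <- b0 * sw
    }
    # analytic length and sinuosity of the main path (dense quadrature)
    main <- segments[[1]]
    dense_n <- 8L * nrow(main)
    td <- seq(0, 1, length.out = dense_n)
    main_d <- vapply(1:3, function(a)
      approx(seq(0, 1, length.out = nrow(main)), main[, a], td)$y,
      numeric(dense_n))
    alen <- sum(sqrt(rowSums(diff(main_d)^2)))
    if (ph == "break") {
      # total length across both segments; sinuosity reported per segment
      alen <- sum(vapply(segments, function(sg)
        sum(sqrt(rowSums(diff(sg)^2))), 0))
    }
    chord <- sqrt(sum((main[nrow(main), ] - main[1, ])^2))
    structure(list(fiber_id = fiber_index, segments = segments,
                   a_profile = a_profile, b_profile = b_profile,
                   phenotype = ph, orientation = par$orientation,
                   analytic_length = alen,
                   analytic_sinuosity = max(1, sum(sqrt(rowSums(diff(segments[[1]])^2))) / chord),
                   diameter_um = dia, eccentricity = ecc, site = site,
                   branch_from = branch_from),
              class = "ft_fiber_truth")
  }
}

# boundary radius profiles (n x K) for one truth segment, on the angular
# grid of its rotation-minimizing frames
truth_radii <- function(truth, si, frames, n_angles = 60L) {
  a <- truth$a_profile[[si]]; b <- truth$b_profile[[si]]
  theta <- (seq_len(n_angles) - 1) * 2 * pi / n_angles
  ab <- a * b
  outer(seq_along(a), seq_len(n_angles), function(i, k) {
    dth <- theta[k] - truth$orientation
    ab[i] / sqrt((b[i] * cos(dth))^2 + (a[i] * sin(dth))^2)
  })
}

#' Generate a complete phantom volume with labels, seeds, and ground truth
#'
#' Places fibers on the lattice with hard no-overlap rejection (tube
#' surfaces at least one voxel apart; colliding fibers are redrawn with a
#' different phase/direction and progressively slightly smaller diameter,
#' then skipped after the retry cap and reported in \code{n_rejected}).
#' Rasterizes each fiber's tube into an integer label volume, builds a thin
#' seed mask per fiber (standing in for a manually painted centerline
#' guess), and renders the grayscale volume as the two-level intensity model
#' blurred by \code{blur_sigma} with additive Gaussian noise.
#'
#' @param spec \code{\link{phantom_spec}}.
#' @param max_retries placement retries per fiber (default 6).
#' @return list with \code{volume} (\code{ft_volume}), \code{labels} (full
#'   tube interiors, \code{ft_labels}), \code{seeds} (thin per-fiber seed
#'   masks, \code{ft_labels}), \code{truths} (list of
#'   \code{ft_fiber_truth}), \code{analytic_packing_pct},
#'   \code{voxel_packing_pct}, \code{n_rejected}, \code{spec}.
#' @export
generate_phantom <- function(spec, max_retries = 6L) {
  stopifnot(inherits(spec, "ft_phantom_spec"))
  lat <- phantom_lattice(spec)
  placed_idx <- which(!is.na(lat$pos[, 1]))
  if (length(placed_idx) == 0L)
    stop("packing target infeasible: no fiber fits the usable cross-section")
  vs <- spec$voxel_size
  dims <- spec$grid_shape

  accepted <- list()
  coarse <- list()   # per accepted fiber: list(pts = m x 3, r = m)
  n_rejected <- 0L
  clearance <- 0.6 * vs
  coarse_of <- function(truth) {
    pts <- do.call(rbind, truth$segments)
    rr <- unlist(truth$a_profile)
    keep <- seq(1L, nrow(pts), by = 2L)
    list(pts = pts[keep, , drop = FALSE], r = rr[keep])
  }
  collides <- function(cand) {
    for (acc in coarse) {
      dmat <- sqrt(outer(cand$pts[, 1], acc$pts[, 1], "-")^2 +
                   outer(cand$pts[, 2], acc$pts[, 2], "-")^2 +
                   outer(cand$pts[, 3], acc$pts[, 3], "-")^2)
      sep <- dmat - outer(cand$r, acc$r, "+")
      if (min(sep) < clearance) return(TRUE)
    }
    FALSE
  }
  n_rejected <- spec$n_fibers - length(placed_idx)
  # pathological fibers go first so their loops/branches claim their room and
  # displace neighbours (focal lesions), not the other way round
  phen0 <- vapply(placed_idx, function(i)
    fiber_params(spec, i)$phenotype, "")
  placed_idx <- placed_idx[order(!(phen0 %in% c("buckle", "split")))]
  for (i in placed_idx) {
    placed <- FALSE
    for (retry in 0:max_retries) {
      truth <- generate_centerline(spec, i, lattice = lat, retry = retry)
      cand <- coarse_of(truth)
      if (!collides(cand)) {
        accepted[[length(accepted) + 1L]] <- truth
        coarse[[length(coarse) + 1L]] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) n_rejected <- n_rejected + 1L
  }
  if (length(accepted) == 0L)
    stop("packing target infeasible: no fiber could be placed")

  lab <- array(0L, dims)
  seed_lab <- array(0L, dims)
  best_margin <- array(-Inf, dims)
  analytic_vol <- 0
  for (k in seq_along(accepted)) {
    truth <- accepted[[k]]
    accepted[[k]]$fiber_id <- k
    for (si in seq_along(truth$segments)) {
      seg_pts <- truth$segments[[si]]
      if (nrow(seg_pts) < 3L) next
      fr <- frames(structure(list(points = seg_pts, spacing = vs,
                                  fiber_id = k), class = "ft_centerline"))
      radii <- truth_radii(truth, si, fr)
      res <- .tube_fill_cpp(as.integer(dims), vs, seg_pts, fr$normal,
                            fr$binormal, fr$tangent, radii, vs, TRUE)
      if (length(res$idx) > 0L) {
        idx <- as.integer(res$idx)
        take <- res$margin > best_margin[idx]
        idx <- idx[take]
        lab[idx] <- k
        best_margin[idx] <- res$margin[take]
      }
      seed_r <- matrix(1.3 * vs, nrow(seg_pts), 8L)
      res_s <- .tube_fill_cpp(as.integer(dims), vs, seg_pts, fr$normal,
                              fr$binormal, fr$tangent, seed_r, vs, TRUE)
      if (length(res_s$idx) > 0L) seed_lab[as.integer(res_s$idx)] <- k
      seglen <- sqrt(rowSums(diff(seg_pts)^2))
      mid_a <- (truth$a_profile[[si]][-1] + truth$a_profile[[si]][-length(truth$a_profile[[si]])]) / 2
      mid_b <- (truth$b_profile[[si]][-1] + truth$b_profile[[si]][-length(truth$b_profile[[si]])]) / 2
      analytic_vol <- analytic_vol + sum(pi * mid_a * mid_b * seglen)
    }
  }
  # seeds must not leak into a neighbouring fiber's tube
  seed_lab[lab > 0L & seed_lab != lab] <- 0L

  vol_dat <- array(spec$bg_intensity, dims)
  vol_dat[lab > 0L] <- spec$fg_intensity
  vol <- ft_volume(vol_dat, vs)
  if (spec$blur_sigma > 0) vol <- gaussian_blur(vol, spec$blur_sigma)
  if (spec$noise_sigma > 0) {
    noise <- with_seed(derive_seed(spec$seed, "noise"),
                       rnorm(prod(dims), 0, spec$noise_sigma))
    vol$data <- vol$data + array(noise, dims)
  }
  grid_vol <- prod(dims) * vs^3
  usable_pack <- 100 * analytic_vol / (lat$usable_area * lat$L)
  if (usable_pack < spec$packing_pct / 2)
    stop("packing target infeasible: achieved ", round(usable_pack, 1),
         "% of the usable cross-section against a target of ",
         spec$packing_pct, "%")
  if (usable_pack < spec$packing_pct - 10)
    warning("achieved packing ", round(usable_pack, 1),
            "% falls short of the ", spec$packing_pct, "% target (",
            n_rejected, " fibers rejected)")
  list(volume = vol,
       labels = ft_labels(lab, vs),
       seeds = ft_labels(seed_lab, vs),
       truths = accepted,
       analytic_packing_pct = 100 * analytic_vol / grid_vol,
       usable_packing_pct = usable_pack,
       voxel_packing_pct = 100 * sum(lab > 0L) / prod(dims),
       n_rejected = n_rejected,
       spec = spec)
}

#' Analytic morphometry of phantom ground truth
#'
#' Computes the recovery targets directly from the generative parameters (no
#' voxels involved): per-fiber analytic length and sinuosity, and
#' per-cross-section equivalent diameter and eccentricity sampled every
#' \code{spacing} micrometers of arc length.
#'
#' @param truths list of \code{ft_fiber_truth}.
#' @param spacing cross-section sampling distance, micrometers.
#' @return list of data frames \code{per_fiber} (fiber_id, phenotype,
#'   length_um, sinuosity, diameter_um, eccentricity) and \code{per_section}
#'   (fiber_id, arc_position_um, diameter_um, eccentricity).
#' @export
truth_morphometry <- function(truths, spacing = 9.2) {
  if (spacing <= 0) stop("spacing must be > 0")
  pf <- list(); ps <- list()
  for (truth in truths) {
    main <- truth$segments[[1]]
    seg <- sqrt(rowSums(diff(main)^2))
    arc <- c(0, cumsum(seg))
    pos <- seq(0, arc[length(arc)], by = spacing)
    idx <- vapply(pos, function(p) which.min(abs(arc - p)), 0L)
    a <- truth$a_profile[[1]][idx]; b <- truth$b_profile[[1]][idx]
    pf[[length(pf) + 1L]] <- data.frame(
      fiber_id = truth$fiber_id, phenotype = truth$phenotype,
      length_um = truth$analytic_length,
      sinuosity = truth$analytic_sinuosity,
      diameter_um = median(2 * sqrt(a * b)),
      eccentricity = truth$eccentricity)
    ps[[length(ps) + 1L]] <- data.frame(
      fiber_id = truth$fiber_id, arc_position_um = pos,
      diameter_um = 2 * sqrt(a * b),
      eccentricity = sqrt(1 - (b / a)^2))
  }
  list(per_fiber = do.call(rbind, pf), per_section = do.call(rbind, ps))
}

#' Phantom presets emulating the three study conditions
#'
#' Scaled-down fiber populations emulating a healthy control sample (thick,
#' straight, densely packed fibers), an atrophic sample (thinner fibers,
#' broader sinuosity distribution, occasional buckling) and a severely
#' atrophic sample (sparse, mixed diameters with swelling, fiber splitting
#' and disjoint breaks). Diameters are scaled to half the biological medians
#' so that tens of fibers fit in a desk-scale grid; sinuosity and
#' eccentricity distributions match the reference populations, and packing
#' fractions preserve the dense/dense/sparse contrast achievable with rigid
#' circular tubes.
#'
#' @param type "healthy", "atrophic", or "severe".
#' @param seed RNG seed.
#' @param noise_sigma additive noise level (default 8, i.e. 10 percent of
#'   the 80-unit foreground/background contrast).
#' @return a \code{\link{phantom_spec}}.
#' @export
phantom_preset <- function(type = c("healthy", "atrophic", "severe"),
                           seed = 1L, noise_sigma = 8) {
  type <- match.arg(type)
  switch(type,
    healthy = phantom_spec(
      grid_shape = c(328, 328, 64), voxel_size = 1.6, n_fibers = 120,
      diameter_um = c(37.2, 5.2), sinuosity = c(1.02, 0.02),
      eccentricity_target = 0.54, packing_pct = 52,
      pathology = c(buckle = 0, split = 0, "break" = 0, swell = 0),
      noise_sigma = noise_sigma, seed = seed),
    atrophic = phantom_spec(
      grid_shape = c(276, 276, 64), voxel_size = 1.6, n_fibers = 132,
      diameter_um = c(25.1, 9.2), sinuosity = c(1.06, 0.09),
      eccentricity_target = 0.57, packing_pct = 36,
      pathology = c(buckle = 0.06, split = 0, "break" = 0, swell = 0),
      noise_sigma = noise_sigma, seed = seed + 101L),
    severe = phantom_spec(
      grid_shape = c(336, 336, 64), voxel_size = 1.6, n_fibers = 34,
      diameter_um = c(35.6, 14.4), sinuosity = c(1.12, 0.11),
      eccentricity_target = 0.43, packing_pct = 20,
      pathology = c(buckle = 0, split = 0.08, "break" = 0.10, swell = 0.25),
      noise_sigma = noise_sigma, seed = seed + 202L))
}
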