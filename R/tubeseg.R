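#' Spoke-sampling and surface-detection parameters
#'
#' Defaults follow the reference acquisition at 1.32 um voxels: 60 spokes at
#' 6 degrees angular resolution, reaching 140 um out from the centerline with
#' a radial sampling density of 3.2 um. The spoke length is meant to exceed
#' the largest expected fiber radius plus a safety margin; for small-fiber
#' volumes a tighter \code{max_radius} (and a radial step equal to the voxel
#' size) localizes the boundary more precisely at negligible cost.
#'
#' @param n_spokes number of angular spokes (default 60).
#' @param angular_step degrees between spokes; must tile 360.
#' @param max_radius spoke length in micrometers (default 140).
#' @param radial_step radial sampling density in micrometers (default 3.2).
#' @param delta_spoke max radius change between adjacent spokes, in radial
#'   samples (default 2).
#' @param delta_slice max radius change between adjacent slices, in radial
#'   samples (default 1).
#' @param r_min minimum surface radius, in radial samples (default 2),
#'   forbidding collapse onto the centerline.
#' @param refine_iters number of centerline refinement + re-detection passes
#'   (default 1).
#' @return list of validated parameters (class \code{ft_terrain_params}).
#' @export
terrain_params <- function(n_spokes = 60L, angular_step = 360 / n_spokes,
                           max_radius = 140, radial_step = 3.2,
                           delta_spoke = 2L, delta_slice = 1L, r_min = 2L,
                           refine_iters = 1L) {
  if (abs(n_spokes * angular_step - 360) > 1e-9)
    stop("n_spokes * angular_step must equal 360 degrees")
  if (max_radius <= 0 || radial_step <= 0) stop("radii must be positive")
  n_radial <- floor(max_radius / radial_step)
  if (n_radial < 3L) stop("fewer than 3 radial samples; increase max_radius")
  if (r_min < 1L || r_min > n_radial)
    stop("r_min outside the radial sample range")
  if (delta_spoke < 0 || delta_slice < 0) stop("smoothness bounds must be >= 0")
  structure(list(n_spokes = as.integer(n_spokes), angular_step = angular_step,
                 max_radius = max_radius, radial_step = radial_step,
                 n_radial = as.integer(n_radial),
                 delta_spoke = as.integer(delta_spoke),
                 delta_slice = as.integer(delta_slice),
                 r_min = as.integer(r_min),
                 refine_iters = as.integer(refine_iters)),
            class = "ft_terrain_params")
}

#' Sample voxel intensities on radial spokes around a centerline
#'
#' Builds the cylindrical-coordinate "terrain": intensity at (slice i, spoke
#' k, radial sample j) is the trilinear interpolation of the volume at
#' \code{p_i + r_j * (cos(theta_k) * normal_i + sin(theta_k) * binormal_i)},
#' with \code{r_j = j * radial_step} and \code{theta_k = (k - 1) *
#' angular_step}. Samples outside the grid are \code{NA} (invalid).
#'
#' @param v an \code{ft_volume}.
#' @param centerline an \code{ft_centerline}.
#' @param frames matching \code{ft_frames} (computed if NULL).
#' @param params \code{\link{terrain_params}}.
#' @return \code{ft_terrain}: list with \code{intensities} (slice x spoke x
#'   radial array), \code{params}, \code{centerline}, \code{frames}.
#' @export
sample_terrain <- function(v, centerline, frames = NULL,
                           params = terrain_params()) {
  stopifnot(inherits(v, "ft_volume"), inherits(centerline, "ft_centerline"))
  if (is.null(frames)) frames <- fibertube::frames(centerline)
  pts <- centerline$points
  n <- nrow(pts)
  K <- params$n_spokes
  J <- params$n_radial
  theta <- (seq_len(K) - 1) * params$angular_step * pi / 180
  rj <- seq_len(J) * params$radial_step
  # directions per (slice, spoke): n*K x 3
  ct <- cos(theta); st <- sin(theta)
  dirs <- matrix(0, n * K, 3)
  for (a in 1:3) {
    dirs[, a] <- rep(frames$normal[, a], times = K) * rep(ct, each = n) +
                 rep(frames$binormal[, a], times = K) * rep(st, each = n)
  }
  base <- pts[rep(seq_len(n), times = K), , drop = FALSE]
  coords <- matrix(0, n * K * J, 3)
  for (a in 1:3) {
    coords[, a] <- rep(base[, a], times = J) +
      rep(dirs[, a], times = J) * rep(rj, each = n * K)
  }
  vals <- trilinear_sample(v, coords)
  if (all(is.na(vals))) stop("centerline lies entirely outside the volume")
  terr <- array(vals, c(n, K, J))
  structure(list(intensities = terr, params = params,
                 centerline = centerline, frames = frames),
            class = "ft_terrain")
}

#' Radial gradient cost of a spoke terrain
#'
#' Second-order central differences of intensity along each spoke (one-sided
#' at the two radial ends). Minimizing the raw signed gradient selects the
#' strongest negative intensity gradient, i.e. the bright-to-dark transition
#' at the outer fiber border. Invalid (out-of-grid) samples receive +Inf.
#'
#' @param terrain \code{ft_terrain} from \code{\link{sample_terrain}}.
#' @return numeric array (slice x spoke x radial) of costs.
#' @export
gradient_cost <- function(terrain) {
  I <- terrain$intensities
  dr <- terrain$params$radial_step
  J <- dim(I)[3]
  if (J < 3L) stop("need at least 3 radial samples")
  g <- array(NA_real_, dim(I))
  g[, , 2:(J - 1)] <- (I[, , 3:J] - I[, , 1:(J - 2)]) / (2 * dr)
  g[, , 1] <- (I[, , 2] - I[, , 1]) / dr
  g[, , J] <- (I[, , J] - I[, , J - 1]) / dr
  g[is.na(g)] <- Inf
  g
}

#' Globally optimal smooth surface through a cost terrain
#'
#' Finds the radius assignment \code{r(slice, spoke)} minimizing the summed
#' column cost subject to hard smoothness bounds: adjacent spokes (circular)
#' may differ by at most \code{delta_spoke} radial samples and adjacent
#' slices by at most \code{delta_slice}. Solved to global optimality as a
#' minimum s-t cut on the standard optimal-net-surface graph (one node per
#' (column, radial level), infinite downward intra-column arcs, shifted
#' inter-column arcs encoding the smoothness bounds, terminal arcs from the
#' level-wise cost differences).
#'
#' @param cost slice x spoke x radial cost array (finite somewhere in every
#'   column; +Inf marks invalid samples).
#' @param params \code{\link{terrain_params}} supplying the smoothness
#'   bounds, \code{r_min} and \code{radial_step}.
#' @return \code{ft_surface}: list with \code{radius} (slice x spoke matrix,
#'   micrometers), \code{level} (radial sample indices), \code{params}.
#' @export
detect_surface <- function(cost, params) {
  d <- dim(cost)
  ns <- d[1]; nk <- d[2]; nr <- d[3]
  rmin <- params$r_min
  L <- nr - rmin + 1L            # levels rmin..nr
  if (L < 1L) stop("r_min leaves no feasible radial band")
  C <- ns * nk                   # columns, slice-major: col = s + ns*(k-1)
  cmat <- matrix(cost[, , rmin:nr], C, L)  # C x L
  fin <- cmat[is.finite(cmat)]
  if (length(fin) == 0L) stop("no finite cost anywhere in the feasible band")
  M <- max(fin) + (max(fin) - min(fin) + 1) * 2  # surrogate for +Inf
  cmat[!is.finite(cmat)] <- M
  # columns with no valid sample (e.g. spokes leaving the grid entirely)
  # carry no boundary information: give them uniform cost so the smoothness
  # constraints alone determine their radius
  dead <- rowSums(cmat < M) == 0L
  cmat[dead, ] <- 0
  # level-difference weights; base level forced into the closed set
  w <- cmat
  if (L > 1L) w[, 2:L] <- cmat[, 2:L] - cmat[, 1:(L - 1)]
  BIG <- sum(abs(w)) + 1
  w[, 1] <- -BIG
  node <- function(col, l) (col - 1L) * L + l     # 1..C*L
  N <- C * L
  src <- N + 1L; snk <- N + 2L
  # terminal arcs
  wv <- as.vector(t(w))                  # node order: column 1 levels 1..L, ...
  neg <- which(wv < 0); pos <- which(wv > 0)
  ef <- c(rep(src, length(neg)), pos)
  et <- c(neg, rep(snk, length(pos)))
  ec <- c(-wv[neg], wv[pos])
  # intra-column arcs (l -> l-1)
  if (L > 1L) {
    cols <- rep(seq_len(C), each = L - 1L)
    ls <- rep(2:L, times = C)
    ef <- c(ef, node(cols, ls)); et <- c(et, node(cols, ls - 1L))
    ec <- c(ec, rep(BIG, length(cols)))
  }
  # inter-column arcs for neighbour pairs with bound delta:
  # node(c1, l) -> node(c2, l - delta) for l - delta >= 2
  add_pair <- function(c1, c2, delta) {
    if (L <= delta + 1L) return(invisible())
    ls <- (delta + 2L):L
    cc1 <- rep(c1, each = length(ls)); cc2 <- rep(c2, each = length(ls))
    lrep <- rep(ls, times = length(c1))
    ef <<- c(ef, node(cc1, lrep)); et <<- c(et, node(cc2, lrep - delta))
    ec <<- c(ec, rep(BIG, length(cc1)))
  }
  scol <- rep(seq_len(ns), times = nk)
  kcol <- rep(seq_len(nk), each = ns)
  colid <- function(s, k) s + ns * (k - 1L)
  # spoke neighbours, circular in k
  kp <- ifelse(kcol == nk, 1L, kcol + 1L)
  add_pair(colid(scol, kcol), colid(scol, kp), params$delta_spoke)
  add_pair(colid(scol, kp), colid(scol, kcol), params$delta_spoke)
  # slice neighbours
  hs <- scol < ns
  add_pair(colid(scol[hs], kcol[hs]), colid(scol[hs] + 1L, kcol[hs]),
           params$delta_slice)
  add_pair(colid(scol[hs] + 1L, kcol[hs]), colid(scol[hs], kcol[hs]),
           params$delta_slice)
  fl <- .mincut_cpp(snk, as.integer(ef), as.integer(et), as.numeric(ec),
                    src, snk)
  closed <- fl$source_side[seq_len(N)]
  lev <- vapply(seq_len(C), function(col) {
    idx <- ((col - 1L) * L + 1L):(col * L)
    max(which(closed[idx]))
  }, integer(1))
  level <- matrix(lev + rmin - 1L, ns, nk)   # radial sample index
  # sub-sample localization: parabolic interpolation of the cost around the
  # detected level removes the radial quantization of the boundary
  radius <- level * params$radial_step
  cflat <- matrix(cost, C, nr)
  j <- as.vector(level)
  interior <- j > 1L & j < nr
  cm <- cflat[cbind(seq_len(C), pmax(j - 1L, 1L))]
  c0 <- cflat[cbind(seq_len(C), j)]
  cp <- cflat[cbind(seq_len(C), pmin(j + 1L, nr))]
  den <- cm - 2 * c0 + cp
  ok <- interior & is.finite(den) & den > 1e-12
  off <- rep(0, C)
  off[ok] <- pmin(pmax(0.5 * (cm[ok] - cp[ok]) / den[ok], -0.5), 0.5)
  radius <- radius + matrix(off, ns, nk) * params$radial_step
  structure(list(radius = radius, level = level, params = params),
            class = "ft_surface")
}

#' Refine a centerline to the cross-sectional centroid of its surface
#'
#' Moves each centerline point to the area centroid of the cross-sectional
#' polygon whose vertices are the detected spoke boundary points. A perfectly
#' centered centerline is a fixed point of this map.
#'
#' @param centerline \code{ft_centerline}.
#' @param surface \code{ft_surface} detected on that centerline.
#' @param frames the \code{ft_frames} used for spoke sampling.
#' @return refined \code{ft_centerline}.
#' @export
refine_centerline <- function(centerline, surface, frames) {
  pts <- centerline$points
  n <- nrow(pts)
  K <- surface$params$n_spokes
  theta <- (seq_len(K) - 1) * surface$params$angular_step * pi / 180
  ct <- cos(theta); st <- sin(theta)
  disp <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    r <- surface$radius[i, ]
    ok <- is.finite(r)
    if (sum(ok) < 3L) stop("degenerate cross-section polygon at slice ", i)
    x <- r * ct; y <- r * st
    xs <- c(x, x[1]); ys <- c(y, y[1])
    crossp <- xs[-length(xs)] * ys[-1] - xs[-1] * ys[-length(ys)]
    A <- sum(crossp) / 2
    if (abs(A) < 1e-12) next
    cx <- sum((xs[-length(xs)] + xs[-1]) * crossp) / (6 * A)
    cy <- sum((ys[-length(ys)] + ys[-1]) * crossp) / (6 * A)
    disp[i, ] <- cx * frames$normal[i, ] + cy * frames$binormal[i, ]
  }
  # the terminal slices have one-sided tangents and often touch the volume
  # faces, making their centroids unreliable; they inherit the displacement
  # of the nearest interior slice instead
  n_end <- min(3L, (n - 1L) %/% 2L)
  if (n_end > 0L && n > 2L * n_end) {
    for (i in seq_len(n_end)) {
      disp[i, ] <- disp[n_end + 1L, ]
      disp[n - i + 1L, ] <- disp[n - n_end, ]
    }
  }
  out <- centerline
  out$points <- pts + disp
  out
}

#' Segment one fiber as a closed tube around its centerline
#'
#' Runs terrain sampling, gradient cost, optimal-surface detection, and
#' (optionally, \code{refine_iters} times) centroid-based centerline
#' refinement followed by re-detection.
#'
#' @param v \code{ft_volume}.
#' @param centerline \code{ft_centerline}.
#' @param params \code{\link{terrain_params}}.
#' @return list with \code{surface} (\code{ft_surface}), \code{centerline}
#'   (refined), \code{frames}.
#' @export
segment_fiber <- function(v, centerline, params = terrain_params()) {
  cl <- centerline
  for (iter in seq_len(params$refine_iters + 1L)) {
    fr <- frames(cl)
    terr <- sample_terrain(v, cl, fr, params)
    surf <- detect_surface(gradient_cost(terr), params)
    if (iter <= params$refine_iters) {
      # smoothing removes the per-slice jitter of the quantized centroids,
      # which would otherwise inflate arc length and hence sinuosity
      cl <- smooth_centerline(refine_centerline(cl, surf, fr))
    }
  }
  list(surface = surf, centerline = cl, frames = fr)
}

#' Rasterize detected surfaces into a no-overlap label volume
#'
#' A voxel lies inside a fiber when, relative to the nearest centerline
#' point, its in-plane radius is below the angularly interpolated boundary
#' radius. Voxels claimed by several fibers are assigned to the fiber whose
#' boundary they are deepest inside (largest radius margin); remaining ties
#' go to the nearest centerline. The output labels are disjoint by
#' construction.
#'
#' @param segments named list of \code{segment_fiber} results (names are
#'   fiber ids).
#' @param dims grid dimensions of the target volume.
#' @param voxel_size voxel size in micrometers.
#' @return \code{ft_labels} volume; the integer label of fiber k is its
#'   position in \code{segments}, with the id map in attribute
#'   \code{fiber_ids}.
#' @export
rasterize_fibers <- function(segments, dims, voxel_size) {
  lab <- array(0L, dims)
  best_margin <- array(-Inf, dims)
  best_dist <- array(Inf, dims)
  for (k in seq_along(segments)) {
    seg <- segments[[k]]
    cl <- seg$centerline
    fr <- seg$frames
    res <- .tube_fill_cpp(as.integer(dims), voxel_size, cl$points,
                          fr$normal, fr$binormal, fr$tangent,
                          seg$surface$radius, cl$spacing, TRUE)
    if (length(res$idx) == 0L) next
    idx <- as.integer(res$idx)
    take <- res$margin > best_margin[idx] |
      (res$margin == best_margin[idx] & res$dist < best_dist[idx])
    idx <- idx[take]
    lab[idx] <- k
    best_margin[idx] <- res$margin[take]
    best_dist[idx] <- res$dist[take]
  }
  out <- ft_labels(lab, voxel_size)
  attr(out, "fiber_ids") <- names(segments)
  out
}

#' Reflection-pad a volume along z
#'
#' Fibers commonly run through the top and bottom faces of the acquired
#' volume; near those faces the oblique spoke sampling planes would
#' otherwise leave the grid and destabilize the surface detection.
#' Mirror-padding continues the image content plausibly across the faces.
#' The returned volume keeps the original physical coordinates (its origin
#' shifts by \code{-npad} voxels in z).
#'
#' @param v \code{ft_volume}.
#' @param npad number of voxels to add on each z face.
#' @return padded \code{ft_volume}.
#' @export
pad_volume_z <- function(v, npad) {
  npad <- min(as.integer(npad), dim(v$data)[3] - 1L)
  if (npad <= 0L) return(v)
  d <- dim(v$data)
  out <- array(0, c(d[1], d[2], d[3] + 2L * npad))
  out[, , (npad + 1L):(npad + d[3])] <- v$data
  out[, , npad:1] <- v$data[, , 2L:(npad + 1L)]
  out[, , (npad + d[3] + 1L):(npad + 2L * npad + d[3] - npad)] <-
    v$data[, , (d[3] - 1L):(d[3] - npad)]
  ft_volume(out, v$voxel_size, v$origin - c(0, 0, npad * v$voxel_size))
}

#' Segment all fibers of a sample
#'
#' The volume is reflection-padded along z (see \code{\link{pad_volume_z}})
#' so that fibers crossing the top/bottom faces are segmented stably.
#'
#' @param v \code{ft_volume}.
#' @param centerlines list of \code{ft_centerline} (see
#'   \code{\link{extract_centerlines}}).
#' @param params \code{\link{terrain_params}}.
#' @param verbose print per-fiber progress.
#' @return list with \code{segments} (per-fiber surfaces and refined
#'   centerlines) and \code{labels} (\code{ft_labels}).
#' @export
segment_fibers <- function(v, centerlines, params = terrain_params(),
                           verbose = FALSE) {
  vp <- pad_volume_z(v, ceiling(0.6 * params$max_radius / v$voxel_size))
  segments <- list()
  for (fid in names(centerlines)) {
    if (verbose) message("segmenting fiber ", fid)
    segments[[fid]] <- segment_fiber(vp, centerlines[[fid]], params)
  }
  labels <- rasterize_fibers(segments, dim(v$data), v$voxel_size)
  list(segments = segments, labels = labels)
}

#' Export detected surfaces as a long-format table
#'
#' @param segments named list from \code{\link{segment_fibers}}.
#' @return data frame (fiber_id, slice, spoke, radius_um).
#' @export
surface_table <- function(segments) {
  do.call(rbind, lapply(names(segments), function(fid) {
    r <- segments[[fid]]$surface$radius
    data.frame(fiber_id = fid,
               slice = rep(seq_len(nrow(r)), times = ncol(r)),
               spoke = rep(seq_len(ncol(r)), each = nrow(r)),
               radius_um = as.vector(r))
  }))
}
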