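#' Skeletonize one fiber's mask to a curve skeleton
#'
#' Applies topology-preserving 3D thinning (26-connectivity foreground,
#' 6-connectivity background; curve endpoints retained) to the voxel mask of
#' a single fiber, yielding a <= 1 voxel wide skeleton that preserves the
#' topology of the mask. The input mask may be a thin painted seed (the usual
#' case, standing in for a manually drawn centerline guess) or a full tube
#' mask.
#'
#' @param labels an \code{ft_labels} volume.
#' @param fiber_id which label to skeletonize.
#' @return integer matrix (n x 3) of skeleton voxel indices (1-based).
#' @export
skeletonize <- function(labels, fiber_id) {
  stopifnot(inherits(labels, "ft_labels"))
  mask <- labels$data == fiber_id
  if (!any(mask)) stop("empty mask for fiber ", fiber_id)
  thin <- .thin3d_cpp(as.logical(mask), as.integer(dim(labels$data)))
  dim(thin) <- dim(labels$data)
  which(thin, arr.ind = TRUE)
}

# Build the skeleton adjacency graph: vertices are skeleton voxels, edges
# connect 26-neighbours, weighted by Euclidean distance in micrometers.
skeleton_graph <- function(vox, voxel_size = 1) {
  vox <- matrix(as.integer(vox), ncol = 3L)
  n <- nrow(vox)
  if (n == 0L) stop("empty skeleton")
  span <- apply(vox, 2L, max) + 1L
  key <- function(m) (m[, 1] + span[1] * (m[, 2] + span[2] * m[, 3]))
  lookup <- seq_len(n)
  names(lookup) <- as.character(key(vox))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  # keep half the offsets so each pair appears once
  offs <- offs[offs[, 1] > 0 | (offs[, 1] == 0 & offs[, 2] > 0) |
               (offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] > 0), , drop = FALSE]
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(vox, 2L, as.integer(offs[r, ]), "+")
    hit <- lookup[as.character(key(nb))]
    keep <- !is.na(hit)
    if (any(keep)) {
      from <- c(from, which(keep))
      to <- c(to, unname(hit[keep]))
      w <- c(w, rep(sqrt(sum(offs[r, ]^2)) * voxel_size, sum(keep)))
    }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::E(g)$weight <- w
  igraph::V(g)$x <- vox[, 1]; igraph::V(g)$y <- vox[, 2]; igraph::V(g)$z <- vox[, 3]
  g
}

#' Longest branch-free path through a skeleton
#'
#' Returns the simple (non-repeating) voxel path of maximal arc length
#' (26-connectivity, Euclidean edge weights) through the largest connected
#' component of the skeleton. On tree-shaped skeletons (the usual outcome of
#' curve thinning) the result is the exact weighted diameter, found with two
#' shortest-path sweeps. Skeletons containing cycles are solved exactly by
#' exhaustive search when small (<= 30 voxels), otherwise by the double-sweep
#' heuristic with a warning. Ties are broken by the lexicographically
#' smallest endpoint coordinates so the result is deterministic.
#'
#' @param skeleton n x 3 integer matrix of skeleton voxel indices.
#' @param voxel_size voxel edge length in micrometers.
#' @return ordered m x 3 matrix of voxel indices along the path.
#' @export
longest_path <- function(skeleton, voxel_size = 1) {
  vox <- matrix(as.integer(skeleton), ncol = 3L)
  if (nrow(vox) == 0L) stop("empty skeleton")
  if (nrow(vox) == 1L) return(vox)
  g <- skeleton_graph(vox, voxel_size)
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  if (length(keep) < nrow(vox)) {
    g <- igraph::induced_subgraph(g, keep)
    vox <- vox[keep, , drop = FALSE]
  }
  n <- igraph::vcount(g)
  if (n == 1L) return(vox)
  is_tree <- igraph::ecount(g) == n - 1L
  lex_order <- order(vox[, 1], vox[, 2], vox[, 3])
  if (is_tree) {
    path_idx <- double_sweep(g, lex_order)
  } else if (n <= 30L) {
    path_idx <- exhaustive_longest_path(g, vox)
  } else {
    warning("skeleton contains cycles and is large; using double-sweep heuristic")
    path_idx <- double_sweep(g, lex_order)
  }
  vox[path_idx, , drop = FALSE]
}

double_sweep <- function(g, lex_order) {
  pick_far <- function(dvec) {
    far <- which(dvec == max(dvec))
    far[which.min(match(far, lex_order))]
  }
  d1 <- as.numeric(igraph::distances(g, v = lex_order[1]))
  a <- pick_far(d1)
  d2 <- as.numeric(igraph::distances(g, v = a))
  b <- pick_far(d2)
  ends <- sort(c(a, b))
  p <- igraph::shortest_paths(g, from = ends[1], to = ends[2],
                              output = "vpath")$vpath[[1]]
  as.integer(p)
}

# exact longest simple path by DFS over all simple paths (small graphs only)
exhaustive_longest_path <- function(g, vox) {
  n <- igraph::vcount(g)
  adj <- lapply(seq_len(n), function(v) as.integer(igraph::neighbors(g, v)))
  wmat <- matrix(0, n, n)
  el <- igraph::as_edgelist(g, names = FALSE)
  for (r in seq_len(nrow(el))) {
    wmat[el[r, 1], el[r, 2]] <- igraph::E(g)$weight[r]
    wmat[el[r, 2], el[r, 1]] <- igraph::E(g)$weight[r]
  }
  best <- list(len = -1, path = integer(0))
  visited <- rep(FALSE, n)
  dfs <- function(v, len, path) {
    if (len > best$len + 1e-12 ||
        (abs(len - best$len) <= 1e-12 && lex_less(vox, path, best$path))) {
      best <<- list(len = len, path = path)
    }
    visited[v] <<- TRUE
    for (u in adj[[v]]) {
      if (!visited[u]) dfs(u, len + wmat[v, u], c(path, u))
    }
    visited[v] <<- FALSE
  }
  for (v in seq_len(n)) dfs(v, 0, v)
  best$path
}

lex_less <- function(vox, p1, p2) {
  if (length(p2) == 0L) return(TRUE)
  k1 <- vox[p1[1], ]; k2 <- vox[p2[1], ]
  for (a in 1:3) {
    if (k1[a] != k2[a]) return(k1[a] < k2[a])
  }
  FALSE
}

#' Equidistantly resample a polyline into a centerline
#'
#' Places points at equal arc-length steps along the input polyline by linear
#' interpolation; the first and last original endpoints are preserved (the
#' final interval may be shorter than \code{spacing}).
#'
#' @param path m x 3 matrix of ordered points, micrometers (or voxel indices
#'   when \code{voxel_size} is given).
#' @param spacing sectioning distance in micrometers.
#' @param voxel_size if supplied, \code{path} is interpreted as 1-based voxel
#'   indices and converted to physical micrometers first.
#' @param fiber_id label carried along for bookkeeping.
#' @return an \code{ft_centerline}: list with \code{points} (N x 3, um),
#'   \code{spacing}, \code{fiber_id}.
#' @export
resample_centerline <- function(path, spacing, voxel_size = NULL, fiber_id = NA) {
  pts <- matrix(as.numeric(path), ncol = 3L)
  if (!is.null(voxel_size)) pts <- (pts - 0.5) * voxel_size
  if (spacing <= 0) stop("spacing must be > 0")
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  L <- sum(seg)
  if (L < spacing) stop("path arc length (", signif(L, 4),
                        " um) is shorter than the spacing")
  s <- c(0, cumsum(seg))
  targets <- seq(0, L, by = spacing)
  if (L - targets[length(targets)] > 1e-9 * max(L, 1)) targets <- c(targets, L)
  out <- vapply(1:3, function(a) approx(s, pts[, a], xout = targets,
                                        ties = "ordered")$y,
                numeric(length(targets)))
  structure(list(points = matrix(out, ncol = 3L), spacing = spacing,
                 fiber_id = fiber_id),
            class = "ft_centerline")
}

#' @export
print.ft_centerline <- function(x, ...) {
  cat(sprintf("<ft_centerline> fiber %s: %d points, spacing %.4g um, length %.4g um\n",
              as.character(x$fiber_id), nrow(x$points), x$spacing, fiber_length(x)))
  invisible(x)
}

#' Rotation-minimizing frames along a centerline
#'
#' Computes per-point orthonormal triads (tangent, normal, binormal).
#' Tangents come from central differences (one-sided at the ends); the
#' normal is parallel-transported along the curve (rotation-minimizing /
#' Bishop frame) so that spokes do not twist at inflection points, unlike
#' the Frenet frame.
#'
#' @param centerline an \code{ft_centerline} with at least 3 points.
#' @return an \code{ft_frames}: list of N x 3 matrices \code{tangent},
#'   \code{normal}, \code{binormal}.
#' @export
frames <- function(centerline) {
  pts <- centerline$points
  n <- nrow(pts)
  if (n < 3L) stop("need at least 3 points for frames")
  if (any(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2) == 0))
    stop("duplicate consecutive points")
  tang <- matrix(0, n, 3)
  tang[1, ] <- pts[2, ] - pts[1, ]
  tang[n, ] <- pts[n, ] - pts[n - 1, ]
  if (n > 2L) tang[2:(n - 1), ] <- pts[3:n, ] - pts[1:(n - 2), ]
  tang <- tang / sqrt(rowSums(tang^2))
  normal <- matrix(0, n, 3)
  binorm <- matrix(0, n, 3)
  # initial normal: axis least aligned with the first tangent, orthogonalized
  seed <- diag(3)[, which.min(abs(tang[1, ])), drop = TRUE]
  n0 <- seed - sum(seed * tang[1, ]) * tang[1, ]
  normal[1, ] <- n0 / sqrt(sum(n0^2))
  binorm[1, ] <- cross3(tang[1, ], normal[1, ])
  for (i in 2:n) {
    # rotate the previous normal by the rotation taking t_{i-1} to t_i
    v <- cross3(tang[i - 1, ], tang[i, ])
    c_ <- sum(tang[i - 1, ] * tang[i, ])
    if (sum(v^2) < 1e-24) {
      nn <- normal[i - 1, ]
    } else {
      nn <- rotate_about(normal[i - 1, ], v / sqrt(sum(v^2)),
                         atan2(sqrt(sum(v^2)), c_))
    }
    nn <- nn - sum(nn * tang[i, ]) * tang[i, ]
    normal[i, ] <- nn / sqrt(sum(nn^2))
    binorm[i, ] <- cross3(tang[i, ], normal[i, ])
  }
  structure(list(tangent = tang, normal = normal, binormal = binorm),
            class = "ft_frames")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rotate_about <- function(v, axis, angle) {
  # Rodrigues rotation of v about unit axis
  v * cos(angle) + cross3(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

#' Extract centerlines for every fiber in a seed label volume
#'
#' For each label: thin to a skeleton, split into connected components
#' (disjoint components of one seed label are treated as separate fiber
#' records sharing a parent id, so broken fibers are not artificially
#' bridged), take the longest branch-free path per component and resample it
#' equidistantly.
#'
#' @param seeds \code{ft_labels} volume of per-fiber seed masks.
#' @param spacing resampling distance in micrometers; defaults to the voxel
#'   size (matching the convention of sectioning at the image resolution).
#' @param min_length_um components shorter than this are dropped (default
#'   2 x spacing).
#' @return list of \code{ft_centerline}; fiber ids are \code{"<label>"} or
#'   \code{"<label>.<k>"} for split/broken components, with the parent label
#'   in attribute \code{parent}.
#' @export
extract_centerlines <- function(seeds, spacing = NULL,
                                min_length_um = NULL) {
  stopifnot(inherits(seeds, "ft_labels"))
  if (is.null(spacing)) spacing <- seeds$voxel_size
  if (is.null(min_length_um)) min_length_um <- 2 * spacing
  out <- list()
  for (id in label_ids(seeds)) {
    vox <- skeletonize(seeds, id)
    if (nrow(vox) == 0L) next
    mask <- seeds$data == id
    g <- skeleton_graph(vox)
    comp <- igraph::components(g)
    multi <- comp$no > 1L
    for (ci in seq_len(comp$no)) {
      sub <- vox[comp$membership == ci, , drop = FALSE]
      if (nrow(sub) < 2L) next
      path <- longest_path(sub, seeds$voxel_size)
      # thinning recedes from the mask tips by about the mask radius;
      # grow the path back along its end tangents while inside the mask
      path <- extend_path_ends(path, mask)
      pts <- (path - 0.5) * seeds$voxel_size
      seg <- sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                               pts[-nrow(pts), , drop = FALSE])^2)))
      if (seg < max(min_length_um, spacing)) next
      fid <- if (multi) sprintf("%d.%d", id, ci) else as.character(id)
      cl <- resample_centerline(path, spacing, voxel_size = seeds$voxel_size,
                                fiber_id = fid)
      cl <- smooth_centerline(cl)
      attr(cl, "parent") <- id
      out[[fid]] <- cl
    }
  }
  out
}

# Extend a voxel path at both ends along the local end tangent while the
# extension stays inside the given mask (compensates the tip recession of
# topological thinning; cannot jump gaps because growth stops at the first
# background voxel).
extend_path_ends <- function(path, mask, max_steps = 6L) {
  d <- dim(mask)
  grow <- function(p) {
    m <- nrow(p)
    if (m < 3L) return(p)
    ref <- p[max(1L, m - 6L), ]
    dirv <- p[m, ] - ref
    nn <- sqrt(sum(dirv^2))
    if (nn < 1e-9) return(p)
    dirv <- dirv / nn
    last <- p[m, ]
    prev <- last
    for (i in seq_len(max_steps)) {
      cand <- round(last + i * dirv)
      if (any(cand < 1L) || any(cand > d)) break
      if (!mask[cand[1], cand[2], cand[3]]) break
      if (all(cand == prev)) next
      p <- rbind(p, cand)
      prev <- cand
    }
    p
  }
  path <- grow(path)
  path <- grow(path[rev(seq_len(nrow(path))), , drop = FALSE])
  path[rev(seq_len(nrow(path))), , drop = FALSE]
}

#' Smooth a centerline with a centered moving average
#'
#' Voxel-path centerlines carry half-voxel staircase jitter that perturbs the
#' local tangents (and hence the spoke sampling planes). A short centered
#' moving average over the point coordinates removes the jitter while
#' preserving the fiber-scale geometry; the endpoints are kept fixed.
#'
#' @param centerline an \code{ft_centerline}.
#' @param window odd window length in points (default 5).
#' @return smoothed \code{ft_centerline}.
#' @export
smooth_centerline <- function(centerline, window = 5L) {
  pts <- centerline$points
  n <- nrow(pts)
  if (window < 3L || n < window) return(centerline)
  half <- window %/% 2L
  sm <- pts
  for (a in 1:3) {
    cs <- cumsum(c(0, pts[, a]))
    i <- (half + 1L):(n - half)
    sm[i, a] <- (cs[i + half + 1L] - cs[i - half]) / window
  }
  # taper near the ends with shrinking windows
  for (i in seq_len(half)) {
    w <- 2L * i - 1L
    if (i > 1L) {
      sm[i, ] <- colMeans(pts[(i - (i - 1L)):(i + (i - 1L)), , drop = FALSE])
      sm[n - i + 1L, ] <- colMeans(pts[(n - i + 1L - (i - 1L)):(n - i + 1L + (i - 1L)), ,
                                       drop = FALSE])
    }
  }
  out <- centerline
  out$points <- sm
  out
}

#' Serialize centerlines to CSV and back
#'
#' @param centerlines list of \code{ft_centerline}.
#' @param path CSV file path (columns fiber_id, index, x_um, y_um, z_um,
#'   spacing_um).
#' @return \code{read_centerlines}: a list of \code{ft_centerline}.
#' @export
write_centerlines <- function(centerlines, path) {
  rows <- do.call(rbind, lapply(centerlines, function(cl) {
    data.frame(fiber_id = as.character(cl$fiber_id),
               index = seq_len(nrow(cl$points)),
               x_um = cl$points[, 1], y_um = cl$points[, 2],
               z_um = cl$points[, 3], spacing_um = cl$spacing)
  }))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centerlines
#' @export
read_centerlines <- function(path) {
  tb <- read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (fid in unique(tb$fiber_id)) {
    sub <- tb[tb$fiber_id == fid, ]
    sub <- sub[order(sub$index), ]
    out[[as.character(fid)]] <- structure(
      list(points = as.matrix(sub[, c("x_um", "y_um", "z_um")]),
           spacing = sub$spacing_um[1], fiber_id = fid),
      class = "ft_centerline")
  }
  out
}
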