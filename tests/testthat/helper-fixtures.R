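# Shared fixtures, built in code at test time.

# blurred two-level cylinder volume along z, centered at (cx, cy) um
make_cylinder_volume <- function(dims = c(80L, 80L, 64L), voxel = 1.6,
                                 center = NULL, radius = 16, fg = 100,
                                 bg = 20, blur = 1.6) {
  if (is.null(center)) center <- dims[1:2] * voxel / 2
  xs <- (seq_len(dims[1]) - 0.5) * voxel
  ys <- (seq_len(dims[2]) - 0.5) * voxel
  d2 <- outer((xs - center[1])^2, (ys - center[2])^2, "+")
  vol <- array(bg, dims)
  for (k in seq_len(dims[3])) vol[, , k][d2 <= radius^2] <- fg
  v <- ft_volume(vol, voxel)
  if (blur > 0) v <- gaussian_blur(v, blur)
  v
}

straight_centerline <- function(n = 50, spacing = 1.6, origin = c(64, 64, 0.8),
                                dir = c(0, 0, 1)) {
  dir <- dir / sqrt(sum(dir^2))
  pts <- t(vapply(seq_len(n) - 1L, function(i) origin + i * spacing * dir,
                  numeric(3)))
  structure(list(points = pts, spacing = spacing, fiber_id = "t"),
            class = "ft_centerline")
}

# a small digital tube mask: voxels within `radius` voxels of the segment
# between two voxel-coordinate endpoints
digital_tube <- function(dims, from, to, radius) {
  mask <- array(FALSE, dims)
  idx <- which(array(TRUE, dims), arr.ind = TRUE)
  a <- from; b <- to
  ab <- b - a
  len2 <- sum(ab^2)
  t <- pmin(pmax(((idx[, 1] - a[1]) * ab[1] + (idx[, 2] - a[2]) * ab[2] +
                  (idx[, 3] - a[3]) * ab[3]) / len2, 0), 1)
  px <- a[1] + t * ab[1]; py <- a[2] + t * ab[2]; pz <- a[3] + t * ab[3]
  d2 <- (idx[, 1] - px)^2 + (idx[, 2] - py)^2 + (idx[, 3] - pz)^2
  mask[idx[d2 <= radius^2, , drop = FALSE]] <- TRUE
  mask
}

# exhaustive enumeration oracle for the optimal smooth surface: DFS over
# columns in slice-major order with constraint pruning (circular spoke
# bound, slice bound). Returns the minimal total cost and the number of
# feasible configurations visited.
brute_force_surface <- function(cost, delta_spoke, delta_slice, r_min) {
  d <- dim(cost)
  ns <- d[1]; nk <- d[2]; nr <- d[3]
  # shift costs to be nonnegative so partial sums can prune safely; the
  # shift adds the same constant to every complete configuration
  shift <- min(cost)
  cost <- cost - shift
  levels <- r_min:nr
  best <- Inf
  count <- 0
  assign_mat <- matrix(NA_integer_, ns, nk)
  best_assign <- NULL
  rec <- function(pos, acc) {
    if (acc >= best) return()   # prune on partial cost (all costs finite)
    if (pos > ns * nk) {
      count <<- count + 1
      if (acc < best) {
        best <<- acc
        best_assign <<- assign_mat
      }
      return()
    }
    s <- ((pos - 1L) %% ns) + 1L
    k <- ((pos - 1L) %/% ns) + 1L
    for (j in levels) {
      if (k > 1L && abs(j - assign_mat[s, k - 1L]) > delta_spoke) next
      if (k == nk && abs(j - assign_mat[s, 1L]) > delta_spoke) next
      if (s > 1L && !is.na(assign_mat[s - 1L, k]) &&
          abs(j - assign_mat[s - 1L, k]) > delta_slice) next
      assign_mat[s, k] <<- j
      rec(pos + 1L, acc + cost[s, k, j])
      assign_mat[s, k] <<- NA_integer_
    }
  }
  rec(1L, 0)
  list(best = best + shift * ns * nk, count = count, assign = best_assign)
}

surface_cost_of <- function(cost, level) {
  d <- dim(cost)
  sum(cost[cbind(rep(seq_len(d[1]), times = d[2]),
                 rep(seq_len(d[2]), each = d[1]),
                 as.vector(level))])
}

# exhaustive weighted longest simple path on a voxel skeleton
brute_force_longest <- function(vox, voxel_size = 1) {
  vox <- matrix(as.integer(vox), ncol = 3)
  n <- nrow(vox)
  adj <- vector("list", n)
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dd <- vox[i, ] - vox[j, ]
      if (max(abs(dd)) <= 1) {
        adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
        w[i, j] <- w[j, i] <- sqrt(sum(dd^2)) * voxel_size
      }
    }
  }
  best <- 0
  visited <- rep(FALSE, n)
  dfs <- function(v, len) {
    if (len > best) best <<- len
    visited[v] <<- TRUE
    for (u in adj[[v]]) if (!visited[u]) dfs(u, len + w[v, u])
    visited[v] <<- FALSE
  }
  for (v in seq_len(n)) dfs(v, 0)
  best
}

tiny_phantom_spec <- function(seed = 7, noise = 0, ...) {
  phantom_spec(grid_shape = c(64, 64, 48), voxel_size = 1.6, n_fibers = 3,
               diameter_um = c(24, 3), sinuosity = c(1.03, 0.02),
               eccentricity_target = 0.4, packing_pct = 25,
               noise_sigma = noise, seed = seed, ...)
}
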