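#' Fiber length and sinuosity from a centerline
#'
#' The fiber length \code{d} is the summed Euclidean distance between
#' consecutive centerline points. Sinuosity \code{s} is the ratio of \code{d}
#' to the straight-line distance between the first and last point; it lies in
#' \code{[1, Inf)}, where 1 is a perfectly straight fiber. A closed loop
#' (coincident endpoints) has undefined sinuosity and returns \code{Inf} with
#' a warning so such fibers can be reported separately.
#'
#' @param centerline an \code{ft_centerline} (or an N x 3 point matrix).
#' @return length in micrometers / dimensionless sinuosity.
#' @examples
#' cl <- resample_centerline(rbind(c(0, 0, 0), c(3, 4, 0)), spacing = 1)
#' fiber_length(cl)  # 5
#' sinuosity(cl)     # 1
#' @export
fiber_length <- function(centerline) {
  pts <- centerline_points(centerline)
  if (nrow(pts) < 2L) stop("need at least 2 points")
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

#' @rdname fiber_length
#' @export
sinuosity <- function(centerline) {
  pts <- centerline_points(centerline)
  d <- fiber_length(centerline)
  chord <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
  if (chord == 0) {
    warning("closed loop: start equals end, sinuosity undefined (Inf)")
    return(Inf)
  }
  max(d / chord, 1)
}

centerline_points <- function(x) {
  if (inherits(x, "ft_centerline")) x$points
  else matrix(as.numeric(x), ncol = 3L)
}

#' Equivalent circle diameter and ellipse eccentricity
#'
#' \code{equivalent_diameter(A)} is the diameter of the circle with the same
#' area as the fitted cross-sectional ellipse, \code{2 * sqrt(A / pi)}, a
#' proxy for the local fiber thickness. \code{eccentricity(a, b)} is
#' \code{sqrt(1 - b^2 / a^2)} of the fitted ellipse with semi-axes
#' \code{a >= b}: 0 is perfectly circular, values approaching 1 are
#' line-like.
#'
#' @param A ellipse area in square micrometers (> 0).
#' @param a,b semi-major and semi-minor axes (a >= b > 0).
#' @export
equivalent_diameter <- function(A) {
  if (any(A <= 0)) stop("area must be positive")
  2 * sqrt(A / pi)
}

#' @rdname equivalent_diameter
#' @export
eccentricity <- function(a, b) {
  if (any(b <= 0) || any(a < b)) stop("need a >= b > 0")
  sqrt(pmax(0, 1 - b^2 / a^2))
}

#' Direct least-squares ellipse fit
#'
#' Fits a conic constrained to be an ellipse to 2D boundary points using the
#' numerically stable partitioned formulation of the direct least-squares
#' method, and converts it to center, semi-axes (a >= b) and orientation.
#' When the constrained fit is degenerate (e.g. nearly collinear points), a
#' second-moment ellipse is used instead and flagged in the \code{method}
#' field (with a warning).
#'
#' @param boundary n x 2 matrix of boundary points (n >= 6, non-collinear).
#' @return list with \code{a}, \code{b}, \code{center}, \code{angle}
#'   (radians), \code{method} ("direct" or "moments").
#' @export
fit_ellipse <- function(boundary) {
  P <- unique(matrix(as.numeric(boundary), ncol = 2L))
  if (nrow(P) < 6L) stop("need at least 6 distinct boundary points")
  mu <- colMeans(P)
  sc <- max(apply(P, 2L, function(v) diff(range(v))), .Machine$double.eps)
  X <- sweep(P, 2L, mu) / sc
  if (abs(cor(X[, 1], X[, 2])) > 1 - 1e-12 || any(apply(X, 2, sd) < 1e-12))
    stop("boundary points are collinear")
  fit <- tryCatch(direct_ellipse(X), error = function(e) NULL)
  method <- "direct"
  if (is.null(fit)) {
    warning("direct ellipse fit degenerate; falling back to second moments")
    fit <- moment_ellipse(X)
    method <- "moments"
  }
  list(a = fit$a * sc, b = fit$b * sc,
       center = fit$center * sc + mu,
       angle = fit$angle, method = method)
}

direct_ellipse <- function(X) {
  x <- X[, 1]; y <- X[, 2]
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T_ <- -solve(S3, t(S2))
  M <- S1 + S2 %*% T_
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 1e-12)
  if (length(ok) == 0L) stop("no elliptical solution")
  a1 <- V[, ok[1]]
  par <- c(a1, as.vector(T_ %*% a1))   # A B C D E F
  conic_to_ellipse(par)
}

conic_to_ellipse <- function(p) {
  A <- p[1]; B <- p[2]; C <- p[3]; D <- p[4]; E <- p[5]; F <- p[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) stop("conic is not an ellipse")
  x0 <- (2 * C * D - B * E) / den
  y0 <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 + F * B^2 - B * D * E - 4 * A * C * F)
  s <- sqrt((A - C)^2 + B^2)
  ax1 <- -sqrt(num * (A + C + s)) / den
  ax2 <- -sqrt(num * (A + C - s)) / den
  if (!is.finite(ax1) || !is.finite(ax2) || ax1 <= 0 || ax2 <= 0)
    stop("degenerate ellipse")
  a <- max(ax1, ax2); b <- min(ax1, ax2)
  ang <- if (abs(B) < 1e-14 && A <= C) 0
         else if (abs(B) < 1e-14) pi / 2
         else atan2(C - A - s, B)
  if (ax1 < ax2) ang <- ang + pi / 2
  list(a = a, b = b, center = c(x0, y0), angle = ang %% pi)
}

moment_ellipse <- function(X) {
  mu <- colMeans(X)
  S <- stats::cov(X) * (nrow(X) - 1) / nrow(X)
  ev <- eigen(S, symmetric = TRUE)
  # for points uniformly distributed on an ellipse boundary, the second
  # moments are (a^2/2, b^2/2)
  ax <- sqrt(pmax(2 * ev$values, .Machine$double.eps))
  list(a = ax[1], b = ax[2], center = mu,
       angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1]) %% pi)
}

#' Extract orthogonal cross-sections along a fiber
#'
#' Samples the segmentation label volume on planes orthogonal to the local
#' fiber direction, at arc positions spaced \code{spacing} micrometers apart
#' (\code{floor(d / spacing) + 1} sections for a fiber of length d). Each
#' section is a 2D binary mask whose largest connected component's outer
#' boundary is fitted with an ellipse, yielding semi-axes a >= b, ellipse
#' area \code{A = pi * a * b}, equivalent diameter and eccentricity. Empty
#' sections (e.g. across the gap of a broken fiber) are recorded as missing
#' rather than fabricated.
#'
#' @param labels segmentation \code{ft_labels}.
#' @param label integer label of this fiber in \code{labels}.
#' @param centerline refined \code{ft_centerline}.
#' @param frames matching \code{ft_frames} (computed if NULL).
#' @param spacing arc-length distance between sections, micrometers
#'   (default 9.2).
#' @param half_width half-extent of the sampling plane in micrometers
#'   (defaults to 1.2 x the largest detected radius if a surface is given,
#'   else 70).
#' @param surface optional \code{ft_surface} used only to choose
#'   \code{half_width}.
#' @param fiber_id id string carried into the output.
#' @return list of cross-section records: \code{arc_position}, \code{a},
#'   \code{b}, \code{area}, \code{diameter}, \code{eccentricity},
#'   \code{n_pixels}, \code{xyz} (mask pixel coordinates, um), \code{empty},
#'   \code{method}.
#' @export
extract_cross_sections <- function(labels, label, centerline, frames = NULL,
                                   spacing = 9.2, half_width = NULL,
                                   surface = NULL, fiber_id = NA) {
  stopifnot(inherits(labels, "ft_labels"))
  if (spacing <= 0) stop("spacing must be > 0")
  if (is.null(frames)) frames <- fibertube::frames(centerline)
  if (is.null(half_width)) {
    half_width <- if (!is.null(surface)) 1.2 * max(surface$radius) + 2 * labels$voxel_size else 70
  }
  pts <- centerline$points
  n <- nrow(pts)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  d <- arc[n]
  positions <- seq(0, d, by = spacing)
  step <- labels$voxel_size
  offs <- seq(-half_width, half_width, by = step)
  m <- length(offs)
  uu <- rep(offs, times = m)
  ww <- rep(offs, each = m)
  out <- vector("list", length(positions))
  for (si in seq_along(positions)) {
    i <- which.min(abs(arc - positions[si]))
    p <- pts[i, ]; nrm <- frames$normal[i, ]; bin <- frames$binormal[i, ]
    coords <- cbind(p[1] + uu * nrm[1] + ww * bin[1],
                    p[2] + uu * nrm[2] + ww * bin[2],
                    p[3] + uu * nrm[3] + ww * bin[3])
    vi <- round(coords / step + 0.5)
    dlab <- dim(labels$data)
    ok <- vi[, 1] >= 1 & vi[, 1] <= dlab[1] &
          vi[, 2] >= 1 & vi[, 2] <= dlab[2] &
          vi[, 3] >= 1 & vi[, 3] <= dlab[3]
    val <- integer(m * m)
    val[ok] <- labels$data[vi[ok, , drop = FALSE]]
    mask <- matrix(val == label, m, m)
    rec <- list(fiber_id = fiber_id, arc_position = positions[si],
                a = NA_real_, b = NA_real_, area = NA_real_,
                diameter = NA_real_, eccentricity = NA_real_,
                n_pixels = sum(mask), xyz = NULL, empty = !any(mask),
                method = NA_character_)
    if (any(mask)) {
      cc <- label_components(mask, connectivity = 26)
      tb <- tabulate(cc[cc > 0])
      mask <- cc == which.max(tb)
      bnd <- boundary_pixels(mask)
      rec$n_pixels <- sum(mask)
      rec$xyz <- coords[as.vector(mask), , drop = FALSE]
      if (nrow(bnd) >= 6L) {
        bp <- cbind(uu[bnd[, 1] + (bnd[, 2] - 1) * m],
                    ww[bnd[, 1] + (bnd[, 2] - 1) * m])
        # boundary pixel centers lie about half a pixel inside the true
        # boundary; push them outward radially to remove the size bias
        ctr <- colMeans(bp)
        rad <- sweep(bp, 2L, ctr)
        rn <- sqrt(rowSums(rad^2))
        rn[rn < 1e-9] <- 1
        bp <- bp + 0.5 * step * rad / rn
        fit <- tryCatch(fit_ellipse(bp), error = function(e) NULL)
        if (!is.null(fit)) {
          rec$a <- fit$a; rec$b <- fit$b
          rec$area <- pi * fit$a * fit$b
          rec$diameter <- equivalent_diameter(rec$area)
          rec$eccentricity <- eccentricity(fit$a, fit$b)
          rec$method <- fit$method
        }
      }
    }
    out[[si]] <- rec
  }
  out
}

# outer boundary pixels: foreground with a 4-neighbour background (or image
# border); returns array indices
boundary_pixels <- function(mask) {
  d <- dim(mask)
  pad <- matrix(FALSE, d[1] + 2L, d[2] + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- mask
  inner <- pad[2:(d[1] + 1L), 2:(d[2] + 1L)]
  nb4 <- pad[1:d[1], 2:(d[2] + 1L)] & pad[3:(d[1] + 2L), 2:(d[2] + 1L)] &
         pad[2:(d[1] + 1L), 1:d[2]] & pad[2:(d[1] + 1L), 3:(d[2] + 2L)]
  which(inner & !nb4, arr.ind = TRUE)
}

#' Field-of-view cylinder filter for cross-sections
#'
#' Restricts morphometry to the cylindrical subvolume that is fully
#' illuminated: a cross-section is discarded when any pixel of its binary
#' mask lies outside the cylinder in-plane or touches the top or bottom
#' slice of the volume.
#'
#' @param sections list of cross-section records
#'   (\code{\link{extract_cross_sections}}).
#' @param cylinder list with \code{center} (x, y in micrometers),
#'   \code{radius} (micrometers), \code{zlim} (length 2, micrometers).
#' @return the sections with an added logical \code{kept}.
#' @export
fov_filter <- function(sections, cylinder) {
  lapply(sections, function(rec) {
    if (is.null(rec$xyz) || rec$empty) {
      rec$kept <- FALSE
      return(rec)
    }
    dx <- rec$xyz[, 1] - cylinder$center[1]
    dy <- rec$xyz[, 2] - cylinder$center[2]
    inside <- all(dx^2 + dy^2 <= cylinder$radius^2) &&
      all(rec$xyz[, 3] > cylinder$zlim[1]) &&
      all(rec$xyz[, 3] < cylinder$zlim[2])
    rec$kept <- inside
    rec
  })
}

#' Default field-of-view cylinder for a volume
#'
#' The largest circle inscribed in the x-y extent, spanning z except the
#' first and last slice.
#'
#' @param v an \code{ft_volume} or \code{ft_labels}.
#' @return cylinder list for \code{\link{fov_filter}}.
#' @export
fov_cylinder <- function(v) {
  ext <- dim(v$data) * v$voxel_size
  list(center = ext[1:2] / 2, radius = min(ext[1:2]) / 2,
       zlim = c(v$voxel_size, ext[3] - v$voxel_size))
}

#' Unfolded longitudinal cross-section image
#'
#' Samples image intensities in a narrow band that follows the fiber
#' centerline: rows are arc positions along the fiber, columns are signed
#' in-plane offsets along the frame direction at the given azimuth. This
#' "virtually unfolds" a curved fiber into a flat longitudinal section.
#'
#' @param v \code{ft_volume}.
#' @param centerline \code{ft_centerline}.
#' @param frames matching \code{ft_frames} (computed if NULL).
#' @param width band width in micrometers (default 120).
#' @param azimuth direction of the band in the cross-sectional plane,
#'   degrees from the frame normal (default 0).
#' @param step sample step across the band, micrometers (default voxel size).
#' @return numeric matrix (centerline points x offsets); attribute
#'   \code{offsets_um} holds the column offsets.
#' @export
unfold_longitudinal <- function(v, centerline, frames = NULL, width = 120,
                                azimuth = 0, step = v$voxel_size) {
  if (width <= 0) stop("width must be > 0")
  if (is.null(frames)) frames <- fibertube::frames(centerline)
  pts <- centerline$points
  n <- nrow(pts)
  az <- azimuth * pi / 180
  dirs <- cos(az) * frames$normal + sin(az) * frames$binormal
  offs <- seq(-width / 2, width / 2, by = step)
  m <- length(offs)
  coords <- matrix(0, n * m, 3)
  for (a in 1:3) {
    coords[, a] <- rep(pts[, a], times = m) +
      rep(dirs[, a], times = m) * rep(offs, each = n)
  }
  vals <- trilinear_sample(v, coords)
  if (all(is.na(vals))) stop("centerline lies outside the volume")
  img <- matrix(vals, n, m)
  attr(img, "offsets_um") <- offs
  img
}

#' Full morphometry of a segmented sample
#'
#' Computes per-fiber length and sinuosity and per-cross-section ellipse
#' metrics for every segmented fiber, applies the field-of-view filter, and
#' assembles tidy tables.
#'
#' @param seg result of \code{\link{segment_fibers}}.
#' @param spacing cross-section spacing in micrometers (default 9.2).
#' @param cylinder FOV cylinder (default \code{\link{fov_cylinder}} of the
#'   label volume); pass \code{NA} to skip filtering.
#' @return list with data frames \code{per_fiber} (fiber_id, length_um,
#'   sinuosity, n_sections, n_sections_kept) and \code{per_section}
#'   (fiber_id, arc_position_um, a_um, b_um, area_um2, diameter_um,
#'   eccentricity, kept).
#' @export
fiber_morphometry <- function(seg, spacing = 9.2, cylinder = NULL) {
  labels <- seg$labels
  if (is.null(cylinder)) cylinder <- fov_cylinder(labels)
  fibs <- names(seg$segments)
  pf <- list(); ps <- list()
  for (k in seq_along(fibs)) {
    fid <- fibs[k]
    s <- seg$segments[[fid]]
    d <- fiber_length(s$centerline)
    sin_ <- sinuosity(s$centerline)
    secs <- extract_cross_sections(labels, k, s$centerline, s$frames,
                                   spacing = spacing, surface = s$surface,
                                   fiber_id = fid)
    if (is.list(cylinder)) secs <- fov_filter(secs, cylinder)
    else secs <- lapply(secs, function(r) { r$kept <- !r$empty; r })
    ps[[fid]] <- data.frame(
      fiber_id = fid,
      arc_position_um = vapply(secs, `[[`, 0, "arc_position"),
      a_um = vapply(secs, `[[`, 0, "a"),
      b_um = vapply(secs, `[[`, 0, "b"),
      area_um2 = vapply(secs, `[[`, 0, "area"),
      diameter_um = vapply(secs, `[[`, 0, "diameter"),
      eccentricity = vapply(secs, `[[`, 0, "eccentricity"),
      kept = vapply(secs, `[[`, TRUE, "kept"))
    pf[[fid]] <- data.frame(
      fiber_id = fid, length_um = d, sinuosity = sin_,
      n_sections = length(secs),
      n_sections_kept = sum(vapply(secs, `[[`, TRUE, "kept") &
                            !is.na(vapply(secs, `[[`, 0, "diameter"))))
  }
  list(per_fiber = do.call(rbind, pf), per_section = do.call(rbind, ps))
}
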