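#' Create a 3D volume with physical voxel size
#'
#' Containers for scalar image volumes and integer label volumes. Both carry
#' an isotropic voxel size in micrometers. The voxel with (1-based) array
#' index \code{(i, j, k)} has its physical center at
#' \code{(i - 0.5, j - 0.5, k - 0.5) * voxel_size} micrometers; all modules
#' share this convention.
#'
#' @param data 3D numeric array (grayscale) or integer array (labels).
#' @param voxel_size isotropic voxel edge length in micrometers (> 0).
#' @param origin physical offset in micrometers (length 3), default zero.
#' @return An object of class \code{ft_volume} (or \code{ft_labels}): a list
#'   with elements \code{data}, \code{voxel_size}, \code{origin}.
#' @examples
#' v <- ft_volume(array(runif(8^3), c(8, 8, 8)), voxel_size = 1.32)
#' dim(v$data)
#' @export
ft_volume <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || !is.finite(voxel_size) ||
      voxel_size <= 0)
    stop("voxel_size must be a single positive number (micrometers)")
  if (any(dim(data) < 1L)) stop("grid must be non-empty")
  structure(list(data = data, voxel_size = voxel_size, origin = as.numeric(origin)),
            class = "ft_volume")
}

#' @rdname ft_volume
#' @export
ft_labels <- function(data, voxel_size, origin = c(0, 0, 0)) {
  if (any(data < 0, na.rm = TRUE)) stop("labels must be non-negative")
  storage.mode(data) <- "integer"
  v <- ft_volume(data, voxel_size, origin)
  class(v) <- c("ft_labels", "ft_volume")
  v
}

#' @export
print.ft_volume <- function(x, ...) {
  kind <- if (inherits(x, "ft_labels")) "label volume" else "volume"
  cat(sprintf("<ft_%s> %s voxels, %.4g um/voxel", kind,
              paste(dim(x$data), collapse = " x "), x$voxel_size))
  if (inherits(x, "ft_labels")) {
    ids <- label_ids(x)
    cat(sprintf(", %d labels", length(ids)))
  } else {
    cat(sprintf(", range [%.4g, %.4g]", min(x$data), max(x$data)))
  }
  cat("\n")
  invisible(x)
}

#' @rdname ft_volume
#' @param labels an \code{ft_labels} object.
#' @export
label_ids <- function(labels) {
  stopifnot(inherits(labels, "ft_labels"))
  ids <- sort(unique(as.integer(labels$data)))
  ids[ids > 0L]
}

#' Trilinear interpolation of a volume at physical coordinates
#'
#' Values are interpolated between the 8 surrounding voxel centers.
#' Coordinates closer than half a voxel to the grid faces are outside the
#' convex hull of voxel centers; with \code{clamp = TRUE} they are clamped to
#' the nearest center (nearest extrapolation), otherwise they yield \code{NA}.
#'
#' @param v an \code{ft_volume}.
#' @param coords n x 3 matrix of physical coordinates in micrometers.
#' @param clamp clamp out-of-range coordinates instead of returning NA.
#' @return numeric vector of length n.
#' @export
trilinear_sample <- function(v, coords, clamp = FALSE) {
  stopifnot(inherits(v, "ft_volume"))
  coords <- matrix(as.numeric(coords), ncol = 3L)
  d <- dim(v$data)
  # continuous 1-based voxel index: centre of voxel i at (i - 0.5) * vs
  g <- sweep(coords, 2L, v$origin, "-") / v$voxel_size + 0.5
  if (clamp) {
    for (a in 1:3) g[, a] <- pmin(pmax(g[, a], 1), d[a])
  }
  ok <- g[, 1] >= 1 & g[, 1] <= d[1] &
        g[, 2] >= 1 & g[, 2] <= d[2] &
        g[, 3] >= 1 & g[, 3] <= d[3]
  ok[is.na(ok)] <- FALSE
  out <- rep(NA_real_, nrow(coords))
  if (!any(ok)) return(out)
  g <- g[ok, , drop = FALSE]
  f0 <- pmin(floor(g), matrix(rep(d - 1L, each = nrow(g)), ncol = 3L))
  f0 <- pmax(f0, 1)
  fr <- g - f0
  i0 <- f0[, 1]; j0 <- f0[, 2]; k0 <- f0[, 3]
  fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
  lin <- function(i, j, k) i + d[1] * (j - 1) + d[1] * d[2] * (k - 1)
  dat <- v$data
  val <-
    dat[lin(i0,     j0,     k0)]     * (1 - fx) * (1 - fy) * (1 - fz) +
    dat[lin(i0 + 1, j0,     k0)]     * fx       * (1 - fy) * (1 - fz) +
    dat[lin(i0,     j0 + 1, k0)]     * (1 - fx) * fy       * (1 - fz) +
    dat[lin(i0 + 1, j0 + 1, k0)]     * fx       * fy       * (1 - fz) +
    dat[lin(i0,     j0,     k0 + 1)] * (1 - fx) * (1 - fy) * fz +
    dat[lin(i0 + 1, j0,     k0 + 1)] * fx       * (1 - fy) * fz +
    dat[lin(i0,     j0 + 1, k0 + 1)] * (1 - fx) * fy       * fz +
    dat[lin(i0 + 1, j0 + 1, k0 + 1)] * fx       * fy       * fz
  out[ok] <- val
  out
}

#' Downsample a volume by an integer factor with trilinear interpolation
#'
#' The output grid has \code{ceiling(dim / factor)} voxels per axis and voxel
#' size multiplied by \code{factor}. Values are trilinear interpolants of the
#' input at the new voxel centers (clamped at the half-voxel borders).
#'
#' @param v an \code{ft_volume}.
#' @param factor integer >= 1.
#' @return a new \code{ft_volume}.
#' @export
downsample <- function(v, factor) {
  stopifnot(inherits(v, "ft_volume"))
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor))
    stop("factor must be an integer >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(v)
  d <- dim(v$data)
  nd <- as.integer(ceiling(d / factor))
  nvs <- v$voxel_size * factor
  cx <- (seq_len(nd[1]) - 0.5) * nvs
  cy <- (seq_len(nd[2]) - 0.5) * nvs
  cz <- (seq_len(nd[3]) - 0.5) * nvs
  coords <- cbind(rep(cx, times = nd[2] * nd[3]),
                  rep(rep(cy, each = nd[1]), times = nd[3]),
                  rep(cz, each = nd[1] * nd[2]))
  vals <- trilinear_sample(v, sweep(coords, 2L, v$origin, "+"), clamp = TRUE)
  ft_volume(array(vals, nd), nvs, v$origin)
}

#' Separable 3D Gaussian blur
#'
#' Convolves the volume with an isotropic Gaussian of standard deviation
#' \code{sigma_um} (micrometers), applied separably along the three axes.
#' The kernel is truncated at 3 sigma and renormalized at the borders
#' (equivalent to edge replication in the mean).
#'
#' @param v an \code{ft_volume}.
#' @param sigma_um Gaussian standard deviation in micrometers; 0 is identity.
#' @return blurred \code{ft_volume}.
#' @export
gaussian_blur <- function(v, sigma_um) {
  stopifnot(inherits(v, "ft_volume"))
  if (sigma_um < 0) stop("sigma must be >= 0")
  if (sigma_um == 0) return(v)
  s <- sigma_um / v$voxel_size
  half <- max(1L, as.integer(ceiling(3 * s)))
  kern <- exp(-0.5 * ((-half):half / s)^2)
  kern <- kern / sum(kern)
  dat <- v$data
  d <- dim(dat)
  conv_axis1 <- function(m, dlen) {
    # band matrix multiply, rows renormalized at the borders
    K <- matrix(0, dlen, dlen)
    for (o in -half:half) {
      idx <- seq_len(dlen)
      tgt <- idx + o
      keep <- tgt >= 1 & tgt <= dlen
      K[cbind(idx[keep], tgt[keep])] <- K[cbind(idx[keep], tgt[keep])] + kern[o + half + 1]
    }
    K <- K / rowSums(K)
    K %*% m
  }
  # axis 1
  dat <- array(conv_axis1(matrix(dat, d[1]), d[1]), d)
  # axis 2
  dat <- aperm(dat, c(2, 1, 3))
  dat <- array(conv_axis1(matrix(dat, d[2]), d[2]), c(d[2], d[1], d[3]))
  dat <- aperm(dat, c(2, 1, 3))
  # axis 3
  dat <- aperm(dat, c(3, 1, 2))
  dat <- array(conv_axis1(matrix(dat, d[3]), d[3]), c(d[3], d[1], d[2]))
  dat <- aperm(dat, c(2, 3, 1))
  ft_volume(dat, v$voxel_size, v$origin)
}

#' Label connected components of a binary mask
#'
#' @param mask logical 3D array (a 2D matrix is treated as a single slice).
#' @param connectivity 6 (face) or 26 (face/edge/vertex); for 2D input these
#'   correspond to 4- and 8-connectivity.
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  if (length(d) == 2L) d <- c(d, 1L)
  if (length(d) != 3L) stop("mask must be 2D or 3D")
  lab <- .cc_label_cpp(as.logical(mask), as.integer(d), as.integer(connectivity))
  if (length(dim(mask)) == 2L) dim(lab) <- dim(mask)
  lab
}
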