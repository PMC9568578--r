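#' Read and write image volumes (NRRD, multi-page TIFF)
#'
#' NRRD files (raw encoding, little endian, float64 for grayscale, int32 for
#' labels) carry the voxel size in the header and round-trip bit-exactly.
#' Multi-page TIFF stacks are stored as 16-bit grayscale scaled to the data
#' range recorded in a sidecar-free convention: values are written as
#' \code{data / scale} with \code{scale = max(abs(data))}; exact round-trips
#' therefore require 16-bit-quantized data. TIFF carries no voxel-size
#' metadata, so \code{voxel_size} must be supplied when reading TIFF.
#'
#' @param path file path (.nrrd or .tif/.tiff).
#' @param format "nrrd" or "tiff"; inferred from the extension when NULL.
#' @param voxel_size voxel size in micrometers; required for TIFF, optional
#'   override for NRRD.
#' @param labels read/write as integer label volume.
#' @return \code{read_volume}: an \code{ft_volume} (or \code{ft_labels}).
#' @export
read_volume <- function(path, format = NULL, voxel_size = NULL, labels = FALSE) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  format <- infer_format(path, format)
  if (format == "nrrd") {
    vol <- read_nrrd(path)
    if (!is.null(voxel_size)) vol$voxel_size <- voxel_size
    if (is.na(vol$voxel_size))
      stop("NRRD header has no spacing; supply voxel_size explicitly")
  } else {
    if (is.null(voxel_size))
      stop("TIFF stacks carry no voxel-size metadata; supply voxel_size ",
           "(micrometers) from the acquisition or the run config")
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- c(dim(pages[[1]])[1:2], length(pages))
    dat <- array(0, d)
    for (k in seq_along(pages)) dat[, , k] <- pages[[k]][, , drop = TRUE]
    sc <- attr_scale_from_path(path)
    vol <- ft_volume(dat * sc, voxel_size)
  }
  if (labels) {
    vol$data <- array(as.integer(round(vol$data)), dim(vol$data))
    vol <- ft_labels(vol$data, vol$voxel_size, vol$origin)
  }
  vol
}

#' @rdname read_volume
#' @param v an \code{ft_volume} to write.
#' @export
write_volume <- function(v, path, format = NULL) {
  stopifnot(inherits(v, "ft_volume"))
  format <- infer_format(path, format)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (format == "nrrd") {
    write_nrrd(v, path)
  } else {
    sc <- max(abs(v$data), 1e-12)
    if (sc <= 1) sc <- 1   # data already in [0, 1]: quantize without rescaling
    d <- dim(v$data)
    pages <- lapply(seq_len(d[3]), function(k) pmin(pmax(v$data[, , k] / sc, 0), 1))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
    writeLines(sprintf("%.17g", sc), paste0(path, ".scale"))
  }
  invisible(path)
}

infer_format <- function(path, format) {
  if (!is.null(format)) {
    format <- match.arg(tolower(format), c("nrrd", "tiff", "tif"))
    return(if (format == "tif") "tiff" else format)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "nrrd") return("nrrd")
  if (ext %in% c("tif", "tiff")) return("tiff")
  stop("cannot infer format from extension: ", path)
}

attr_scale_from_path <- function(path) {
  sidecar <- paste0(path, ".scale")
  if (file.exists(sidecar)) as.numeric(readLines(sidecar, n = 1L)) else 1
}

# Minimal NRRD (format revision 4) reader/writer: raw encoding, little
# endian, 3D, types double/int32/uint8/int16/uint16.
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000[1-5]$", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1]]
    fields[[tolower(trimws(kv[1]))]] <- trimws(kv[2])
  }
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != 3L) stop("only 3D NRRD volumes are supported")
  type <- fields[["type"]]
  if (!is.null(fields[["encoding"]]) && fields[["encoding"]] != "raw")
    stop("only raw NRRD encoding is supported")
  spacing <- NA_real_
  if (!is.null(fields[["spacings"]])) {
    sp <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
    if (max(sp) - min(sp) > 1e-9 * max(sp))
      stop("anisotropic voxels are not supported (spacings: ",
           fields[["spacings"]], ")")
    spacing <- sp[1]
  } else if (!is.null(fields[["space directions"]])) {
    m <- regmatches(fields[["space directions"]],
                    gregexpr("[-0-9.eE+]+", fields[["space directions"]]))[[1]]
    m <- matrix(as.numeric(m), nrow = 3L)
    sp <- sqrt(colSums(m^2))
    if (max(sp) - min(sp) > 1e-9 * max(sp))
      stop("anisotropic voxels are not supported")
    spacing <- sp[1]
  }
  n <- prod(sizes)
  dat <- switch(type,
    "double" = readBin(con, "double", n, size = 8L, endian = "little"),
    "float"  = readBin(con, "double", n, size = 4L, endian = "little"),
    "int" = , "int32" = readBin(con, "integer", n, size = 4L, endian = "little"),
    "short" = , "int16" = readBin(con, "integer", n, size = 2L, endian = "little"),
    "ushort" = , "uint16" = readBin(con, "integer", n, size = 2L, signed = FALSE,
                                    endian = "little"),
    "uchar" = , "uint8" = readBin(con, "integer", n, size = 1L, signed = FALSE,
                                  endian = "little"),
    stop("unsupported NRRD type: ", type))
  if (length(dat) != n) stop("truncated NRRD data in ", path)
  ft_volume(array(dat, sizes), spacing)
}

write_nrrd <- function(v, path) {
  int_data <- inherits(v, "ft_labels")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           sprintf("type: %s", if (int_data) "int32" else "double"),
           "dimension: 3",
           sprintf("sizes: %s", paste(dim(v$data), collapse = " ")),
           sprintf("spacings: %.10g %.10g %.10g", v$voxel_size, v$voxel_size,
                   v$voxel_size),
           "endian: little",
           "encoding: raw",
           "")
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  if (int_data) {
    writeBin(as.integer(v$data), con, size = 4L, endian = "little")
  } else {
    writeBin(as.numeric(v$data), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Write per-fiber and per-cross-section tables plus a JSON summary
#'
#' Writes \code{per_fiber.csv} (fiber_id, length_um, sinuosity,
#' n_sections_kept, ...), \code{per_section.csv} (fiber_id, arc_position_um,
#' a_um, b_um, area_um2, diameter_um, eccentricity, kept) and
#' \code{summary.json} (fiber count, total length in mm, median/IQR of
#' sinuosity, diameter and eccentricity, volume fraction).
#'
#' @param per_fiber per-fiber morphometry data frame.
#' @param per_section per-cross-section data frame.
#' @param summary summary list (see \code{\link{group_summary}}).
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_tables <- function(per_fiber, per_section, summary, dir) {
  if (is.null(per_fiber) || nrow(per_fiber) == 0L)
    stop("per-fiber table is empty; nothing to write")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fiber = file.path(dir, "per_fiber.csv"),
             section = file.path(dir, "per_section.csv"),
             summary = file.path(dir, "summary.json"))
  write.csv(per_fiber, paths[["fiber"]], row.names = FALSE)
  if (!is.null(per_section) && nrow(per_section) > 0L)
    write.csv(per_section, paths[["section"]], row.names = FALSE)
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
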