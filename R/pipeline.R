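#' Default run configuration
#'
#' The defaults reproduce the reference processing of a 1.32 um (after
#' factor-4 trilinear downsampling) acquisition: centerline sectioning
#' distance 1.32 um (equal to the voxel size), 60 spokes at 6 degrees
#' reaching 140 um with 3.2 um radial sampling, cross-sections every 9.2 um.
#' Every field can be overridden; \code{\link{validate_config}} checks
#' consistency and fills defaults.
#'
#' @param ... named overrides of the default fields.
#' @return validated config list (class \code{ft_config}).
#' @export
default_config <- function(...) {
  validate_config(list(...))
}

#' @rdname default_config
#' @param config a (partial) configuration list.
#' @export
validate_config <- function(config = list()) {
  defaults <- list(
    input = NULL,              # path to grayscale volume, or NULL (phantom)
    labels = NULL,             # path to seed label volume
    voxel_size = NULL,         # um; required for TIFF input
    phantom = NULL,            # ft_phantom_spec for synthetic runs
    downsample_factor = 1L,    # 4 for raw 0.33 um acquisitions
    centerline_spacing = 1.32, # um; NULL = voxel size of the (downsampled) volume
    n_spokes = 60L,
    angular_step = 6,
    max_radius = 140,
    radial_step = 3.2,
    delta_spoke = 2L,
    delta_slice = 1L,
    r_min = 2L,
    refine_iters = 1L,
    section_spacing = 9.2,     # um between cross-sections
    fov = NULL,                # NULL = inscribed cylinder; NA = no filter
    fiber_level_stats = FALSE,
    seed = 1L,
    output_dir = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, config, keep.null = TRUE)
  if (!is.null(cfg$phantom) && !inherits(cfg$phantom, "ft_phantom_spec"))
    stop("phantom must be an ft_phantom_spec")
  if (is.null(cfg$phantom) && is.null(cfg$input))
    stop("config needs either an input volume or a phantom spec")
  if (cfg$downsample_factor < 1 ||
      cfg$downsample_factor != round(cfg$downsample_factor))
    stop("downsample_factor must be an integer >= 1")
  if (!is.null(cfg$centerline_spacing) && cfg$centerline_spacing <= 0)
    stop("centerline_spacing must be > 0")
  if (cfg$section_spacing <= 0) stop("section_spacing must be > 0")
  if (abs(cfg$n_spokes * cfg$angular_step - 360) > 1e-9)
    stop("angular_step (", cfg$angular_step, " deg) does not tile 360 with ",
         cfg$n_spokes, " spokes")
  if (cfg$max_radius < cfg$r_min * cfg$radial_step)
    stop("max_radius smaller than r_min * radial_step")
  # constructs and validates the terrain parameter block
  cfg$terrain <- terrain_params(cfg$n_spokes, cfg$angular_step,
                                cfg$max_radius, cfg$radial_step,
                                cfg$delta_spoke, cfg$delta_slice, cfg$r_min,
                                cfg$refine_iters)
  class(cfg) <- "ft_config"
  cfg
}

#' Run the full fiber analysis pipeline
#'
#' Executes the stages in order: input (read volume + seed labels, or
#' generate a phantom), optional trilinear downsampling, centerline
#' extraction, tube segmentation, morphometry with FOV filtering, and
#' population summary. Writes tables and a machine-readable run manifest
#' when \code{output_dir} is set. Reruns with identical config and seed are
#' bit-identical.
#'
#' @param config \code{ft_config} (see \code{\link{validate_config}}) or a
#'   plain list of overrides.
#' @param group group label attached to the summary.
#' @param verbose print stage progress.
#' @return list with \code{volume}, \code{seeds}, \code{centerlines},
#'   \code{seg} (segments + labels), \code{morph} (per-fiber/per-section
#'   tables), \code{summary}, \code{phantom} (when synthetic),
#'   \code{manifest}.
#' @export
run_pipeline <- function(config = list(), group = "sample", verbose = FALSE) {
  if (!inherits(config, "ft_config")) config <- validate_config(config)
  t_start <- Sys.time()
  stage <- function(name, expr) {
    if (verbose) message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  phantom <- NULL
  counts <- list()
  if (!is.null(config$phantom)) {
    phantom <- stage("phantom", generate_phantom(config$phantom))
    vol <- phantom$volume
    seeds <- phantom$seeds
    counts$fibers_placed <- length(phantom$truths)
    counts$fibers_rejected <- phantom$n_rejected
  } else {
    vol <- stage("input", read_volume(config$input,
                                      voxel_size = config$voxel_size))
    seeds <- stage("input", read_volume(config$labels,
                                        voxel_size = config$voxel_size,
                                        labels = TRUE))
  }
  if (config$downsample_factor > 1L) {
    vol <- stage("downsample", downsample(vol, config$downsample_factor))
  }
  spacing <- if (is.null(config$centerline_spacing)) vol$voxel_size
             else config$centerline_spacing
  cls <- stage("centerlines", extract_centerlines(seeds, spacing = spacing))
  if (length(cls) == 0L) stop("stage 'centerlines' failed: no usable fiber")
  counts$centerlines <- length(cls)
  seg <- stage("segment", segment_fibers(vol, cls, config$terrain,
                                         verbose = verbose))
  fov <- config$fov
  if (is.null(fov)) fov <- fov_cylinder(seg$labels)
  morph <- stage("morphometry",
                 fiber_morphometry(seg, spacing = config$section_spacing,
                                   cylinder = fov))
  summary <- stage("stats",
                   group_summary(morph, labels = seg$labels, group = group,
                                 roi = if (is.list(fov)) fov else NULL))
  manifest <- list(
    package_version = as.character(packageVersion("fibertube")),
    group = group,
    seed = config$seed,
    config = config_echo(config),
    counts = counts,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  res <- list(volume = vol, seeds = seeds, centerlines = cls, seg = seg,
              morph = morph, summary = summary, phantom = phantom,
              manifest = manifest)
  if (!is.null(config$output_dir)) {
    dir <- config$output_dir
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_tables(morph$per_fiber, morph$per_section,
                 summary_json(summary), dir)
    write_centerlines(cls, file.path(dir, "centerlines.csv"))
    write.csv(surface_table(seg$segments), file.path(dir, "surfaces.csv"),
              row.names = FALSE)
    manifest$outputs <- list.files(dir)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

config_echo <- function(config) {
  keep <- setdiff(names(unclass(config)), c("terrain", "phantom"))
  out <- unclass(config)[keep]
  out <- out[!vapply(out, is.null, TRUE)]
  if (!is.null(config$phantom)) out$phantom <- unclass(config$phantom)
  out
}

summary_json <- function(s) {
  lapply(unclass(s), function(x) if (is.list(x)) lapply(x, identity) else x)
}

#' Run a multi-group phantom study
#'
#' Generates one phantom per preset, runs the full pipeline on each, and
#' compares every other group against the reference with Wilcoxon rank-sum
#' and Brown-Forsythe tests (sinuosity on per-fiber values; diameter and
#' eccentricity on pooled FOV-kept cross-sections).
#'
#' @param presets named list of \code{\link{phantom_spec}}s, or a character
#'   vector of preset names understood by \code{\link{phantom_preset}}.
#' @param seed study seed (propagated to the phantoms).
#' @param reference name of the reference group.
#' @param config shared pipeline overrides (list).
#' @param verbose print progress.
#' @return list with \code{results} (per group pipeline results),
#'   \code{summaries}, \code{tests} (comparison data frame).
#' @export
run_study <- function(presets = c("healthy", "atrophic", "severe"),
                      seed = 1L, reference = NULL, config = list(),
                      verbose = FALSE) {
  if (is.character(presets)) {
    nm <- presets
    presets <- lapply(nm, phantom_preset, seed = seed)
    names(presets) <- nm
  }
  if (is.null(reference)) reference <- names(presets)[1]
  results <- list()
  for (g in names(presets)) {
    spec <- presets[[g]]
    cfg <- modifyList(list(
      phantom = spec,
      centerline_spacing = spec$voxel_size,
      radial_step = spec$voxel_size,
      # largest expected fiber radius (incl. swelling) plus a safety margin
      max_radius = min(140, 0.73 * (spec$diameter_um[1] +
                                    2.8 * spec$diameter_um[2]) + 8),
      seed = seed), config, keep.null = TRUE)
    results[[g]] <- run_pipeline(cfg, group = g, verbose = verbose)
  }
  morphs <- lapply(results, `[[`, "morph")
  tests <- compare_groups(morphs, reference = reference)
  list(results = results,
       summaries = lapply(results, `[[`, "summary"),
       tests = tests)
}
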