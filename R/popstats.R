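#' Muscle tissue volume fraction
#'
#' Percentage of voxels carrying a nonzero fiber label, within an optional
#' cylindrical region of interest (default: the whole grid).
#'
#' @param labels \code{ft_labels}.
#' @param roi optional cylinder list (\code{center}, \code{radius},
#'   \code{zlim}; see \code{\link{fov_cylinder}}).
#' @return percentage in [0, 100].
#' @export
volume_fraction <- function(labels, roi = NULL) {
  stopifnot(inherits(labels, "ft_labels"))
  fg <- labels$data > 0L
  if (is.null(roi)) return(100 * sum(fg) / length(fg))
  d <- dim(labels$data)
  vs <- labels$voxel_size
  cx <- (seq_len(d[1]) - 0.5) * vs
  cy <- (seq_len(d[2]) - 0.5) * vs
  cz <- (seq_len(d[3]) - 0.5) * vs
  in_xy <- outer((cx - roi$center[1])^2, (cy - roi$center[2])^2, "+") <=
    roi$radius^2
  in_z <- cz >= roi$zlim[1] & cz <= roi$zlim[2]
  roi_mask <- array(rep(in_xy, times = d[3]), d) &
    array(rep(in_z, each = d[1] * d[2]), d)
  if (!any(roi_mask)) stop("empty region of interest")
  100 * sum(fg & roi_mask) / sum(roi_mask)
}

#' Distribution summary with boxplot statistics
#'
#' Median and interquartile range using linear-interpolation quartiles
#' (\code{stats::quantile} type 7), plus boxplot statistics: quartiles and
#' whiskers at 1.5 IQR beyond the quartiles, truncated at the sample
#' extrema.
#'
#' @param values numeric vector (NA dropped; at least one value).
#' @return list with \code{n}, \code{median}, \code{iqr}, \code{q1},
#'   \code{q3}, \code{whisker_low}, \code{whisker_high}.
#' @export
summarize_metric <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values to summarize")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  list(n = length(values), median = q[2], iqr = iqr, q1 = q[1], q3 = q[3],
       whisker_low = max(min(values), q[1] - 1.5 * iqr),
       whisker_high = min(max(values), q[3] + 1.5 * iqr))
}

#' Group-level composition summary
#'
#' Assembles the sample characteristics reported for a fiber population:
#' number of fibers, total centerline length (mm), muscle volume fraction
#' (%), and median/IQR summaries of sinuosity, equivalent diameter and
#' eccentricity.
#'
#' @param morph result of \code{\link{fiber_morphometry}}.
#' @param labels segmentation \code{ft_labels} (for the volume fraction);
#'   optional.
#' @param group group label string.
#' @param roi optional ROI cylinder for the volume fraction.
#' @param kept_only use only cross-sections kept by the FOV filter
#'   (default TRUE).
#' @return list (class \code{ft_group_summary}).
#' @export
group_summary <- function(morph, labels = NULL, group = "sample", roi = NULL,
                          kept_only = TRUE) {
  pf <- morph$per_fiber
  ps <- morph$per_section
  if (kept_only) ps <- ps[ps$kept, , drop = FALSE]
  out <- list(
    group = group,
    n_fibers = nrow(pf),
    total_length_mm = sum(pf$length_um) / 1000,
    volume_fraction_pct = if (!is.null(labels)) volume_fraction(labels, roi)
                          else NA_real_,
    sinuosity = summarize_metric(pf$sinuosity),
    diameter_um = summarize_metric(ps$diameter_um),
    eccentricity = summarize_metric(ps$eccentricity))
  class(out) <- "ft_group_summary"
  out
}

#' @export
print.ft_group_summary <- function(x, ...) {
  cat(sprintf("<group %s> %d fibers, total length %.1f mm", x$group,
              x$n_fibers, x$total_length_mm))
  if (is.finite(x$volume_fraction_pct))
    cat(sprintf(", volume fraction %.1f%%", x$volume_fraction_pct))
  cat(sprintf("\n  sinuosity    median %.3f IQR %.3f\n", x$sinuosity$median,
              x$sinuosity$iqr))
  cat(sprintf("  diameter     median %.1f IQR %.1f um\n", x$diameter_um$median,
              x$diameter_um$iqr))
  cat(sprintf("  eccentricity median %.2f IQR %.2f\n", x$eccentricity$median,
              x$eccentricity$iqr))
  invisible(x)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Nonparametric test of equal distribution location between two fiber
#' populations (exact for small untied samples, tie-corrected normal
#' approximation with continuity correction otherwise; two-sided).
#'
#' @param x,y numeric samples (each with >= 2 values).
#' @return list (class \code{ft_test}): \code{test}, \code{statistic},
#'   \code{p_value}, \code{n}.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) stop("each group needs >= 2 values")
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  structure(list(test = "wilcoxon_rank_sum",
                 statistic = unname(wt$statistic),
                 p_value = min(1, wt$p.value),
                 n = c(length(x), length(y))),
            class = "ft_test")
}

#' Brown-Forsythe test of equal spread
#'
#' Median-centered Levene test: a one-way ANOVA F-test on the absolute
#' deviations from each group's median. Location shifts leave the statistic
#' unchanged; a degenerate case with zero deviations in both groups returns
#' statistic 0 and p = 1.
#'
#' @param x,y numeric samples (each with >= 2 values).
#' @return list (class \code{ft_test}).
#' @export
brown_forsythe <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) stop("each group needs >= 2 values")
  z <- c(abs(x - median(x)), abs(y - median(y)))
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  if (all(z < .Machine$double.eps)) {
    res <- list(statistic = 0, p_value = 1)
  } else {
    aov_tab <- anova(lm(z ~ g))
    res <- list(statistic = aov_tab$`F value`[1],
                p_value = aov_tab$`Pr(>F)`[1])
    if (!is.finite(res$statistic)) res <- list(statistic = 0, p_value = 1)
  }
  structure(list(test = "brown_forsythe", statistic = res$statistic,
                 p_value = res$p_value, n = c(length(x), length(y))),
            class = "ft_test")
}

#' @export
print.ft_test <- function(x, ...) {
  cat(sprintf("<%s> statistic %.4g, p = %.3g (n = %s)\n", x$test, x$statistic,
              x$p_value, paste(x$n, collapse = ", ")))
  invisible(x)
}

#' Pearson correlation between diameter and eccentricity
#'
#' @param diameters,eccentricities paired numeric vectors (n >= 3).
#' @return list (class \code{ft_test}) with \code{statistic} = r.
#' @export
pearson_r <- function(diameters, eccentricities) {
  ok <- is.finite(diameters) & is.finite(eccentricities)
  d <- diameters[ok]; e <- eccentricities[ok]
  if (length(d) < 3L) stop("need at least 3 paired values")
  if (sd(d) == 0 || sd(e) == 0) stop("zero variance in one variable")
  ct <- cor.test(d, e, method = "pearson")
  structure(list(test = "pearson", statistic = unname(ct$estimate),
                 p_value = ct$p.value, n = length(d)),
            class = "ft_test")
}

#' Kernel density estimate of a metric distribution
#'
#' Gaussian kernel with Silverman's rule-of-thumb bandwidth. The returned
#' curve integrates to 1 over its support grid. A degenerate sample (all
#' values equal) yields a delta-like narrow kernel with a warning.
#'
#' @param values numeric sample (>= 2 values).
#' @param bw bandwidth or rule (default \code{"nrd0"}, Silverman).
#' @param n grid size.
#' @return data frame with \code{x}, \code{density}.
#' @export
kde_curve <- function(values, bw = "nrd0", n = 512) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least 2 values")
  if (sd(values) == 0) {
    warning("degenerate sample (all values equal); using a narrow kernel")
    bw <- max(abs(values[1]) * 1e-6, 1e-9)
  }
  den <- density(values, bw = bw, n = n)
  data.frame(x = den$x, density = den$y)
}

#' Pairwise group comparisons of morphometry metrics
#'
#' Runs the Wilcoxon rank-sum and Brown-Forsythe tests for each metric
#' between a reference group and every other group. Sinuosity is compared on
#' per-fiber values; diameter and eccentricity on cross-section values
#' (pooled across fibers by default, or one median per fiber with
#' \code{fiber_level = TRUE} as a robustness option).
#'
#' @param morphs named list of \code{\link{fiber_morphometry}} results.
#' @param reference name of the reference group (default the first).
#' @param fiber_level aggregate cross-section metrics to one median per
#'   fiber before testing.
#' @return data frame (metric, group1, group2, test, statistic, p_value,
#'   n1, n2).
#' @export
compare_groups <- function(morphs, reference = names(morphs)[1],
                           fiber_level = FALSE) {
  metric_values <- function(m, metric) {
    if (metric == "sinuosity") return(m$per_fiber$sinuosity)
    ps <- m$per_section[m$per_section$kept, , drop = FALSE]
    v <- ps[[metric]]
    if (fiber_level)
      v <- vapply(split(v, ps$fiber_id), median, 0, na.rm = TRUE)
    v
  }
  rows <- list()
  for (metric in c("sinuosity", "diameter_um", "eccentricity")) {
    ref <- metric_values(morphs[[reference]], metric)
    for (g in setdiff(names(morphs), reference)) {
      other <- metric_values(morphs[[g]], metric)
      for (t in list(wilcoxon_rank_sum(ref, other),
                     brown_forsythe(ref, other))) {
        rows[[length(rows) + 1L]] <- data.frame(
          metric = metric, group1 = reference, group2 = g, test = t$test,
          statistic = t$statistic, p_value = t$p_value,
          n1 = t$n[1], n2 = t$n[2])
      }
    }
  }
  do.call(rbind, rows)
}
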