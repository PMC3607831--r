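#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_smooth
#'   facet_wrap labs theme_minimal
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy voxel-wise statistical maps into a per-voxel tibble
#'
#' One row per in-mask voxel: 0-based voxel indices, MNI mm coordinates, and
#' the beta / t / partial-r values.
#'
#' @param x An [scn_statmaps] object.
#' @param ... Unused.
#' @export
tidy.scn_statmaps <- function(x, ...) {
  idx <- which(x$mask$mask)
  ijk <- arrayInd(idx, dim(x$mask$mask)) - 1L
  mm <- voxel_to_mni(ijk, x$affine)
  tibble(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
         x = mm[, 1], y = mm[, 2], z = mm[, 3],
         beta = x$beta[idx], t = x$t[idx], partial_r = x$partial_r[idx])
}

#' @rdname tidy.scn_statmaps
#' @export
glance.scn_statmaps <- function(x, ...) {
  tv <- x$t[x$mask$mask]
  tibble(df = x$df, n_voxels = x$mask$n_voxels,
         n_infinite_t = sum(!is.finite(tv) & !is.na(tv)),
         max_t = max(tv[is.finite(tv)]),
         one_sided = x$meta$one_sided %||% "none")
}

#' Tidy a fitted group-interaction result
#'
#' One row per in-mask voxel with the interaction coefficient, its t, and
#' the per-group slopes.
#'
#' @param x An `scn_interaction`.
#' @param ... Unused.
#' @export
tidy.scn_interaction <- function(x, ...) {
  idx <- which(x$mask$mask)
  ijk <- arrayInd(idx, dim(x$mask$mask)) - 1L
  mm <- voxel_to_mni(ijk, x$affine)
  tibble(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
         x = mm[, 1], y = mm[, 2], z = mm[, 3],
         beta3 = x$beta3[idx], t = x$t[idx],
         slope_ref = x$slope_ref[idx], slope_comp = x$slope_comp[idx])
}

#' @rdname tidy.scn_interaction
#' @export
glance.scn_interaction <- function(x, ...) {
  tv <- x$t[x$mask$mask]
  tibble(reference = x$spec$group_pair[1], comparison = x$spec$group_pair[2],
         direction = x$spec$direction, df = x$df,
         n_voxels = x$mask$n_voxels,
         min_t = min(tv[is.finite(tv)]), max_t = max(tv[is.finite(tv)]))
}

#' Bar chart of network extent across age groups
#'
#' Mirrors the voxel-count-by-group panels: one bar per group, faceted by
#' seed when several seeds are present.
#'
#' @param object An `scn_trajectory` tibble from [trajectory_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scn_trajectory <- function(object, ...) {
  object <- mutate(object,
                   group = factor(.data$group, levels = unique(.data$group)))
  g <- ggplot(object, aes(x = .data$group, y = .data$wholebrain)) +
    geom_col(fill = "grey30") +
    labs(x = "age group", y = "significant voxels (whole brain)") +
    theme_minimal()
  if (length(unique(object$seed)) > 1L) g <- g + facet_wrap(~seed, scales = "free_y")
  g
}

#' Per-group covariance-slope scatter plot at a contrast peak
#'
#' Seed-sphere mean GM against peak-sphere mean GM per subject, with one
#' least-squares line per group -- the visual check that a significant
#' interaction reflects genuinely different slopes.
#'
#' @param object An `scn_slope_data` tibble from [slope_scatter_data()].
#' @param ... Unused.
#' @export
autoplot.scn_slope_data <- function(object, ...) {
  ggplot(object, aes(x = .data$seed_value, y = .data$peak_value,
                     colour = .data$group)) +
    geom_point(alpha = 0.6, size = 1.2) +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.8) +
    labs(x = "seed GM volume", y = "peak-sphere GM volume", colour = "group") +
    theme_minimal()
}

#' Axial montage of a t map
#'
#' Quick-look plot of the t statistic on a few axial slices.
#'
#' @param stat An [scn_statmaps] or `scn_interaction` object.
#' @param slices 0-based k indices to show (default: 4 evenly spaced).
#' @param threshold Hide voxels with `|t|` below this (default 0).
#' @return A ggplot object.
#' @export
plot_stat_slices <- function(stat, slices = NULL, threshold = 0) {
  d <- dim(stat$mask$mask)
  if (is.null(slices)) {
    slices <- unique(round(seq(d[3] * 0.25, d[3] * 0.75, length.out = 4))) - 1L
  }
  df <- tidy(stat) %>%
    filter(.data$k %in% slices, is.finite(.data$t), abs(.data$t) >= threshold)
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$t)) +
    ggplot2::geom_raster() +
    facet_wrap(~k, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "grey95", high = "firebrick") +
    ggplot2::coord_equal() +
    labs(x = "MNI x (mm)", y = "MNI y (mm)", fill = "t") +
    theme_minimal()
}
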