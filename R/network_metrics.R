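#' Hemispheric extent of a thresholded network map
#'
#' Classifies every suprathreshold voxel by the sign of its MNI x coordinate
#' relative to the seed's hemisphere: ipsilateral (same sign), contralateral
#' (opposite sign), or midline (x exactly 0 at the voxel center; counted in
#' whole-brain but in neither hemisphere). Whole-brain equals the total
#' suprathreshold voxel count, so
#' `wholebrain = ipsilateral + contralateral + midline` always.
#'
#' @param binary_map Logical 3D array (or `scn_clusters`).
#' @param seed One-row seed tibble; its `x` must be nonzero to define the
#'   seed hemisphere.
#' @param affine Grid affine (taken from `binary_map` when it is an
#'   `scn_clusters`).
#' @param group Optional group label to carry through.
#' @return One-row tibble: `seed`, `group`, `seed_hemisphere`,
#'   `ipsilateral`, `contralateral`, `midline`, `wholebrain`.
#' @export
count_extent <- function(binary_map, seed, affine = NULL, group = NA_character_) {
  if (inherits(binary_map, "scn_clusters")) {
    affine <- binary_map$affine
    binary_map <- binary_map$binary
  }
  affine <- check_affine(affine)
  if (seed$x[1] == 0) abort("hemisphere undefined for a midline seed (x = 0)")
  seed_sign <- sign(seed$x[1])
  idx <- which(binary_map)
  xs <- if (length(idx)) {
    grid_mni_coords(dim(binary_map), affine)[idx, 1]
  } else numeric()
  tibble(
    seed = seed$name[1],
    group = group,
    seed_hemisphere = if (seed_sign > 0) "right" else "left",
    ipsilateral = sum(sign(xs) == seed_sign),
    contralateral = sum(sign(xs) == -seed_sign),
    midline = sum(xs == 0),
    wholebrain = length(idx)
  )
}

#' Extent trajectory across ordered age groups
#'
#' Orders per-(seed, group) extent rows by the given group sequence and tags
#' each seed's whole-brain trajectory with a qualitative shape derived from
#' the signs of successive relative changes. A change whose magnitude is at
#' most `flat_tol` of the trajectory's maximum count is "flat" (judging
#' stability against the plot's dynamic range). Sign patterns map to:
#' `(0,0)` flat, `(-,-)` contracting, `(-,0)` contracting then flat,
#' `(+,-)` inverted-V, `(-,+)` V, `(+,+)` expanding, `(+,0)` expanding then
#' flat, `(0,-)` flat then contracting, `(0,+)` flat then expanding.
#'
#' @param summaries Tibble of [count_extent()] rows across seeds and groups.
#' @param group_order Character vector of group labels, chronological
#'   (default `c("Y", "M", "O")`).
#' @param flat_tol Relative flatness tolerance (default 0.1).
#' @return Tibble (class `scn_trajectory`) ordered by seed then group, with
#'   a per-seed `shape` column.
#' @export
trajectory_table <- function(summaries, group_order = c("Y", "M", "O"),
                             flat_tol = 0.1) {
  missing_groups <- setdiff(group_order, unique(summaries$group))
  if (length(missing_groups)) {
    abort(paste0("missing group(s) in summaries: ", paste(missing_groups, collapse = ", ")))
  }
  out <- summaries %>%
    filter(.data$group %in% group_order) %>%
    mutate(group = factor(.data$group, levels = group_order)) %>%
    arrange(.data$seed, .data$group) %>%
    group_by(.data$seed) %>%
    mutate(shape = shape_tag(.data$wholebrain, flat_tol)) %>%
    ungroup() %>%
    mutate(group = as.character(.data$group))
  class(out) <- c("scn_trajectory", class(out))
  out
}

# qualitative shape of a count sequence from signs of relative changes;
# flatness is judged against the trajectory's dynamic range (its maximum
# count), mirroring how "relatively stable" reads off a voxel-count plot
shape_tag <- function(counts, flat_tol = 0.1) {
  if (length(counts) < 2L) return(rep("flat", length(counts)))
  d <- diff(counts)
  base <- max(counts, 1)
  s <- ifelse(abs(d) / base <= flat_tol, 0L, sign(d))
  key <- paste(s, collapse = ",")
  tag <- switch(key,
    "0,0" = "flat",
    "-1,-1" = "contracting",
    "-1,0" = "contracting then flat",
    "1,-1" = "inverted-V",
    "-1,1" = "V",
    "1,1" = "expanding",
    "1,0" = "expanding then flat",
    "0,-1" = "flat then contracting",
    "0,1" = "flat then expanding",
    paste(ifelse(s < 0, "contracting", ifelse(s > 0, "expanding", "flat")),
          collapse = " then ")
  )
  rep(tag, length(counts))
}

#' Write the trajectory TSV and per-seed extent bar charts
#'
#' Writes `trajectory.tsv` (seed, group, ipsilateral, contralateral,
#' midline, wholebrain, shape), one cluster-table TSV per supplied map, and
#' one bar-chart figure per seed. File naming is deterministic; rerunning
#' with the same inputs reproduces the TSVs byte-identically.
#'
#' @param trajectories An `scn_trajectory` tibble.
#' @param cluster_tables Optional named list of cluster tibbles to write
#'   alongside.
#' @param out_dir Output directory (created if needed).
#' @param figures Write bar-chart figures (default TRUE; PNG when the device
#'   is available, PDF otherwise).
#' @return Character vector of written file paths, invisibly.
#' @export
render_summary <- function(trajectories, cluster_tables = NULL, out_dir,
                           figures = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  traj_path <- file.path(out_dir, "trajectory.tsv")
  readr::write_tsv(
    trajectories[, c("seed", "group", "seed_hemisphere", "ipsilateral",
                     "contralateral", "midline", "wholebrain", "shape")],
    traj_path)
  paths <- c(paths, traj_path)
  for (nm in names(cluster_tables)) {
    p <- file.path(out_dir, paste0(nm, "_clusters.tsv"))
    write_cluster_table(cluster_tables[[nm]], p)
    paths <- c(paths, p)
  }
  if (figures) {
    ext <- if (capabilities("png")) "png" else "pdf"
    for (sd in unique(trajectories$seed)) {
      p <- file.path(out_dir, paste0(sd, "_extent.", ext))
      g <- ggplot2::autoplot(trajectories[trajectories$seed == sd, ])
      ggplot2::ggsave(p, g, width = 5, height = 4, dpi = 150)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
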