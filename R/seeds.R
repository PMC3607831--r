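#' The eight canonical seed regions
#'
#' Sphere seeds (4 mm radius) at the MNI coordinates of eight large-scale
#' networks: primary visual (right calcarine sulcus), primary auditory
#' (right Heschl's gyrus), primary motor (right precentral gyrus),
#' language-related speech (left IFG pars opercularis), semantic (left
#' temporal pole), salience (right frontoinsular cortex), executive control
#' (right DLPFC) and default-mode (right angular gyrus).
#'
#' @return A tibble with columns `name`, `x`, `y`, `z`, `radius_mm`.
#' @export
default_seed_set <- function() {
  tibble(
    name = c("calcarine_R", "heschl_R", "precentral_R", "ifg_opercularis_L",
             "temporal_pole_L", "frontoinsular_R", "dlpfc_R", "angular_R"),
    x = c(9, 46, 28, -50, -38, 38, 44, 46),
    y = c(-81, -18, -16, 18, 10, 26, 36, -59),
    z = c(7, 10, 66, 7, -28, -10, 20, 23),
    radius_mm = 4
  )
}

#' Contralateral seed by x-sign flip
#'
#' Mirrors each seed across the midsagittal plane by negating its MNI x
#' coordinate; the name gains (or loses) a `_contra` suffix so flipping is an
#' involution.
#'
#' @param seeds Tibble of seeds (columns `name`, `x`, `y`, `z`, `radius_mm`).
#' @return Tibble of the same shape.
#' @export
flip_seed <- function(seeds) {
  check_seeds(seeds)
  seeds %>%
    mutate(
      x = ifelse(.data$x == 0, 0, -.data$x),
      name = ifelse(grepl("_contra$", .data$name),
                    sub("_contra$", "", .data$name),
                    paste0(.data$name, "_contra"))
    )
}

check_seeds <- function(seeds) {
  req <- c("name", "x", "y", "z", "radius_mm")
  if (!is.data.frame(seeds) || !all(req %in% names(seeds))) {
    abort("seeds must be a data frame with columns name, x, y, z, radius_mm")
  }
  if (any(seeds$radius_mm <= 0)) abort("seed radius_mm must be > 0")
  invisible(seeds)
}

#' Sphere ROI mask on an analysis grid
#'
#' A voxel belongs to the sphere when the Euclidean distance from its
#' mm-center to the seed center is at most `radius_mm` (closed ball on voxel
#' centers).
#'
#' @param seed One-row seed tibble (or a list with `x`, `y`, `z`,
#'   `radius_mm`).
#' @param dim3 Grid dimensions (length 3).
#' @param affine Grid affine.
#' @return An `scn_mask`; errors if no voxel falls inside the sphere.
#' @export
sphere_mask <- function(seed, dim3, affine) {
  affine <- check_affine(affine)
  ctr <- c(seed$x[1], seed$y[1], seed$z[1])
  r <- seed$radius_mm[1]
  if (r <= 0) abort("seed radius_mm must be > 0")
  xyz <- grid_mni_coords(dim3, affine)
  d2 <- (xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 + (xyz[, 3] - ctr[3])^2
  inside <- d2 <= r^2 + 1e-9
  if (!any(inside)) {
    abort(sprintf("sphere at (%g, %g, %g) r=%g mm contains no grid voxel",
                  ctr[1], ctr[2], ctr[3], r))
  }
  new_mask(array(inside, dim3), affine)
}

#' Per-subject mean GM signal inside a seed sphere
#'
#' The covariate of interest for covariance mapping: each subject's
#' arithmetic mean GM volume over the sphere's voxels, in cohort order. The
#' sphere is evaluated on the full grid; the GM analysis mask is deliberately
#' not applied to the seed (a warning is logged if the sphere leaves the
#' mask).
#'
#' @param cohort An `scn_cohort`.
#' @param seed One-row seed tibble.
#' @param mask Optional `scn_mask`, used only to warn when the sphere is not
#'   fully inside the analysis mask.
#' @return A tibble (class `scn_seed_signal`) with the cohort covariates plus
#'   a `value` column; attributes `seed` and `n_voxels_in_sphere`.
#' @export
extract_seed_signal <- function(cohort, seed, mask = NULL) {
  stopifnot(inherits(cohort, "scn_cohort"))
  sm <- sphere_mask(seed, dim(cohort$data)[1:3], cohort$affine)
  if (!is.null(mask)) {
    outside <- sum(sm$mask & !mask$mask)
    if (outside > 0) {
      scn_log(sprintf("seed '%s': %d of %d sphere voxels outside the analysis mask",
                      seed$name[1], outside, sm$n_voxels))
    }
  }
  flat <- matrix(cohort$data, ncol = n_subjects(cohort))
  vals <- colMeans(flat[as.vector(sm$mask), , drop = FALSE])
  out <- cohort$covariates %>% mutate(value = vals)
  attr(out, "seed") <- as_tibble(seed[1, , drop = FALSE])
  attr(out, "n_voxels_in_sphere") <- sm$n_voxels
  class(out) <- c("scn_seed_signal", class(out))
  out
}

#' Read / write seed sets as TSV
#'
#' @param path TSV file with columns `name`, `x`, `y`, `z`, `radius_mm`.
#' @return `read_seed_set()` returns the seed tibble; `write_seed_set()`
#'   returns `path` invisibly.
#' @export
read_seed_set <- function(path) {
  seeds <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_seeds(seeds)
  seeds
}

#' @rdname read_seed_set
#' @param seeds Seed tibble.
#' @export
write_seed_set <- function(seeds, path) {
  check_seeds(seeds)
  readr::write_tsv(seeds, path)
  invisible(path)
}
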