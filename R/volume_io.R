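#' Gray-matter image and cohort containers
#'
#' A `gm_image` holds one subject's 3D grid of modulated gray-matter (GM)
#' volume values together with the 4x4 voxel-to-MNI affine. An `scn_cohort`
#' stacks the images of all subjects on one common grid (a 4D array indexed
#' `[i, j, k, subject]`) next to a covariates tibble with one row per subject.
#'
#' Voxel indices are 0-based throughout the package (array element
#' `[i+1, j+1, k+1]` corresponds to voxel index `(i, j, k)`); all reported
#' coordinates are MNI mm.
#'
#' @param data 3D numeric array of GM volume values.
#' @param affine 4x4 voxel-index (0-based) to MNI-mm transform.
#' @param subject_id Subject identifier string.
#' @param nan_action How to treat non-finite voxels: `"error"` (default) or
#'   `"zero"` (replace with 0 and log the count).
#' @return A `gm_image` object.
#' @export
gm_image <- function(data, affine, subject_id = "subject", nan_action = c("error", "zero")) {
  nan_action <- match.arg(nan_action)
  if (length(dim(data)) != 3L) abort("`data` must be a 3D array.")
  affine <- check_affine(affine)
  bad <- !is.finite(data)
  if (any(bad)) {
    if (nan_action == "error") {
      abort(sprintf("image '%s' contains %d non-finite voxels", subject_id, sum(bad)))
    }
    scn_log(sprintf("image '%s': %d non-finite voxels set to 0", subject_id, sum(bad)))
    data[bad] <- 0
  }
  structure(list(data = data, affine = affine, subject_id = subject_id),
            class = "gm_image")
}

check_affine <- function(affine) {
  affine <- unclass(affine)
  attributes(affine) <- list(dim = dim(affine))
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L))) {
    abort("`affine` must be a 4x4 matrix.")
  }
  det3 <- det(affine[1:3, 1:3])
  if (!is.finite(det3) || abs(det3) < .Machine$double.eps * 100) {
    abort("affine is singular (non-invertible).")
  }
  affine
}

#' Construct a cohort from a 4D array and a covariates table
#'
#' @param data 4D numeric array `[i, j, k, subject]`.
#' @param affine Shared 4x4 voxel-to-MNI affine.
#' @param covariates Data frame with columns `subject_id`, `group`, `gender`
#'   and `age`; row order defines subject order.
#' @return An `scn_cohort`.
#' @export
new_cohort <- function(data, affine, covariates) {
  if (length(dim(data)) != 4L) abort("`data` must be a 4D array [i, j, k, subject].")
  affine <- check_affine(affine)
  covariates <- as_tibble(covariates)
  req <- c("subject_id", "group", "gender", "age")
  missing_cols <- setdiff(req, names(covariates))
  if (length(missing_cols)) {
    abort(paste0("covariates table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(covariates) != dim(data)[4L]) {
    abort(sprintf("covariates has %d rows but data has %d subjects",
                  nrow(covariates), dim(data)[4L]))
  }
  if (anyNA(covariates$group) || anyNA(covariates$gender)) {
    abort("covariates contain missing group or gender values")
  }
  covariates$subject_id <- as.character(covariates$subject_id)
  covariates$group <- as.character(covariates$group)
  covariates$gender <- as.character(covariates$gender)
  structure(list(data = data, affine = affine, covariates = covariates),
            class = "scn_cohort")
}

#' @export
print.scn_cohort <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<scn_cohort> %d subjects on a %dx%dx%d grid (%.3g x %.3g x %.3g mm voxels)\n",
              d[4], d[1], d[2], d[3],
              voxel_sizes(x$affine)[1], voxel_sizes(x$affine)[2], voxel_sizes(x$affine)[3]))
  print(dplyr::count(x$covariates, .data$group, .data$gender))
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort An `scn_cohort`.
#' @export
n_subjects <- function(cohort) dim(cohort$data)[4L]

#' Voxel dimensions (mm) implied by an affine
#' @param affine 4x4 voxel-to-mm transform.
#' @return Length-3 vector of voxel edge lengths in mm.
#' @export
voxel_sizes <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

#' Convert MNI mm coordinates to (fractional, 0-based) voxel indices
#'
#' @param coord_mm Numeric vector `(x, y, z)` or an n x 3 matrix of MNI mm
#'   coordinates.
#' @param affine 4x4 voxel-to-mm transform (must be invertible).
#' @return Same shape as the input: fractional 0-based voxel indices.
#' @export
mni_to_voxel <- function(coord_mm, affine) {
  affine <- check_affine(affine)
  pts <- as_points(coord_mm)
  inv <- solve(affine)
  out <- t(inv[1:3, 1:3] %*% t(pts) + inv[1:3, 4])
  restore_points(out, coord_mm)
}

#' Convert (0-based) voxel indices to MNI mm coordinates
#' @inheritParams mni_to_voxel
#' @param ijk Numeric vector `(i, j, k)` or n x 3 matrix of 0-based voxel
#'   indices (fractional allowed).
#' @export
voxel_to_mni <- function(ijk, affine) {
  affine <- check_affine(affine)
  pts <- as_points(ijk)
  out <- t(affine[1:3, 1:3] %*% t(pts) + affine[1:3, 4])
  restore_points(out, ijk)
}

as_points <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 3L) abort("coordinate matrix must have 3 columns")
    x
  } else {
    if (length(x) != 3L) abort("coordinate must have length 3")
    matrix(x, nrow = 1L)
  }
}

restore_points <- function(out, input) {
  if (is.matrix(input)) out else drop(out)
}

# MNI mm coordinates of every voxel center, as an N x 3 matrix in linear
# (column-major) voxel order. Cached computation is cheap enough not to cache.
grid_mni_coords <- function(dim3, affine) {
  ijk <- cbind(
    rep.int(seq_len(dim3[1]) - 1L, dim3[2] * dim3[3]),
    rep.int(rep(seq_len(dim3[2]) - 1L, each = dim3[1]), dim3[3]),
    rep(seq_len(dim3[3]) - 1L, each = dim3[1] * dim3[2])
  )
  t(affine[1:3, 1:3] %*% t(ijk) + affine[1:3, 4])
}

#' Standard 2 mm MNI analysis grid
#'
#' The usual 91 x 109 x 91 grid at 2 mm isotropic resolution with origin at
#' MNI (-90, -126, -72), matching common whole-brain templates.
#' @return List with `dim` (length-3 integer) and `affine` (4x4 matrix).
#' @export
mni_grid_2mm <- function() {
  affine <- diag(c(2, 2, 2, 1))
  affine[1:3, 4] <- c(-90, -126, -72)
  list(dim = c(91L, 109L, 91L), affine = affine)
}

#' Gaussian FWHM to kernel standard deviation in voxels
#'
#' @param fwhm_mm Full width at half maximum in mm.
#' @param voxel_size_mm Voxel edge length(s) in mm.
#' @return Kernel sigma in voxel units (vectorised over `voxel_size_mm`).
#' @export
fwhm_to_sigma <- function(fwhm_mm, voxel_size_mm) {
  (fwhm_mm / voxel_size_mm) / (2 * sqrt(2 * log(2)))
}

# normalized, truncated (radius 6*sigma) discrete Gaussian kernel values
gauss_kernel <- function(sigma_vox) {
  r <- max(1L, as.integer(ceiling(6 * sigma_vox)))
  g <- exp(-(0:r)^2 / (2 * sigma_vox^2))
  g / (g[1] + 2 * sum(g[-1]))
}

# d x d zero-padded convolution matrix for a symmetric kernel
conv_matrix <- function(d, g) {
  r <- length(g) - 1L
  K <- matrix(0, d, d)
  idx <- abs(outer(seq_len(d), seq_len(d), "-"))
  keep <- idx <= r
  K[keep] <- g[idx[keep] + 1L]
  K
}

smooth_array3d <- function(a, sigma_vox) {
  d <- dim(a)
  for (ax in 1:3) {
    if (sigma_vox[ax] <= 0) next
    K <- conv_matrix(d[ax], gauss_kernel(sigma_vox[ax]))
    perm <- c(ax, setdiff(1:3, ax))
    m <- K %*% matrix(aperm(a, perm), nrow = d[ax])
    a <- aperm(array(m, d[perm]), order(perm))
  }
  a
}

#' Smooth a GM image or cohort with an isotropic-FWHM Gaussian kernel
#'
#' Separable truncated-Gaussian convolution with zero padding outside the
#' grid (GM maps are zero outside the head). The per-axis kernel sigma in
#' voxels is `fwhm_mm / voxel_size / (2 * sqrt(2 * log(2)))`, so anisotropic
#' voxels get per-axis sigmas. The discrete kernel is normalised to unit sum,
#' so an interior impulse preserves total image mass.
#'
#' @param x A `gm_image`, an `scn_cohort` (each subject smoothed), or a 3D
#'   array (then `affine` is required).
#' @param fwhm_mm Positive full width at half maximum in mm.
#' @param affine Affine, only used when `x` is a bare array.
#' @return Object of the same type as `x`, on the same grid.
#' @export
smooth_gaussian <- function(x, fwhm_mm, affine = NULL) {
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm <= 0) {
    abort("`fwhm_mm` must be a positive scalar")
  }
  if (inherits(x, "gm_image")) {
    sig <- fwhm_to_sigma(fwhm_mm, voxel_sizes(x$affine))
    x$data <- smooth_array3d(x$data, sig)
    x
  } else if (inherits(x, "scn_cohort")) {
    sig <- fwhm_to_sigma(fwhm_mm, voxel_sizes(x$affine))
    for (s in seq_len(n_subjects(x))) {
      x$data[, , , s] <- smooth_array3d(x$data[, , , s], sig)
    }
    x
  } else if (is.array(x) && length(dim(x)) == 3L) {
    affine <- check_affine(affine)
    smooth_array3d(x, fwhm_to_sigma(fwhm_mm, voxel_sizes(affine)))
  } else {
    abort("`x` must be a gm_image, scn_cohort, or 3D array")
  }
}

#' Brain analysis mask
#'
#' Logical 3D grid selecting the voxels entered into voxel-wise analysis.
#'
#' @param mask Logical 3D array.
#' @param affine Grid affine.
#' @return An `scn_mask` with fields `mask`, `affine`, `n_voxels`.
#' @export
new_mask <- function(mask, affine) {
  if (!is.logical(mask) || length(dim(mask)) != 3L) abort("`mask` must be a logical 3D array")
  affine <- check_affine(affine)
  structure(list(mask = mask, affine = affine, n_voxels = sum(mask)),
            class = "scn_mask")
}

#' @export
print.scn_mask <- function(x, ...) {
  cat(sprintf("<scn_mask> %d of %d voxels in mask\n", x$n_voxels, length(x$mask)))
  invisible(x)
}

#' Build a whole-brain GM analysis mask from the cohort mean image
#'
#' A voxel enters the mask when the across-subject mean GM value exceeds
#' `threshold` (absolute units of the modulated GM maps). The threshold is an
#' explicit, logged analysis parameter; there is no implicit masking.
#'
#' @param cohort An `scn_cohort`.
#' @param threshold Mean-GM cutoff; default 0.1.
#' @return An `scn_mask`.
#' @export
make_gm_mask <- function(cohort, threshold = 0.1) {
  stopifnot(inherits(cohort, "scn_cohort"))
  if (n_subjects(cohort) < 1L) abort("cohort is empty")
  mean_map <- rowMeans(matrix(cohort$data, ncol = n_subjects(cohort)))
  m <- array(mean_map > threshold, dim(cohort$data)[1:3])
  if (!any(m)) abort(sprintf("threshold %g excludes all voxels", threshold))
  scn_log(sprintf("GM mask: %d of %d voxels above mean-GM threshold %g",
                  sum(m), length(m), threshold))
  new_mask(m, cohort$affine)
}

#' Read a cohort of NIfTI GM maps with its covariates table
#'
#' Images are matched to covariate rows by subject ID and loaded in covariate
#' row order, so covariate row i corresponds to image i in all downstream
#' design matrices. Paths may be named by subject ID; unnamed paths are
#' matched by file name (base name with `.nii`/`.nii.gz` and an optional
#' `_gm` suffix stripped must equal the subject ID).
#'
#' @param image_paths Character vector of NIfTI file paths, optionally named
#'   by subject ID.
#' @param covariates_path Path to a TSV/CSV file with header columns
#'   `subject_id`, `group`, `gender`, `age` (or a data frame).
#' @param nan_action Passed to [gm_image()].
#' @return An `scn_cohort`.
#' @export
load_cohort <- function(image_paths, covariates_path, nan_action = c("error", "zero")) {
  nan_action <- match.arg(nan_action)
  covariates <- if (is.data.frame(covariates_path)) {
    as_tibble(covariates_path)
  } else {
    read_covariates(covariates_path)
  }
  ids <- as.character(covariates$subject_id)
  path_ids <- names(image_paths)
  if (is.null(path_ids) || any(path_ids == "")) {
    path_ids <- sub("(_gm)?\\.nii(\\.gz)?$", "", basename(image_paths))
  }
  missing_imgs <- setdiff(ids, path_ids)
  if (length(missing_imgs)) {
    abort(paste0("no image found for subject(s): ", paste(missing_imgs, collapse = ", ")))
  }
  paths <- image_paths[match(ids, path_ids)]
  absent <- paths[!file.exists(paths)]
  if (length(absent)) abort(paste0("missing file(s): ", paste(absent, collapse = ", ")))

  first <- read_gm_nifti(paths[[1]])
  d3 <- dim(first$data)
  data <- array(NA_real_, c(d3, length(paths)))
  for (s in seq_along(paths)) {
    img <- read_gm_nifti(paths[[s]])
    if (!identical(dim(img$data), d3) || max(abs(img$affine - first$affine)) > 1e-4) {
      abort(sprintf("inconsistent geometry: '%s' does not match '%s'",
                    paths[[s]], paths[[1]]))
    }
    gi <- gm_image(img$data, img$affine, ids[s], nan_action = nan_action)
    data[, , , s] <- gi$data
  }
  new_cohort(data, first$affine, covariates)
}

read_covariates <- function(path) {
  if (!file.exists(path)) abort(paste0("covariates file not found: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  cov <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  req <- c("subject_id", "group", "gender", "age")
  missing_cols <- setdiff(req, names(cov))
  if (length(missing_cols)) {
    abort(paste0("covariates table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  cov
}

read_gm_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  list(data = array(as.numeric(img), dim(img)[1:3]), affine = check_affine(aff))
}

#' Write a 3D map (or logical mask) as NIfTI with a given affine
#'
#' @param map 3D numeric or logical array.
#' @param affine 4x4 voxel-to-mm transform.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_map <- function(map, affine, path) {
  affine <- check_affine(affine)
  if (is.logical(map)) map <- array(as.numeric(map), dim(map))
  map[!is.finite(map)] <- 0
  img <- RNifti::asNifti(map)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
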