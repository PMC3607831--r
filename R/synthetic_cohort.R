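#' Specification of a synthetic GM cohort with planted covariance networks
#'
#' The generator emulates a cross-sectional VBM cohort: each subject's map is
#' `X_s(v) = mu(v) + sum_k A_{k,g(s)}(v) f_{k,s} + gamma(v) gender_s +
#' eps_s(v)`, with latent network factors `f_{k,s} ~ N(0,1)` independent
#' across networks and subjects, a smooth anatomical baseline `mu`, a gender
#' confound map `gamma`, and Gaussian noise of sd `noise_sigma` smoothed
#' with `noise_fwhm_mm` (smoothing makes the noise spatially autocorrelated,
#' which is what distinguishes Bonferroni from permutation FWE control; note
#' it also shrinks the marginal noise sd below `noise_sigma`).
#'
#' Each network's loading map `A_{k,g}` is a union of spheres; every sphere
#' carries one amplitude per group, so both the amplitude and the spatial
#' extent of a planted network can differ between groups.
#'
#' Group sizes and gender splits default to the cohort the analysis is
#' designed for: three age groups of 80 subjects, with 50/30, 50/30 and
#' 55/25 female/male splits.
#'
#' @param dim3 Grid dimensions; default `c(48, 56, 48)` at 2 mm isotropic.
#' @param affine Grid affine; default 2 mm isotropic centered on MNI 0 (odd
#'   mm coordinates, so no voxel center sits exactly on the midline).
#' @param groups Named integer vector of subjects per group.
#' @param gender_split Named list: per group, a named vector of counts per
#'   gender level (e.g. `c(F = 50, M = 30)`).
#' @param template List describing the baseline `mu`: `amplitude`, `radius_frac`
#'   (semi-axes as a fraction of the half field of view) and `power` of the
#'   super-Gaussian blob.
#' @param networks List of networks; each is a list with `name` and
#'   `loadings`, a tibble with columns `x`, `y`, `z`, `radius_mm` and one
#'   amplitude column per group.
#' @param confound List with `x`, `y`, `z`, `radius_mm`, `amplitude` for the
#'   gender effect map (amplitude added for the second sorted gender level),
#'   or `NULL`.
#' @param noise_sigma Pre-smoothing noise sd (> 0).
#' @param noise_fwhm_mm FWHM of the smoothing applied to the noise (0 = none).
#' @param age_range Named list of `c(lo, hi)` ages per group (uniform draws).
#' @param rng_seed Integer seed; identical spec + seed gives a bit-identical
#'   cohort.
#' @return A `scn_generator_spec`.
#' @export
generator_spec <- function(dim3 = c(48L, 56L, 48L),
                           affine = NULL,
                           groups = c(Y = 80L, M = 80L, O = 80L),
                           gender_split = list(Y = c(F = 50L, M = 30L),
                                               M = c(F = 50L, M = 30L),
                                               O = c(F = 55L, M = 25L)),
                           template = list(amplitude = 0.6, radius_frac = 0.75,
                                           power = 4),
                           networks = list(),
                           confound = NULL,
                           noise_sigma = 1.0,
                           noise_fwhm_mm = 6,
                           age_range = list(Y = c(18, 23), M = c(30, 58),
                                            O = c(61, 89)),
                           rng_seed = 1L) {
  if (is.null(affine)) {
    affine <- diag(c(2, 2, 2, 1))
    affine[1:3, 4] <- -(dim3 - 1)   # voxel centers at odd mm, symmetric about 0
  }
  affine <- check_affine(affine)
  if (any(groups < 2L)) abort("each group needs at least 2 subjects")
  if (noise_sigma <= 0) abort("noise_sigma must be > 0")
  for (nw in networks) {
    missing_amp <- setdiff(names(groups), names(nw$loadings))
    if (length(missing_amp)) {
      abort(sprintf("network '%s' lacks amplitude column(s): %s",
                    nw$name, paste(missing_amp, collapse = ", ")))
    }
    if (!all(is.finite(as.matrix(nw$loadings[names(groups)])))) {
      abort(sprintf("network '%s' has non-finite amplitudes", nw$name))
    }
  }
  structure(list(dim3 = as.integer(dim3), affine = affine, groups = groups,
                 gender_split = gender_split, template = template,
                 networks = networks, confound = confound,
                 noise_sigma = noise_sigma, noise_fwhm_mm = noise_fwhm_mm,
                 age_range = age_range, rng_seed = as.integer(rng_seed)),
            class = "scn_generator_spec")
}

# smooth anatomical baseline: super-Gaussian "head" blob
template_map <- function(spec) {
  xyz <- grid_mni_coords(spec$dim3, spec$affine)
  half_fov <- (spec$dim3 * voxel_sizes(spec$affine)) / 2
  r <- spec$template$radius_frac * half_fov
  p <- spec$template$power
  u <- (abs(xyz[, 1]) / r[1])^p + (abs(xyz[, 2]) / r[2])^p + (abs(xyz[, 3]) / r[3])^p
  array(spec$template$amplitude * exp(-u), spec$dim3)
}

sphere_indicator <- function(spec, x, y, z, radius_mm) {
  sm <- sphere_mask(tibble(name = "s", x = x, y = y, z = z, radius_mm = radius_mm),
                    spec$dim3, spec$affine)
  sm$mask
}

# per-group loading maps for one network: list of 3D arrays named by group
network_loading_maps <- function(spec, nw) {
  maps <- lapply(names(spec$groups), function(g) array(0, spec$dim3))
  names(maps) <- names(spec$groups)
  for (i in seq_len(nrow(nw$loadings))) {
    row <- nw$loadings[i, ]
    ind <- sphere_indicator(spec, row$x, row$y, row$z, row$radius_mm)
    for (g in names(spec$groups)) {
      maps[[g]][ind] <- maps[[g]][ind] + row[[g]]
    }
  }
  maps
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws the covariates table (group, gender, age), latent network factors,
#' and smoothed voxel noise, and assembles each subject's GM map according
#' to the generative model of [generator_spec()]. Fully determined by the
#' spec's `rng_seed`.
#'
#' @param spec A `scn_generator_spec`.
#' @return List with `cohort` (an `scn_cohort`) and `truth`, which holds
#'   `factors` (tibble subject x network), per-network union truth masks and
#'   per-group loading maps, and `loadings_long` (tibble: network, sphere
#'   coordinates, group, amplitude) from which any pair-of-regions slope is
#'   `a_to / a_from` per group.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "scn_generator_spec"))
  gnames <- names(spec$groups)
  n_total <- sum(spec$groups)

  covariates <- withr_seed(spec$rng_seed, {
    rows <- lapply(gnames, function(g) {
      split <- spec$gender_split[[g]]
      genders <- rep(names(split), times = split)
      if (length(genders) != spec$groups[[g]]) {
        abort(sprintf("gender split for group '%s' sums to %d, expected %d",
                      g, length(genders), spec$groups[[g]]))
      }
      ar <- spec$age_range[[g]] %||% c(20, 80)
      tibble(subject_id = sprintf("%s%03d", g, seq_len(spec$groups[[g]])),
             group = g, gender = genders,
             age = round(stats::runif(spec$groups[[g]], ar[1], ar[2]), 1))
    })
    bind_rows(rows)
  })

  mu <- template_map(spec)
  nets <- lapply(spec$networks, function(nw) {
    maps <- network_loading_maps(spec, nw)
    list(name = nw$name, maps = maps,
         mask = Reduce(`|`, lapply(maps, function(m) m != 0)))
  })
  gamma_map <- if (!is.null(spec$confound)) {
    cf <- spec$confound
    array(cf$amplitude * sphere_indicator(spec, cf$x, cf$y, cf$z, cf$radius_mm),
          spec$dim3)
  } else NULL
  gender_levels <- sort(unique(covariates$gender))
  gender01 <- as.numeric(covariates$gender == gender_levels[min(2, length(gender_levels))])

  k <- length(nets)
  data <- array(0, c(spec$dim3, n_total))
  sig <- fwhm_to_sigma(spec$noise_fwhm_mm, voxel_sizes(spec$affine))
  factors <- withr_seed(spec$rng_seed + 1L, {
    matrix(rnorm(n_total * max(k, 1L)), nrow = n_total)
  })
  withr_seed(spec$rng_seed + 2L, {
    for (s in seq_len(n_total)) {
      img <- mu
      g <- covariates$group[s]
      if (k > 0) {
        for (ki in seq_len(k)) {
          img <- img + nets[[ki]]$maps[[g]] * factors[s, ki]
        }
      }
      if (!is.null(gamma_map)) img <- img + gamma_map * gender01[s]
      eps <- array(rnorm(prod(spec$dim3), sd = spec$noise_sigma), spec$dim3)
      if (spec$noise_fwhm_mm > 0) eps <- smooth_array3d(eps, sig)
      data[, , , s] <- img + eps
    }
  })

  truth <- list(
    factors = as_tibble(setNames(
      as.data.frame(factors[, seq_len(max(k, 1L)), drop = FALSE]),
      if (k > 0) vapply(nets, `[[`, "", "name") else "f1"
    )) %>% mutate(subject_id = covariates$subject_id, .before = 1),
    networks = nets,
    loadings_long = loadings_long(spec),
    template = mu,
    gamma = gamma_map
  )
  list(cohort = new_cohort(data, spec$affine, covariates), truth = truth)
}

loadings_long <- function(spec) {
  if (!length(spec$networks)) {
    return(tibble(network = character(), sphere = integer(), x = numeric(),
                  y = numeric(), z = numeric(), radius_mm = numeric(),
                  group = character(), amplitude = numeric()))
  }
  bind_rows(lapply(spec$networks, function(nw) {
    nw$loadings %>%
      mutate(network = nw$name, sphere = row_number()) %>%
      tidyr::pivot_longer(dplyr::all_of(names(spec$groups)),
                          names_to = "group", values_to = "amplitude") %>%
      select("network", "sphere", "x", "y", "z", "radius_mm", "group", "amplitude")
  }))
}

#' Desk-scale preset scenario with planted network trajectories
#'
#' Three age groups (Y, M, O) on a compact 24 x 28 x 24 grid (2 mm). Two
#' "cognitive-like" networks keep their seed sphere loaded in every group but
#' lose their distal spheres after young adulthood, so their detectable
#' extent contracts Y to M and stays flat M to O. A "motor-like" network is
#' confined to its right-hemisphere seed in Y and O but gains a contralateral
#' homologous sphere in M, giving an inverted-V extent profile. A gender
#' confound blob and smoothed noise are always present.
#'
#' @param n_per_group Named vector of group sizes (default the 80/80/80
#'   design with its gender splits; smaller values rescale the splits
#'   proportionally).
#' @param noise_sigma Pre-smoothing noise sd (default 1).
#' @param rng_seed Seed.
#' @return A `scn_generator_spec`.
#' @export
planted_scn_scenario <- function(n_per_group = c(Y = 80L, M = 80L, O = 80L),
                                 noise_sigma = 1.0, rng_seed = 20260101L) {
  frac <- list(Y = c(F = 50, M = 30) / 80, M = c(F = 50, M = 30) / 80,
               O = c(F = 55, M = 25) / 80)
  split <- lapply(names(n_per_group), function(g) {
    f <- round(unname(frac[[g]]["F"]) * n_per_group[[g]])
    c(F = f, M = n_per_group[[g]] - f)
  })
  names(split) <- names(n_per_group)

  cog <- function(name, seed_xyz, distal1, distal2) {
    list(name = name, loadings = tibble(
      x = c(seed_xyz[1], distal1[1], distal2[1]),
      y = c(seed_xyz[2], distal1[2], distal2[2]),
      z = c(seed_xyz[3], distal1[3], distal2[3]),
      radius_mm = c(4, 5, 5),
      Y = c(0.15, 0.13, 0.12),
      M = c(0.15, 0, 0),
      O = c(0.15, 0, 0)
    ))
  }
  motor <- list(name = "motorlike", loadings = tibble(
    x = c(11, -11), y = c(-5, -5), z = c(17, 17),
    radius_mm = c(4, 4),
    Y = c(0.15, 0), M = c(0.15, 0.13), O = c(0.15, 0)
  ))
  generator_spec(
    dim3 = c(24L, 28L, 24L),
    groups = n_per_group,
    gender_split = split,
    networks = list(
      cog("speechlike", c(-15, 9, 5), c(-15, -13, 11), c(13, 9, 5)),
      cog("dmnlike", c(15, -17, 9), c(-13, -17, 9), c(9, 13, -5)),
      motor
    ),
    confound = list(x = 9, y = 17, z = -9, radius_mm = 6, amplitude = 0.05),
    noise_sigma = noise_sigma,
    noise_fwhm_mm = 6,
    rng_seed = rng_seed
  )
}

#' Seed set matching the preset scenario's planted networks
#'
#' One 4 mm seed per planted network, centered on the network's first
#' (always-loaded) sphere.
#'
#' @param spec A generator spec with networks.
#' @return Seed tibble (`name`, `x`, `y`, `z`, `radius_mm`).
#' @export
scenario_seed_set <- function(spec = planted_scn_scenario()) {
  bind_rows(lapply(spec$networks, function(nw) {
    tibble(name = nw$name, x = nw$loadings$x[1], y = nw$loadings$y[1],
           z = nw$loadings$z[1], radius_mm = 4)
  }))
}

#' Write a synthetic cohort (and its ground truth) to disk
#'
#' Per-subject NIfTI maps (`<subject_id>_gm.nii.gz`), `covariates.tsv`,
#' per-network truth masks (`truth_<network>.nii.gz`), and the generator
#' spec as `generator_spec.json`. Reloading with [load_cohort()] round-trips
#' the voxel data exactly.
#'
#' @param cohort An `scn_cohort`.
#' @param truth Optional ground-truth list from [generate_cohort()].
#' @param out_dir Output directory.
#' @param spec Optional generator spec to serialise alongside.
#' @return Named list of written paths, invisibly.
#' @export
write_cohort <- function(cohort, truth = NULL, out_dir, spec = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  img_paths <- character(n_subjects(cohort))
  for (s in seq_len(n_subjects(cohort))) {
    id <- cohort$covariates$subject_id[s]
    img_paths[s] <- file.path(out_dir, paste0(id, "_gm.nii.gz"))
    write_nifti_map(cohort$data[, , , s], cohort$affine, img_paths[s])
  }
  cov_path <- file.path(out_dir, "covariates.tsv")
  readr::write_tsv(cohort$covariates, cov_path)
  truth_paths <- character()
  for (nw in truth$networks) {
    p <- file.path(out_dir, paste0("truth_", nw$name, ".nii.gz"))
    write_nifti_map(nw$mask, cohort$affine, p)
    truth_paths <- c(truth_paths, p)
  }
  spec_path <- NULL
  if (!is.null(spec)) {
    spec_path <- file.path(out_dir, "generator_spec.json")
    write_generator_spec(spec, spec_path)
  }
  invisible(list(images = img_paths, covariates = cov_path,
                 truth = truth_paths, spec = spec_path))
}

#' Serialise / restore a generator spec as JSON
#'
#' A spec written and re-read regenerates the identical cohort.
#'
#' @param spec A `scn_generator_spec`.
#' @param path JSON path.
#' @export
write_generator_spec <- function(spec, path) {
  ser <- unclass(spec)
  ser$affine <- as.vector(spec$affine)
  ser$groups <- as.list(spec$groups)                 # keep group names in JSON
  ser$gender_split <- lapply(spec$gender_split, as.list)
  ser$networks <- lapply(spec$networks, function(nw) {
    list(name = nw$name, loadings = nw$loadings)
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_generator_spec
#' @export
read_generator_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  generator_spec(
    dim3 = raw$dim3,
    affine = matrix(as.numeric(raw$affine), 4, 4),
    groups = vapply(raw$groups, as.integer, integer(1)),
    gender_split = lapply(raw$gender_split, function(s) vapply(s, as.integer, integer(1))),
    template = raw$template,
    networks = if (is.data.frame(raw$networks)) {
      # jsonlite simplifies a homogeneous list of networks to a data frame
      lapply(seq_len(nrow(raw$networks)), function(i) {
        list(name = raw$networks$name[i],
             loadings = as_tibble(raw$networks$loadings[[i]]))
      })
    } else {
      lapply(raw$networks, function(nw) {
        list(name = nw$name, loadings = as_tibble(nw$loadings))
      })
    },
    confound = raw$confound,
    noise_sigma = raw$noise_sigma,
    noise_fwhm_mm = raw$noise_fwhm_mm,
    age_range = lapply(raw$age_range, unlist),
    rng_seed = raw$rng_seed
  )
}
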