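#' Specification of a between-group covariance-slope comparison
#'
#' Two groups are compared voxel-by-voxel with the interaction linear model
#' `V_i = b0 + b1 V_j + b2 Group + b3 (V_j x Group) + confounds + e`, where
#' `V_j` is the seed signal, `V_i` the voxel GM value, and Group is
#' treatment-coded (reference = 0, comparison = 1). `b3` is the difference
#' in covariance slope (comparison minus reference), tested with the Student
#' t statistic on the pooled residual variance.
#'
#' @param group_pair Character vector `c(reference, comparison)`; must name
#'   two distinct groups present in the cohort.
#' @param confounds Nuisance covariate columns (default `"gender"`).
#' @param direction `"two_sided"`, `"ref_gt_comp"` (reference slope larger,
#'   i.e. b3 < 0; the usual "Y > M" aging contrast), or `"comp_gt_ref"`.
#' @return An `scn_interaction_spec`.
#' @export
interaction_spec <- function(group_pair, confounds = "gender",
                             direction = c("two_sided", "ref_gt_comp", "comp_gt_ref")) {
  direction <- match.arg(direction)
  if (length(group_pair) != 2L || group_pair[1] == group_pair[2]) {
    abort("group_pair must name two distinct groups")
  }
  structure(list(group_pair = group_pair, confounds = confounds,
                 direction = direction),
            class = "scn_interaction_spec")
}

# subset a cohort to given groups, preserving subject order
subset_cohort <- function(cohort, groups) {
  keep <- cohort$covariates$group %in% groups
  new_cohort(cohort$data[, , , keep, drop = FALSE], cohort$affine,
             cohort$covariates[keep, ])
}

# assemble the pooled two-group interaction design
interaction_design <- function(cohort, seed_vec, spec) {
  grp <- cohort$covariates$group
  missing_groups <- setdiff(spec$group_pair, unique(grp))
  if (length(missing_groups)) {
    abort(paste0("group(s) absent from cohort: ", paste(missing_groups, collapse = ", ")))
  }
  small <- names(which(table(grp)[spec$group_pair] < 5))
  if (length(small)) {
    abort(paste0("insufficient group size (< 5 subjects): ", paste(small, collapse = ", ")))
  }
  g <- as.numeric(grp == spec$group_pair[2])   # treatment coding: reference = 0
  X <- cbind(intercept = 1, seed = seed_vec, group = g, seed_x_group = seed_vec * g)
  for (cn in spec$confounds) {
    col <- cohort$covariates[[cn]]
    if (anyNA(col)) abort(sprintf("confound '%s' has missing values", cn))
    X <- cbind(X, encode_covariate(col, cn))
  }
  validate_design(X)
  contrast <- as.numeric(colnames(X) == "seed_x_group")
  structure(list(X = X, contrast = contrast, n = nrow(X), p = ncol(X),
                 df = nrow(X) - ncol(X), seed_col = 2L),
            class = "scn_design")
}

#' Fit the voxel-wise group-interaction model
#'
#' Subsets the cohort to the two groups of `spec`, fits the pooled
#' interaction model at every in-mask voxel by OLS, and returns the t map of
#' the interaction coefficient b3 together with per-group slope maps
#' (reference slope `b1`, comparison slope `b1 + b3`).
#' `df = n_pooled - 4 - n_confound_columns`.
#'
#' @param cohort An `scn_cohort` (may contain more groups; others are
#'   dropped).
#' @param seed_signal Seed signal for the full cohort (an `scn_seed_signal`
#'   or numeric vector in cohort order).
#' @param spec An [interaction_spec()].
#' @param mask An `scn_mask`.
#' @return An `scn_interaction`: fields `t` (t_beta3 map), `beta3`, `df`,
#'   `slope_ref`, `slope_comp`, `mask`, `affine`, `spec`, plus the fitted
#'   two-group `cohort_pair` design info in `meta`.
#' @export
fit_interaction <- function(cohort, seed_signal, spec, mask) {
  stopifnot(inherits(cohort, "scn_cohort"), inherits(spec, "scn_interaction_spec"),
            inherits(mask, "scn_mask"))
  seed_vec <- seed_signal_values(seed_signal, n_subjects(cohort))
  keep <- cohort$covariates$group %in% spec$group_pair
  pair <- new_cohort(cohort$data[, , , keep, drop = FALSE], cohort$affine,
                     cohort$covariates[keep, ])
  sv <- seed_vec[keep]
  des <- interaction_design(pair, sv, spec)

  d3 <- dim(pair$data)[1:3]
  idx <- which(as.vector(mask$mask))
  Y <- t(matrix(pair$data, ncol = n_subjects(pair))[idx, , drop = FALSE])

  qrX <- qr(des$X)
  B <- qr.coef(qrX, Y)
  R <- qr.resid(qrX, Y)
  sigma2 <- colSums(R^2) / des$df
  piv <- qrX$pivot
  xtx_inv <- matrix(0, des$p, des$p)
  xtx_inv[piv, piv] <- chol2inv(qr.R(qrX))
  cvar <- drop(t(des$contrast) %*% xtx_inv %*% des$contrast)
  b3 <- drop(crossprod(des$contrast, B))
  se <- sqrt(sigma2 * cvar)
  tv <- ifelse(se > 0, b3 / se, sign(b3) * Inf)
  tv[se == 0 & b3 == 0] <- 0

  to_map <- function(v) { m <- array(NA_real_, d3); m[idx] <- v; m }
  structure(list(
    t = to_map(tv), beta3 = to_map(b3), df = des$df,
    slope_ref = to_map(B["seed", ]),
    slope_comp = to_map(B["seed", ] + b3),
    mask = mask, affine = cohort$affine, spec = spec,
    meta = list(columns = colnames(des$X), n_pooled = des$n),
    design = des, cohort_pair = pair
  ), class = "scn_interaction")
}

#' @export
print.scn_interaction <- function(x, ...) {
  cat(sprintf("<scn_interaction> %s (ref) vs %s: df = %d, %d in-mask voxels\n",
              x$spec$group_pair[1], x$spec$group_pair[2], x$df, x$mask$n_voxels))
  invisible(x)
}

# directional statistic surface for an interaction result: for ref>comp the
# evidence is b3 < 0, so threshold -t; two_sided thresholds |t|.
directional_stat <- function(result) {
  tv <- result$t
  switch(result$spec$direction,
    two_sided = abs(tv),
    ref_gt_comp = -tv,
    comp_gt_ref = tv
  )
}

#' FWE-thresholded cluster table for a fitted group contrast
#'
#' Thresholds the (direction-adjusted) interaction t map with the requested
#' FWE method and returns Table-2-style rows (peak x/y/z, voxel size, maxT)
#' labeled with the contrast (e.g. `"Y > M"` for direction `ref_gt_comp`).
#' For two-sided tests the Bonferroni quantile uses `alpha/2`; for the
#' permutation method the max-|T| (or signed max) distribution is used.
#'
#' @param result An `scn_interaction` from [fit_interaction()].
#' @param tspec An [threshold_spec()].
#' @return An `scn_clusters` whose table carries a `contrast` column.
#' @export
contrast_pair <- function(result, tspec = threshold_spec()) {
  stopifnot(inherits(result, "scn_interaction"))
  dstat <- list(t = directional_stat(result), df = result$df,
                mask = result$mask, affine = result$affine)
  two_sided <- result$spec$direction == "two_sided"
  if (tspec$method == "bonferroni") {
    tv <- inmask_finite_t(dstat)
    N <- length(tv)
    alpha <- if (two_sided) tspec$alpha_fwe / 2 else tspec$alpha_fwe
    t_star <- qt(1 - alpha / N, df = result$df)
  } else {
    maxT <- permutation_interaction_max_t(result, tspec, two_sided = two_sided)
    t_star <- stats::quantile(maxT, 1 - tspec$alpha_fwe, type = 1, names = FALSE)
  }
  cl <- threshold_and_cluster(dstat, t_star, tspec)
  # report the signed peak t of the original map at each peak voxel
  if (nrow(cl$table)) {
    cl$table <- cl$table %>%
      mutate(contrast = contrast_label(result$spec), .before = 1)
  } else {
    cl$table <- cl$table %>% mutate(contrast = character())
  }
  cl
}

contrast_label <- function(spec) {
  switch(spec$direction,
    ref_gt_comp = paste(spec$group_pair[1], ">", spec$group_pair[2]),
    comp_gt_ref = paste(spec$group_pair[2], ">", spec$group_pair[1]),
    two_sided = paste(spec$group_pair[1], "!=", spec$group_pair[2])
  )
}

# Freedman-Lane permutation of the interaction regressor against the
# nuisance-reduced design [1, seed, group, confounds].
permutation_interaction_max_t <- function(result, tspec, two_sided = FALSE) {
  des <- result$design
  interest_col <- which(des$contrast != 0)
  stat_fun <- if (two_sided) abs else identity
  X <- des$X
  Z <- X[, -interest_col, drop = FALSE]
  qrZ <- qr(Z)
  rx <- qr.resid(qrZ, X[, interest_col])
  dir_sign <- if (result$spec$direction == "ref_gt_comp") -1 else 1
  idx <- which(as.vector(result$mask$mask))
  pair <- result$cohort_pair
  Y <- t(matrix(pair$data, ncol = n_subjects(pair))[idx, , drop = FALSE])
  RY <- qr.resid(qrZ, Y)
  keep <- colSums(RY^2) > 0
  RY <- RY[, keep, drop = FALSE]
  RYn <- sweep(RY, 2, sqrt(colSums(RY^2)), "/")
  rx_ss <- sqrt(sum(rx^2))
  n <- length(rx); df <- des$df
  withr_seed(tspec$rng_seed, {
    perms <- cbind(seq_len(n), replicate(tspec$n_permutations - 1L, sample.int(n)))
  })
  Xp <- matrix(rx[perms], nrow = n) / rx_ss
  r <- crossprod(RYn, Xp)
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  tmat <- dir_sign * r * sqrt(df) / sqrt(1 - r^2)
  apply(stat_fun(tmat), 2, max)
}

#' Per-subject seed/peak value pairs for slope plots
#'
#' For each subject, the seed-sphere mean GM value and the mean GM in a
#' sphere (default 4 mm) centered on a peak voxel, tagged by group -- the
#' data behind per-group covariance-slope scatter plots at a contrast peak.
#'
#' @param cohort An `scn_cohort`.
#' @param seed_signal Seed signal for the cohort.
#' @param peak_mm Length-3 MNI mm coordinate of the peak.
#' @param radius_mm Sphere radius at the peak (default 4).
#' @param groups Optional group subset to keep.
#' @return Tibble (class `scn_slope_data`) with `subject_id`, `group`,
#'   `seed_value`, `peak_value`.
#' @export
slope_scatter_data <- function(cohort, seed_signal, peak_mm, radius_mm = 4,
                               groups = NULL) {
  stopifnot(inherits(cohort, "scn_cohort"))
  seed_vec <- seed_signal_values(seed_signal, n_subjects(cohort))
  peak_seed <- tibble(name = "peak", x = peak_mm[1], y = peak_mm[2],
                      z = peak_mm[3], radius_mm = radius_mm)
  peak_sig <- extract_seed_signal(cohort, peak_seed)
  out <- cohort$covariates %>%
    select("subject_id", "group") %>%
    mutate(seed_value = seed_vec, peak_value = peak_sig$value)
  if (!is.null(groups)) out <- out %>% filter(.data$group %in% groups)
  class(out) <- c("scn_slope_data", class(out))
  out
}
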