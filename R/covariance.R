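#' Design matrix for seed-covariance regression
#'
#' Builds the multiple-regression design used at every voxel: an intercept,
#' the seed signal (covariate of interest), and nuisance covariates. Binary
#' nuisance columns such as gender are treatment-coded 0/1 with the first
#' sorted level as reference; the coefficient of interest is unaffected by
#' this choice. The contrast selects the seed coefficient.
#'
#' @param cohort An `scn_cohort`.
#' @param seed_signal An `scn_seed_signal` (or a bare numeric vector in
#'   cohort order).
#' @param confounds Character vector of covariate column names to adjust for
#'   (default `"gender"`).
#' @return An `scn_design`: list with `X` (n x p matrix), `contrast`,
#'   `n`, `p`, `df`, `seed_col`.
#' @export
build_design <- function(cohort, seed_signal, confounds = "gender") {
  stopifnot(inherits(cohort, "scn_cohort"))
  seed_vec <- seed_signal_values(seed_signal, n_subjects(cohort))
  cov <- cohort$covariates
  missing_cols <- setdiff(confounds, names(cov))
  if (length(missing_cols)) {
    abort(paste0("confound column(s) not in covariates: ",
                 paste(missing_cols, collapse = ", ")))
  }
  X <- cbind(intercept = 1, seed = seed_vec)
  for (cn in confounds) {
    col <- cov[[cn]]
    if (anyNA(col)) abort(sprintf("confound '%s' has missing values", cn))
    X <- cbind(X, encode_covariate(col, cn))
  }
  validate_design(X)
  contrast <- as.numeric(colnames(X) == "seed")
  structure(list(X = X, contrast = contrast, n = nrow(X), p = ncol(X),
                 df = nrow(X) - ncol(X), seed_col = 2L),
            class = "scn_design")
}

seed_signal_values <- function(seed_signal, n) {
  v <- if (is.data.frame(seed_signal)) seed_signal$value else as.numeric(seed_signal)
  if (length(v) != n) {
    abort(sprintf("seed signal has length %d but cohort has %d subjects", length(v), n))
  }
  v
}

encode_covariate <- function(col, name) {
  if (is.numeric(col)) {
    m <- matrix(col, ncol = 1, dimnames = list(NULL, name))
  } else {
    lev <- sort(unique(as.character(col)))
    if (length(lev) < 2L) abort(sprintf("confound '%s' is constant", name))
    # treatment coding: first sorted level is the reference (all-zero row)
    m <- sapply(lev[-1], function(l) as.numeric(col == l))
    m <- matrix(m, nrow = length(col),
                dimnames = list(NULL, paste0(name, lev[-1])))
  }
  m
}

validate_design <- function(X) {
  if (nrow(X) <= ncol(X)) {
    abort(sprintf("degenerate design: n = %d <= p = %d", nrow(X), ncol(X)))
  }
  if (qr(X)$rank < ncol(X)) abort("degenerate design: columns are collinear")
  invisible(X)
}

#' Voxel-wise statistical maps
#'
#' Container for the beta, t and partial-correlation maps of one fitted
#' voxel-wise model, with its residual degrees of freedom and mask.
#' The partial correlation is derived voxel-wise as
#' `partial_r = t / sqrt(t^2 + df)`. Out-of-mask voxels hold `NA`.
#'
#' @name scn_statmaps
NULL

new_statmaps <- function(beta, t, df, mask, affine, meta = list()) {
  partial_r <- t / sqrt(t^2 + df)
  inf <- is.infinite(t)                 # zero-residual voxels: |partial_r| = 1
  partial_r[inf] <- sign(t[inf])
  structure(list(beta = beta, t = t, partial_r = partial_r,
                 df = df, mask = mask, affine = affine, meta = meta),
            class = "scn_statmaps")
}

#' @export
print.scn_statmaps <- function(x, ...) {
  tv <- x$t[x$mask$mask]
  cat(sprintf("<scn_statmaps> df = %d, %d in-mask voxels, t range [%.3g, %.3g]\n",
              x$df, x$mask$n_voxels, min(tv[is.finite(tv)]), max(tv[is.finite(tv)])))
  invisible(x)
}

#' Fit the seed-covariance model at every in-mask voxel
#'
#' Mass-univariate ordinary least squares: for each in-mask voxel, subject GM
#' values are regressed on the design; the contrast t statistic is
#' `t = contrast . beta_hat / SE` with `df = n - p`. Estimation uses one QR
#' decomposition of the design applied to all voxels at once (optionally in
#' column blocks), so results are independent of voxel processing order and
#' of block size. Voxels with zero residual variance get a signed-infinite t
#' (logged); they are excluded from FWE calibration downstream.
#'
#' @param cohort An `scn_cohort`.
#' @param design An `scn_design` from [build_design()].
#' @param mask An `scn_mask` on the cohort grid.
#' @param block_size Number of voxels per processing block (memory knob;
#'   results are identical for any value).
#' @return An [scn_statmaps] object.
#' @export
fit_voxelwise <- function(cohort, design, mask, block_size = 65536L) {
  stopifnot(inherits(cohort, "scn_cohort"), inherits(design, "scn_design"),
            inherits(mask, "scn_mask"))
  d3 <- dim(cohort$data)[1:3]
  if (!identical(dim(mask$mask), d3)) abort("mask shape does not match cohort grid")
  if (mask$n_voxels < 1L) abort("mask is empty")
  idx <- which(as.vector(mask$mask))
  Y <- matrix(cohort$data, ncol = n_subjects(cohort))[idx, , drop = FALSE]

  fit <- ols_contrast_t(t(Y), design$X, design$contrast, block_size = block_size)
  n_inf <- sum(!is.finite(fit$t))
  if (n_inf > 0) {
    scn_log(sprintf("fit_voxelwise: %d zero-residual voxel(s) with infinite t", n_inf))
  }
  beta_map <- array(NA_real_, d3); beta_map[idx] <- fit$cb
  t_map <- array(NA_real_, d3); t_map[idx] <- fit$t
  new_statmaps(beta_map, t_map, fit$df, mask, cohort$affine,
               meta = list(columns = colnames(design$X), contrast = design$contrast))
}

# contrast t statistics for Y (n x V) on X via one QR decomposition
ols_contrast_t <- function(Y, X, contrast, block_size = 65536L) {
  n <- nrow(X); p <- ncol(X); df <- n - p
  qrX <- qr(X)
  piv <- qrX$pivot
  xtx_inv <- matrix(0, p, p)
  xtx_inv[piv, piv] <- chol2inv(qr.R(qrX))
  cvar <- drop(t(contrast) %*% xtx_inv %*% contrast)
  V <- ncol(Y)
  cb <- numeric(V); sigma2 <- numeric(V)
  starts <- seq(1L, V, by = block_size)
  for (s0 in starts) {
    s1 <- min(s0 + block_size - 1L, V)
    Yb <- Y[, s0:s1, drop = FALSE]
    B <- qr.coef(qrX, Yb)
    R <- qr.resid(qrX, Yb)
    cb[s0:s1] <- drop(crossprod(contrast, B))
    sigma2[s0:s1] <- colSums(R^2) / df
  }
  se <- sqrt(sigma2 * cvar)
  t <- ifelse(se > 0, cb / se, sign(cb) * Inf)
  t[se == 0 & cb == 0] <- 0
  list(cb = cb, t = t, df = df, sigma2 = sigma2)
}

#' One-sided positive-covariance statistic surface
#'
#' SCN mapping asks which voxels covary positively with the seed; negative-t
#' voxels carry no evidence and are dropped (set to `NA`) before
#' thresholding.
#'
#' @param stat An [scn_statmaps] object.
#' @return The same object with non-positive t (and the derived maps) masked
#'   out, tagged `one_sided = "positive"`.
#' @export
positive_covariance_map <- function(stat) {
  stopifnot(inherits(stat, "scn_statmaps"))
  drop_v <- !is.na(stat$t) & stat$t <= 0
  stat$t[drop_v] <- NA_real_
  stat$beta[drop_v] <- NA_real_
  stat$partial_r[drop_v] <- NA_real_
  stat$meta$one_sided <- "positive"
  stat
}

#' Export statistical maps as NIfTI plus a JSON sidecar
#'
#' Writes `<prefix>_beta.nii.gz`, `<prefix>_t.nii.gz`,
#' `<prefix>_partial_r.nii.gz` and `<prefix>.json` (df, design columns,
#' contrast).
#'
#' @param stat An [scn_statmaps] object.
#' @param prefix Output path prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_statmaps <- function(stat, prefix) {
  stopifnot(inherits(stat, "scn_statmaps"))
  paths <- c(
    write_nifti_map(stat$beta, stat$affine, paste0(prefix, "_beta.nii.gz")),
    write_nifti_map(stat$t, stat$affine, paste0(prefix, "_t.nii.gz")),
    write_nifti_map(stat$partial_r, stat$affine, paste0(prefix, "_partial_r.nii.gz"))
  )
  side <- list(df = stat$df, n_voxels = stat$mask$n_voxels,
               design_columns = stat$meta$columns, contrast = stat$meta$contrast,
               one_sided = stat$meta$one_sided %||% "none")
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, paste0(prefix, ".json")))
}
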