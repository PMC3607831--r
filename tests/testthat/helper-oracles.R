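# Independent oracles and small fixtures used across the suite.

# normal-equations OLS oracle (deliberately distinct from the package's
# QR-based path)
naive_ols_contrast <- function(y, X, contrast) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * drop(t(contrast) %*% solve(XtX) %*% contrast))
  tval <- drop(t(contrast) %*% beta) / se
  list(beta = drop(beta), cb = drop(t(contrast) %*% beta), t = tval, df = df,
       partial_r = tval / sqrt(tval^2 + df))
}

# brute-force 26-connectivity flood fill (queue-based BFS)
flood_fill_26 <- function(supra) {
  d <- dim(supra)
  labels <- array(0L, d)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  nxt <- 0L
  for (start in which(supra & labels == 0L)) {
    if (labels[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    labels[start] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(v, d)
      for (o in seq_len(nrow(off))) {
        nb <- ijk + off[o, ]
        if (any(nb < 1) || any(nb > d)) next
        lin <- nb[1] + (nb[2] - 1L) * d[1] + (nb[3] - 1L) * d[1] * d[2]
        if (supra[lin] && labels[lin] == 0L) {
          labels[lin] <- nxt
          queue <- c(queue, lin)
        }
      }
    }
  }
  list(labels = labels, n = nxt)
}

# symmetric small grid: voxel centers at odd mm, none on the midline
small_grid <- function(dim3 = c(16L, 16L, 16L), vox = 2) {
  affine <- diag(c(vox, vox, vox, 1))
  affine[1:3, 4] <- -(dim3 - 1) * vox / 2
  list(dim = dim3, affine = affine)
}

# cohort straight from arrays, bypassing disk
array_cohort <- function(data4d, affine, groups = NULL, genders = NULL) {
  n <- dim(data4d)[4]
  new_cohort(data4d, affine, tibble::tibble(
    subject_id = sprintf("s%03d", seq_len(n)),
    group = groups %||% rep("Y", n),
    gender = genders %||% rep(c("F", "M"), length.out = n),
    age = seq(20, 80, length.out = n)
  ))
}

# stat-map stub with a given t array
fake_statmaps <- function(t_map, df, affine, mask = NULL) {
  mask <- mask %||% scnmapr:::new_mask(array(TRUE, dim(t_map)), affine)
  scnmapr:::new_statmaps(beta = t_map, t = t_map, df = df, mask = mask,
                         affine = affine)
}

# pure-noise generator spec (no planted networks)
null_generator_spec <- function(n = 40L, dim3 = c(16L, 16L, 16L),
                                noise_sigma = 1.0, noise_fwhm_mm = 6,
                                rng_seed = 1L) {
  generator_spec(
    dim3 = dim3,
    groups = c(Y = n),
    gender_split = list(Y = c(F = ceiling(n * 0.625), M = floor(n * 0.375))),
    networks = list(),
    confound = NULL,
    noise_sigma = noise_sigma, noise_fwhm_mm = noise_fwhm_mm,
    age_range = list(Y = c(18, 23)),
    rng_seed = rng_seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
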