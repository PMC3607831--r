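two_group_cohort <- function(n_per = 12L, dim3 = c(3L, 3L, 2L), seed = 1L) {
  g <- small_grid(dim3)
  set.seed(seed)
  n <- 2L * n_per
  data <- array(rnorm(prod(dim3) * n), c(dim3, n))
  cohort <- array_cohort(data, g$affine,
                         groups = rep(c("Y", "M"), each = n_per),
                         genders = rep(c("F", "M"), length.out = n))
  list(cohort = cohort, grid = g, sig = rnorm(n))
}

test_that("interaction fit matches a pooled normal-equations oracle", {
  tg <- two_group_cohort()
  spec <- interaction_spec(c("Y", "M"), confounds = "gender")
  mask <- new_mask(array(TRUE, tg$grid$dim), tg$grid$affine)
  res <- fit_interaction(tg$cohort, tg$sig, spec, mask)
  expect_identical(res$df, 24L - 5L)  # n_pooled - 4 - n_confound_cols

  gind <- as.numeric(tg$cohort$covariates$group == "M")
  X <- cbind(1, tg$sig, gind, tg$sig * gind,
             as.numeric(tg$cohort$covariates$gender == "M"))
  contrast <- c(0, 0, 0, 1, 0)
  Y <- matrix(tg$cohort$data, ncol = 24)
  for (v in seq_len(nrow(Y))) {
    o <- naive_ols_contrast(Y[v, ], X, contrast)
    expect_equal(res$beta3[v], o$cb, tolerance = 1e-8)
    expect_equal(res$t[v], o$t, tolerance = 1e-8)
    # slope maps: reference = b1, comparison = b1 + b3
    expect_equal(res$slope_ref[v], unname(o$beta[2]), tolerance = 1e-8)
    expect_equal(res$slope_comp[v], unname(o$beta[2] + o$beta[4]), tolerance = 1e-8)
  }
})

test_that("swapping reference and comparison negates beta3 and its t", {
  tg <- two_group_cohort(seed = 2L)
  mask <- new_mask(array(TRUE, tg$grid$dim), tg$grid$affine)
  a <- fit_interaction(tg$cohort, tg$sig, interaction_spec(c("Y", "M")), mask)
  b <- fit_interaction(tg$cohort, tg$sig, interaction_spec(c("M", "Y")), mask)
  expect_equal(b$beta3, -a$beta3, tolerance = 1e-10)
  expect_equal(b$t, -a$t, tolerance = 1e-10)
  # slope(comparison) - slope(reference) carries the sign of beta3
  expect_equal(sign(a$slope_comp - a$slope_ref), sign(a$beta3))
})

test_that("adding a constant to all voxels changes only the intercept", {
  tg <- two_group_cohort(seed = 3L)
  mask <- new_mask(array(TRUE, tg$grid$dim), tg$grid$affine)
  spec <- interaction_spec(c("Y", "M"))
  a <- fit_interaction(tg$cohort, tg$sig, spec, mask)
  shifted <- tg$cohort; shifted$data <- shifted$data + 5.5
  b <- fit_interaction(shifted, tg$sig, spec, mask)
  expect_equal(b$beta3, a$beta3, tolerance = 1e-10)
  expect_equal(b$t, a$t, tolerance = 1e-10)
  expect_equal(b$slope_ref, a$slope_ref, tolerance = 1e-10)
})

test_that("identical data in both groups gives beta3 = 0 exactly", {
  g <- small_grid(c(3L, 3L, 2L))
  n_per <- 10L
  set.seed(4)
  half <- array(rnorm(prod(g$dim) * n_per), c(g$dim, n_per))
  data <- array(c(half, half), c(g$dim, 2L * n_per))
  sig_half <- rnorm(n_per)
  cohort <- array_cohort(data, g$affine,
                         groups = rep(c("Y", "M"), each = n_per),
                         genders = rep(c("F", "M"), length.out = 2L * n_per))
  mask <- new_mask(array(TRUE, g$dim), g$affine)
  res <- fit_interaction(cohort, c(sig_half, sig_half),
                         interaction_spec(c("Y", "M"), confounds = character()),
                         mask)
  expect_equal(max(abs(res$beta3[mask$mask])), 0, tolerance = 1e-10)
})

test_that("group size and membership preconditions are enforced", {
  tg <- two_group_cohort()
  mask <- new_mask(array(TRUE, tg$grid$dim), tg$grid$affine)
  expect_error(interaction_spec(c("Y", "Y")), "distinct")
  expect_error(
    fit_interaction(tg$cohort, tg$sig, interaction_spec(c("Y", "Z")), mask),
    "absent")
  small <- tg$cohort
  keep <- c(which(small$covariates$group == "Y"),
            which(small$covariates$group == "M")[1:3])
  small <- new_cohort(small$data[, , , keep, drop = FALSE], small$affine,
                      small$covariates[keep, ])
  expect_error(
    fit_interaction(small, tg$sig[keep], interaction_spec(c("Y", "M")), mask),
    "insufficient group size")
})

test_that("a one-sided contrast in the wrong direction yields an empty table", {
  # planted slope difference: comparison (M) has the LARGER slope
  g <- small_grid(c(4L, 4L, 4L))
  n_per <- 30L
  set.seed(6)
  sig <- rnorm(2L * n_per)
  grp <- rep(c("Y", "M"), each = n_per)
  slopes <- ifelse(grp == "M", 2.0, 0.2)
  data <- array(rnorm(prod(g$dim) * 2 * n_per, sd = 0.3), c(g$dim, 2L * n_per))
  for (s in seq_len(2L * n_per)) data[2, 2, 2, s] <- slopes[s] * sig[s] + rnorm(1, sd = 0.1)
  cohort <- array_cohort(data, g$affine, groups = grp)
  mask <- new_mask(array(TRUE, g$dim), g$affine)

  planted_mm <- voxel_to_mni(c(1, 1, 1), g$affine)
  wrong <- fit_interaction(cohort, sig,
                           interaction_spec(c("Y", "M"), direction = "ref_gt_comp"),
                           mask)
  cl_wrong <- contrast_pair(wrong, threshold_spec(alpha_fwe = 0.01))
  expect_identical(nrow(cl_wrong$table), 0L)
  # the planted effect itself can never appear in the opposite direction
  expect_lt(-wrong$t[2, 2, 2], 0)

  right <- fit_interaction(cohort, sig,
                           interaction_spec(c("Y", "M"), direction = "comp_gt_ref"),
                           mask)
  cl_right <- contrast_pair(right, threshold_spec(alpha_fwe = 0.01))
  expect_gt(nrow(cl_right$table), 0L)
  expect_identical(cl_right$table$contrast[1], "M > Y")
  expect_equal(c(cl_right$table$x[1], cl_right$table$y[1], cl_right$table$z[1]),
               planted_mm)
})

test_that("slope scatter data self-pairs at the seed and recovers planted slopes", {
  spec <- planted_scn_scenario(n_per_group = c(Y = 60L, M = 60L, O = 60L))
  gen <- generate_cohort(spec)
  seeds <- scenario_seed_set(spec)
  sig <- extract_seed_signal(gen$cohort, seeds[1, ])

  # peak sphere == seed sphere: the two values coincide subject-by-subject
  self <- slope_scatter_data(gen$cohort, sig,
                             c(seeds$x[1], seeds$y[1], seeds$z[1]), radius_mm = 4)
  expect_equal(self$seed_value, self$peak_value)

  # distal sphere of the speech-like network: per-group OLS slopes approach
  # the planted amplitude ratio (distal / seed), zero for M
  ll <- gen$truth$loadings_long
  distal <- ll[ll$network == "speechlike" & ll$sphere == 2 & ll$group == "Y", ]
  seed_amp <- ll[ll$network == "speechlike" & ll$sphere == 1 & ll$group == "Y", ]
  sd_data <- slope_scatter_data(gen$cohort, sig, c(distal$x, distal$y, distal$z),
                                radius_mm = distal$radius_mm,
                                groups = c("Y", "M"))
  fitY <- lm(peak_value ~ seed_value, data = sd_data[sd_data$group == "Y", ])
  fitM <- lm(peak_value ~ seed_value, data = sd_data[sd_data$group == "M", ])
  expect_equal(unname(coef(fitY)[2]), distal$amplitude / seed_amp$amplitude,
               tolerance = 0.35)
  expect_lt(abs(coef(fitM)[2]), 0.25)

  # pooled slope is invariant to shuffling the group labels
  pooled1 <- unname(coef(lm(peak_value ~ seed_value, data = sd_data))[2])
  shuffled <- sd_data
  set.seed(9); shuffled$group <- sample(shuffled$group)
  pooled2 <- unname(coef(lm(peak_value ~ seed_value, data = shuffled))[2])
  expect_identical(pooled1, pooled2)
})
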