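test_that("design matrix has intercept + seed + confounds with a seed contrast", {
  spec <- null_generator_spec(n = 80L, rng_seed = 3L)
  gen <- generate_cohort(spec)
  sig <- rnorm(80)
  des <- build_design(gen$cohort, sig, confounds = "gender")
  expect_identical(c(des$n, des$p, des$df), c(80L, 3L, 77L))
  expect_identical(colnames(des$X), c("intercept", "seed", "genderM"))
  expect_identical(des$contrast, c(0, 1, 0))

  # gender is treatment-coded 0/1 with the first sorted level as reference
  expect_setequal(unique(des$X[, "genderM"]), c(0, 1))
  expect_identical(des$X[, "genderM"], as.numeric(gen$cohort$covariates$gender == "M"))

  expect_error(build_design(gen$cohort, rep(1, 80)), "degenerate design")
  des0 <- build_design(gen$cohort, sig, confounds = character())
  expect_identical(des0$p, 2L)
})

test_that("voxel-wise fit matches the frozen normal-equations oracle", {
  # fixed 6-subject, single-voxel instance (expected values computed with an
  # independent normal-equations solver and frozen)
  g <- small_grid(c(2L, 2L, 2L))
  seed_vec <- c(1, 2, 3, 4, 5, 6)
  voxel <- c(1.1, 1.9, 3.2, 3.8, 5.1, 5.9)
  data <- array(0, c(g$dim, 6))
  for (s in 1:6) data[1, 1, 1, s] <- voxel[s]
  cohort <- array_cohort(data, g$affine)
  mask <- new_mask(array(c(TRUE, rep(FALSE, 7)), g$dim), g$affine)
  des <- build_design(cohort, seed_vec, confounds = character())
  stat <- fit_voxelwise(cohort, des, mask)
  expect_identical(stat$df, 4L)
  expect_equal(stat$beta[1, 1, 1], 0.977142857143, tolerance = 1e-10)
  expect_equal(stat$t[1, 1, 1], 24.554169024727, tolerance = 1e-10)
  expect_equal(stat$partial_r[1, 1, 1], 0.996699155576, tolerance = 1e-10)
})

test_that("fit agrees with the oracle on random small instances, any block size", {
  g <- small_grid(c(2L, 2L, 2L))
  set.seed(99)
  for (rep in 1:5) {
    n <- sample(8:20, 1)
    data <- array(rnorm(prod(g$dim) * n), c(g$dim, n))
    cohort <- array_cohort(data, g$affine,
                           genders = sample(c("F", "M"), n, replace = TRUE))
    if (length(unique(cohort$covariates$gender)) < 2) next
    sig <- rnorm(n)
    des <- build_design(cohort, sig, confounds = "gender")
    mask <- new_mask(array(TRUE, g$dim), g$affine)
    stat <- fit_voxelwise(cohort, des, mask)
    stat1 <- fit_voxelwise(cohort, des, mask, block_size = 1L)
    expect_identical(stat$t, stat1$t)  # blocking cannot change results
    Y <- matrix(data, ncol = n)
    for (v in seq_len(nrow(Y))) {
      o <- naive_ols_contrast(Y[v, ], des$X, des$contrast)
      expect_equal(stat$beta[v], o$cb, tolerance = 1e-8)
      expect_equal(stat$t[v], o$t, tolerance = 1e-8)
      expect_equal(stat$partial_r[v], o$partial_r, tolerance = 1e-8)
    }
  }
})

test_that("a voxel equal to the seed signal has partial correlation 1", {
  g <- small_grid(c(2L, 2L, 2L))
  n <- 10
  sig <- rnorm(n)
  data <- array(0, c(g$dim, n))
  for (s in seq_len(n)) data[1, 1, 1, s] <- sig[s]
  cohort <- array_cohort(data, g$affine)
  des <- build_design(cohort, sig, confounds = character())
  mask <- new_mask(array(c(TRUE, rep(FALSE, 7)), g$dim), g$affine)
  stat <- suppressMessages(fit_voxelwise(cohort, des, mask))
  # residuals vanish up to float rounding: t is effectively infinite
  expect_gt(stat$t[1, 1, 1], 1e12)
  expect_equal(stat$partial_r[1, 1, 1], 1, tolerance = 1e-12)
})

test_that("rescaling all images scales beta but leaves t and partial_r fixed", {
  g <- small_grid(c(4L, 4L, 4L))
  set.seed(7)
  n <- 15
  data <- array(rnorm(prod(g$dim) * n, mean = 1), c(g$dim, n))
  cohort <- array_cohort(data, g$affine)
  sig <- rnorm(n)
  des <- build_design(cohort, sig, confounds = "gender")
  mask <- new_mask(array(TRUE, g$dim), g$affine)
  s1 <- fit_voxelwise(cohort, des, mask)
  cohort2 <- cohort; cohort2$data <- cohort$data * 3.7
  s2 <- fit_voxelwise(cohort2, des, mask)
  expect_equal(s2$beta, 3.7 * s1$beta, tolerance = 1e-10)
  expect_equal(s2$t, s1$t, tolerance = 1e-10)
  expect_equal(s2$partial_r, s1$partial_r, tolerance = 1e-10)
})

test_that("null t statistics reject at the nominal two-sided rate", {
  # independent-noise voxels, fresh seed covariate each replicate
  set.seed(2024)
  n <- 30; V <- 300; reps <- 30
  g <- small_grid(c(5L, 6L, 10L))
  mask <- new_mask(array(TRUE, g$dim), g$affine)
  crit <- qt(0.975, n - 3)
  rej <- 0; tot <- 0
  for (r in seq_len(reps)) {
    data <- array(rnorm(V * n), c(g$dim, n))
    cohort <- array_cohort(data, g$affine)
    des <- build_design(cohort, rnorm(n), confounds = "gender")
    stat <- fit_voxelwise(cohort, des, mask)
    rej <- rej + sum(abs(stat$t[mask$mask]) > crit)
    tot <- tot + V
  }
  expect_lt(abs(rej / tot - 0.05), 0.01)
})

test_that("gender adjustment removes a planted pure-gender effect", {
  # gender effect, zero network signal: adjusted t must stay null-calibrated
  set.seed(515)
  n <- 40; V <- 250; reps <- 20
  g <- small_grid(c(5L, 5L, 10L))
  mask <- new_mask(array(TRUE, g$dim), g$affine)
  crit <- qt(0.975, n - 3)
  rej <- 0; tot <- 0
  for (r in seq_len(reps)) {
    genders <- rep(c("F", "M"), length.out = n)
    gshift <- as.numeric(genders == "M") * 2          # strong confound
    data <- array(rnorm(V * n), c(g$dim, n))
    for (s in seq_len(n)) data[, , , s] <- data[, , , s] + gshift[s]
    cohort <- array_cohort(data, g$affine, genders = genders)
    # seed signal also carries the gender effect, as a real seed would
    sig <- rnorm(n) + gshift
    des <- build_design(cohort, sig, confounds = "gender")
    stat <- fit_voxelwise(cohort, des, mask)
    rej <- rej + sum(abs(stat$t[mask$mask]) > crit)
    tot <- tot + V
  }
  expect_lt(abs(rej / tot - 0.05), 0.012)
})

test_that("positive covariance surface is one-sided", {
  g <- small_grid(c(4L, 4L, 4L))
  mask <- new_mask(array(TRUE, g$dim), g$affine)

  neg <- fake_statmaps(array(-abs(rnorm(64)), g$dim), df = 10, g$affine, mask)
  pos_neg <- positive_covariance_map(neg)
  expect_identical(sum(!is.na(pos_neg$t)), 0L)

  set.seed(1)
  sym <- fake_statmaps(array(rnorm(64), g$dim), df = 10, g$affine, mask)
  pos_sym <- positive_covariance_map(sym)
  frac <- mean(!is.na(pos_sym$t))
  expect_gt(frac, 0.3); expect_lt(frac, 0.7)
})
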