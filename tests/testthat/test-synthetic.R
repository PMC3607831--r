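test_that("generation is bit-identical under a fixed seed", {
  spec <- planted_scn_scenario(n_per_group = c(Y = 5L, M = 5L, O = 5L),
                               rng_seed = 123L)
  g1 <- generate_cohort(spec)
  g2 <- generate_cohort(spec)
  expect_identical(serialize(g1$cohort, NULL), serialize(g2$cohort, NULL))
  g3 <- generate_cohort(planted_scn_scenario(n_per_group = c(Y = 5L, M = 5L, O = 5L),
                                             rng_seed = 124L))
  expect_false(identical(g1$cohort$data, g3$cohort$data))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(555); before <- rnorm(3)
  set.seed(555); invisible(generate_cohort(null_generator_spec(n = 3L, dim3 = c(6L, 6L, 6L))))
  after <- rnorm(3)
  expect_identical(before, after)
})

test_that("planted covariance between two regions matches the closed form", {
  # two spheres loaded with amplitudes a1, a2; region-mean noise variance is
  # sigma^2 * ||w||^2 with w the smoothing kernel applied to indicator/m
  # (kernel symmetry), so the expected correlation has a closed form.
  dim3 <- c(16L, 16L, 16L)
  a1 <- 0.15; a2 <- 0.12; sigma <- 1.0; fwhm <- 6
  s1 <- tibble::tibble(name = "r1", x = -7, y = 1, z = 1, radius_mm = 4)
  s2 <- tibble::tibble(name = "r2", x = 9, y = -5, z = -3, radius_mm = 4)
  spec <- generator_spec(
    dim3 = dim3, groups = c(Y = 500L),
    gender_split = list(Y = c(F = 300L, M = 200L)),
    networks = list(list(name = "net", loadings = tibble::tibble(
      x = c(s1$x, s2$x), y = c(s1$y, s2$y), z = c(s1$z, s2$z),
      radius_mm = 4, Y = c(a1, a2)))),
    confound = NULL, noise_sigma = sigma, noise_fwhm_mm = fwhm,
    age_range = list(Y = c(18, 23)), rng_seed = 77L
  )
  gen <- generate_cohort(spec)
  v1 <- extract_seed_signal(gen$cohort, s1)$value
  v2 <- extract_seed_signal(gen$cohort, s2)$value
  r_obs <- cor(v1, v2)

  region_noise_var <- function(seed) {
    sm <- sphere_mask(seed, dim3, spec$affine)
    ind <- array(0, dim3); ind[sm$mask] <- 1 / sm$n_voxels
    w <- smooth_gaussian(ind, fwhm, affine = spec$affine)
    sigma^2 * sum(w^2)
  }
  r_exp <- (a1 * a2) / sqrt((a1^2 + region_noise_var(s1)) *
                              (a2^2 + region_noise_var(s2)))
  expect_equal(r_obs, r_exp, tolerance = 0.05)
})

test_that("written cohorts reload exactly, truth masks match their spheres", {
  spec <- planted_scn_scenario(n_per_group = c(Y = 3L, M = 3L, O = 3L),
                               rng_seed = 9L)
  gen <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  paths <- write_cohort(gen$cohort, gen$truth, dir, spec = spec)
  reloaded <- load_cohort(paths$images, paths$covariates)
  expect_equal(reloaded$data, gen$cohort$data, tolerance = 0)
  expect_equal(as.data.frame(reloaded$covariates),
               as.data.frame(gen$cohort$covariates))

  # truth masks equal the brute-force union of the network's spheres
  for (ni in seq_along(spec$networks)) {
    nw <- spec$networks[[ni]]
    brute <- array(FALSE, spec$dim3)
    for (i in seq_len(nrow(nw$loadings))) {
      sm <- sphere_mask(nw$loadings[i, ], spec$dim3, spec$affine)
      brute <- brute | sm$mask
    }
    expect_identical(gen$truth$networks[[ni]]$mask, brute)
    ondisk <- scnmapr:::read_gm_nifti(
      file.path(dir, paste0("truth_", nw$name, ".nii.gz")))
    expect_identical(ondisk$data > 0.5, brute)
  }

  # spec JSON reload regenerates the identical cohort
  spec2 <- read_generator_spec(file.path(dir, "generator_spec.json"))
  gen2 <- generate_cohort(spec2)
  expect_identical(serialize(gen2$cohort, NULL), serialize(gen$cohort, NULL))
})

test_that("preset scenario encodes the study's group sizes and gender splits", {
  spec <- planted_scn_scenario()
  expect_identical(unname(spec$groups), c(80L, 80L, 80L))
  expect_identical(names(spec$groups), c("Y", "M", "O"))
  expect_equal(unname(spec$gender_split$Y), c(50, 30))
  expect_equal(unname(spec$gender_split$O), c(55, 25))
  expect_identical(length(spec$networks), 3L)
  # every planted sphere lies on the grid
  for (nw in spec$networks) {
    for (i in seq_len(nrow(nw$loadings))) {
      expect_no_error(sphere_mask(nw$loadings[i, ], spec$dim3, spec$affine))
    }
  }
  # age ranges follow the cohort design
  expect_equal(spec$age_range$Y, c(18, 23))
  expect_equal(spec$age_range$O, c(61, 89))
})

test_that("gender adjustment exactly cancels a planted gender confound", {
  # two cohorts share every random draw; one also carries a gender effect.
  # With gender in the design, the seed-contrast t map must be unchanged:
  # the planted effect lies in the nuisance column space.
  base <- list(
    dim3 = c(12L, 12L, 12L), groups = c(Y = 60L),
    gender_split = list(Y = c(F = 30L, M = 30L)),
    networks = list(),
    noise_sigma = 1, noise_fwhm_mm = 4,
    age_range = list(Y = c(18, 23)), rng_seed = 31L
  )
  spec_c <- do.call(generator_spec, c(base, list(
    confound = list(x = 1, y = 1, z = 1, radius_mm = 6, amplitude = 0.4))))
  spec_0 <- do.call(generator_spec, c(base, list(confound = NULL)))
  gen_c <- generate_cohort(spec_c)
  gen_0 <- generate_cohort(spec_0)

  mask <- suppressMessages(make_gm_mask(gen_0$cohort, 0.1))
  seed <- tibble::tibble(name = "s", x = 1, y = 1, z = 1, radius_mm = 4)
  fit_one <- function(gen) {
    sig <- extract_seed_signal(gen$cohort, seed)
    des <- build_design(gen$cohort, sig, confounds = "gender")
    fit_voxelwise(gen$cohort, des, mask)
  }
  stat_c <- fit_one(gen_c)
  stat_0 <- fit_one(gen_0)
  expect_equal(stat_c$t, stat_0$t, tolerance = 1e-8)
  # without adjustment the gender blob does inflate the statistics
  sig_c <- extract_seed_signal(gen_c$cohort, seed)
  des_noadj <- build_design(gen_c$cohort, sig_c, confounds = character())
  stat_noadj <- fit_voxelwise(gen_c$cohort, des_noadj, mask)
  blob <- sphere_mask(tibble::tibble(name = "b", x = 1, y = 1, z = 1,
                                     radius_mm = 6), spec_c$dim3, spec_c$affine)
  expect_gt(mean(stat_noadj$t[blob$mask]), mean(stat_c$t[blob$mask]))
})
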