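#' Read and validate a pipeline run configuration
#'
#' The pipeline is driven by one YAML file. Recognised keys (defaults in
#' parentheses):
#' \preformatted{
#' cohort_dir:   directory with <subject_id>_gm.nii.gz + covariates.tsv
#' output_dir:   where stage outputs go
#' mask:         {threshold: 0.1}
#' seeds:        "default" | "scenario" | path to a seed TSV
#' smoothing:    {apply: false, fwhm_mm: 12}
#' threshold:    {alpha_fwe: 0.05, method: bonferroni, extent_k: 0,
#'                n_permutations: 1000}
#' groups:       chronological group order (["Y", "M", "O"])
#' contrasts:    "all_pairs" | list of [reference, comparison]
#' confounds:    ["gender"]
#' direction:    ref_gt_comp | comp_gt_ref | two_sided (ref_gt_comp)
#' flat_tol:     0.1
#' rng_seed:     1
#' simulate:     {preset: planted_scn, n_per_group: 80, noise_sigma: 1.0}
#' }
#' Every stage writes a JSON sidecar recording the config hash, rng seed,
#' package version and threshold provenance.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated `scn_config` list.
#' @export
read_run_config <- function(config) {
  if (inherits(config, "scn_config")) return(config)
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    yaml::read_yaml(config)
  } else if (is.list(config)) config else {
    abort("config must be a file path or a list")
  }
  defaults <- list(
    mask = list(threshold = 0.1),
    seeds = "default",
    smoothing = list(apply = FALSE, fwhm_mm = 12),
    threshold = list(alpha_fwe = 0.05, method = "bonferroni", extent_k = 0L,
                     n_permutations = 1000L),
    groups = c("Y", "M", "O"),
    contrasts = "all_pairs",
    confounds = "gender",
    direction = "ref_gt_comp",
    flat_tol = 0.1,
    rng_seed = 1L
  )
  cfg <- modifyList(defaults, cfg)
  if (is.null(cfg$output_dir)) abort("config needs `output_dir`")
  th <- cfg$threshold
  th$rng_seed <- th$rng_seed %||% cfg$rng_seed
  cfg$threshold <- do.call(threshold_spec, th)
  class(cfg) <- "scn_config"
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass_deep(cfg), auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

write_sidecar <- function(path, cfg, extra = list()) {
  side <- c(list(config_md5 = config_hash(cfg),
                 rng_seed = cfg$rng_seed,
                 package = "scnmapr",
                 version = as.character(utils::packageVersion("scnmapr"))),
            extra)
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

resolve_seeds <- function(cfg) {
  if (identical(cfg$seeds, "default")) {
    default_seed_set()
  } else if (identical(cfg$seeds, "scenario")) {
    scenario_seed_set(scenario_from_config(cfg))
  } else {
    read_seed_set(cfg$seeds)
  }
}

scenario_from_config <- function(cfg) {
  sim <- cfg$simulate %||% list()
  n <- sim$n_per_group %||% 80L
  if (length(n) == 1L) n <- setNames(rep(as.integer(n), length(cfg$groups)), cfg$groups)
  planted_scn_scenario(n_per_group = n,
                       noise_sigma = sim$noise_sigma %||% 1.0,
                       rng_seed = cfg$rng_seed)
}

load_config_cohort <- function(cfg) {
  dir <- cfg$cohort_dir
  if (is.null(dir) || !dir.exists(dir)) {
    abort("config `cohort_dir` is missing or does not exist; run scn_simulate first or point it at real data")
  }
  imgs <- list.files(dir, pattern = "_gm\\.nii(\\.gz)?$", full.names = TRUE)
  if (!length(imgs)) abort(paste0("no *_gm.nii[.gz] images under ", dir))
  cohort <- load_cohort(imgs, file.path(dir, "covariates.tsv"))
  if (isTRUE(cfg$smoothing$apply)) {
    scn_log(sprintf("smoothing cohort at %g mm FWHM", cfg$smoothing$fwhm_mm))
    cohort <- smooth_gaussian(cohort, cfg$smoothing$fwhm_mm)
  }
  cohort
}

#' Pipeline stage: simulate a synthetic cohort to disk
#'
#' Generates the preset planted-network scenario (scaled by
#' `simulate.n_per_group` / `simulate.noise_sigma`) under the config's
#' `rng_seed` and writes it to `cohort_dir`.
#'
#' @param config Path to YAML config or list (see [read_run_config()]).
#' @return The written cohort directory, invisibly.
#' @export
scn_simulate <- function(config) {
  cfg <- read_run_config(config)
  if (is.null(cfg$cohort_dir)) abort("config needs `cohort_dir` for simulation output")
  spec <- scenario_from_config(cfg)
  gen <- generate_cohort(spec)
  write_cohort(gen$cohort, gen$truth, cfg$cohort_dir, spec = spec)
  write_sidecar(file.path(cfg$cohort_dir, "provenance.json"), cfg,
                list(stage = "simulate", n_subjects = n_subjects(gen$cohort)))
  scn_log(sprintf("simulated %d subjects into %s", n_subjects(gen$cohort), cfg$cohort_dir))
  invisible(cfg$cohort_dir)
}

#' Pipeline stage: per-seed, per-group covariance maps
#'
#' For every (seed, group) pair: extracts the seed signal, fits the
#' voxel-wise covariance model with the configured confounds, applies the
#' configured FWE height (and extent) threshold to the positive-covariance
#' map, and writes the stat-map NIfTI triplet, the thresholded binary map,
#' and the cluster TSV under `output_dir/maps/`.
#'
#' @inheritParams scn_simulate
#' @return Tibble indexing the written bundles, invisibly.
#' @export
scn_map <- function(config) {
  cfg <- read_run_config(config)
  cohort <- load_config_cohort(cfg)
  seeds <- resolve_seeds(cfg)
  mask <- make_gm_mask(cohort, cfg$mask$threshold)
  out <- file.path(cfg$output_dir, "maps")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (si in seq_len(nrow(seeds))) {
    seed <- seeds[si, ]
    for (g in cfg$groups) {
      sub <- subset_cohort(cohort, g)
      sig <- extract_seed_signal(sub, seed, mask)
      design <- build_design(sub, sig, confounds = cfg$confounds)
      stat <- fit_voxelwise(sub, design, mask)
      pos <- positive_covariance_map(stat)
      t_star <- fwe_height_threshold(pos, cfg$threshold, cohort = sub, design = design)
      cl <- threshold_and_cluster(pos, as.numeric(t_star), cfg$threshold)
      prefix <- file.path(out, paste0(seed$name, "_", g))
      write_statmaps(stat, prefix)
      write_nifti_map(cl$binary, cohort$affine, paste0(prefix, "_thresholded.nii.gz"))
      write_cluster_table(cl, paste0(prefix, "_clusters.tsv"))
      write_sidecar(paste0(prefix, "_provenance.json"), cfg, list(
        stage = "map", seed = seed$name, group = g, df = stat$df,
        n_mask_voxels = mask$n_voxels, method = cfg$threshold$method,
        alpha_fwe = cfg$threshold$alpha_fwe, t_star = as.numeric(t_star),
        extent_k = cfg$threshold$extent_k,
        n_suprathreshold = sum(cl$binary)))
      rows[[length(rows) + 1L]] <- tibble(seed = seed$name, group = g,
                                          prefix = prefix,
                                          n_clusters = nrow(cl$table),
                                          n_voxels = sum(cl$binary))
    }
  }
  res <- bind_rows(rows)
  scn_log(sprintf("mapped %d (seed, group) bundles into %s", nrow(res), out))
  invisible(res)
}

#' Pipeline stage: pairwise group-interaction contrasts
#'
#' For every seed and every (reference, comparison) group pair, fits the
#' interaction model on the two groups and writes the FWE-thresholded
#' contrast cluster table under `output_dir/contrasts/`.
#'
#' @inheritParams scn_simulate
#' @return Tibble indexing the written tables, invisibly.
#' @export
scn_contrast <- function(config) {
  cfg <- read_run_config(config)
  cohort <- load_config_cohort(cfg)
  seeds <- resolve_seeds(cfg)
  mask <- make_gm_mask(cohort, cfg$mask$threshold)
  pairs <- if (identical(cfg$contrasts, "all_pairs")) {
    utils::combn(cfg$groups, 2, simplify = FALSE)
  } else {
    cfg$contrasts
  }
  out <- file.path(cfg$output_dir, "contrasts")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (si in seq_len(nrow(seeds))) {
    seed <- seeds[si, ]
    sig <- extract_seed_signal(cohort, seed, mask)
    for (pr in pairs) {
      ispec <- interaction_spec(group_pair = c(pr[[1]], pr[[2]]),
                                confounds = cfg$confounds,
                                direction = cfg$direction)
      res <- fit_interaction(cohort, sig, ispec, mask)
      cl <- contrast_pair(res, cfg$threshold)
      fname <- paste0(seed$name, "_", pr[[1]], "gt", pr[[2]], "_clusters.tsv")
      write_cluster_table(cl, file.path(out, fname))
      write_sidecar(file.path(out, paste0(seed$name, "_", pr[[1]], "gt", pr[[2]],
                                          "_provenance.json")), cfg, list(
        stage = "contrast", seed = seed$name,
        reference = pr[[1]], comparison = pr[[2]], df = res$df,
        method = cfg$threshold$method, alpha_fwe = cfg$threshold$alpha_fwe,
        t_star = cl$t_star, n_clusters = nrow(cl$table)))
      rows[[length(rows) + 1L]] <- tibble(
        seed = seed$name, reference = pr[[1]], comparison = pr[[2]],
        n_clusters = nrow(cl$table),
        path = file.path(out, fname))
    }
  }
  res <- bind_rows(rows)
  scn_log(sprintf("wrote %d contrast tables into %s", nrow(res), out))
  invisible(res)
}

#' Pipeline stage: extent trajectories and figures
#'
#' Reads the thresholded maps written by [scn_map()], counts ipsilateral /
#' contralateral / midline / whole-brain voxels per (seed, group), tags each
#' seed's trajectory shape, and writes `trajectory.tsv` plus per-seed bar
#' charts under `output_dir/summary/`.
#'
#' @inheritParams scn_simulate
#' @return The trajectory tibble, invisibly.
#' @export
scn_summarize <- function(config) {
  cfg <- read_run_config(config)
  seeds <- resolve_seeds(cfg)
  mapdir <- file.path(cfg$output_dir, "maps")
  if (!dir.exists(mapdir)) {
    abort("map outputs not found; run the `map` stage before `summarize`")
  }
  rows <- list()
  for (si in seq_len(nrow(seeds))) {
    seed <- seeds[si, ]
    for (g in cfg$groups) {
      p <- file.path(mapdir, paste0(seed$name, "_", g, "_thresholded.nii.gz"))
      if (!file.exists(p)) {
        abort(sprintf("missing map output for seed '%s' group '%s'; rerun the map stage",
                      seed$name, g))
      }
      img <- read_gm_nifti(p)
      rows[[length(rows) + 1L]] <-
        count_extent(img$data > 0.5, seed, img$affine, group = g)
    }
  }
  traj <- trajectory_table(bind_rows(rows), group_order = cfg$groups,
                           flat_tol = cfg$flat_tol)
  out <- file.path(cfg$output_dir, "summary")
  render_summary(traj, cluster_tables = NULL, out_dir = out)
  write_sidecar(file.path(out, "provenance.json"), cfg,
                list(stage = "summarize", n_rows = nrow(traj)))
  scn_log(sprintf("trajectory table with %d rows written to %s", nrow(traj), out))
  invisible(traj)
}
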