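#' Family-wise-error thresholding specification
#'
#' Height (and optionally extent) control of the voxel-wise t maps at
#' `alpha_fwe`. Two methods are offered: closed-form Bonferroni over the
#' in-mask voxel count, and Freedman-Lane permutation max-T, which respects
#' the spatial dependence of smoothed maps. Extent control is either a fixed
#' minimum cluster size `extent_k`, or (with the permutation method and
#' `extent_alpha` set) the FWE quantile of the max-cluster-size permutation
#' distribution at the cluster-forming height threshold.
#'
#' @param alpha_fwe Family-wise alpha in (0, 1); default 0.05.
#' @param method `"bonferroni"` or `"permutation_maxT"`.
#' @param extent_k Minimum cluster size in voxels (default 0 = height only).
#' @param extent_alpha Optional cluster-extent FWE alpha (permutation only).
#' @param n_permutations Number of permutations (>= 100), identity included.
#' @param rng_seed Integer seed for the permutation stream.
#' @return An `scn_threshold_spec`.
#' @export
threshold_spec <- function(alpha_fwe = 0.05,
                           method = c("bonferroni", "permutation_maxT"),
                           extent_k = 0L, extent_alpha = NULL,
                           n_permutations = 1000L, rng_seed = 1L) {
  method <- match.arg(method)
  if (!is.numeric(alpha_fwe) || alpha_fwe <= 0 || alpha_fwe >= 1) {
    abort("alpha_fwe must lie in (0, 1)")
  }
  if (extent_k < 0) abort("extent_k must be >= 0")
  if (method == "permutation_maxT" && n_permutations < 100L) {
    abort("n_permutations must be >= 100 for permutation_maxT")
  }
  structure(list(alpha_fwe = alpha_fwe, method = method,
                 extent_k = as.integer(extent_k), extent_alpha = extent_alpha,
                 n_permutations = as.integer(n_permutations),
                 rng_seed = as.integer(rng_seed)),
            class = "scn_threshold_spec")
}

# finite in-mask one-sided stat values of a statmaps-like object
inmask_finite_t <- function(stat) {
  tv <- stat$t[stat$mask$mask]
  tv[is.finite(tv)]
}

#' Critical t value under family-wise error control
#'
#' Bonferroni: the one-sided Student-t quantile at `1 - alpha/N` with the
#' model's residual df, N = number of finite in-mask voxels. Permutation
#' max-T: the `1 - alpha` empirical quantile of the maximum t statistic over
#' Freedman-Lane permutations of the (confound-residualised) covariate of
#' interest against confound-residualised data; the identity permutation is
#' always included.
#'
#' @param stat An [scn_statmaps] (or interaction) object.
#' @param spec An [threshold_spec()].
#' @param cohort,design Required for the permutation method: the cohort and
#'   `scn_design` that produced `stat`.
#' @return Critical value `t_star` (scalar) with attribute `"maxT"` holding
#'   the permutation distribution when applicable.
#' @export
fwe_height_threshold <- function(stat, spec, cohort = NULL, design = NULL) {
  stopifnot(inherits(spec, "scn_threshold_spec"))
  tv <- inmask_finite_t(stat)
  N <- length(tv)
  if (N < 1L) abort("no finite in-mask statistics to threshold")
  if (spec$method == "bonferroni") {
    t_star <- qt(1 - spec$alpha_fwe / N, df = stat$df, lower.tail = TRUE)
    scn_log(sprintf("FWE height threshold (bonferroni): alpha=%g, N=%d, df=%d, t*=%.4f",
                    spec$alpha_fwe, N, stat$df, t_star))
    t_star
  } else {
    if (is.null(cohort) || is.null(design)) {
      abort("permutation_maxT needs `cohort` and `design`")
    }
    if (spec$n_permutations * spec$alpha_fwe < 1) {
      abort("too few permutations for the requested alpha")
    }
    maxT <- permutation_max_t(cohort, design, stat$mask,
                              n_perm = spec$n_permutations,
                              rng_seed = spec$rng_seed)
    t_star <- stats::quantile(maxT, 1 - spec$alpha_fwe, type = 1, names = FALSE)
    scn_log(sprintf("FWE height threshold (permutation max-T): alpha=%g, %d perms, t*=%.4f",
                    spec$alpha_fwe, spec$n_permutations, t_star))
    attr(t_star, "maxT") <- maxT
    t_star
  }
}

# Freedman-Lane residual permutation: residualise the covariate of interest
# and the data against the nuisance part of the design, then permute the
# residualised covariate. Returns the max one-sided t per permutation (the
# first entry is the identity permutation, i.e. the observed max t).
permutation_max_t <- function(cohort, design, mask, n_perm, rng_seed,
                              interest_col = NULL) {
  interest_col <- interest_col %||% which(design$contrast != 0)
  if (length(interest_col) != 1L) abort("permutation requires a single-column contrast")
  X <- design$X
  Z <- X[, -interest_col, drop = FALSE]   # nuisance (includes intercept)
  x <- X[, interest_col]
  qrZ <- qr(Z)
  rx <- qr.resid(qrZ, x)
  idx <- which(as.vector(mask$mask))
  Y <- t(matrix(cohort$data, ncol = n_subjects(cohort))[idx, , drop = FALSE])
  RY <- qr.resid(qrZ, Y)
  if (sum(rx^2) == 0) abort("covariate of interest is collinear with the nuisance design")
  keep <- colSums(RY^2) > 0
  RY <- RY[, keep, drop = FALSE]
  if (ncol(RY) == 0L) abort("no voxel with residual variance to permute")
  df <- design$df

  # unit-variance columns so the permuted statistic is a plain correlation
  ry_ss <- sqrt(colSums(RY^2))
  RYn <- sweep(RY, 2, ry_ss, "/")
  rx_ss <- sqrt(sum(rx^2))

  n <- length(rx)
  withr_seed(rng_seed, {
    perms <- cbind(seq_len(n),
                   replicate(n_perm - 1L, sample.int(n)))
  })
  Xp <- matrix(rx[perms], nrow = n) / rx_ss
  r <- crossprod(RYn, Xp)                  # V x n_perm partial correlations
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  tmat <- r * sqrt(df) / sqrt(1 - r^2)
  apply(tmat, 2, max)
}

# evaluate expr with a temporary RNG state seeded at `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# 26-neighbourhood offsets (half set: positive lexicographic direction)
offsets26_half <- function() {
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  off[off[, 3] > 0 | (off[, 3] == 0 & (off[, 2] > 0 | (off[, 2] == 0 & off[, 1] > 0))), ,
      drop = FALSE]
}

# label suprathreshold voxels into 26-connected components via igraph
label_components <- function(supra) {
  d <- dim(supra)
  idx <- which(supra)
  labels <- array(0L, d)
  if (!length(idx)) return(list(labels = labels, n = 0L))
  rank <- array(0L, d)
  rank[idx] <- seq_along(idx)
  ijk <- arrayInd(idx, d)
  off <- offsets26_half()
  edges <- vector("list", nrow(off))
  for (o in seq_len(nrow(off))) {
    nb <- sweep(ijk, 2, off[o, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
    hit <- supra[nb_lin]
    if (!any(hit)) next
    edges[[o]] <- cbind(rank[idx[ok][hit]], rank[nb_lin[hit]])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  # renumber components deterministically by their lowest linear voxel index
  first_idx <- vapply(split(idx, comp$membership), min, numeric(1))
  relabel <- rank(first_idx, ties.method = "first")
  labels[idx] <- relabel[comp$membership]
  list(labels = labels, n = comp$no)
}

#' Threshold a t map and label suprathreshold clusters
#'
#' Voxels with `t > t_star` (one-sided, positive) are labeled into
#' 26-connected components; clusters smaller than `spec$extent_k` are
#' removed. Each surviving cluster is summarised by its peak (the in-cluster
#' voxel of maximal t; ties broken by lowest linear voxel index) converted to
#' MNI mm, its extent in voxels, and its max t.
#'
#' @param stat An [scn_statmaps] (or interaction) object.
#' @param t_star Finite height threshold.
#' @param spec An [threshold_spec()] (supplies `extent_k`).
#' @return An `scn_clusters`: list with `binary` (logical 3D array) and
#'   `table` (tibble with columns `x`, `y`, `z`, `hemisphere`, `region`,
#'   `voxel_size`, `maxT`, sorted by descending size then max t).
#' @export
threshold_and_cluster <- function(stat, t_star, spec = threshold_spec()) {
  if (!is.finite(t_star)) abort("t_star must be finite")
  tmap <- stat$t
  supra <- !is.na(tmap) & tmap > t_star & stat$mask$mask
  lab <- label_components(supra)
  rows <- list()
  keep_map <- array(FALSE, dim(supra))
  if (lab$n > 0) {
    for (cl in seq_len(lab$n)) {
      vox <- which(lab$labels == cl)
      if (length(vox) < spec$extent_k) next
      tv <- tmap[vox]
      tv[!is.finite(tv)] <- .Machine$double.xmax   # zero-residual voxels peak last of ties
      peak <- vox[which.max(tv)]                   # which.max: first max = lowest index
      ijk0 <- arrayInd(peak, dim(supra)) - 1L
      mm <- voxel_to_mni(as.numeric(ijk0), stat$affine)
      keep_map[vox] <- TRUE
      rows[[length(rows) + 1L]] <- tibble(
        x = mm[1], y = mm[2], z = mm[3],
        hemisphere = hemisphere_of(mm[1]),
        region = "",
        voxel_size = length(vox),
        maxT = max(tmap[vox])
      )
    }
  }
  tab <- if (length(rows)) {
    bind_rows(rows) %>% arrange(desc(.data$voxel_size), desc(.data$maxT))
  } else {
    empty_cluster_table()
  }
  structure(list(binary = keep_map, table = tab, t_star = t_star,
                 affine = stat$affine),
            class = "scn_clusters")
}

empty_cluster_table <- function() {
  tibble(x = numeric(), y = numeric(), z = numeric(),
         hemisphere = character(), region = character(),
         voxel_size = integer(), maxT = numeric())
}

hemisphere_of <- function(x_mm) {
  ifelse(x_mm > 0, "right", ifelse(x_mm < 0, "left", "midline"))
}

#' @export
print.scn_clusters <- function(x, ...) {
  cat(sprintf("<scn_clusters> t* = %.4f, %d cluster(s), %d voxels\n",
              x$t_star, nrow(x$table), sum(x$binary)))
  if (nrow(x$table)) print(x$table)
  invisible(x)
}

#' Cluster-extent FWE threshold by permutation
#'
#' The minimum cluster size controlling cluster-level FWE at
#' `spec$extent_alpha`: the `1 - extent_alpha` quantile of the maximum
#' 26-connected cluster size observed over Freedman-Lane permutations at the
#' cluster-forming height threshold `t_star`.
#'
#' @inheritParams fwe_height_threshold
#' @param t_star Cluster-forming height threshold.
#' @return Integer extent threshold (voxels).
#' @export
fwe_extent_threshold <- function(stat, spec, t_star, cohort, design) {
  stopifnot(inherits(spec, "scn_threshold_spec"))
  alpha <- spec$extent_alpha %||% spec$alpha_fwe
  interest_col <- which(design$contrast != 0)
  X <- design$X
  Z <- X[, -interest_col, drop = FALSE]
  qrZ <- qr(Z)
  rx <- qr.resid(qrZ, X[, interest_col])
  idx <- which(as.vector(stat$mask$mask))
  Y <- t(matrix(cohort$data, ncol = n_subjects(cohort))[idx, , drop = FALSE])
  RY <- qr.resid(qrZ, Y)
  ry_ss <- sqrt(colSums(RY^2))
  ry_ss[ry_ss == 0] <- Inf
  RYn <- sweep(RY, 2, ry_ss, "/")
  rx_ss <- sqrt(sum(rx^2))
  n <- length(rx); df <- design$df
  d3 <- dim(stat$mask$mask)
  withr_seed(spec$rng_seed, {
    perms <- cbind(seq_len(n), replicate(spec$n_permutations - 1L, sample.int(n)))
  })
  max_sizes <- integer(spec$n_permutations)
  for (pi in seq_len(spec$n_permutations)) {
    r <- drop(crossprod(RYn, rx[perms[, pi]] / rx_ss))
    r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    tv <- r * sqrt(df) / sqrt(1 - r^2)
    supra <- array(FALSE, d3)
    supra[idx] <- tv > t_star
    lab <- label_components(supra)
    max_sizes[pi] <- if (lab$n > 0) max(tabulate(lab$labels[lab$labels > 0L])) else 0L
  }
  k <- stats::quantile(max_sizes, 1 - alpha, type = 1, names = FALSE)
  scn_log(sprintf("FWE extent threshold (permutation): alpha=%g, k*=%d voxels", alpha, k))
  as.integer(k)
}

#' Write / read a cluster table as TSV
#'
#' Columns `x`, `y`, `z`, `hemisphere`, `region` (blank allowed),
#' `voxel_size`, `maxT`; deterministic row order (descending size, then
#' descending max t). An empty table yields a header-only file.
#'
#' @param table Cluster tibble (or `scn_clusters`).
#' @param path Output TSV path.
#' @return `path` invisibly; `read_cluster_table()` returns the tibble.
#' @export
write_cluster_table <- function(table, path) {
  if (inherits(table, "scn_clusters")) table <- table$table
  cols <- c("x", "y", "z", "hemisphere", "region", "voxel_size", "maxT")
  extra <- setdiff(names(table), cols)
  tab <- table[, c(intersect(c("contrast", "seed", "group"), extra), cols)]
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname write_cluster_table
#' @export
read_cluster_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    hemisphere = readr::col_character(),
                    region = readr::col_character(),
                    voxel_size = readr::col_integer()
                  )) %>%
    mutate(region = ifelse(is.na(.data$region), "", .data$region))
}
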