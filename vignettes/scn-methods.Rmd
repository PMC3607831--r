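---
title: "Mapping structural covariance networks: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping structural covariance networks: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(scnmapr)
```

## What the package computes

A structural covariance network (SCN) is the set of voxels whose gray-matter
(GM) volume covaries, across subjects, with the mean GM volume of a small
seed region. `scnmapr` takes preprocessed VBM inputs — per-subject modulated,
normalised GM maps on one grid, plus a covariates table — and produces, per
seed and group: voxel-wise beta / t / partial-correlation maps,
FWE-thresholded cluster tables, between-group covariance-slope contrast
maps, and hemispheric extent counts with trajectory shape tags. Everything
upstream of the modulated GM maps (segmentation, normalisation, modulation)
is out of scope and assumed done.

## The seed-covariance model

For a seed sphere $j$ and voxel $i$, each group is fit separately by
ordinary least squares:

$$V_i = \beta_0 + \beta_1 V_j + \beta_2\,\mathrm{gender} + \varepsilon,$$

where $V_j$ is the subject's mean GM over the sphere's voxels. Gender is the
only default nuisance covariate: the groups have unequal gender splits, so
its effect on covariance patterns must be removed, whereas age is *not*
adjusted within groups (group membership is the age variable; a continuous
age adjustment inside a narrow group would absorb the quantity under study).
An `age` confound can still be requested via `confounds = c("gender",
"age")`.

Estimation is exact OLS through one QR decomposition of the design applied
to all in-mask voxels simultaneously; results are therefore independent of
voxel order and of the `block_size` memory knob, and they are checked in the
test suite against an independent normal-equations solver at $10^{-8}$
relative tolerance. The contrast t statistic uses $\mathrm{df} = n - p$, and
the reported partial correlation is $r = t/\sqrt{t^2 + \mathrm{df}}$.
Voxels with numerically zero residual variance (possible in synthetic data)
receive a signed-infinite t, are logged, count as $|r| = 1$, and are
excluded from FWE calibration.

Positive covariance is the scientific target: `positive_covariance_map()`
discards non-positive t values before thresholding, making the subsequent
test one-sided.

## Seeds

`default_seed_set()` carries the eight canonical network seeds (primary
visual, auditory and motor cortex; speech and semantic language areas;
salience, executive-control and default-mode association cortex) as 4 mm
spheres at fixed MNI coordinates; `flip_seed()` mirrors a seed across the
midline by negating x, and is an involution. Sphere membership is a closed
ball on voxel *centers* (distance $\le$ radius), which is deterministic and
matches common ROI-toolbox behaviour; membership is validated against
exhaustive enumeration in the tests. Seed signals are extracted from the
same (already smoothed) images used voxel-wise — the inputs are assumed
smoothed once upstream, and extracting from a differently processed copy
would break the interpretation of seed autocorrelation. If a sphere pokes
outside the analysis mask, all its on-grid voxels are still averaged, with a
logged warning: the ROI is defined geometrically, not by the mask.

## Masking, smoothing and coordinates

The analysis mask is an explicit, logged parameter: voxels whose
across-subject mean GM exceeds `threshold` (default 0.1 in the units of the
modulated maps). Nothing is masked implicitly.

`smooth_gaussian()` implements separable Gaussian convolution with per-axis
kernel sigma $\mathrm{FWHM}/\mathrm{voxel}/(2\sqrt{2\ln 2})$ (so 12 mm FWHM
on 2 mm voxels gives 2.5479 voxels), kernels truncated at $6\sigma$ and
discretely normalised to unit sum, and zero padding at the boundary — GM
maps are zero outside the head, so zero padding is the physically sensible
boundary condition; an impulse deeper than the truncation radius preserves
total mass to $10^{-6}$.

Voxel indices are 0-based internally; every user-facing coordinate is MNI
mm through the image affine. `mni_grid_2mm()` provides the standard
91×109×91 grid for work at full MNI extent.

## Family-wise error control

Two height-threshold methods share one contract (FWE $\alpha$, default
0.05):

* **Bonferroni** — closed form: the one-sided Student-t quantile at
  $1-\alpha/N$ with $N$ the number of finite in-mask statistics.
  Conservative under the positive spatial dependence of smoothed maps.
* **Permutation max-T** — Freedman–Lane: the covariate of interest and the
  data are residualised against the nuisance design (intercept + confounds),
  the residualised covariate is permuted, and the maximum one-sided t over
  voxels is recorded per permutation; the threshold is the $1-\alpha$
  empirical quantile. The identity permutation is always included, so the
  corrected p-value can never fall below $1/n_\mathrm{perm}$. The scheme
  respects exchangeability under nuisance covariates and adapts to spatial
  dependence.

Extent control is a fixed minimum cluster size `extent_k` by default (0 =
height-only); with the permutation method, `extent_alpha` switches to the
FWE quantile of the max-cluster-size permutation distribution at a given
cluster-forming threshold. Random-field-theory thresholds, FDR and TFCE are
deliberately out of scope.

Clusters are 26-connected components (fixed for determinism; the adjacency
is built in-package and components are delegated to igraph, while the test
oracle is an independent flood fill). Cluster peaks are the in-cluster
maximum t, ties broken by lowest linear voxel index; tables are sorted by
descending size, then descending max t.

## Between-group slope contrasts

For a group pair (reference, comparison), both groups are pooled and fit
with

$$V_i = b_0 + b_1 V_j + b_2\,\mathrm{Group} + b_3\,(V_j \times
\mathrm{Group}) + \mathrm{gender} + e,$$

Group treatment-coded 0/1, a single pooled residual variance (one
$\varepsilon$ term), and $\mathrm{df} = n_\mathrm{pooled} - 4 -
\#\mathrm{confounds}$. $b_3$ is the slope difference; the per-group slopes
are recovered as $b_1$ (reference) and $b_1 + b_3$ (comparison). Only the
two groups being compared enter the fit — the two-level Group model implies
exactly that — and each group must contribute at least 5 subjects. The
chronologically younger group is the natural reference, so a "young >
older" contrast is the one-sided test $b_3 < 0$ (`direction =
"ref_gt_comp"`); two-sided tests use $\alpha/2$ per tail for Bonferroni and
max-|T| for permutation. Gender is retained as a confound here for
consistency with the covariance maps. `slope_scatter_data()` +
`autoplot()` reproduce the per-group slope scatter at a contrast peak
(seed-sphere mean against a 4 mm sphere at the peak).

## Extent trajectories

`count_extent()` classifies each suprathreshold voxel by the sign of its
voxel-center MNI x relative to the seed's hemisphere; midline voxels (x
exactly 0) are reported separately and included in whole-brain, so
ipsilateral + contralateral + midline = whole-brain always. Hemisphere
assignment by x-sign (not an anatomical mask) keeps the flip-seed symmetry
exact: counting a mirrored map with the flipped seed swaps the two counts.

`trajectory_table()` tags each seed's whole-brain trajectory from the signs
of successive changes, where a change counts as flat when its magnitude is
at most `flat_tol` (default 10%) of the trajectory's **maximum** count.
The maximum — the plot's dynamic range — is the right yardstick at package
scale: a desk-scale network whose stable phase is a ~34-voxel seed core can
wobble by a few voxels of threshold-crossing halo between groups, which is
noise relative to a 200-voxel young-group extent but would exceed 10% of
the small preceding count. Sign patterns map to tags: (−,0) "contracting
then flat", (+,−) "inverted-V", (−,+) "V", (0,0) "flat", and so on.

## The synthetic cohort generator

`generate_cohort()` draws

$$X_s(v) = \mu(v) + \sum_k A_{k,g(s)}(v)\, f_{k,s} +
\gamma(v)\,\mathrm{gender}_s + \epsilon_s(v),$$

with independent standard-normal network factors $f_{k,s}$, a smooth
super-Gaussian "head" baseline $\mu$, sphere-union loading maps $A$ with
per-sphere, per-group amplitudes, a spherical gender-confound map
$\gamma$, and Gaussian noise of sd `noise_sigma` smoothed at
`noise_fwhm_mm`. Noise smoothing matters: spatial autocorrelation is what
separates Bonferroni from permutation thresholds, so it is on by default
(6 mm, a compromise between realism and desk-scale grids; it also shrinks
the marginal noise sd below `noise_sigma` — at 6 mm FWHM on 2 mm voxels by
a factor of about 0.10). Everything is determined by `rng_seed`
(covariates, factors and noise use separate derived streams), and a spec
written to JSON regenerates the identical cohort.

Default cohort structure mirrors the study design the analysis targets:
three age groups Y (18–23), M (30–58), O (61–89) of 80 subjects with
female/male splits 50/30, 50/30 and 55/25.

`planted_scn_scenario()` is the validation preset, on a compact
24×28×24 grid at 2 mm: two "cognitive-like" networks whose seed sphere
(amplitude 0.15) is loaded in every group but whose distal spheres
(0.13/0.12) are loaded only in Y — extent contracts Y→M and stays flat
M→O — and a "motor-like" network loaded only at its right seed in Y and O
but gaining a contralateral homologue (0.13) in M, an inverted-V profile.
Amplitudes of ~0.15 against an effective smoothed-noise sd of ~0.10 give
voxel–seed correlations around 0.7–0.8, typical of strong real SCN nodes.

What the generator does **not** emulate: cortical anatomy and folding,
segmentation and registration error, factor cross-correlations (off by
default, configurable), non-Gaussian noise, or longitudinal structure.
Passing tests therefore demonstrate correctness of the estimators,
error control under smooth Gaussian dependence, and recoverability of
planted effects — not robustness to real-data artefacts.

## Validation sizes and numerical choices

The test suite and the acceptance script validate at desk scale: null
calibration on 200 cohorts of 40 subjects on a $16^3$ grid with 250
permutations each; planted-network recovery on 50 replicates of the preset
at its full 80 subjects per group (the two groups the contrast uses); the
end-to-end pipeline at the preset's full 240 subjects. These sizes are the
package's validation choices and complete in about a minute each.

Other fixed numerical decisions: kernel truncation at $6\sigma$;
closed-ball sphere membership with a $10^{-9}$ slack on the squared radius
(guards float ties at exact-boundary voxels); treatment coding with the
first sorted level as reference for binary covariates (the seed and
interaction contrasts are invariant to this choice, verified by test);
NaN input voxels rejected by default or zeroed-and-logged on request;
permutation quantiles of type 1 (a genuine order statistic). No global
signal normalisation or grand-mean scaling is applied anywhere — modulated
non-linear-only GM maps are already brain-size corrected, and silent
rescaling would contaminate the covariance structure under study.

## Known limitations

* Bonferroni is conservative under smoothing; the permutation method is the
  calibrated choice but costs $n_\mathrm{perm}$ refits (vectorised, still
  fast at typical mask sizes).
* Cluster tables carry empty `region` labels; anatomical naming requires an
  atlas lookup that is deliberately out of scope.
* The interaction model assumes one pooled residual variance across both
  groups; strongly heteroscedastic groups would need a Welch-type variant
  that the printed model does not define.
* Hemispheric counts use the x-sign convention, which differs from an
  anatomical hemisphere mask near the midline.
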