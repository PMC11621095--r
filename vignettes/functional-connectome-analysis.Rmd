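---
title: "Graph-theoretic group analysis of functional connectomes with fconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-theoretic group analysis of functional connectomes with fconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fconn)
```

## The analysis

`fconn` implements the standard graph-theoretic pipeline for comparing the
topological organization of resting-state functional brain networks between
two groups (here: patients with anterior ischemic optic neuropathy versus
healthy controls, but nothing in the code is disease-specific):

1. **ROI-level denoising.** Inputs are per-subject matrices of regional mean
   BOLD series (volumes x 90 AAL regions, TR = 1 s, 400 volumes of which the
   first 10 are discarded). Head-motion QC excludes subjects whose maximum
   translation exceeds 1.5 mm or maximum rotation exceeds 1.5 degrees on any
   axis. Nuisance regression removes an intercept, a linear trend, the
   Friston-24 motion expansion and the global signal by ordinary least
   squares, and an ideal frequency-domain filter restricts the signal to
   0.01-0.08 Hz. Framewise displacement is computed in the convention of a
   50 mm head sphere (`FD_t = sum |d translation| + 50 * sum |d rotation|`),
   and its subject mean enters the group model as a covariate.
2. **Network construction.** Pearson correlations between all pairs of the
   90 regional series give a 90 x 90 matrix; Fisher's r-to-z transform is
   applied off-diagonal. Each weighted connectome is binarized at every
   sparsity `S` of the grid 0.032, 0.042, ..., 0.492 (47 levels) by keeping
   the `k = round(S * 4005)` most positive z values, so all subjects have
   identical edge counts at each level.
3. **Graph metrics.** At every sparsity: clustering coefficient `Cp`,
   characteristic path length `Lp`, global and local efficiency
   `Eglob`/`Eloc`, and nodal degree, efficiency, betweenness and local
   efficiency. Small-world indices `gamma = Cp/Cp_rand`,
   `lambda = Lp/Lp_rand` and `sigma = gamma/lambda` are computed against
   degree-preserving (double-edge-swap) random networks.
4. **Group inference.** Every metric is summarized per subject as the
   trapezoidal area under its curve across the sparsity grid (AUC), and
   groups are compared by the t statistic of the group coefficient in an
   ordinary-least-squares model with age, sex, education and mean FD as
   covariates. Global metrics are tested uncorrected at `p < 0.05`; nodal
   metrics are Bonferroni-corrected within each metric (family of 90 nodes).
5. **Network-based statistic (NBS).** The same GLM is fitted per connection
   (4005 Fisher-z edges); connections exceeding a primary threshold form
   supra-threshold graphs whose connected components are tested by
   permutation of group labels: each component's family-wise corrected p is
   `(1 + #{permutation max component size >= observed}) / (1 + n_perm)`.

## Why AUC over a sparsity sweep

Any single binarization threshold is arbitrary, and groups can differ in
overall correlation strength; fixing sparsity rather than correlation value
equates network density across subjects, and integrating each metric over
the whole sweep yields a threshold-free per-subject summary. The lower grid
bound (0.032) keeps the mean degree above the fragmentation regime; the
upper bound (0.492) stays below the density at which binary networks lose
topological specificity.

## Conventions and numerical choices

Several conventions differ between toolboxes, so the ones fixed here are
stated explicitly:

* `Cp` and `Eloc` average over **all** N nodes; isolated nodes and nodes of
  degree < 2 contribute 0.
* `Lp` on a fragmented graph is the mean over connected ordered pairs, with
  a warning carrying the component count. The low end of the sparsity grid
  can fragment networks, and this keeps `Lp` finite while matching common
  toolbox behaviour; `Eglob` handles disconnection natively (`1/Inf = 0`).
* Nodal local efficiency is the global efficiency of the subgraph induced by
  a node's neighbours.
* Betweenness is unnormalized; only group contrasts are used downstream and
  any normalization constant cancels in the t statistic.
* Binarization ranks signed Fisher-z values (most positive correlations are
  kept), with `round` half-away-from-zero for the edge count and
  lexicographic (i, j) tie-breaking, so results are deterministic and
  invariant to monotone weight transforms. Magnitude ranking (`rank =
  "abs"`) is available as an option.
* The AUC uses the trapezoid rule on the exact grid values (generated from
  integer indices to avoid floating-point drift).
* Null networks: 1000 degree-matched random networks per network by default
  (10 x edge-count attempted swaps each); the validation suite uses 100 per
  network to keep runtimes practical, which changes `Cp_rand`/`Lp_rand`
  estimates by well under 1%.
* The NBS primary threshold defaults to an edge-level `p < 0.01`
  (two-tailed), applied within each signed tail; increased
  (patient > control) and decreased (patient < control) connectivity are
  analysed as two separate one-tailed NBS runs, each with its own
  family-wise control. The `+1` permutation-p convention keeps corrected p
  values strictly positive. The number of permutations defaults to 5000;
  the validation suite uses 1000 (and 400 for the 20-seed error-control
  study).
* Covariates are mean-centered before fitting (the group t is unchanged;
  conditioning improves). A zero-variance outcome returns `t = 0, p = 1`
  with a warning instead of propagating NaN.
* Pipeline order is discard -> nuisance regression/detrend -> band-pass;
  residualization is idempotent. Whether mean FD additionally enters the
  subject-level nuisance model is configurable
  (`include_mean_fd`); the default uses it only at the group level.
* The global signal is the mean over the 90 regional series; no voxel data
  exists at the ROI stage, so this deliberately deviates from voxel-wise
  global-signal regression.

## The synthetic cohort generator

No patient data are distributed, so `synth_cohort` generates a two-group
cohort with the statistical structure the analysis assumes. Every region's
series is a linear mix of band-limited Gaussian latent processes

```
x_i = cw * M[module(i)] + cl * L_i + cb * G + (planted terms) + noise_sd * eps_i
```

where `M` are six module signals **interleaved** over the region index (so
within-module edges act as long-range shortcuts), `L_i` is a ring-lattice
neighbourhood field (kernel-smoothed white latents whose correlation decays
with region-index distance, supplying clustered lattice edges), and `G` is a
global signal. The mix is band-limited with the same filter the
preprocessing module exposes, so the generator's spectrum matches the
analysed band. Covariance is positive semi-definite by construction (an
explicit factor model); couplings outside `[0, 1)` are rejected with an
error naming the offending parameter.

The lattice + interleaved-module geometry is deliberate: binarizing such a
covariance at any sparsity yields a Watts-Strogatz-like graph (clustered
lattice neighbourhoods plus module shortcuts), and the default couplings
were chosen, once, so that group-mean networks of both groups satisfy
`gamma > 1`, `sigma > 1` and `lambda` within about 1.2 of unity over the
entire default grid. Defaults: within-module coupling 0.51 (control) /
0.455 (patient), lattice coupling 0.62 / 0.575, global coupling 0.18,
lattice kernel length 1.6 regions, region noise SD 0.5.

Three group effects can be planted:

* **Reduced patient coupling** (the within-module and lattice defaults
  above), which lowers patient `Cp` and `Eloc` at matched sparsity.
* **Planted edges**: 15 region pairs, each with its own shared latent that
  is coupled (0.65) in only one group - five occipito-parietal pairs present
  only in patients (increased connectivity) and ten fronto-temporal pairs
  present only in controls (decreased in patients). These are what NBS
  should localize.
* **A planted nodal deficit**: region 42 (right amygdala) anchors a
  five-node clustered neighbourhood (a hub latent over the node and its
  ring neighbours within distance 2, coupling 0.8) that exists in both
  groups; in patients the node's couplings - including the hub coupling -
  are attenuated (default attenuation 0, i.e. full decoupling), which
  selectively depresses its nodal local efficiency. The hub is needed to
  make the deficit detectable: without an elevated, stable control-side
  neighbourhood, the node's local-efficiency AUC difference is swamped by
  the sampling variability of band-limited correlation estimates
  (roughly 55 effective degrees of freedom in a 390-volume, 0.01-0.08 Hz
  series).

Planted-effect magnitudes are free parameters of the generator, not
estimates of any real effect size. Covariates are synthetic (age ~
N(54.6, 9.9) for patients / N(42.5, 10.2) for controls, sex ~
Bernoulli(0.5), education ~ N(12, 3) years) and exist purely to exercise
covariate adjustment. Motion is a stationary AR(1) walk (translations with
stationary SD `motion_scale` mm; rotations scaled by 1/50), so QC
exclusions can be provoked by raising `motion_scale`.

What the generator does **not** emulate: voxel-level structure and spatial
smoothing, physiological noise spectra, hemodynamic nonlinearity,
inter-subject anatomical variability, distance-dependent motion artefacts,
or realistic hub/rich-club architecture. Passing recovery tests on this
cohort therefore demonstrates the pipeline's correctness and sensitivity
under a known truth - not performance guarantees on real fMRI data.

## Worked example

```{r example, eval = FALSE}
spec <- cohort_spec(n_patients = 15, n_controls = 12, seed = 42)
cohort <- generate_cohort(spec)
subjects <- lapply(cohort$subjects, preprocess_subject)
conns <- lapply(subjects, function(s) build_connectome(s$timeseries))
names(conns) <- vapply(cohort$subjects, `[[`, character(1), "subject_id")

manifest <- cohort_manifest(cohort)
manifest$mean_fd <- vapply(subjects, `[[`, numeric(1), "mean_fd")
design <- design_matrix(manifest)

grid <- sparsity_grid()
mt <- metric_table(conns, grid, nodal = TRUE, n_nulls = 0)
auc <- auc_table(mt, grid)
test_global(auc, design, metrics = c("Cp", "Eloc"))
nbs_permutation_test(conns, design, tail = "patient_lt",
                     n_permutations = 1000, seed = 99)
```

The same flow, end to end with all outputs written to disk, is
`run_all(run_config(seed = 42))`; a thin command-line wrapper lives at
`inst/scripts/fconn-pipeline.R`.

## Problem sizes used in validation

The test-suite simulations are scaled to desk hardware as the package's own
choice of study size: small-world recovery uses the full default cohort
(30 + 24) with 100 nulls per network; planted-effect recovery uses 15 + 12
subjects with 1000 NBS permutations; error control uses 20 independent null
cohorts of 15 + 12 with 400 permutations per NBS run. Graph-metric
correctness does not depend on simulation at all - it is checked against
independent brute-force oracles (Floyd-Warshall distances, explicit
triangle enumeration, exhaustive shortest-path counting, union-find
components) on dozens of random small graphs plus closed-form cases.

## Known limitations

* The pipeline starts at ROI series; no voxel-level processing (slice
  timing, realignment, normalization, smoothing) is included.
* Only binary, positively-thresholded networks are analysed; weighted
  metrics, modularity and rich-club coefficients are out of scope.
* Whether band-pass should precede or follow nuisance regression is
  ambiguous in common practice; the order fixed here (regression first)
  removes motion/global variance before the spectral cut.
* The Bonferroni family for nodal tests is defined per metric (90 nodes);
  a stricter 90 x 4 family can be requested via the `family` argument.
* NBS component size is counted in edges (extent); intensity-weighted
  variants are not implemented.
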