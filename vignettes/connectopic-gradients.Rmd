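---
title: "Local-global connectopic gradient mapping: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local-global connectopic gradient mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(congradr)
```

## The model

Connectopic gradient mapping summarizes how the functional connectivity (FC)
profile of a seed region (for example, the thalamus) changes from voxel to
voxel, as a small number of smoothly varying spatial modes ("gradients")
rather than discrete parcels. Given a seed timeseries matrix
$A \in \mathbb{R}^{t \times m}$ and a target timeseries matrix
$B \in \mathbb{R}^{t \times n}$ (typically the neocortex, $n \gg m$), the
pipeline is:

1. **Fingerprints.** Each seed voxel receives a connectivity fingerprint —
   a row of $C$, its vector of Pearson correlations with target features.
   Four variants are supported:
   * `original`: $C = \mathrm{corr}(A, \tilde B) \in \mathbb{R}^{m \times p}$
     where $\tilde B = U\Sigma$ are the SVD spatial modes of the
     (column-standardized) target, $p = \min(t-1, n)$;
   * `rescaled`: $C = \mathrm{corr}(A, \tilde B)\,\Sigma$ — the correlation
     step normalizes away each mode's singular value, treating dominant and
     negligible modes equally; multiplying back by $\Sigma$ restores the
     target's variance structure;
   * `voxelwise`: $C = \mathrm{corr}(A, B) \in \mathbb{R}^{m \times n}$,
     the lossless seed-to-target FC without any SVD;
   * `within_seed`: no fingerprints — the seed's own $m \times m$ Pearson
     FC matrix is used directly as the similarity input.
2. **Similarity.** $S_{ij}$ compares fingerprints $i$ and $j$ (cosine by
   default, two-profile $\eta^2$ as an option).
3. **Embedding.** A manifold method (Laplacian eigenmap, diffusion map
   embedding, or PCA) applied to the row-sparsified similarity matrix
   yields gradients $G \in \mathbb{R}^{m \times g}$ (default $g = 3$).
4. **Group analysis.** Individual similarity matrices are averaged into a
   group template; individual gradients are matched to the template
   (Hungarian assignment) and aligned (orthogonal Procrustes).

## The local-global equivalences

Two algebraic identities motivate the variant taxonomy, and double as the
package's strongest correctness checks. Write $\hat A$ for the seed matrix
with centered, unit-norm columns (Pearson correlation is the inner product
on such columns).

* **Original ≡ within-seed** (local). $\mathrm{corr}(A, U\Sigma) =
  \hat A^\top U$, because correlation divides out each mode's scale. When
  the centered target spans the full $(t-1)$-dimensional centered time
  space, $UU^\top$ is the identity on centered signals, so row inner
  products give $\hat A^\top U U^\top \hat A = \hat A^\top \hat A$ — the
  within-seed FC matrix. With the cosine measure (fingerprint row norms are
  all 1 here) the original-variant similarity matrix *equals* the
  within-seed FC matrix. The original pipeline therefore measures the
  seed's internal (local) connectome, not its embedding in the target.
* **Rescaled ≡ voxelwise** (global). $\tilde B V^\top = B$, so rescaled
  fingerprint row inner products are $\hat A^\top U\Sigma^2 U^\top\hat A =
  \hat A^\top BB^\top \hat A$, identical up to one global factor to the
  voxelwise row inner products — provided all target columns share a common
  norm. Cosine similarity removes the global factor, making the two
  similarity matrices equal. This identity is why ingestion z-scores
  *both* seed and target voxels (see below).

The test suite asserts both identities entrywise at `1e-8` on random and
on generated cohorts, and asserts that unaligned gradients from the paired
variants correlate at `>= 0.999` across all three manifold methods.

## Conventions and numerical choices

* **Ingestion.** Every voxel timeseries is z-scored (zero mean, unit SD)
  when a `timeseries_matrix` is built. Pearson-correlation fingerprints are
  invariant to this, and equal target column norms make the
  rescaled/voxelwise identity exact rather than approximate. Zero-variance
  voxels are rejected with an explicit message (volume extraction drops and
  logs them instead). The similarity step works from sufficient statistics
  accumulated over feature blocks, so the $m \times n$ fingerprint matrix
  never needs to be materialized beyond one block at a time; the blockwise
  and dense paths agree to `1e-12`.
* **Measure.** Cosine is the default because it turns both equivalences
  into exact identities; $\eta^2$ (on pointwise profile means, as in the
  classic formulation) is retained as an option.
* **Sparsification.** Per row, the top `ceiling((1 - sparsity) * (m - 1))`
  off-diagonal entries by value are kept (default sparsity 0.9, i.e. top
  10%), ties broken by column index; the matrix is then symmetrized by
  averaging with its transpose (row-wise top-k is asymmetric, and averaging
  is the least-committal symmetric completion). Surviving negative entries
  are clipped to zero for the graph methods (Laplacian theory needs
  non-negative weights); PCA consumes the signed sparsified matrix.
* **Laplacian eigenmap.** Generalized eigenvectors of $Lf = \lambda Df$,
  computed via the symmetric normalized Laplacian; the trivial constant
  eigenvector at $\lambda = 0$ is dropped before counting $g$ gradients.
  Explained "variance" for LE uses inverse-eigenvalue weighting
  ($1/\lambda$, normalized): small Laplacian eigenvalues are the smooth,
  dominant modes, and this mapping yields a non-increasing profile in
  $[0, 1]$ comparable across methods.
* **Diffusion map.** Anisotropic normalization $\alpha = 0.5$ and
  diffusion time 0 with multiscale weights $\lambda/(1-\lambda)$ — the
  defaults of the toolbox ecosystem this package interoperates with.
  Eigenvector columns are unit-normalized *before* weighting, so the
  coordinate norms decay exactly with the spectrum (a testable invariant).
* **PCA.** Principal axes of the column-centered sparsified matrix;
  gradients are the scores, which are exactly uncorrelated.
* **Determinism.** A dense symmetric eigensolver is used throughout
  (regions up to a few thousand voxels decompose in well under a second;
  the iterative-solver path planned for larger problems is not needed at
  the supported scales and is deliberately absent). Every gradient column
  is sign-fixed so its largest-magnitude coordinate is positive, making
  unaligned output bitwise reproducible.
* **Connectivity.** A disconnected sparsified graph is an error that
  reports component sizes rather than a silent multi-component embedding.

## Alignment

Individual gradients need not match the group template's component order
or signs. Matching maximizes $\sum_i |\mathrm{corr}(G^{ind}_i,
G^{grp}_{\pi(i)})|$ over bijections $\pi$ (linear assignment, solved
exactly); absolute correlation handles the sign indeterminacy, and matched
signs are recorded. Procrustes alignment then finds the orthogonal
transform (rotation + reflection, no scaling) minimizing the Frobenius
distance after column centering. Both matrices are normalized by their
*whole-matrix* Frobenius norm rather than per column: per-column variance
normalization is not invariant under rotations that mix columns, and would
prevent exact recovery of an individual that is a pure rotation of the
template — a property the test suite requires at `1e-8`. Per-gradient
stability is the mean absolute correlation between aligned individual and
group gradients; the retention rule keeps gradients whose stability
exceeds 0.5. On synthetic cohorts the first three gradients pass at the
default noise level and fail at ten times the noise, so the rule is
exercised in both directions.

## Geometry and prediction analyses

* **RSA.** The gradient dissimilarity $D_{ij} = 1 -
  \mathrm{corr}(G_{i\cdot}, G_{j\cdot})$ (Pearson distance across the $g$
  coordinates) is correlated against the voxel-pair Euclidean distance
  matrix, Pearson on upper-triangle vectors by default (Spearman exposed).
  The permutation null re-labels voxels — rows of $G$ are jointly permuted,
  preserving each matrix's internal structure (a Mantel-style scheme) — and
  the p-value is $(b+1)/(n_{perm}+1)$.
* **Nucleus classification.** Linear discriminant analysis predicts atlas
  nucleus labels from voxelwise group gradients with repeated stratified
  5-fold CV (pooled accuracy per repetition, splits re-randomized each
  repetition, no confound adjustment). The chance level is estimated by
  re-running the CV on permuted labels; for balanced labels it sits at the
  sum of squared class proportions.
* **Phenotype prediction.** Subject-level features are the flattened
  aligned gradients, z-scored within subject across all features (the
  within-individual z-scoring axis is ambiguous in the field; across-all-
  features is adopted and stated). A LASSO with nested CV predicts each
  phenotype: the inner 10-fold loop picks the penalty by minimum MSE over
  a 50-point log grid from the data-driven maximal penalty down to `1e-4`
  of it; outer-fold held-out predictions are pooled per repetition and
  scored by Spearman correlation. Predictions and truth are mean-centered
  within each outer fold before pooling: near-constant fold predictions
  equal the training mean, which is *anti-correlated* with the held-out
  fold, biasing a naively pooled correlation to about $-0.16$ at 5 folds
  under the null; fold-centering removes the artifact while keeping the
  stability of pooling. An all-constant prediction vector is scored 0 (no
  predictive relationship) rather than NA. All randomness flows from one
  master seed through a documented hash-spawning scheme (`spawn_seed`), so
  every repetition is independently reproducible.

## The synthetic world

`synth_config()` / `generate_cohort()` produce desk-scale cohorts with
planted structure so that every stage is testable without any download:

* ~250 seed voxels (ellipsoid in an 8×8×8 grid), 600 target voxels,
  t = 120 timepoints, 20 subjects, K = 6 latent "network" timecourses —
  small enough that the full acceptance sweep runs in seconds, large
  enough that `n >= t - 1` holds, which the equivalence identities need.
* Each seed voxel mixes the networks with softmax-kernel weights that vary
  smoothly along a planted axis; the default axis is oblique,
  `(1, 0.5, 0.25)/|.|`, because an axis-aligned direction collapses the
  planted coordinate onto eight discrete grid planes and the resulting
  ties disconnect the sparsified affinity graph — a degenerate geometry,
  not a harder problem.
* Gaussian sensor noise at SD 0.5 per unit-SD signal is the default — a
  moderate single-voxel SNR regime; at this level all three manifold
  methods recover the planted axis at Spearman $|\rho| \ge 0.9$, and at
  ten times the noise the retention rule correctly rejects.
* Nucleus labels are six contiguous equal-count bins along the planted
  axis; phenotypes are sparse linear functions of the per-subject jittered
  voxel coordinates plus noise.

What the generator does **not** emulate: hemodynamic autocorrelation,
motion or physiological artifacts, spatial noise correlations, multi-run
structure, or realistic network topographies. A green test therefore
establishes the *mathematical* behavior of the pipeline (identities,
recovery, calibration, determinism) — not performance on real fMRI.
Two caveats surfaced by the tests: with noise fully off, the softmax
mixing plateaus at the coordinate extremes create exact fingerprint ties,
so rank recovery saturates near (not at) $|\rho| = 1$; and a saturated
noiseless similarity matrix is a degenerate input for PCA, which is
exercised at the default noise level instead.

## Limitations

* Volumetric NIfTI-1 and TSV are the interchange formats; surface/CIFTI
  ingestion is out of scope (grayordinate pipelines live upstream).
* The NIfTI reader/writer is deliberately minimal (single-file `.nii`,
  optionally gzipped; uint8/int16/int32/float32/float64; sform or
  quaternion affines) and was cross-checked against a reference
  implementation during development.
* No joint multi-subject alignment (each subject aligns to the group
  template only), no embeddings beyond LE/DE/PCA, no preprocessing.
* Group-difference hypothesis testing is limited to the significant-
  fraction summary; full between-group statistics are out of scope.
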