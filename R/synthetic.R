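# Synthetic cohort generator with planted connectopic structure.
#
# The generator emulates, at desk scale, the data regime the gradient
# pipeline expects: per-subject seed and target timeseries whose
# seed-to-target connectivity varies smoothly along one or more planted
# spatial axes, a toy 6-nucleus parcellation of the seed along the primary
# axis, and phenotypes that are noisy linear functions of subject-level
# gradient features. Ground truth is returned alongside and is never
# consumed by any estimation code path.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a cohort that exercises every pipeline stage in a few
#' seconds: an ellipsoidal seed of ~250 voxels in an 8x8x8 grid, a 600-voxel
#' target block (>= t - 1, so the full-rank equivalence identities apply),
#' t = 120 timepoints, K = 6 latent network timecourses, one planted
#' oblique gradient axis (oblique so the planted coordinate is continuous
#' rather than collapsing onto the few distinct grid planes an axis-aligned
#' direction would give), Gaussian sensor noise at half the signal SD,
#' and three phenotype metrics with sparse random loadings.
#'
#' @param n_subjects cohort size.
#' @param seed_grid 3-vector: seed bounding grid (ellipsoid mask inscribed).
#' @param target_grid 3-vector: target block grid (all voxels used).
#' @param t timepoints per subject (>= 10).
#' @param K number of latent network timecourses.
#' @param gradient_axes list of 3-vectors, planted axis directions in voxel
#'   space (normalized internally); the first axis defines nucleus bins.
#' @param mixing_sharpness softmax-kernel sharpness of the network mixing
#'   weights along the planted axes; larger = steeper connectopic change.
#' @param noise_sd white-noise SD added to each unit-SD seed voxel signal.
#' @param target_noise_sd white-noise SD for target voxels.
#' @param subject_jitter_sd SD of the per-subject perturbation of voxel
#'   gradient coordinates (drives true individual differences).
#' @param n_nuclei number of contiguous nucleus bins along axis 1.
#' @param phenotypes named list of per-metric loading vectors over the seed
#'   voxel gradient coordinates, or `NULL` to draw `n_phenotypes` sparse
#'   random loadings from the master seed.
#' @param n_phenotypes number of auto-generated phenotype metrics.
#' @param phenotype_noise_sd noise SD on phenotypes, as a fraction of each
#'   metric's signal SD.
#' @param voxel_size_mm isotropic voxel size for the affine.
#' @param master_seed master seed; all randomness is spawned from it.
#' @return `congradr_synth_config` list.
#' @export
synth_config <- function(n_subjects = 20L,
                         seed_grid = c(8L, 8L, 8L),
                         target_grid = c(10L, 10L, 6L),
                         t = 120L,
                         K = 6L,
                         gradient_axes = list(c(1, 0.5, 0.25)),
                         mixing_sharpness = 10,
                         noise_sd = 0.5,
                         target_noise_sd = 0.2,
                         subject_jitter_sd = 0.03,
                         n_nuclei = 6L,
                         phenotypes = NULL,
                         n_phenotypes = 3L,
                         phenotype_noise_sd = 0.5,
                         voxel_size_mm = 2,
                         master_seed = 2024L) {
  stopifnot(t >= 10L, noise_sd >= 0, target_noise_sd >= 0,
            length(seed_grid) == 3L, length(target_grid) == 3L,
            K >= 2L, n_nuclei >= 2L, n_subjects >= 1L)
  axes <- lapply(gradient_axes, function(a) {
    a <- as.numeric(a)
    stopifnot(length(a) == 3L, sum(a^2) > 0)
    a / sqrt(sum(a^2))
  })
  structure(
    list(n_subjects = as.integer(n_subjects), seed_grid = as.integer(seed_grid),
         target_grid = as.integer(target_grid), t = as.integer(t),
         K = as.integer(K), gradient_axes = axes,
         mixing_sharpness = mixing_sharpness, noise_sd = noise_sd,
         target_noise_sd = target_noise_sd,
         subject_jitter_sd = subject_jitter_sd, n_nuclei = as.integer(n_nuclei),
         phenotypes = phenotypes, n_phenotypes = as.integer(n_phenotypes),
         phenotype_noise_sd = phenotype_noise_sd,
         voxel_size_mm = voxel_size_mm, master_seed = as.integer(master_seed)),
    class = "congradr_synth_config"
  )
}

# ellipsoid mask voxel indices (1-based ijk) within a grid
ellipsoid_mask_ijk <- function(grid) {
  ctr <- (grid + 1) / 2
  semi <- grid / 2
  ijk <- as.matrix(expand.grid(i = seq_len(grid[1]), j = seq_len(grid[2]),
                               k = seq_len(grid[3])))
  r2 <- ((ijk[, 1] - ctr[1]) / semi[1])^2 + ((ijk[, 2] - ctr[2]) / semi[2])^2 +
    ((ijk[, 3] - ctr[3]) / semi[3])^2
  unname(ijk[r2 <= 1, , drop = FALSE])
}

# normalized projection of voxel positions onto an axis, in [0, 1]
axis_coordinate <- function(ijk, axis) {
  s <- as.numeric(ijk %*% axis)
  (s - min(s)) / (max(s) - min(s))
}

# smooth network mixing weights along a coordinate: softmax of a squared-
# distance kernel to K anchor points spread over [0, 1]; rows unit-L2 so the
# mixed signal has approximately unit variance
mixing_weights <- function(coord, K, sharpness) {
  anchors <- seq(0, 1, length.out = K)
  logw <- -sharpness * outer(coord, anchors, function(s, c) (s - c)^2)
  w <- exp(logw - apply(logw, 1L, max))
  w / sqrt(rowSums(w^2))
}

#' Generate a synthetic cohort with planted gradients
#'
#' Per subject, K latent network timecourses are drawn i.i.d. N(0, 1);
#' every target voxel mixes the networks with smooth weights along the
#' target block's long axis, and every seed voxel mixes them with weights
#' that vary smoothly and monotonically along the planted axis (softmax
#' kernel, see [synth_config()]), plus white noise. Per-subject gradient
#' coordinates are the population coordinates plus Gaussian jitter;
#' phenotypes are linear functions of the subject's coordinate vector plus
#' noise. Nucleus labels are equal-count contiguous bins of the axis-1
#' coordinate. Everything is deterministic given the master seed.
#'
#' @param config a [synth_config()].
#' @return `congradr_cohort`: list with `subjects` (per subject: `seed`,
#'   `target` [timeseries_matrix()]s), `labels`, `phenotypes` (data.frame,
#'   subject rows), `geometry` (m x 3 mm coordinates), `seed_ijk`
#'   (1-based indices), `affine`, `truth` (planted coordinates `coord`
#'   [m x n_axes], per-subject coordinates `subject_coord`, phenotype
#'   `loadings`, `axes`), and `config`.
#' @export
generate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "congradr_synth_config"))
  cfg <- config
  seed_ijk <- ellipsoid_mask_ijk(cfg$seed_grid)
  m <- nrow(seed_ijk)
  tgt_ijk <- as.matrix(expand.grid(i = seq_len(cfg$target_grid[1]),
                                   j = seq_len(cfg$target_grid[2]),
                                   k = seq_len(cfg$target_grid[3])))
  n <- nrow(tgt_ijk)
  if (n < cfg$t - 1L) {
    stop("target voxel count (", n, ") < t - 1 (", cfg$t - 1L,
         "): full-rank equivalence identities would not hold; enlarge ",
         "target_grid or reduce t", call. = FALSE)
  }

  coord <- vapply(cfg$gradient_axes, function(a) axis_coordinate(seed_ijk, a),
                  numeric(m))                       # m x n_axes
  tgt_coord <- axis_coordinate(tgt_ijk, c(1, 0, 0))

  # population nucleus labels: equal-count contiguous bins along axis 1
  qs <- quantile(coord[, 1], probs = seq(0, 1, length.out = cfg$n_nuclei + 1))
  labels <- as.integer(cut(coord[, 1], breaks = unique(qs),
                           include.lowest = TRUE))

  # phenotype loadings: sparse random over seed voxels (axis-1 coordinates)
  loadings <- cfg$phenotypes
  if (is.null(loadings)) {
    loadings <- list()
    for (mtr in seq_len(cfg$n_phenotypes)) {
      set.seed(spawn_seed(cfg$master_seed, paste0("loadings/", mtr)))
      l <- numeric(m)
      nz <- sample.int(m, max(5L, round(0.1 * m)))
      l[nz] <- rnorm(length(nz))
      loadings[[paste0("metric", mtr)]] <- l
    }
  }

  tgt_w <- mixing_weights(tgt_coord, cfg$K, cfg$mixing_sharpness)

  subjects <- vector("list", cfg$n_subjects)
  subject_coord <- array(NA_real_, c(m, ncol(coord), cfg$n_subjects))
  pheno <- matrix(NA_real_, cfg$n_subjects, length(loadings))
  for (s in seq_len(cfg$n_subjects)) {
    set.seed(spawn_seed(cfg$master_seed, paste0("subject", s)))
    H <- matrix(rnorm(cfg$t * cfg$K), cfg$t, cfg$K)
    # per-subject jittered gradient coordinates
    cs <- coord + matrix(rnorm(length(coord), sd = cfg$subject_jitter_sd),
                         nrow = m)
    cs <- pmin(pmax(cs, 0), 1)
    subject_coord[, , s] <- cs
    # seed mixing: average of kernels over planted axes
    w <- 0
    for (ax in seq_len(ncol(cs))) {
      w <- w + mixing_weights(cs[, ax], cfg$K, cfg$mixing_sharpness)
    }
    w <- w / sqrt(rowSums(w^2))
    seed_sig <- H %*% t(w) +
      matrix(rnorm(cfg$t * m, sd = cfg$noise_sd), cfg$t, m)
    tgt_sig <- H %*% t(tgt_w) +
      matrix(rnorm(cfg$t * n, sd = cfg$target_noise_sd), cfg$t, n)
    subjects[[s]] <- list(
      seed = timeseries_matrix(seed_sig, seq_len(m), "seed"),
      target = timeseries_matrix(tgt_sig, seq_len(n), "target")
    )
    # phenotype = loadings . subject axis-1 coordinates + noise
    for (mi in seq_along(loadings)) {
      pheno[s, mi] <- sum(loadings[[mi]] * cs[, 1])
    }
  }
  set.seed(spawn_seed(cfg$master_seed, "phenotype_noise"))
  for (mi in seq_along(loadings)) {
    sig_sd <- sd(pheno[, mi])
    if (!is.finite(sig_sd) || sig_sd == 0) sig_sd <- 1
    pheno[, mi] <- pheno[, mi] +
      rnorm(cfg$n_subjects, sd = cfg$phenotype_noise_sd * sig_sd)
  }
  phenotypes <- as.data.frame(pheno)
  names(phenotypes) <- names(loadings)
  phenotypes <- cbind(subject = paste0("sub", sprintf("%03d",
                                                      seq_len(cfg$n_subjects))),
                      phenotypes)

  affine <- diag(c(rep(cfg$voxel_size_mm, 3), 1))
  affine[1:3, 4] <- -cfg$voxel_size_mm * (cfg$seed_grid / 2)
  geometry <- voxel_coordinates(seed_ijk - 1L, affine)

  structure(
    list(subjects = subjects, labels = labels, phenotypes = phenotypes,
         geometry = geometry, seed_ijk = seed_ijk, affine = affine,
         truth = list(coord = coord, subject_coord = subject_coord,
                      loadings = loadings, axes = cfg$gradient_axes),
         config = cfg),
    class = "congradr_cohort"
  )
}

#' @export
print.congradr_cohort <- function(x, ...) {
  cat(sprintf(
    "<congradr_cohort> %d subjects, %d seed voxels, %d target voxels, t=%d\n",
    length(x$subjects), nrow(x$geometry),
    n_voxels(x$subjects[[1]]$target), x$config$t))
  invisible(x)
}

#' Recovery of planted gradient coordinates
#'
#' Absolute Spearman correlation between each estimated gradient and each
#' planted axis coordinate, with the best gradient-to-axis assignment
#' (Hungarian on `1 - |rho|`) reported per axis.
#'
#' @param estimated `congradr_gradients` or m x g matrix.
#' @param truth `congradr_cohort` truth element, or an m x n_axes
#'   coordinate matrix.
#' @return list with `score` (per-axis best `|rho|`), `assignment`
#'   (gradient index per axis), `all` (g x n_axes `|rho|` matrix).
#' @export
truth_recovery_score <- function(estimated, truth) {
  G <- if (inherits(estimated, "congradr_gradients")) estimated$gradients else as.matrix(estimated)
  coord <- if (is.list(truth) && !is.null(truth$coord)) truth$coord else as.matrix(truth)
  if (nrow(G) != nrow(coord)) stop("voxel order mismatch", call. = FALSE)
  n_axes <- ncol(coord)
  if (n_axes > ncol(G)) {
    warning("more planted axes than gradients; scoring the first ",
            ncol(G), " axes")
    coord <- coord[, seq_len(ncol(G)), drop = FALSE]
    n_axes <- ncol(coord)
  }
  A <- abs(cor(G, coord, method = "spearman"))   # g x n_axes
  cost <- 1 - A
  # pad to square for assignment when g > n_axes
  if (ncol(cost) < nrow(cost)) {
    cost <- cbind(cost, matrix(1, nrow(cost), nrow(cost) - ncol(cost)))
  }
  a <- as.integer(clue::solve_LSAP(cost))        # gradient i -> column a[i]
  assignment <- integer(n_axes)
  for (i in seq_along(a)) if (a[i] <= n_axes) assignment[a[i]] <- i
  score <- vapply(seq_len(n_axes), function(ax) A[assignment[ax], ax],
                  numeric(1))
  list(score = score, assignment = assignment, all = A)
}
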