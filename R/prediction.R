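# Downstream prediction: nucleus-label discriminant analysis with repeated
# stratified CV and permutation chance level; nested-CV LASSO phenotype
# prediction with weight-map summaries.

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Nucleus-label classification from group gradients
#'
#' Linear discriminant analysis predicting atlas nucleus labels from the
#' voxelwise group gradients, scored by repeated stratified k-fold
#' cross-validation (pooled accuracy over held-out voxels per repetition;
#' fold splits re-randomized each repetition). No confound adjustment is
#' performed. Background voxels (label 0 or NA) are excluded.
#'
#' @param G `congradr_gradients` or m x g feature matrix.
#' @param labels integer or factor of length m; 0/NA treated as background.
#' @param k_folds folds per repetition (default 5).
#' @param repetitions number of repetitions (default 20).
#' @param seed master seed; each repetition draws a spawned sub-seed.
#' @return `congradr_classification`: `per_rep_accuracy`, `fold_log`
#'   (repetition x voxel fold ids), `classes`.
#' @export
classify_nuclei <- function(G, labels, k_folds = 5L, repetitions = 20L,
                            seed = 1L) {
  X <- if (inherits(G, "congradr_gradients")) G$gradients else as.matrix(G)
  labels <- as.vector(labels)
  if (length(labels) != nrow(X)) {
    stop("labels length (", length(labels), ") != voxel count (", nrow(X), ")",
         call. = FALSE)
  }
  keep <- !is.na(labels) & labels != 0
  X <- X[keep, , drop = FALSE]
  y <- droplevels(factor(labels[keep]))
  if (nlevels(y) < 2L) stop("need at least 2 non-empty classes", call. = FALSE)
  sizes <- table(y)
  if (any(sizes < k_folds)) {
    stop("class(es) smaller than the fold count: ",
         paste(names(sizes)[sizes < k_folds], collapse = ", "), call. = FALSE)
  }
  acc <- numeric(repetitions)
  fold_log <- matrix(0L, repetitions, length(y))
  for (r in seq_len(repetitions)) {
    set.seed(spawn_seed(seed, paste0("classify/rep", r)))
    fold <- stratified_folds(y, k_folds)
    fold_log[r, ] <- fold
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      fit <- MASS::lda(X[tr, , drop = FALSE], grouping = y[tr])
      pred[!tr] <- predict(fit, X[!tr, , drop = FALSE])$class
    }
    acc[r] <- mean(pred == y)
  }
  structure(list(per_rep_accuracy = acc, fold_log = fold_log,
                 classes = levels(y), k_folds = k_folds, seed = seed),
            class = "congradr_classification")
}

#' Permutation chance level for nucleus classification
#'
#' Re-runs [classify_nuclei()] (one repetition each) with the label vector
#' permuted, giving an empirical chance accuracy and its null distribution.
#'
#' @param labels,G,k_folds as in [classify_nuclei()].
#' @param n_perm number of permutations (>= 99 recommended; >= 19 enforced).
#' @param seed master seed.
#' @return list with `chance` (mean null accuracy) and `null` (length
#'   `n_perm`).
#' @export
chance_accuracy <- function(labels, G, n_perm = 99L, seed = 1L, k_folds = 5L) {
  if (n_perm < 19L) stop("n_perm too small", call. = FALSE)
  labels <- as.vector(labels)
  null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    set.seed(spawn_seed(seed, paste0("chance/perm", b)))
    perm <- labels
    nz <- !is.na(labels) & labels != 0
    perm[nz] <- sample(labels[nz])
    null[b] <- classify_nuclei(G, perm, k_folds = k_folds, repetitions = 1L,
                               seed = spawn_seed(seed, paste0("chance/cv", b))
    )$per_rep_accuracy
  }
  list(chance = mean(null), null = null)
}

#' Z-score features within subject
#'
#' Each subject's feature row (flattened voxel-by-gradient coordinates) is
#' standardized across all of its features.
#'
#' @param features subject x feature matrix.
#' @return matrix of the same shape with zero row means and unit row SDs.
#' @export
zscore_within_subject <- function(features) {
  t(apply(as.matrix(features), 1L, function(r) (r - mean(r)) / sd(r)))
}

#' Nested cross-validated LASSO phenotype prediction
#'
#' Subject phenotypes are predicted from within-subject z-scored gradient
#' features with an L1-penalized linear model. The penalty is chosen per
#' outer training fold by inner k-fold CV (minimum mean squared error over a
#' 50-point logarithmic grid spanning the data-driven maximal penalty down
#' to 1e-4 of it); held-out predictions from the outer folds are
#' concatenated and scored per repetition as the Spearman correlation with
#' the true phenotype. Both predictions and truth are mean-centered within
#' each outer fold before pooling: near-constant fold predictions carry a
#' fold-mean offset that is anti-correlated with the held-out values, which
#' would bias the pooled correlation well below zero under the null;
#' fold-centering removes that artifact while keeping the stability of
#' pooling. The weight map is the average of the outer-fold coefficient
#' vectors across folds and repetitions.
#'
#' @param features subject x feature matrix (rows z-scored internally unless
#'   `zscore = FALSE`).
#' @param y numeric phenotype, one per subject; subjects with missing y are
#'   dropped (count reported via message).
#' @param outer,inner outer/inner fold counts (default 10/10).
#' @param repetitions number of nested-CV repetitions (default 20).
#' @param seed master seed; every repetition and inner split uses a spawned
#'   sub-seed.
#' @param zscore apply [zscore_within_subject()] first (default TRUE).
#' @return `congradr_prediction`: `per_rep_rho`, `weight_map` (mean
#'   coefficients), `predictions` (repetitions x subjects), `fold_log`,
#'   `n_subjects`.
#' @export
lasso_predict <- function(features, y, outer = 10L, inner = 10L,
                          repetitions = 20L, seed = 1L, zscore = TRUE) {
  features <- as.matrix(features)
  y <- as.numeric(y)
  if (length(y) != nrow(features)) {
    stop("phenotype length != subject count", call. = FALSE)
  }
  drop_n <- sum(is.na(y))
  if (drop_n) {
    message("dropping ", drop_n, " subject(s) with missing phenotype")
    keep <- !is.na(y)
    features <- features[keep, , drop = FALSE]
    y <- y[keep]
  }
  n <- length(y)
  if (n < 20L) stop("need at least 20 subjects after dropping missing values",
                    call. = FALSE)
  if (sd(y) == 0) stop("phenotype is constant", call. = FALSE)
  if (any(!is.finite(features))) stop("features must be finite", call. = FALSE)
  X <- if (zscore) zscore_within_subject(features) else features

  rho <- numeric(repetitions)
  preds <- matrix(NA_real_, repetitions, n)
  wsum <- numeric(ncol(X))
  nfit <- 0L
  fold_log <- matrix(0L, repetitions, n)
  for (r in seq_len(repetitions)) {
    set.seed(spawn_seed(seed, paste0("lasso/rep", r)))
    fold <- sample(rep_len(seq_len(outer), n))
    fold_log[r, ] <- fold
    for (f in seq_len(outer)) {
      tr <- which(fold != f)
      te <- which(fold == f)
      set.seed(spawn_seed(seed, paste0("lasso/rep", r, "/fold", f)))
      foldid <- sample(rep_len(seq_len(inner), length(tr)))
      cvfit <- glmnet::cv.glmnet(X[tr, , drop = FALSE], y[tr], alpha = 1,
                                 foldid = foldid, nlambda = 50,
                                 lambda.min.ratio = 1e-4,
                                 standardize = TRUE)
      preds[r, te] <- as.numeric(predict(cvfit, X[te, , drop = FALSE],
                                         s = "lambda.min"))
      w <- as.numeric(stats::coef(cvfit, s = "lambda.min"))[-1L]
      wsum <- wsum + w
      nfit <- nfit + 1L
    }
    pc <- preds[r, ]
    yc <- y
    for (f in seq_len(outer)) {
      te <- fold == f
      pc[te] <- pc[te] - mean(pc[te])
      yc[te] <- yc[te] - mean(yc[te])
    }
    # an all-constant prediction (maximal penalty in every fold) carries no
    # predictive signal; score it 0 rather than NA
    rho[r] <- if (sd(pc) == 0) 0 else cor(pc, yc, method = "spearman")
  }
  structure(list(per_rep_rho = rho, weight_map = wsum / nfit,
                 predictions = preds, fold_log = fold_log, n_subjects = n,
                 outer = outer, inner = inner, seed = seed),
            class = "congradr_prediction")
}

#' Fraction of repetitions with significant positive correlation
#'
#' Per repetition, a one-sided asymptotic test of Spearman rho > 0
#' (`t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df), Bonferroni
#' corrected for `n_comparisons`; returns the fraction of repetitions whose
#' corrected p falls below `alpha`.
#'
#' @param per_rep_rho numeric vector of per-repetition correlations.
#' @param n_subjects sample size behind each correlation (>= 5).
#' @param alpha significance level (default 0.05).
#' @param n_comparisons Bonferroni divisor (>= 1).
#' @return fraction in `[0, 1]`.
#' @export
significance_summary <- function(per_rep_rho, n_subjects, alpha = 0.05,
                                 n_comparisons = 1L) {
  if (n_subjects < 5L) stop("n_subjects must be >= 5", call. = FALSE)
  if (n_comparisons < 1L) stop("n_comparisons must be >= 1", call. = FALSE)
  rho <- pmin(pmax(as.numeric(per_rep_rho), -1), 1)
  tt <- ifelse(abs(rho) >= 1, sign(rho) * Inf,
               rho * sqrt((n_subjects - 2) / (1 - rho^2)))
  p <- pt(tt, df = n_subjects - 2, lower.tail = FALSE)
  mean(pmin(p * n_comparisons, 1) < alpha & rho > 0)
}

#' Per-nucleus contribution of a predictive weight map
#'
#' Mean absolute weight across each nucleus's voxels (over all gradients),
#' normalized to sum to one across nuclei. Empty nuclei are excluded with a
#' warning.
#'
#' @param weight_map m x g matrix (or length `m * g` vector) of weights.
#' @param labels nucleus label per voxel (0/NA = background).
#' @return named numeric vector of contributions summing to 1.
#' @export
nucleus_contribution <- function(weight_map, labels) {
  W <- as.matrix(weight_map)
  labels <- as.vector(labels)
  if (length(labels) != nrow(W)) {
    if (length(weight_map) %% length(labels) == 0) {
      W <- matrix(as.numeric(weight_map), nrow = length(labels))
    } else {
      stop("weight map and labels do not share voxel support", call. = FALSE)
    }
  }
  keep <- !is.na(labels) & labels != 0
  W <- W[keep, , drop = FALSE]
  y <- factor(labels[keep])
  contrib <- vapply(levels(y), function(cl) {
    mean(abs(W[y == cl, , drop = FALSE]))
  }, numeric(1))
  empty <- !is.finite(contrib)
  if (any(empty)) {
    warning("excluding empty nucleus(es): ",
            paste(names(contrib)[empty], collapse = ", "))
    contrib <- contrib[!empty]
  }
  contrib / sum(contrib)
}

#' Consistency of two predictive weight maps
#'
#' Spearman correlation between the vectorized weight maps.
#'
#' @param weight_map_a,weight_map_b numeric arrays of identical shape.
#' @return Spearman correlation.
#' @export
weight_consistency <- function(weight_map_a, weight_map_b) {
  a <- as.numeric(weight_map_a)
  b <- as.numeric(weight_map_b)
  if (length(a) != length(b)) {
    stop("weight maps must share voxel-by-gradient support", call. = FALSE)
  }
  if (all(a == 0) || all(b == 0)) {
    stop("all-zero weight map: consistency undefined", call. = FALSE)
  }
  cor(a, b, method = "spearman")
}
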