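# Group templates, Hungarian gradient matching, Procrustes alignment,
# stability, and cross-variant gradient comparison.

#' Group-level gradient template
#'
#' Averages individual similarity matrices element-wise and embeds the mean,
#' giving the group-level gradients that individual gradients are
#' subsequently matched and aligned to.
#'
#' @param similarities list of `congradr_similarity` objects sharing size
#'   and voxel order.
#' @param method,g,sparsity,... passed to [embed_gradients()].
#' @return `congradr_group_template`: list with `mean_similarity`,
#'   `group_gradients`, and `per_gradient_stability` (NULL until
#'   [gradient_stability()] is run).
#' @export
group_template <- function(similarities, method = "DE", g = 3L,
                           sparsity = 0.9, ...) {
  stopifnot(length(similarities) >= 1L)
  mats <- lapply(similarities, function(s) {
    if (inherits(s, "congradr_similarity")) s$data else as.matrix(s)
  })
  m <- nrow(mats[[1L]])
  ok <- vapply(mats, function(x) nrow(x) == m && ncol(x) == m, logical(1))
  if (!all(ok)) {
    stop("similarity matrices differ in size (first mismatch: subject ",
         which(!ok)[1L], ")", call. = FALSE)
  }
  ids <- if (inherits(similarities[[1L]], "congradr_similarity")) {
    similarities[[1L]]$voxel_ids
  } else seq_len(m)
  mean_S <- Reduce(`+`, mats) / length(mats)
  meas <- if (inherits(similarities[[1L]], "congradr_similarity")) {
    similarities[[1L]]$measure
  } else NA_character_
  varv <- if (inherits(similarities[[1L]], "congradr_similarity")) {
    similarities[[1L]]$variant
  } else NA_character_
  Sm <- new_similarity(mean_S, measure = meas, variant = varv, voxel_ids = ids)
  gg <- embed_gradients(Sm, method = method, g = g, sparsity = sparsity, ...)
  structure(
    list(mean_similarity = Sm, group_gradients = gg,
         per_gradient_stability = NULL),
    class = "congradr_group_template"
  )
}

#' Match individual gradients to group gradients (Hungarian algorithm)
#'
#' Individual-level gradients need not come out in the group's component
#' order, and their signs are arbitrary. This solves the linear assignment
#' problem maximizing the total absolute Pearson correlation between
#' individual and group gradient columns, and records the sign of each
#' matched correlation.
#'
#' @param individual,group `congradr_gradients` with equal voxel count and
#'   gradient count.
#' @return `congradr_match`: `permutation` (`permutation[i]` is the group
#'   component matched to individual component `i`; a bijection), `signs`
#'   (per individual component), `match_scores` (absolute correlations).
#' @export
match_hungarian <- function(individual, group) {
  Gi <- if (inherits(individual, "congradr_gradients")) individual$gradients else individual
  Gg <- if (inherits(group, "congradr_gradients")) group$gradients else group
  if (ncol(Gi) != ncol(Gg)) {
    stop("gradient counts differ: ", ncol(Gi), " vs ", ncol(Gg), call. = FALSE)
  }
  if (nrow(Gi) != nrow(Gg)) {
    stop("voxel counts differ: ", nrow(Gi), " vs ", nrow(Gg), call. = FALSE)
  }
  R <- cor(Gi, Gg)
  cost <- 1 - abs(R)
  a <- as.integer(clue::solve_LSAP(cost))  # a[i]: group comp for ind comp i
  signs <- vapply(seq_along(a), function(i) {
    if (R[i, a[i]] < 0) -1 else 1
  }, numeric(1))
  scores <- vapply(seq_along(a), function(i) abs(R[i, a[i]]), numeric(1))
  structure(list(permutation = a, signs = signs, match_scores = scores),
            class = "congradr_match")
}

#' Reorder and sign-correct an individual gradient set per a match
#'
#' Applies a [match_hungarian()] result so the individual's columns are in
#' group component order with matched correlations positive.
#'
#' @param individual `congradr_gradients`.
#' @param match `congradr_match`.
#' @return `congradr_gradients` in group order.
#' @export
apply_match <- function(individual, match) {
  G <- individual$gradients
  g <- ncol(G)
  out <- matrix(0, nrow(G), g)
  ev <- numeric(g)
  er <- numeric(g)
  for (i in seq_len(g)) {
    out[, match$permutation[i]] <- match$signs[i] * G[, i]
    ev[match$permutation[i]] <- individual$eigenvalues[i]
    er[match$permutation[i]] <- individual$explained_ratio[i]
  }
  new_gradient_set(out, ev, individual$method, individual$variant, er,
                   aligned = individual$aligned,
                   voxel_ids = individual$voxel_ids)
}

#' Procrustes alignment of individual gradients to the group template
#'
#' Finds the orthogonal transform (rotation + reflection; no scaling beyond
#' a whole-matrix norm match, no translation beyond column centering)
#' minimizing the Frobenius distance between the individual's matched
#' gradients and the group gradients. Both matrices are column-centered and
#' normalized to unit Frobenius norm before solving; the whole-matrix
#' normalization (rather than per-column) is used because it is invariant
#' under rotations that mix columns, so an individual that is an exact
#' orthogonal rotation of the template is recovered exactly.
#'
#' @param individual `congradr_gradients` already permuted/sign-corrected
#'   (see [apply_match()]); if `match` is supplied it is applied first.
#' @param group `congradr_gradients` group template.
#' @param match optional `congradr_match`.
#' @return aligned `congradr_gradients` (`aligned = TRUE`), with the
#'   orthogonal transform in attribute `"rotation"`.
#' @export
procrustes_align <- function(individual, group, match = NULL) {
  if (!is.null(match)) individual <- apply_match(individual, match)
  X <- individual$gradients
  Y <- if (inherits(group, "congradr_gradients")) group$gradients else group
  if (nrow(X) != nrow(Y) || ncol(X) != ncol(Y)) {
    stop("gradient matrices must share dimensions", call. = FALSE)
  }
  Xc <- center_cols(X)
  Yc <- center_cols(Y)
  fx <- sqrt(sum(Xc^2))
  fy <- sqrt(sum(Yc^2))
  if (fx == 0 || fy == 0) stop("degenerate (all-constant) gradient matrix",
                               call. = FALSE)
  Xc <- Xc / fx
  Yc <- Yc / fy
  M <- crossprod(Xc, Yc)
  sv <- svd(M)
  if (min(sv$d) < max(sv$d) * 1e-10) {
    stop("rank-degenerate gradient matrix: Procrustes rotation is not unique",
         call. = FALSE)
  }
  Q <- sv$u %*% t(sv$v)
  aligned <- Xc %*% Q * fy
  aligned <- sweep(aligned, 2L, colMeans(Y), "+")
  out <- new_gradient_set(aligned, individual$eigenvalues, individual$method,
                          individual$variant, individual$explained_ratio,
                          aligned = TRUE, voxel_ids = individual$voxel_ids)
  attr(out, "rotation") <- Q
  out
}

#' Per-gradient stability of aligned individual gradients
#'
#' For each gradient index, the mean over subjects of the absolute spatial
#' correlation between the aligned individual gradient and the group
#' gradient. Used by the retention rule: a gradient is retained when its
#' stability exceeds the threshold (conventionally 0.5).
#'
#' @param aligned_individuals list of aligned `congradr_gradients`.
#' @param group group `congradr_gradients` (or a `congradr_group_template`).
#' @return numeric vector of per-gradient mean absolute correlations.
#' @export
gradient_stability <- function(aligned_individuals, group) {
  if (inherits(group, "congradr_group_template")) group <- group$group_gradients
  if (!length(aligned_individuals)) stop("empty subject list", call. = FALSE)
  Gg <- group$gradients
  g <- ncol(Gg)
  acc <- numeric(g)
  for (ind in aligned_individuals) {
    Gi <- if (inherits(ind, "congradr_gradients")) ind$gradients else ind
    acc <- acc + abs(diag(cor(Gi, Gg)))
  }
  acc / length(aligned_individuals)
}

#' Gradient retention rule
#'
#' @param stability per-gradient stability from [gradient_stability()].
#' @param threshold retention threshold (default 0.5).
#' @return logical vector: which gradients pass.
#' @export
retain_gradients <- function(stability, threshold = 0.5) {
  stability > threshold
}

#' Cross-variant similarity of unaligned gradients
#'
#' For every pair of fingerprint variants, Hungarian-matches each subject's
#' unaligned gradients between the two variants and averages the matched
#' absolute correlations, first within subject over gradients (or per
#' gradient if `per_gradient = TRUE`), then across subjects. This is the
#' statistic that exposes the original==within-seed and rescaled==voxelwise
#' equivalences. Aligned inputs are rejected: alignment to a common template
#' would contaminate the comparison.
#'
#' @param gsets nested list: `gsets[[subject]][[variant]]` of unaligned
#'   `congradr_gradients`; variant names taken from the inner list names.
#' @param per_gradient return a per-gradient breakdown instead of the
#'   gradient-averaged summary.
#' @return variant x variant matrix of mean absolute correlations (or a
#'   list of `g` such matrices when `per_gradient = TRUE`).
#' @export
unaligned_cross_variant_similarity <- function(gsets, per_gradient = FALSE) {
  stopifnot(length(gsets) >= 1L)
  variants <- names(gsets[[1L]])
  if (is.null(variants)) stop("inner lists must be named by variant",
                              call. = FALSE)
  for (subj in gsets) {
    for (gs in subj) {
      if (isTRUE(gs$aligned)) {
        stop("cross-variant similarity is defined on unaligned gradients; ",
             "an aligned gradient set was supplied", call. = FALSE)
      }
    }
  }
  nv <- length(variants)
  g <- ncol(gsets[[1L]][[1L]]$gradients)
  acc <- array(0, c(nv, nv, g))
  for (subj in gsets) {
    for (i in seq_len(nv)) {
      for (j in seq_len(nv)) {
        mt <- match_hungarian(subj[[i]], subj[[j]])
        sc <- numeric(g)
        sc[mt$permutation] <- mt$match_scores
        acc[i, j, ] <- acc[i, j, ] + sc
      }
    }
  }
  acc <- acc / length(gsets)
  dimnames(acc) <- list(variants, variants, paste0("G", seq_len(g)))
  if (per_gradient) {
    lapply(seq_len(g), function(k) acc[, , k])
  } else {
    apply(acc, c(1, 2), mean)
  }
}

#' Z-scored local-minus-global gradient difference maps
#'
#' Z-scores each gradient column over voxels and subtracts the global from
#' the local map, gradient by gradient, yielding per-voxel difference maps.
#'
#' @param local,global_ `congradr_gradients` with matched gradient order and
#'   a common voxel set.
#' @return m x g matrix of z-score differences.
#' @export
zscore_and_difference <- function(local, global_) {
  Gl <- if (inherits(local, "congradr_gradients")) local$gradients else local
  Gg <- if (inherits(global_, "congradr_gradients")) global_$gradients else global_
  if (nrow(Gl) != nrow(Gg) || ncol(Gl) != ncol(Gg)) {
    stop("gradient matrices must share dimensions", call. = FALSE)
  }
  zl <- scale(Gl)
  zg <- scale(Gg)
  unname(zl - zg)
}
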