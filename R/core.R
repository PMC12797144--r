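# Connectivity fingerprints and voxel-to-voxel similarity.
#
# Variants implemented:
#   original  - seed voxels correlated against SVD spatial modes of the target
#   rescaled  - original fingerprints rescaled column-wise by singular values
#   voxelwise - seed voxels correlated against every target voxel (no SVD)
#   within_seed - the seed's own voxel-to-voxel Pearson FC used directly

#' Spatial modes of a target region via SVD
#'
#' Decomposes the (already column-standardized) target timeseries
#' `B = U D V'` and returns the temporally uncorrelated spatial modes
#' `UD` truncated to `p` components. Because every column is centered the
#' matrix rank is at most `t - 1`, hence the default `p = min(t - 1, n)`.
#'
#' @param target a [timeseries_matrix()] (or plain matrix) for the target
#'   region.
#' @param p number of components to keep; default `min(t - 1, n)`.
#' @return `congradr_modes`: list with `modes` (t x p matrix `UD`),
#'   `singular_values` (length p, non-increasing), `p`, and `v` (the n x p
#'   right singular vectors, kept for reconstruction/diagnostics).
#' @export
#' @examples
#' tgt <- timeseries_matrix(matrix(rnorm(2000), 20, 100), region_tag = "target")
#' sm <- compute_spatial_modes(tgt)
#' sm$p # 19
compute_spatial_modes <- function(target, p = NULL) {
  target <- as_timeseries(target, "target")
  t_len <- n_timepoints(target)
  n <- n_voxels(target)
  p_max <- min(t_len - 1L, n)
  if (is.null(p)) p <- p_max
  if (p < 1L || p > p_max) {
    stop("p must be in [1, min(t-1, n)] = [1, ", p_max, "], got ", p,
         call. = FALSE)
  }
  sv <- svd(target$data, nu = p, nv = p)
  d <- sv$d[seq_len(p)]
  if (any(d < max(sv$d) * 1e-12)) {
    stop("target matrix is rank deficient: components ",
         paste(which(d < max(sv$d) * 1e-12), collapse = ", "),
         " have (near-)zero singular values; reduce p", call. = FALSE)
  }
  structure(
    list(modes = sv$u %*% diag(d, p, p), singular_values = d, p = p, v = sv$v),
    class = "congradr_modes"
  )
}

#' Connectivity fingerprints of seed voxels
#'
#' Builds the seed-voxel-by-feature fingerprint matrix `C` under one of three
#' variants: `original` correlates each seed voxel against each SVD spatial
#' mode, `rescaled` multiplies column `j` of the original fingerprints by the
#' corresponding singular value (restoring the variance structure the
#' correlation step discards), and `voxelwise` correlates each seed voxel
#' against each target voxel directly.
#'
#' @param seed,target [timeseries_matrix()] objects sharing the same number
#'   of timepoints.
#' @param variant `"original"`, `"rescaled"`, or `"voxelwise"`.
#' @param modes optional precomputed [compute_spatial_modes()] result
#'   (ignored for `voxelwise`).
#' @return `congradr_fingerprints`: list with `data` (m x q), `variant`,
#'   and for SVD variants the `singular_values` used.
#' @export
fingerprints <- function(seed, target,
                         variant = c("original", "rescaled", "voxelwise"),
                         modes = NULL) {
  variant <- match.arg(variant)
  seed <- as_timeseries(seed, "seed")
  target <- as_timeseries(target, "target")
  if (n_timepoints(seed) != n_timepoints(target)) {
    stop("seed (t=", n_timepoints(seed), ") and target (t=",
         n_timepoints(target), ") timepoint counts differ", call. = FALSE)
  }
  sv_used <- NULL
  if (variant == "voxelwise") {
    C <- cor(seed$data, target$data)
  } else {
    if (is.null(modes)) modes <- compute_spatial_modes(target)
    C <- cor(seed$data, modes$modes)
    if (variant == "rescaled") {
      C <- sweep(C, 2L, modes$singular_values, "*")
      sv_used <- modes$singular_values
    }
  }
  if (any(!is.finite(C))) {
    stop("non-finite fingerprint entries; check for degenerate voxels",
         call. = FALSE)
  }
  structure(list(data = C, variant = variant, singular_values = sv_used),
            class = "congradr_fingerprints")
}

#' Within-seed functional connectivity matrix
#'
#' The m x m Pearson correlation matrix of the seed voxel timeseries, used
#' directly as the similarity input for the within-seed (local) gradient
#' variant, skipping fingerprints entirely.
#'
#' @param seed a [timeseries_matrix()] (or plain matrix).
#' @return `congradr_similarity` with `measure = "pearson_fc"`,
#'   `variant = "within_seed"`.
#' @export
within_seed_fc <- function(seed) {
  seed <- as_timeseries(seed, "seed")
  if (n_voxels(seed) < 2L) stop("need at least 2 seed voxels", call. = FALSE)
  S <- cor(seed$data)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  new_similarity(S, measure = "pearson_fc", variant = "within_seed",
                 voxel_ids = seed$voxel_ids)
}

new_similarity <- function(S, measure, variant = NA_character_,
                           voxel_ids = seq_len(nrow(S))) {
  dimnames(S) <- NULL
  structure(
    list(data = S, measure = measure, variant = variant,
         voxel_ids = as.integer(voxel_ids)),
    class = "congradr_similarity"
  )
}

#' @export
print.congradr_similarity <- function(x, ...) {
  cat(sprintf("<congradr_similarity> %d x %d, measure=%s, variant=%s\n",
              nrow(x$data), ncol(x$data), x$measure, x$variant))
  invisible(x)
}

#' Fingerprint similarity matrix
#'
#' Compares the connectivity fingerprints of all seed voxel pairs. `cosine`
#' is the normalized inner product of fingerprint rows. `eta2` is the
#' two-profile eta-squared: one minus the sum of squared deviations of the
#' two profiles around their pointwise means, over the total sum of squares
#' around the grand mean of those pointwise means. Both are computed from
#' sufficient statistics (row cross-products, row sums, row sums of squares)
#' accumulated over feature blocks of at most `block_size` columns, so the
#' m x q fingerprint matrix is the only dense object ever held; results are
#' identical to the single-block path.
#'
#' @param fp a [fingerprints()] result (or plain m x q matrix).
#' @param measure `"cosine"` or `"eta2"`.
#' @param block_size maximum number of feature columns processed per block.
#' @param voxel_ids optional voxel ids carried onto the output.
#' @return `congradr_similarity` (m x m, symmetric, unit diagonal).
#' @export
#' @examples
#' similarity(rbind(c(1, 2), c(3, 4)), "eta2")$data[1, 2] # 0.2
similarity <- function(fp, measure = c("cosine", "eta2"),
                       block_size = 10000L, voxel_ids = NULL) {
  measure <- match.arg(measure)
  variant <- NA_character_
  if (inherits(fp, "congradr_fingerprints")) {
    variant <- fp$variant
    fp <- fp$data
  }
  fp <- as.matrix(fp)
  m <- nrow(fp)
  q <- ncol(fp)
  if (m < 2L) stop("need at least 2 fingerprint rows", call. = FALSE)
  if (any(!is.finite(fp))) stop("fingerprints must be finite", call. = FALSE)

  # blockwise sufficient statistics
  G <- matrix(0, m, m)     # row cross-products  fp %*% t(fp)
  rs <- numeric(m)         # row sums
  r2 <- numeric(m)         # row sums of squares
  for (start in seq(1L, q, by = block_size)) {
    idx <- start:min(q, start + block_size - 1L)
    blk <- fp[, idx, drop = FALSE]
    G <- G + tcrossprod(blk)
    rs <- rs + rowSums(blk)
    r2 <- r2 + rowSums(blk^2)
  }

  if (measure == "cosine") {
    nrm <- sqrt(r2)
    if (any(nrm < .Machine$double.eps * q * 10)) {
      stop("all-zero fingerprint row(s): ",
           paste(head(which(nrm < .Machine$double.eps * q * 10), 5L),
                 collapse = ", "),
           "; cosine similarity undefined", call. = FALSE)
    }
    S <- G / tcrossprod(nrm)
  } else {
    # eta2(i,j) = 1 - num/den with pointwise means m_k = (a_k + b_k)/2 and
    # grand mean M = mean_k m_k:
    #   num = sum_k (a_k - m_k)^2 + (b_k - m_k)^2 = (r2_i + r2_j - 2 G_ij)/2
    #   den = r2_i + r2_j - 2 M (rs_i + rs_j) + 2 q M^2
    Msum <- outer(rs, rs, "+")          # q * 2M
    Mij <- Msum / (2 * q)
    num <- (outer(r2, r2, "+") - 2 * G) / 2
    den <- outer(r2, r2, "+") - 2 * Mij * Msum + 2 * q * Mij^2
    S <- ifelse(den > .Machine$double.eps * q * 100, 1 - num / den, 1)
  }
  S <- (S + t(S)) / 2
  diag(S) <- 1
  new_similarity(S, measure = measure, variant = variant,
                 voxel_ids = voxel_ids %||% seq_len(m))
}

#' Build a similarity matrix under any variant
#'
#' Dispatcher over the four fingerprint variants: `original`, `rescaled`,
#' and `voxelwise` run the fingerprint-then-similarity chain; `within_seed`
#' ignores the target and the measure and returns the seed's Pearson FC
#' matrix. With the cosine measure and a target whose centered timeseries
#' span the full `t - 1`-dimensional time space, `original` reproduces
#' `within_seed` exactly, and `rescaled` reproduces `voxelwise` exactly.
#'
#' @param seed,target [timeseries_matrix()] objects (target unused for
#'   `within_seed`).
#' @param variant one of `"original"`, `"rescaled"`, `"voxelwise"`,
#'   `"within_seed"`.
#' @param measure `"cosine"` (default) or `"eta2"`; for `within_seed` only
#'   `"pearson_fc"` (or NULL) is accepted.
#' @param p optional SVD component count for the SVD variants.
#' @param block_size see [similarity()].
#' @return `congradr_similarity` with variant/measure provenance.
#' @export
build_similarity <- function(seed, target = NULL,
                             variant = c("original", "rescaled", "voxelwise",
                                         "within_seed"),
                             measure = NULL, p = NULL, block_size = 10000L) {
  variant <- match.arg(variant)
  seed <- as_timeseries(seed, "seed")
  if (variant == "within_seed") {
    if (!is.null(measure) && !identical(measure, "pearson_fc")) {
      stop("within_seed similarity is Pearson FC by definition; measure \"",
           measure, "\" is not applicable", call. = FALSE)
    }
    return(within_seed_fc(seed))
  }
  if (is.null(target)) stop("variant \"", variant, "\" requires a target",
                            call. = FALSE)
  measure <- measure %||% "cosine"
  fp <- fingerprints(seed, target, variant = variant,
                     modes = if (variant != "voxelwise" && !is.null(p)) {
                       compute_spatial_modes(target, p = p)
                     })
  similarity(fp, measure = measure, block_size = block_size,
             voxel_ids = seed$voxel_ids)
}
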