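# Anatomical constraints on gradients: representational similarity analysis
# against voxel geometry, and spatial comparison with external maps.

#' Voxel-pair gradient dissimilarity (Pearson distance)
#'
#' `D[i, j] = 1 - cor(G[i, ], G[j, ])`: one minus the Pearson correlation
#' between the g-dimensional gradient coordinate vectors of voxels i and j.
#' Needs `g >= 2` (correlation across gradient coordinates).
#'
#' @param G `congradr_gradients` or an m x g matrix.
#' @return m x m dissimilarity matrix (0 diagonal, range `[0, 2]`).
#' @export
gradient_dissimilarity <- function(G) {
  X <- if (inherits(G, "congradr_gradients")) G$gradients else as.matrix(G)
  if (ncol(X) < 2L) {
    stop("Pearson distance across gradient coordinates needs g >= 2",
         call. = FALSE)
  }
  rs <- apply(X, 1L, sd)
  if (any(rs < .Machine$double.eps * 100)) {
    stop("voxel(s) with zero variance across gradient coordinates: ",
         paste(head(which(rs < .Machine$double.eps * 100), 5L), collapse = ", "),
         call. = FALSE)
  }
  D <- 1 - cor(t(X))
  diag(D) <- 0
  unname(D)
}

#' Voxel coordinates from mask indices and an affine
#'
#' Converts 0-based voxel grid indices to millimeter coordinates with the
#' center-of-voxel convention: `xyz = affine %*% c(i, j, k, 1)`.
#'
#' @param ijk m x 3 matrix of 0-based voxel indices.
#' @param affine 4 x 4 voxel-to-world matrix.
#' @return m x 3 matrix of millimeter coordinates.
#' @export
voxel_coordinates <- function(ijk, affine = diag(4)) {
  ijk <- as.matrix(ijk)
  stopifnot(ncol(ijk) == 3L, all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps) {
    stop("affine is singular", call. = FALSE)
  }
  xyz1 <- cbind(ijk, 1) %*% t(affine)
  unname(xyz1[, 1:3, drop = FALSE])
}

#' RSA of gradient dissimilarity against voxel geometry
#'
#' Correlates the upper triangle of the gradient Pearson-distance matrix
#' against the upper triangle of the voxel-pair Euclidean distance matrix.
#' The permutation null re-labels voxels: rows of G are jointly permuted
#' (equivalently the dissimilarity matrix is row/column permuted), keeping
#' each matrix's internal structure intact (a Mantel-style test). The
#' p-value is `(b + 1) / (n_perm + 1)` with `b` the count of null values at
#' or above the observed correlation.
#'
#' @param G `congradr_gradients` or m x g matrix (`g >= 2`).
#' @param coordinates m x 3 millimeter coordinates (see
#'   [voxel_coordinates()]).
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed for the permutation stream.
#' @param cor_method `"pearson"` (default) or `"spearman"` for the
#'   second-order correlation.
#' @return `congradr_rsa`: list with `observed_r`, `null_distribution`,
#'   `p_value`.
#' @export
rsa_geometry <- function(G, coordinates, n_perm = 999L, seed = 1L,
                         cor_method = c("pearson", "spearman")) {
  cor_method <- match.arg(cor_method)
  X <- if (inherits(G, "congradr_gradients")) G$gradients else as.matrix(G)
  coordinates <- as.matrix(coordinates)
  m <- nrow(X)
  if (m < 4L) stop("need at least 4 voxels for RSA", call. = FALSE)
  if (nrow(coordinates) != m) {
    stop("coordinate rows (", nrow(coordinates), ") != voxel count (", m, ")",
         call. = FALSE)
  }
  if (n_perm < 99L) stop("n_perm must be >= 99", call. = FALSE)
  D <- gradient_dissimilarity(X)
  E <- as.matrix(dist(coordinates))
  ut <- upper.tri(D)
  ev <- E[ut]
  observed <- cor(D[ut], ev, method = cor_method)
  null <- numeric(n_perm)
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    p <- sample.int(m)
    null[b] <- cor(D[p, p][ut], ev, method = cor_method)
  }
  pval <- (sum(null >= observed) + 1) / (n_perm + 1)
  structure(list(observed_r = observed, null_distribution = null,
                 p_value = pval, cor_method = cor_method, n_perm = n_perm),
            class = "congradr_rsa")
}

#' @export
print.congradr_rsa <- function(x, ...) {
  cat(sprintf("<congradr_rsa> observed r = %.4f, p = %.4g (%d permutations, %s)\n",
              x$observed_r, x$p_value, x$n_perm, x$cor_method))
  invisible(x)
}

#' Spatial correlation between two voxel maps
#'
#' Pearson correlation over the voxels the two maps share. Maps may be bare
#' numeric vectors (matched positionally) or vectors named by voxel id, in
#' which case the intersection of ids is used.
#'
#' @param map_a,map_b numeric voxel maps.
#' @param method correlation type, default Pearson.
#' @return correlation coefficient (sign reported as-is).
#' @export
spatial_map_correlation <- function(map_a, map_b,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!is.null(names(map_a)) && !is.null(names(map_b))) {
    common <- intersect(names(map_a), names(map_b))
    map_a <- map_a[common]
    map_b <- map_b[common]
  } else if (length(map_a) != length(map_b)) {
    stop("unnamed maps must have equal length", call. = FALSE)
  }
  keep <- is.finite(map_a) & is.finite(map_b)
  if (sum(keep) < 3L) {
    stop("fewer than 3 common finite voxels", call. = FALSE)
  }
  cor(map_a[keep], map_b[keep], method = method)
}
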