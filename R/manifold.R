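# Gradient embedding: row-wise sparsification followed by Laplacian eigenmap,
# diffusion map embedding, or PCA.

#' Row-wise sparsification of a similarity matrix
#'
#' For each row the top `(1 - sparsity)` fraction of off-diagonal entries
#' (by value; `k = ceiling((1 - sparsity) * (m - 1))`, ties broken by column
#' index) is retained and the rest zeroed; the diagonal is excluded from
#' ranking and kept. The result is symmetrized by averaging with its
#' transpose. For the Laplacian/diffusion paths surviving negative entries
#' are clipped to zero (graph weights must be non-negative); the PCA path
#' consumes the signed sparsified matrix.
#'
#' @param S `congradr_similarity` or plain square symmetric matrix.
#' @param sparsity fraction of connections dropped per row, in `[0, 1)`;
#'   the conventional default is 0.9 (keep top 10%).
#' @param clip_negative clip negative entries to zero after symmetrization.
#' @return dense numeric affinity matrix with attribute `"sparsity"`.
#' @export
sparsify_rows <- function(S, sparsity = 0.9, clip_negative = TRUE) {
  if (inherits(S, "congradr_similarity")) S <- S$data
  assert_square_symmetric(S)
  if (!is.numeric(sparsity) || sparsity < 0 || sparsity >= 1) {
    stop("sparsity must be in [0, 1), got ", sparsity, call. = FALSE)
  }
  m <- nrow(S)
  k <- as.integer(ceiling((1 - sparsity) * (m - 1L)))
  if (k < 1L) {
    stop("sparsity ", sparsity, " retains zero off-diagonal entries per row",
         call. = FALSE)
  }
  W <- matrix(0, m, m)
  for (i in seq_len(m)) {
    off <- setdiff(seq_len(m), i)
    keep <- off[order(S[i, off], decreasing = TRUE)[seq_len(k)]]
    W[i, keep] <- S[i, keep]
  }
  W <- (W + t(W)) / 2
  diag(W) <- diag(S)
  if (clip_negative) W[W < 0] <- 0
  attr(W, "sparsity") <- sparsity
  W
}

new_gradient_set <- function(gradients, eigenvalues, method, variant,
                             explained_ratio, aligned = FALSE,
                             voxel_ids = seq_len(nrow(gradients))) {
  dimnames(gradients) <- NULL
  structure(
    list(gradients = gradients, eigenvalues = as.numeric(eigenvalues),
         method = method, variant = variant,
         explained_ratio = as.numeric(explained_ratio),
         aligned = aligned, voxel_ids = as.integer(voxel_ids)),
    class = "congradr_gradients"
  )
}

#' @export
print.congradr_gradients <- function(x, ...) {
  cat(sprintf(
    "<congradr_gradients> %d voxels x %d gradients, method=%s, variant=%s, %s\n",
    nrow(x$gradients), ncol(x$gradients), x$method, x$variant,
    if (isTRUE(x$aligned)) "aligned" else "unaligned"))
  cat("  explained ratio:", paste(sprintf("%.3f", x$explained_ratio),
                                  collapse = " "), "\n")
  invisible(x)
}

#' Embed a similarity matrix into gradients
#'
#' Converts a (sparsified) voxel-to-voxel similarity matrix into a
#' voxel-by-gradient embedding:
#'
#' * `LE` — Laplacian eigenmap: generalized eigenvectors of `L f = lambda D f`
#'   for the graph Laplacian of the non-negative affinity, taking the `g`
#'   smallest non-trivial eigenpairs (the constant eigenvector at
#'   `lambda = 0` is dropped).
#' * `DE` — diffusion map embedding with anisotropic normalization exponent
#'   `alpha` (default 0.5) and multiscale eigenvalue weighting
#'   `lambda / (1 - lambda)` at `diffusion_time = 0` (or `lambda^time`
#'   otherwise). Eigenvector columns are unit-normalized before weighting, so
#'   coordinate norms decay with the spectrum.
#' * `PCA` — principal axes of the column-centered (signed) sparsified
#'   matrix; gradients are the scores.
#'
#' Each gradient column has a fixed sign convention (largest-magnitude
#' coordinate positive) so unaligned output is reproducible. The dense
#' symmetric eigensolver is used throughout; matrices up to a few thousand
#' voxels are handled in well under a second.
#'
#' @param S `congradr_similarity`, or a plain matrix; a pre-sparsified
#'   affinity can be passed with `sparsity = NULL`.
#' @param method `"LE"`, `"DE"`, or `"PCA"`.
#' @param g number of gradients to keep (default 3).
#' @param sparsity row sparsification level applied before embedding
#'   (default 0.9); `NULL` or 0 to skip.
#' @param alpha diffusion-map anisotropic normalization exponent.
#' @param diffusion_time diffusion time; 0 selects multiscale weighting.
#' @return `congradr_gradients` carrying the m x g embedding, the `g`
#'   retained eigenvalues, per-gradient explained-variance ratios, and
#'   method/variant provenance.
#' @export
embed_gradients <- function(S, method = c("LE", "DE", "PCA"), g = 3L,
                            sparsity = 0.9, alpha = 0.5, diffusion_time = 0) {
  method <- match.arg(method)
  variant <- NA_character_
  voxel_ids <- NULL
  if (inherits(S, "congradr_similarity")) {
    variant <- S$variant
    voxel_ids <- S$voxel_ids
    S <- S$data
  }
  assert_square_symmetric(S)
  m <- nrow(S)
  voxel_ids <- voxel_ids %||% seq_len(m)
  if (g < 1L || g > m - 1L) {
    stop("g must be in [1, m-1] = [1, ", m - 1L, "], got ", g, call. = FALSE)
  }
  W <- if (is.null(sparsity) || identical(sparsity, 0)) {
    W0 <- S
    if (method != "PCA") W0[W0 < 0] <- 0
    W0
  } else {
    sparsify_rows(S, sparsity, clip_negative = method != "PCA")
  }

  if (method == "PCA") {
    X <- center_cols(W)
    sv <- svd(X)
    ev <- sv$d^2 / (m - 1)
    if (g > sum(sv$d > max(sv$d) * 1e-12)) {
      stop("g = ", g, " exceeds the rank of the centered similarity matrix",
           call. = FALSE)
    }
    scores <- sv$u[, seq_len(g), drop = FALSE] %*%
      diag(sv$d[seq_len(g)], g, g)
    return(new_gradient_set(
      fix_column_signs(scores), ev[seq_len(g)], method, variant,
      variance_explained(ev, "PCA")[seq_len(g)], voxel_ids = voxel_ids))
  }

  # graph methods need a connected non-negative affinity
  comp <- graph_components(W)
  if (max(comp) > 1L) {
    stop("affinity graph is disconnected (", max(comp), " components of sizes ",
         paste(tabulate(comp), collapse = ", "),
         "); lower the sparsity or check the similarity matrix", call. = FALSE)
  }
  d <- rowSums(W)

  if (method == "LE") {
    dh <- 1 / sqrt(d)
    Lsym <- diag(m) - (dh * W) * rep(dh, each = m) # D^-1/2 W D^-1/2
    e <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
    lam <- rev(e$values)          # ascending
    vec <- e$vectors[, m:1, drop = FALSE]
    lam_nt <- lam[-1L]            # drop trivial lambda = 0
    vec_nt <- vec[, -1L, drop = FALSE]
    grad <- dh * vec_nt[, seq_len(g), drop = FALSE]  # D^-1/2 u
    grad <- sweep(grad, 2L, sqrt(colSums(grad^2)), "/")
    return(new_gradient_set(
      fix_column_signs(grad), lam_nt[seq_len(g)], method, variant,
      variance_explained(pmax(lam_nt, 0), "LE")[seq_len(g)],
      voxel_ids = voxel_ids))
  }

  # DE
  da <- d^alpha
  W1 <- W / outer(da, da)
  d1 <- rowSums(W1)
  dh <- 1 / sqrt(d1)
  M <- (dh * W1) * rep(dh, each = m)
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)   # descending
  lam <- e$values
  vec <- e$vectors
  lam_nt <- lam[-1L]              # drop trivial lambda ~= 1
  vec_nt <- vec[, -1L, drop = FALSE]
  if (any(lam_nt[seq_len(g)] >= 1 - 1e-12)) {
    stop("diffusion operator has repeated unit eigenvalues; graph is ",
         "effectively disconnected", call. = FALSE)
  }
  w <- if (diffusion_time <= 0) {
    lam_nt[seq_len(g)] / (1 - lam_nt[seq_len(g)])
  } else {
    lam_nt[seq_len(g)]^diffusion_time
  }
  psi <- dh * vec_nt[, seq_len(g), drop = FALSE]   # right eigenvectors of P
  psi <- sweep(psi, 2L, sqrt(colSums(psi^2)), "/")
  grad <- sweep(psi, 2L, w, "*")
  new_gradient_set(
    fix_column_signs(grad), lam_nt[seq_len(g)], method, variant,
    variance_explained(pmax(lam_nt, 0), "DE")[seq_len(g)],
    voxel_ids = voxel_ids)
}

#' Explained-variance profile of an eigenvalue spectrum
#'
#' Normalizes a full (non-trivial) eigenvalue spectrum to per-component
#' ratios in `[0, 1]`. For `PCA` and `DE` the ratio is each eigenvalue over
#' the sum of the positive spectrum; for `LE` dominance is inverse to the
#' eigenvalue (small Laplacian eigenvalues are smooth, dominant modes), so
#' the ratio is `(1/lambda)` normalized over the spectrum.
#'
#' @param eigenvalues numeric spectrum as produced by [embed_gradients()]
#'   (non-trivial part, most dominant first per method convention).
#' @param method `"LE"`, `"DE"`, or `"PCA"`.
#' @return numeric vector of ratios, non-increasing, summing to at most 1.
#' @export
#' @examples
#' variance_explained(c(4, 2, 2), "PCA") # 0.50 0.25 0.25
variance_explained <- function(eigenvalues, method = c("LE", "DE", "PCA")) {
  method <- match.arg(method)
  ev <- as.numeric(eigenvalues)
  if (method == "PCA" && any(ev < -max(abs(ev)) * 1e-8)) {
    stop("negative PCA eigenvalues beyond numerical tolerance", call. = FALSE)
  }
  if (method == "LE") {
    if (any(ev < 0)) stop("Laplacian eigenvalues must be non-negative",
                          call. = FALSE)
    inv <- ifelse(ev > .Machine$double.eps, 1 / ev, Inf)
    if (any(!is.finite(inv))) {
      # zero eigenvalue beyond the trivial one: all dominance mass there
      r <- as.numeric(!is.finite(inv))
      return(r / sum(r))
    }
    return(inv / sum(inv))
  }
  pos <- pmax(ev, 0)
  if (sum(pos) <= 0) return(rep(0, length(ev)))
  pos / sum(pos)
}
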