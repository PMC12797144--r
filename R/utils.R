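# Internal helpers: seed spawning, column standardization, small checks.

#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic routines in the package draw their RNG state from a single
#' master seed through this deterministic spawning scheme, so that any
#' component can be re-run in isolation with the exact stream it saw inside
#' the full pipeline. The scheme hashes the master seed together with a
#' character key using a 32-bit multiplicative hash and returns a value in
#' `[0, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param key character label of the consumer (e.g. `"subject3/noise"`).
#' @return An integer usable with [set.seed()].
#' @export
#' @examples
#' spawn_seed(2024, "subject1")
spawn_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(key))
  h <- as.double(master) %% 2147483647
  for (ch in utf8ToInt(paste(key, collapse = "/"))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# z-score columns; error on zero-variance columns with their indices named
zscore_cols <- function(x, what = "matrix") {
  s <- apply(x, 2L, sd)
  bad <- which(!is.finite(s) | s < .Machine$double.eps^0.5 * 10)
  if (length(bad)) {
    stop(sprintf(
      "%s has %d zero-variance column(s): %s. Remove these voxels from the mask (e.g. re-run extraction, which drops and logs constant voxels).",
      what, length(bad), paste(head(bad, 10L), collapse = ", ")
    ), call. = FALSE)
  }
  scale(x, center = TRUE, scale = s)[, , drop = FALSE]
}

# center columns without rescaling
center_cols <- function(x) {
  sweep(x, 2L, colMeans(x), "-")
}

# unit-normalize columns (assumed already centered); used for correlation algebra
unitnorm_cols <- function(x) {
  nrm <- sqrt(colSums(x^2))
  sweep(x, 2L, nrm, "/")
}

assert_square_symmetric <- function(S, tol = 1e-8, what = "similarity matrix") {
  if (!is.matrix(S) || nrow(S) != ncol(S)) {
    stop(what, " must be a square matrix", call. = FALSE)
  }
  if (max(abs(S - t(S))) > tol) {
    stop(what, " is not symmetric within tolerance ", tol, call. = FALSE)
  }
  invisible(TRUE)
}

# connected components of a non-negative affinity matrix (BFS on W > 0)
graph_components <- function(W) {
  m <- nrow(W)
  comp <- integer(m)
  cur <- 0L
  for (i in seq_len(m)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      queue <- i
      comp[i] <- cur
      while (length(queue)) {
        v <- queue[1L]
        queue <- queue[-1L]
        nb <- which(W[v, ] > 0 & comp == 0L)
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  comp
}

# fixed sign convention: flip each column so its largest-|.| entry is positive
fix_column_signs <- function(G) {
  for (j in seq_len(ncol(G))) {
    k <- which.max(abs(G[, j]))
    if (G[k, j] < 0) G[, j] <- -G[, j]
  }
  G
}

`%||%` <- function(a, b) if (is.null(a)) b else a
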