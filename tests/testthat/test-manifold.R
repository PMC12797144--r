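# Sparsification and gradient embedding.

test_that("sparsify_rows keeps the top fraction per row (sort oracle)", {
  sparsify_oracle <- function(S, sparsity, clip = TRUE) {
    m <- nrow(S)
    k <- ceiling((1 - sparsity) * (m - 1))
    W <- matrix(0, m, m)
    for (i in seq_len(m)) {
      off <- setdiff(seq_len(m), i)
      keep <- off[order(S[i, off], decreasing = TRUE)[seq_len(k)]]
      W[i, keep] <- S[i, keep]
    }
    W <- (W + t(W)) / 2
    diag(W) <- diag(S)
    if (clip) W[W < 0] <- 0
    W
  }
  set.seed(3)
  X <- matrix(rnorm(25), 5, 5); S5 <- (X + t(X)) / 2; diag(S5) <- 1
  expect_equal(unname(sparsify_rows(S5, 0.6)),
               sparsify_oracle(S5, 0.6), tolerance = 1e-15,
               ignore_attr = TRUE)

  # 11 x 11: 10 off-diagonal entries per row, sparsity 0.9 -> exactly 1
  # retained per row before symmetrization (so at most 2 nonzero after)
  X <- matrix(runif(121), 11, 11); S11 <- (X + t(X)) / 2; diag(S11) <- 1
  W <- sparsify_rows(S11, 0.9)
  expect_equal(unname(W), sparsify_oracle(S11, 0.9), tolerance = 1e-15,
               ignore_attr = TRUE)
  # per-row retention before symmetrization is exactly 1 = ceiling(0.1 * 10)
  expect_equal(ceiling((1 - 0.9) * 10), 1)
  # and every row keeps at least its own top connection afterwards
  expect_true(all(rowSums(W > 0) - 1L >= 1))

  # sparsity 0: unchanged apart from negative clipping
  S5c <- S5; S5c[S5c < 0] <- 0
  expect_equal(unname(sparsify_rows(S5, 0)), unname(S5c),
               ignore_attr = TRUE)
  expect_equal(unname(sparsify_rows(S5, 0, clip_negative = FALSE)),
               unname(S5), ignore_attr = TRUE)
  expect_error(sparsify_rows(S5, 1), "sparsity")
})

test_that("two-block similarity: gradient 1 sign-separates the blocks", {
  blocks <- matrix(0.05, 20, 20)
  blocks[1:10, 1:10] <- 1
  blocks[11:20, 11:20] <- 1
  set.seed(30)
  J <- matrix(rnorm(400, sd = 0.005), 20, 20)  # break exact rank degeneracy
  blocks <- blocks + (J + t(J)) / 2
  diag(blocks) <- 1
  for (m in c("LE", "DE", "PCA")) {
    G <- embed_gradients(blocks, m, g = 2, sparsity = NULL)
    g1 <- G$gradients[, 1]
    expect_true(all(sign(g1[1:10]) == sign(g1[1])), label = m)
    expect_true(all(sign(g1[11:20]) == -sign(g1[1])), label = m)
  }
})

test_that("exchangeable voxels give a degenerate spectrum", {
  S <- matrix(0.5, 12, 12); diag(S) <- 1
  for (m in c("LE", "DE", "PCA")) {
    G <- embed_gradients(S, m, g = 3, sparsity = NULL)
    r <- G$explained_ratio
    expect_lt(diff(range(r)), 1e-8)
  }
})

test_that("variance profiles: arithmetic, ordering, dense-solver oracle", {
  expect_equal(variance_explained(c(4, 2, 2), "PCA"), c(0.5, 0.25, 0.25))
  expect_equal(variance_explained(rep(3, 5), "DE"), rep(0.2, 5))
  expect_error(variance_explained(c(1, -0.5), "PCA"), "negative")

  # random PSD matrix: PCA ratios match trace-normalized dense eigenvalues
  set.seed(9)
  A <- matrix(rnorm(100), 10, 10)
  P <- crossprod(A)
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(variance_explained(ev, "PCA"), ev / sum(ev))
  # LE: inverse-eigenvalue weighting, non-increasing in [0, 1]
  r <- variance_explained(sort(abs(rnorm(6)) + 0.1), "LE")
  expect_true(all(diff(r) <= 1e-12) && all(r >= 0 & r <= 1))
  expect_equal(sum(r), 1)

  # PCA on a rank-2 similarity matrix: two nonzero components
  u <- rnorm(15); v <- rnorm(15)
  S2 <- tcrossprod(u) + tcrossprod(v)
  G <- embed_gradients(S2, "PCA", g = 2, sparsity = NULL)
  expect_equal(sum(G$explained_ratio), 1, tolerance = 1e-8)
})

test_that("embedding determinism, sign convention, permutation equivariance", {
  set.seed(12)
  X <- matrix(runif(30 * 30), 30, 30)
  S <- (X + t(X)) / 2; diag(S) <- 1
  for (m in c("LE", "DE", "PCA")) {
    G1 <- embed_gradients(S, m, g = 3, sparsity = 0.5)
    G2 <- embed_gradients(S, m, g = 3, sparsity = 0.5)
    expect_identical(G1$gradients, G2$gradients)
    # largest-|.| coordinate positive in every column
    expect_true(all(apply(G1$gradients, 2,
                          function(cl) cl[which.max(abs(cl))] > 0)))
    # permuting voxels permutes gradients
    set.seed(match(m, c("LE", "DE", "PCA")))
    p <- sample(30)
    Gp <- embed_gradients(S[p, p], m, g = 3, sparsity = 0.5)
    expect_lt(max(abs(abs(Gp$gradients) - abs(G1$gradients[p, ]))), 1e-8)
  }
})

test_that("LE eigenvalues non-negative; DE coordinate norms decay", {
  set.seed(21)
  X <- matrix(runif(40 * 40), 40, 40)
  S <- (X + t(X)) / 2; diag(S) <- 1
  Gle <- embed_gradients(S, "LE", g = 5, sparsity = 0.5)
  expect_true(all(Gle$eigenvalues >= -1e-12))
  expect_true(all(diff(Gle$eigenvalues) >= -1e-12))
  Gde <- embed_gradients(S, "DE", g = 5, sparsity = 0.5)
  nrm <- sqrt(colSums(Gde$gradients^2))
  expect_true(all(diff(nrm) <= 1e-12))
})

test_that("disconnected graphs and invalid g are rejected", {
  S <- diag(6)
  S[1:3, 1:3] <- 1
  S[4:6, 4:6] <- 1
  expect_error(embed_gradients(S, "LE", g = 1, sparsity = NULL),
               "disconnected .*2 components")
  X <- matrix(runif(36), 6, 6); Sx <- (X + t(X)) / 2; diag(Sx) <- 1
  expect_error(embed_gradients(Sx, "LE", g = 6, sparsity = NULL), "g must be")
})
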