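# Group templates, Hungarian matching, Procrustes, stability, comparisons.

make_gradients <- function(G, method = "DE", variant = "voxelwise") {
  congradr:::new_gradient_set(G, seq(ncol(G), 1), method, variant,
                              rep(1 / ncol(G), ncol(G)))
}

test_that("group template averages similarity matrices (accumulation oracle)", {
  sims <- lapply(1:5, function(s) {
    set.seed(s)
    X <- matrix(rnorm(400), 20, 20)
    S <- cov2cor(crossprod(X))
    congradr:::new_similarity(S, "cosine", "voxelwise")
  })
  tm <- group_template(sims, method = "PCA", g = 2, sparsity = 0)
  acc <- matrix(0, 20, 20)
  for (s in sims) acc <- acc + s$data
  expect_lt(max(abs(tm$mean_similarity$data - acc / 5)), 1e-12)

  # single subject: template gradients equal the subject's own
  tm1 <- group_template(sims[1], method = "PCA", g = 2, sparsity = 0)
  g1 <- embed_gradients(sims[[1]], "PCA", g = 2, sparsity = 0)
  expect_equal(tm1$group_gradients$gradients, g1$gradients)
  # two identical subjects: mean equals either input
  tm2 <- group_template(sims[c(1, 1)], method = "PCA", g = 2, sparsity = 0)
  expect_equal(tm2$mean_similarity$data, sims[[1]]$data)

  expect_error(group_template(list(sims[[1]],
                                   congradr:::new_similarity(diag(5), "cosine"))),
               "differ in size")
})

test_that("Hungarian matching recovers permutations and sign flips", {
  set.seed(3)
  Gg <- make_gradients(matrix(rnorm(150), 50, 3))
  # individual = group columns in order (2,3,1), first column negated
  Gi <- make_gradients(cbind(-Gg$gradients[, 2], Gg$gradients[, 3],
                             Gg$gradients[, 1]))
  mt <- match_hungarian(Gi, Gg)
  expect_identical(mt$permutation, c(2L, 3L, 1L))
  expect_equal(mt$signs, c(-1, 1, 1))
  expect_equal(mt$match_scores, rep(1, 3))
  expect_equal(apply_match(Gi, mt)$gradients, Gg$gradients)

  # identity case
  mt0 <- match_hungarian(Gg, Gg)
  expect_identical(mt0$permutation, 1:3)
  expect_equal(mt0$signs, rep(1, 3))

  # random pair: assignment matches exhaustive search over all 3! bijections
  Gi2 <- make_gradients(matrix(rnorm(150), 50, 3))
  mt2 <- match_hungarian(Gi2, Gg)
  A <- abs(cor(Gi2$gradients, Gg$gradients))
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  scores <- vapply(perms, function(p) sum(A[cbind(1:3, p)]), numeric(1))
  expect_equal(sum(A[cbind(1:3, mt2$permutation)]), max(scores))
  # total score at least that of the identity assignment
  expect_gte(sum(mt2$match_scores), sum(diag(A)))

  expect_error(match_hungarian(make_gradients(matrix(rnorm(100), 50, 2)), Gg),
               "gradient counts differ")
})

test_that("Procrustes recovers orthogonal rotations exactly", {
  set.seed(5)
  Gg <- make_gradients(matrix(rnorm(120), 40, 3))
  Q0 <- random_orthogonal(3, seed = 6)
  Gi <- make_gradients(Gg$gradients %*% Q0)
  al <- procrustes_align(Gi, Gg)
  expect_lt(sqrt(sum((al$gradients - Gg$gradients)^2)), 1e-8)
  expect_true(al$aligned)
  Q <- attr(al, "rotation")
  expect_lt(max(abs(crossprod(Q) - diag(3))), 1e-10)

  # identity input: transform is the identity
  al0 <- procrustes_align(Gg, Gg)
  expect_lt(max(abs(attr(al0, "rotation") - diag(3))), 1e-10)
})

test_that("Procrustes is optimal and preserves the column space", {
  set.seed(8)
  Gg <- make_gradients(matrix(rnorm(120), 40, 3))
  Gi <- make_gradients(matrix(rnorm(120), 40, 3))
  al <- procrustes_align(Gi, Gg)
  d_post <- sum((al$gradients - Gg$gradients)^2)

  # alignment cannot be worse than the norm-matched unrotated configuration
  Xc <- scale(Gi$gradients, scale = FALSE)
  Yc <- scale(Gg$gradients, scale = FALSE)
  Xn <- Xc / sqrt(sum(Xc^2)) * sqrt(sum(Yc^2))
  d_pre <- sum((sweep(Xn, 2, colMeans(Gg$gradients), "+") - Gg$gradients)^2)
  expect_lte(d_post, d_pre + 1e-12)

  # closed-form optimum from the independent oracle
  if (requireNamespace("vegan", quietly = TRUE)) {
    vp <- vegan::procrustes(Yc / sqrt(sum(Yc^2)), Xc / sqrt(sum(Xc^2)),
                            scale = FALSE)
    expect_lt(max(abs(attr(al, "rotation") - vp$rotation)), 1e-10)
  }

  # subspace unchanged: canonical correlations between column spaces are 1
  cc <- svd(crossprod(svd(Xc)$u, svd(al$gradients -
    matrix(colMeans(al$gradients), 40, 3, byrow = TRUE))$u))$d
  expect_lt(max(abs(cc - 1)), 1e-10)

  # rank-degenerate input is rejected
  Gdeg <- make_gradients(cbind(Gi$gradients[, 1], Gi$gradients[, 1],
                               Gi$gradients[, 2]))
  expect_error(procrustes_align(Gdeg, Gg), "rank-degenerate")
})

test_that("gradient stability: trivial cases and loop oracle", {
  set.seed(10)
  Gg <- make_gradients(matrix(rnorm(90), 30, 3))
  same <- lapply(1:4, function(i) Gg)
  expect_equal(gradient_stability(same, Gg), rep(1, 3))

  noisy <- lapply(1:6, function(i) {
    set.seed(100 + i)
    make_gradients(Gg$gradients + matrix(rnorm(90, sd = 2), 30, 3))
  })
  st <- gradient_stability(noisy, Gg)
  loop <- rowMeans(vapply(noisy, function(nn) {
    abs(diag(cor(nn$gradients, Gg$gradients)))
  }, numeric(3)))
  expect_lt(max(abs(st - loop)), 1e-12)

  # pure-noise individuals: stability is low
  pure <- lapply(1:10, function(i) {
    set.seed(200 + i)
    make_gradients(matrix(rnorm(90), 30, 3))
  })
  expect_true(all(gradient_stability(pure, Gg) < 0.5))
  expect_identical(retain_gradients(c(0.9, 0.6, 0.3)),
                   c(TRUE, TRUE, FALSE))
  expect_error(gradient_stability(list(), Gg), "empty")
})

test_that("cross-variant similarity: self = 1, aligned rejected", {
  set.seed(12)
  g1 <- make_gradients(matrix(rnorm(90), 30, 3))
  g2 <- make_gradients(matrix(rnorm(90), 30, 3))
  gsets <- list(list(a = g1, b = g2), list(a = g2, b = g1))
  M <- unaligned_cross_variant_similarity(gsets)
  expect_equal(unname(diag(M)), c(1, 1))
  expect_equal(M, t(M))
  al <- g1; al$aligned <- TRUE
  expect_error(unaligned_cross_variant_similarity(list(list(a = al, b = g2))),
               "unaligned")
})

test_that("z-scored difference maps: zero case and hand arithmetic", {
  set.seed(14)
  G <- matrix(rnorm(60), 20, 3)
  expect_true(all(zscore_and_difference(G, G) == 0))

  # analytic pair: column (1..4) has mean 2.5, sd ~1.29
  local <- matrix(c(1, 2, 3, 4), 4, 2)
  globl <- matrix(c(2, 4, 6, 8), 4, 2)
  d <- zscore_and_difference(local, globl)
  zl <- (c(1, 2, 3, 4) - 2.5) / sd(c(1, 2, 3, 4))
  zg <- (c(2, 4, 6, 8) - 5) / sd(c(2, 4, 6, 8))
  expect_equal(d[, 1], zl - zg)
  expect_error(zscore_and_difference(local, matrix(0, 3, 2)),
               "share dimensions")
})
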