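# Fingerprints and similarity matrices.

test_that("spatial modes: dimensions, ordering, reconstruction", {
  tgt <- random_ts(20, 40, seed = 1, region_tag = "target")
  sm <- compute_spatial_modes(tgt)
  expect_equal(sm$p, 19L) # min(t - 1, n)
  expect_true(all(diff(sm$singular_values) <= 0))
  # columns mutually orthogonal
  gram <- crossprod(sm$modes)
  expect_lt(max(abs(gram - diag(diag(gram)))), 1e-8)
  # full-rank SVD reconstruction oracle: B ~ modes %*% t(V)
  recon <- sm$modes %*% t(sm$v)
  expect_lt(max(abs(recon - tgt$data)), 1e-8)

  # p larger than t - 1 rejected
  expect_error(compute_spatial_modes(tgt, p = 20), "min\\(t-1, n\\)")
  # n smaller than t - 1 caps p at n
  expect_equal(compute_spatial_modes(random_ts(10, 5, 2, "target"))$p, 5L)
})

test_that("degenerate (constant) voxels are rejected at ingestion", {
  x <- matrix(rnorm(30), 10, 3)
  x[, 2] <- 7
  expect_error(timeseries_matrix(x, region_tag = "target"),
               "zero-variance column\\(s\\): 2")
})

test_that("fingerprint variants: definitions and errors", {
  seed <- random_ts(20, 15, seed = 1)
  tgt <- random_ts(20, 40, seed = 2, region_tag = "target")

  # voxelwise: seed voxel equal to target voxel k gives entry 1
  tgt2 <- timeseries_matrix(cbind(seed$data[, 3], tgt$data[, -1]),
                            region_tag = "target")
  fv <- fingerprints(seed, tgt2, "voxelwise")
  expect_equal(fv$data[3, 1], 1)
  expect_true(all(abs(fv$data) <= 1 + 1e-12))

  # rescaled = original scaled column-wise by the singular values
  sm <- compute_spatial_modes(tgt)
  fo <- fingerprints(seed, tgt, "original", modes = sm)
  fr <- fingerprints(seed, tgt, "rescaled", modes = sm)
  expect_equal(fr$data, sweep(fo$data, 2, sm$singular_values, "*"))
  expect_true(all(abs(fo$data) <= 1 + 1e-12))

  # row-wise inner products of rescaled == voxelwise up to one global factor
  gr <- tcrossprod(fr$data)
  gv <- tcrossprod(fingerprints(seed, tgt, "voxelwise")$data)
  ratio <- gr[1, 1] / gv[1, 1]
  expect_lt(max(abs(gr - ratio * gv)) / max(abs(gr)), 1e-6)

  expect_error(fingerprints(seed, random_ts(21, 10, 3, "target")),
               "timepoint counts differ")
})

test_that("within-seed FC equals the pairwise Pearson loop", {
  seed <- random_ts(30, 10, seed = 7)
  S <- within_seed_fc(seed)
  loop <- matrix(1, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    loop[i, j] <- cor(seed$data[, i], seed$data[, j])
  }
  expect_lt(max(abs(S$data - loop)), 1e-12)
  expect_identical(S$measure, "pearson_fc")

  # duplicated and sign-flipped voxels
  x <- matrix(rnorm(40), 20, 2)
  dup <- timeseries_matrix(cbind(x, x[, 1], -x[, 2]))
  Sd <- within_seed_fc(dup)$data
  expect_equal(Sd[1, 3], 1)
  expect_equal(Sd[2, 4], -1)
})

test_that("eta2 and cosine similarity: hand cases and naive oracle", {
  # hand evaluation: rows (1,2) and (3,4) -> pointwise means (2,3),
  # grand mean 2.5, eta2 = 1 - 4/5
  expect_equal(similarity(rbind(c(1, 2), c(3, 4)), "eta2")$data[1, 2], 0.2)
  expect_equal(similarity(rbind(c(1, 5), c(1, 5)), "eta2")$data[1, 2], 1)
  expect_equal(similarity(rbind(c(1, 0), c(0, 1)), "cosine")$data[1, 2], 0)
  expect_equal(similarity(rbind(c(1, 2), c(2, 4)), "cosine")$data[1, 2], 1)

  # naive two-loop eta2 oracle on random 5 x 4 fingerprints
  set.seed(11)
  fp <- matrix(rnorm(20), 5, 4)
  S <- similarity(fp, "eta2")$data
  for (i in 1:5) for (j in 1:5) {
    if (i == j) next
    a <- fp[i, ]; b <- fp[j, ]
    mm <- (a + b) / 2; M <- mean(mm)
    ref <- 1 - sum((a - mm)^2 + (b - mm)^2) / sum((a - M)^2 + (b - M)^2)
    expect_lt(abs(S[i, j] - ref), 1e-12)
  }

  expect_error(similarity(rbind(c(0, 0), c(1, 2)), "cosine"), "all-zero")
})

test_that("similarity invariants hold on random fingerprints", {
  for (s in 1:5) {
    set.seed(s)
    fp <- matrix(rnorm(80), 10, 8)
    for (meas in c("cosine", "eta2")) {
      S <- similarity(fp, meas)$data
      expect_lt(max(abs(S - t(S))), 1e-12)
      expect_equal(unname(diag(S)), rep(1, 10))
      if (meas == "eta2") {
        expect_true(all(S >= -1e-12 & S <= 1 + 1e-12))
      } else {
        expect_true(all(abs(S) <= 1 + 1e-12))
      }
    }
  }
})

test_that("blockwise similarity matches the single-block path", {
  set.seed(4)
  fp <- matrix(rnorm(12 * 37), 12, 37)
  for (meas in c("cosine", "eta2")) {
    expect_lt(max(abs(similarity(fp, meas, block_size = 5L)$data -
                      similarity(fp, meas, block_size = 10000L)$data)), 1e-12)
  }
})

test_that("equivalence identities: original==within-seed, rescaled==voxelwise", {
  seed <- random_ts(20, 15, seed = 1)
  tgt <- random_ts(20, 40, seed = 2, region_tag = "target") # n >= t - 1
  S_or <- build_similarity(seed, tgt, "original", "cosine")
  S_ws <- build_similarity(seed, variant = "within_seed")
  expect_lt(max(abs(S_or$data - S_ws$data)), 1e-8)

  S_re <- build_similarity(seed, tgt, "rescaled", "cosine")
  S_vx <- build_similarity(seed, tgt, "voxelwise", "cosine")
  expect_lt(max(abs(S_re$data - S_vx$data)), 1e-8)

  # provenance recorded
  expect_identical(S_re$variant, "rescaled")
  expect_identical(S_re$measure, "cosine")
  expect_identical(build_similarity(seed, variant = "within_seed")$data,
                   within_seed_fc(seed)$data)
  expect_error(build_similarity(seed, variant = "within_seed",
                                measure = "cosine"), "not applicable")
})

test_that("voxelwise similarity is invariant to orthogonal target recombination", {
  # signed permutations preserve column norms, so the correlation step sees
  # an exact orthogonal rotation of the target representation; the general
  # rotation case is covered by the rescaled==voxelwise identity (V rotation)
  seed <- random_ts(12, 10, seed = 5)
  tgt <- random_ts(12, 10, seed = 6, region_tag = "target")
  set.seed(8)
  perm <- sample(10)
  signs <- sample(c(-1, 1), 10, replace = TRUE)
  tgt_rot <- timeseries_matrix(sweep(tgt$data[, perm], 2, signs, "*"),
                               region_tag = "target")
  S1 <- build_similarity(seed, tgt, "voxelwise", "cosine")$data
  S2 <- build_similarity(seed, tgt_rot, "voxelwise", "cosine")$data
  expect_lt(max(abs(S1 - S2)), 1e-10)
})
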