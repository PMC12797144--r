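# Nucleus classification and phenotype prediction.

make_separable <- function(n_per = 15, classes = 6, seed = 1) {
  set.seed(seed)
  y <- rep(seq_len(classes), each = n_per)
  g1 <- y + rnorm(length(y), sd = 0.01)    # thresholds on gradient 1
  G <- cbind(g1, rnorm(length(y)), rnorm(length(y)))
  list(G = G, y = y)
}

test_that("classification: separable case, determinism, errors", {
  d <- make_separable()
  cls <- classify_nuclei(d$G, d$y, repetitions = 3, seed = 5)
  expect_equal(cls$per_rep_accuracy, rep(1, 3))
  # fold log is a stratified partition
  expect_true(all(apply(cls$fold_log, 1, function(f) all(table(f) == 18))))

  cls2 <- classify_nuclei(d$G, d$y, repetitions = 3, seed = 5)
  expect_identical(cls$per_rep_accuracy, cls2$per_rep_accuracy)

  expect_error(classify_nuclei(d$G, rep(c(1, 2), c(3, 87)), k_folds = 5),
               "smaller than the fold count")
  expect_error(classify_nuclei(d$G, rep(1, 90)), "at least 2")
})

test_that("shuffled labels give chance-level accuracy", {
  d <- make_separable(n_per = 20)
  set.seed(9)
  y_perm <- sample(d$y)
  cls <- classify_nuclei(d$G, y_perm, repetitions = 10, seed = 2)
  se <- sd(cls$per_rep_accuracy) / sqrt(10)
  # mean accuracy within 3 SE of 1/6 (plus a small floor for the SE
  # estimate itself)
  expect_lt(abs(mean(cls$per_rep_accuracy) - 1 / 6), 3 * se + 0.03)

  ch <- chance_accuracy(y_perm, d$G, n_perm = 30, seed = 4)
  expect_lt(abs(ch$chance - 1 / 6), 0.05)
  ch2 <- chance_accuracy(y_perm, d$G, n_perm = 30, seed = 4)
  expect_identical(ch$null, ch2$null)
})

test_that("LASSO recovers planted signal and stays null on noise", {
  set.seed(11)
  n <- 100; p <- 60
  X <- matrix(rnorm(n * p), n, p)
  Z <- zscore_within_subject(X)
  w <- numeric(p); w[1:5] <- c(3, -2, 1.5, 2.5, -1)
  y <- as.numeric(Z %*% w)   # noiseless linear function of 5 features
  fit <- lasso_predict(X, y, outer = 5, inner = 5, repetitions = 3, seed = 11)
  expect_gte(mean(fit$per_rep_rho), 0.95)
  # recovered weights concentrate on the planted features
  ord <- order(abs(fit$weight_map), decreasing = TRUE)
  expect_true(all(1:5 %in% ord[1:10]))

  # null: phenotype independent of features; average over independent
  # draws (per-repetition values share the data and are highly correlated,
  # so repetitions alone do not shrink the estimator's variance)
  null_means <- vapply(1:3, function(d) {
    set.seed(12 + d)
    mean(lasso_predict(X, rnorm(n), outer = 5, inner = 5, repetitions = 3,
                       seed = 12 + d)$per_rep_rho)
  }, numeric(1))
  expect_lt(abs(mean(null_means)), 0.1)

  # determinism
  fitb <- lasso_predict(X, y, outer = 5, inner = 5, repetitions = 3,
                        seed = 11)
  expect_identical(fit$per_rep_rho, fitb$per_rep_rho)

  # nested-CV hygiene: outer folds partition the subjects every repetition
  expect_true(all(apply(fit$fold_log, 1,
                        function(f) length(unique(f)) == 5 &&
                          all(tabulate(f) == 20))))

  expect_error(lasso_predict(X, rep(1, n)), "constant")
  expect_message(lasso_predict(X, replace(y, 1:3, NA), outer = 5, inner = 5,
                               repetitions = 1, seed = 1), "dropping 3")
})

test_that("significance summary: closed cases and per-element oracle", {
  expect_equal(significance_summary(rep(0.9, 10), 100), 1)
  expect_equal(significance_summary(rep(0, 10), 100), 0)
  rho <- c(0.9, 0.5, 0.05, -0.3, 0.25)
  n <- 60; k <- 4
  frac <- significance_summary(rho, n, n_comparisons = k)
  p <- pt(rho * sqrt((n - 2) / (1 - rho^2)), n - 2, lower.tail = FALSE)
  expect_equal(frac, mean(pmin(p * k, 1) < 0.05 & rho > 0))
  expect_error(significance_summary(rho, 3), ">= 5")
})

test_that("nucleus contributions: trivial cases and group-by oracle", {
  labels <- rep(1:4, each = 5)
  W <- matrix(0, 20, 3)
  W[labels == 2, ] <- 1
  ct <- nucleus_contribution(W, labels)
  expect_equal(unname(ct["2"]), 1)

  W2 <- matrix(0.7, 20, 3)
  expect_equal(unname(nucleus_contribution(W2, labels)), rep(0.25, 4))

  set.seed(6)
  W3 <- matrix(rnorm(60), 20, 3)
  ct3 <- nucleus_contribution(W3, labels)
  ref <- tapply(rowMeans(abs(W3)), labels, mean)
  expect_lt(max(abs(ct3 - ref / sum(ref))), 1e-12)

  expect_warning(nucleus_contribution(W3, rep(c(1, 2, 0), c(10, 10, 0))),
                 NA) # background handled silently, no empty class here
})

test_that("weight-map consistency matches the rank-then-Pearson oracle", {
  set.seed(7)
  a <- matrix(rnorm(30), 10, 3)
  b <- matrix(rnorm(30), 10, 3)
  expect_equal(weight_consistency(a, a), 1)
  av <- as.numeric(a)
  expect_equal(weight_consistency(a, matrix(-av, 10, 3)), -1)
  expect_lt(abs(weight_consistency(a, b) -
                cor(rank(as.numeric(a)), rank(as.numeric(b)))), 1e-12)
  expect_error(weight_consistency(a, matrix(0, 10, 3)), "all-zero")
})
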