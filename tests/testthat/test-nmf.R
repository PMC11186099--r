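test_that("rank-1 matrices are factorized essentially exactly", {
  set.seed(1)
  u <- rexp(40); v <- rexp(25)
  X <- outer(u, v)
  dimnames(X) <- list(sprintf("g%02d", 1:40), sprintf("c%02d", 1:25))
  r <- nmf_once(X, k = 1, seed = 2, max_iter = 2000, tol = 0)
  expect_lt(r$frobenius_error / sqrt(sum(X^2)), 1e-6)
})

test_that("planted rank-3 factors are recovered up to permutation and scale", {
  set.seed(3)
  W0 <- matrix(rexp(60 * 3), 60)
  H0 <- matrix(rexp(3 * 40), 3)
  X <- W0 %*% H0
  r <- nmf_once(X, k = 3, seed = 5, max_iter = 3000, tol = 0)
  expect_lt(r$frobenius_error / sqrt(sum(X^2)), 1e-4)
  cosines <- perm_match_cosine(W0, r$W)
  expect_true(all(cosines >= 0.95))
})

test_that("the multiplicative-update objective never increases", {
  set.seed(4)
  X <- matrix(rexp(50 * 30), 50)
  r <- nmf_once(X, k = 4, seed = 6, max_iter = 200, tol = 0,
                trace_error = TRUE)
  d <- diff(r$error_trace)
  expect_true(all(d <= 1e-6 * r$error_trace[1]))
})

test_that("input validation rejects bad ranks and missing values", {
  X <- matrix(1, 5, 5)
  expect_error(nmf_once(X, k = 5), "out of range")
  X[1, 1] <- NA
  expect_error(nmf_once(X, k = 2), "NaN")
  expect_error(nmf_once(matrix(-1, 4, 4), k = 2), "non-negative")
})

test_that("restarts are deterministic and reach the planted optimum often", {
  set.seed(8)
  X <- matrix(rexp(40 * 3), 40) %*% matrix(rexp(3 * 30), 3)
  a <- nmf_restarts(X, k = 3, n_restarts = 10, seed = 1,
                    max_iter = 4000, tol = 0)
  b <- nmf_restarts(X, k = 3, n_restarts = 10, seed = 1,
                    max_iter = 4000, tol = 0)
  errs <- vapply(a, function(r) r$frobenius_error, numeric(1))
  expect_identical(errs, vapply(b, function(r) r$frobenius_error,
                                numeric(1)))
  expect_true(all(errs >= min(errs)))
  expect_gte(mean(errs / sqrt(sum(X^2)) <= 1e-3), 0.8)
})

test_that("outlier filtering isolates the odd component out", {
  base <- c(1, rep(0, 9))
  comps <- matrix(rep(base, 9), 10)
  orth <- c(rep(0, 9), 1)
  comps <- cbind(comps, orth)
  fl <- filter_outlier_components(comps, rate = 0.10)
  expect_identical(fl$kept_index, 1:9)

  fl0 <- filter_outlier_components(comps, rate = 0)
  expect_identical(ncol(fl0$kept), 10L)

  set.seed(2)
  big <- matrix(abs(rnorm(20 * 40)), 20)
  big <- sweep(big, 2, sqrt(colSums(big^2)), "/")
  fl2 <- filter_outlier_components(big, rate = 0.25)
  expect_equal(ncol(fl2$kept), 40 - floor(0.25 * 40))
  expect_error(filter_outlier_components(big[, 1, drop = FALSE]),
               "fewer than 2")
})

test_that("consensus equals bundle medians on tight noiseless bundles", {
  set.seed(5)
  centers <- diag(3)[, c(1, 2, 3)]
  comps <- cbind(matrix(centers[, 1], 3, 5), matrix(centers[, 2], 3, 3),
                 matrix(centers[, 3], 3, 2))
  comps <- comps + abs(matrix(rnorm(30, 0, 1e-4), 3))
  comps <- sweep(comps, 2, sqrt(colSums(comps^2)), "/")
  rownames(comps) <- c("a", "b", "c")
  W <- consensus_components(comps, 3, seed = 1)
  # columns ordered by cluster size: 5, 3, 2
  med1 <- apply(comps[, 1:5], 1, median)
  expect_equal(unname(W[, 1]), unname(med1 / sqrt(sum(med1^2))),
               tolerance = 1e-12)
  # permuting the inputs gives the same consensus under the ordering rule
  W2 <- consensus_components(comps[, c(6:8, 1:5, 9:10)], 3, seed = 1)
  expect_equal(W, W2, tolerance = 1e-6)
})

test_that("NNLS refit is exact and matches the reference solver", {
  set.seed(6)
  W <- matrix(rexp(30 * 4), 30)
  h <- c(2, 0, 1.5, 0)
  x <- W %*% h
  H <- refit_activities(cbind(cell = as.numeric(x)), W)
  expect_lt(max(abs(H[, 1] - h)), 1e-8)

  z <- refit_activities(cbind(zero = rep(0, 30)), W)
  expect_true(all(z == 0))

  skip_if_not_installed("pracma")
  X <- matrix(rexp(30 * 8), 30)
  H2 <- refit_activities(X, W)
  expect_true(all(H2 >= 0))
  for (j in seq_len(ncol(X))) {
    ref <- pracma::lsqnonneg(W, X[, j])$x
    expect_equal(unname(H2[, j]), ref, tolerance = 1e-6)
  }
})

test_that("Z-scoring weights centres, scales, and preserves ranks", {
  W <- cbind(p1 = c(1, 2, 3), p2 = c(5, 1, 2))
  rownames(W) <- c("a", "b", "c")
  Z <- zscore_weights(W)
  expect_equal(unname(Z[, 1]), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)
  expect_true(all(abs(colMeans(Z)) < 1e-9))
  expect_true(all(abs(sqrt(colMeans(Z^2)) - 1) < 1e-9))
  expect_identical(order(Z[, 2]), order(W[, 2]))
  expect_error(zscore_weights(cbind(c(1, 1, 1))), "zero-SD")
})

test_that("consensus factorization recovers planted programs stably", {
  set.seed(9)
  k <- 5
  W0 <- matrix(0, 80, k)
  for (j in seq_len(k)) W0[((j - 1) * 16 + 1):(j * 16), j] <- rexp(16) + 1
  H0 <- matrix(rexp(k * 60), k)
  X <- W0 %*% H0 + matrix(abs(rnorm(80 * 60, 0, 0.05)), 80)
  dimnames(X) <- list(sprintf("g%02d", 1:80), sprintf("c%02d", 1:60))
  c1 <- consensus_nmf(X, k, n_restarts = 12, seed = 1, max_iter = 400,
                      refit = TRUE)
  expect_true(all(perm_match_cosine(W0, c1$W_consensus) >= 0.95))
  expect_true(all(c1$H_consensus >= 0))
  expect_true(all(abs(colMeans(c1$Wz)) < 1e-9))
  expect_equal(c1$kept_component_fraction, 1 - floor(0.1 * 12 * k) / (12 * k))

  # stability across master seeds
  c2 <- consensus_nmf(X, k, n_restarts = 12, seed = 77, max_iter = 400)
  expect_gte(median(perm_match_cosine(c1$W_consensus, c2$W_consensus)),
             0.95)

  # replicate-level filtering variant keeps whole restarts
  c3 <- consensus_nmf(X, k, n_restarts = 12, seed = 1, max_iter = 200,
                      filter_level = "replicate")
  expect_equal(c3$kept_component_fraction, 11 / 12)
})
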