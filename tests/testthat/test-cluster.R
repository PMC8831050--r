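test_that("single-component EM reduces to the sample moments", {
  set.seed(1)
  X <- matrix(rnorm(60, 5, 2), 30, 2)
  f <- emFit(X, 1, seed = 1)
  expect_equal(as.numeric(f$model@means), colMeans(X), tolerance = 1e-8)
  expect_equal(f$model@weights, 1.0)
  R <- emResponsibilities(f$model, X)
  expect_true(all(abs(R - 1) < 1e-12))
})

test_that("EM recovers two well-separated 1-D populations", {
  set.seed(2)
  x <- matrix(c(rnorm(500, 0, 1), rnorm(500, 10, 1)), ncol = 1)
  f <- emFit(x, 2, seed = 3)
  mu <- sort(as.numeric(f$model@means))
  expect_lt(abs(mu[1] - 0), 0.3)
  expect_lt(abs(mu[2] - 10), 0.3)
  expect_true(all(diff(f$model@logLikTrace) > -1e-9))
})

test_that("responsibilities are row-stochastic and match a brute-force density oracle", {
  set.seed(3)
  X <- matrix(rnorm(40), 20, 2)
  f <- emFit(X, 2, seed = 1)
  R <- emResponsibilities(f$model, X)
  expect_equal(rowSums(R), rep(1, 20), tolerance = 1e-9)

  # independent oracle: explicit weighted normal densities per component
  pts <- matrix(rnorm(10), 5, 2)
  m <- f$model
  num <- sapply(seq_len(m@k), function(cc)
    m@weights[cc] * apply(pts, 1, function(p)
      prod(dnorm(p, m@means[cc, ], m@sds[cc, ]))))
  oracle <- num / rowSums(num)
  expect_equal(emResponsibilities(m, pts), oracle,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("a midpoint between symmetric components splits evenly", {
  m <- new("GaussianMixtureModel", k = 2L, weights = c(0.5, 0.5),
           means = rbind(-3, 3), sds = rbind(1, 1), covariances = list(),
           covarianceMode = "diagonal", logLikTrace = c(-1, -1),
           converged = TRUE, varFloor = 1e-9)
  R <- emResponsibilities(m, matrix(0, 1, 1))
  expect_equal(as.numeric(R), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("full-covariance EM separates correlated clusters", {
  set.seed(12)
  S <- matrix(c(1, 0.8, 0.8, 1), 2)
  A <- chol(S)
  X <- rbind(matrix(rnorm(300), 150, 2) %*% A,
             sweep(matrix(rnorm(300), 150, 2) %*% A, 2, c(8, 8), `+`))
  f <- emFit(X, 2, seed = 2, covarianceMode = "full")
  truth <- Partition(rep(1:2, each = 150))
  expect_gte(adjustedRandIndex(f$partition, truth), 0.95)
  expect_true(all(diff(f$model@logLikTrace) > -1e-9))
})

test_that("EM rejects more components than rows", {
  expect_error(emFit(matrix(rnorm(6), 3, 2), 4), "k must lie")
})

test_that("a lone SOM node contracts to the data centroid", {
  set.seed(4)
  X <- matrix(rnorm(200, 3, 1.5), 100, 2)
  f <- somFit(X, 1, 1, epochs = 60, seed = 2)
  rel <- sqrt(sum((f$model@codebook[1, ] - colMeans(X))^2)) /
    mean(apply(X, 2, sd))
  expect_lt(rel, 0.05)
})

test_that("a 2x1 map splits two well-separated blobs exactly", {
  set.seed(5)
  X <- rbind(matrix(rnorm(100, 0, 0.3), 50, 2),
             matrix(rnorm(100, 8, 0.3), 50, 2))
  f <- somFit(X, 2, 1, epochs = 60, seed = 3)
  truth <- Partition(rep(1:2, each = 50))
  expect_equal(adjustedRandIndex(f$partition, truth), 1.0)
})

test_that("SOM training is deterministic given its seed", {
  set.seed(6)
  X <- matrix(rnorm(120), 40, 3)
  f1 <- somFit(X, 2, 2, epochs = 20, seed = 9)
  f2 <- somFit(X, 2, 2, epochs = 20, seed = 9)
  expect_identical(f1$model@codebook, f2$model@codebook)
  expect_identical(partitionLabels(f1$partition), partitionLabels(f2$partition))
  expect_error(somFit(X, 2, 2, epochs = 0), "epochs")
})

test_that("SOM quantization error improves over training (median across seeds)", {
  set.seed(7)
  X <- matrix(rnorm(300), 100, 3)
  drop <- vapply(1:5, function(s) {
    qe <- somFit(X, 2, 2, epochs = 30, seed = s)$model@quantizationError
    qe[length(qe)] <= qe[1]
  }, logical(1))
  expect_gte(sum(drop), 3)
})

test_that("assignment reproduces training labels and matches a centroid oracle", {
  set.seed(8)
  X <- rbind(matrix(rnorm(60, 0, 0.5), 30, 2),
             matrix(rnorm(60, 6, 0.5), 30, 2))
  f <- emFit(X, 2, seed = 1)
  expect_identical(partitionLabels(clusterAssign(f$model, X)),
                   partitionLabels(f$partition))
  # a point at a component mean belongs to that component
  at <- clusterAssign(f$model, f$model@means[2, , drop = FALSE])
  expect_equal(partitionLabels(at), 2L)

  # spherical equal-weight model: argmax responsibility = nearest centroid
  m <- new("GaussianMixtureModel", k = 3L, weights = rep(1 / 3, 3),
           means = rbind(c(0, 0), c(5, 0), c(0, 5)),
           sds = matrix(1, 3, 2), covariances = list(),
           covarianceMode = "diagonal", logLikTrace = c(-1, -1),
           converged = TRUE, varFloor = 1e-9)
  pts <- matrix(rnorm(40, 2, 3), 20, 2)
  d2 <- sapply(1:3, function(cc) rowSums(sweep(pts, 2, m@means[cc, ])^2))
  oracle <- max.col(-d2, ties.method = "first")
  expect_identical(partitionLabels(clusterAssign(m, pts)), oracle)

  s <- somFit(X, 2, 1, epochs = 30, seed = 2)
  expect_identical(partitionLabels(clusterAssign(s$model, X)),
                   partitionLabels(s$partition))
  expect_error(clusterAssign(s$model, X[, 1, drop = FALSE]), "shape")
})

test_that("EM agrees with an independent mixture implementation on easy data", {
  set.seed(10)
  X <- rbind(matrix(rnorm(200, 0, 1), 100, 2),
             matrix(rnorm(200, 7, 1), 100, 2))
  ours <- emFit(X, 2, seed = 5)
  suppressPackageStartupMessages(library(mclust))
  mc <- Mclust(X, G = 2, modelNames = "VVI", verbose = FALSE)
  expect_gte(adjustedRandIndex(ours$partition,
                               Partition(mc$classification)), 0.98)
})
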