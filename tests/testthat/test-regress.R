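test_that("the RBF kernel follows the gamma-squared form", {
  expect_equal(rbfKernel(c(1, 2), c(1, 2), 0.05), 1.0)
  expect_equal(rbfKernel(c(0, 0), c(0.06, 0.08), 0.1), exp(-1))
  set.seed(1)
  for (i in 1:5) {
    x <- rnorm(4); y <- rnorm(4); g <- runif(1, 0.01, 2)
    expect_equal(rbfKernel(x, y, g), rbfKernel(y, x, g))
  }
  expect_error(rbfKernel(1, 1, 0), "gamma")
  expect_error(rbfKernel(1:2, 1:3, 1), "dimension")
})

test_that("the tuning grids match the published ranges and steps", {
  g <- svrGrids("full")
  expect_length(g$gamma, 19)
  expect_length(g$epsilon, 20)
  expect_length(g$cost, 221)
  expect_equal(range(g$gamma), c(0.01, 0.1))
  expect_equal(range(g$epsilon), c(1e-4, 2e-3))
  expect_equal(range(g$cost), c(3, 4.1))
  f <- svrGrids("fast")
  expect_true(all(f$gamma %in% g$gamma))
  expect_true(all(f$epsilon %in% g$epsilon))
  expect_true(all(f$cost %in% g$cost))
  expect_equal(lengths(f), c(gamma = 5L, epsilon = 5L, cost = 56L))
})

test_that("constant targets are reproduced within the tube", {
  set.seed(2)
  X <- matrix(rnorm(40, 0, 0.05), 20, 2)
  fit <- svrTrain(X, rep(7, 20), svrParams(3.5, 0.001, 0.05))
  expect_true(all(abs(predict(fit, X) - 7) <= 0.001 + 1e-6))
})

test_that("the dual solution is feasible and satisfies the tube KKT condition", {
  set.seed(3)
  X <- matrix(rnorm(120, 0, 0.04), 60, 2)
  y <- 20 + 200 * X[, 1] + 50 * sin(40 * X[, 2]) + rnorm(60, 0, 0.5)
  p <- svrParams(4, 0.5, 0.08)
  fit <- svrTrain(X, y, p, tolerance = 1e-7)
  d <- svrDuals(fit)
  expect_true(all(abs(d$coef) <= d$C + 1e-6 * d$C))
  expect_lt(abs(sum(d$coef)), 1e-6 * d$C)
  # rows strictly inside the epsilon tube are not support points
  resid <- abs(predict(fit, X) - y)
  inside <- which(resid < p@epsilon - 1e-6)
  expect_false(any(inside %in% d$supportIndex))
})

test_that("noiseless smooth 1-D data is interpolated to tube accuracy", {
  x <- matrix(seq(0, 2 * pi, length.out = 40), ncol = 1)
  y <- sin(x[, 1])
  fit <- svrTrain(x, y, svrParams(C = 100, epsilon = 0.01, gamma = 1.5))
  expect_lte(sqrt(mean((predict(fit, x) - y)^2)), 0.01 + 0.01)
})

test_that("grid search returns the single cell of a degenerate grid", {
  set.seed(4)
  X <- matrix(rnorm(60, 0, 0.05), 30, 2)
  y <- rnorm(30, 20, 3)
  g <- list(gamma = 0.05, epsilon = 0.001, cost = 3.5)
  p <- gridSearch(X, y, g, folds = 5, seed = 1)
  expect_equal(p@gamma, 0.05)
  expect_equal(p@epsilon, 0.001)
  expect_equal(p@cost, 3.5)
})

test_that("grid search recovers a planted kernel bandwidth", {
  # response is an RBF bump of width 0.05; a 20x wider kernel oversmooths
  set.seed(5)
  X <- matrix(runif(80, -0.15, 0.15), 80, 1)
  y <- 10 * exp(-X[, 1]^2 / 0.05^2)
  g <- list(gamma = c(0.05, 1.0), epsilon = 0.001, cost = c(4))
  p <- gridSearch(X, y, g, folds = 5, seed = 2)
  expect_equal(p@gamma, 0.05)
})

test_that("grid search never leaves the configured grid", {
  set.seed(6)
  X <- matrix(rnorm(50, 0, 0.05), 25, 2)
  y <- rnorm(25, 15, 2)
  g <- list(gamma = c(0.02, 0.08), epsilon = c(1e-4, 1e-3), cost = c(3, 4))
  p <- gridSearch(X, y, g, folds = 5, seed = 3)
  expect_true(p@gamma %in% g$gamma)
  expect_true(p@epsilon %in% g$epsilon)
  expect_true(p@cost %in% g$cost)
})

test_that("ensemble prediction is exactly the member mean", {
  set.seed(7)
  X <- matrix(rnorm(80, 0, 0.05), 40, 2)
  y <- 20 + 100 * X[, 1] + rnorm(40)
  p <- svrParams(3.5, 0.001, 0.07)
  ens <- trainEnsemble(X, y, p, nMembers = 4, seed = 2)
  Xt <- matrix(rnorm(20, 0, 0.05), 10, 2)
  memberMean <- rowMeans(vapply(ens@members, function(m) predict(m, Xt),
                                numeric(10)))
  expect_equal(predict(ens, Xt), memberMean, tolerance = 1e-12)

  # bootstrap disabled: every member identical to a single fit
  ens1 <- trainEnsemble(X, y, p, nMembers = 3, seed = 2, bootstrap = FALSE)
  single <- svrTrain(X, y, p)
  expect_equal(predict(ens1, Xt), predict(single, Xt), tolerance = 1e-12)
})

test_that("bagging does not hurt: ensemble beats the median member on noisy data", {
  wins <- 0
  for (r in 1:10) {
    set.seed(100 + r)
    n <- 90
    X <- matrix(rnorm(2 * n, 0, 0.05), n, 2)
    f <- function(Z) 25 + 60 * sin(25 * Z[, 1]) + 150 * Z[, 2]
    y <- f(X) + rnorm(n, 0, 3)
    Xt <- matrix(rnorm(2 * n, 0, 0.05), n, 2)
    yt <- f(Xt) + rnorm(n, 0, 3)
    ens <- trainEnsemble(X, y, svrParams(4, 0.001, 0.07), nMembers = 8,
                         seed = r)
    ensRMSE <- sqrt(mean((predict(ens, Xt) - yt)^2))
    memberRMSE <- vapply(ens@members, function(m)
      sqrt(mean((predict(m, Xt) - yt)^2)), numeric(1))
    if (ensRMSE <= stats::median(memberRMSE)) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("a single-cluster consensus yields a plain global model", {
  gen <- tinyTable(nSubjects = 8, recordingsPerSubject = 8, seed = 6)
  te <- gen$table
  n <- length(motorUPDRS(te))
  cons <- Partition(rep(1L, n), k = 1L)
  cfg <- clusterwiseConfig(grids = list(gamma = 0.05, epsilon = 0.001,
                                        cost = 3.5), minClusterSize = 10)
  model <- fitClusterwise(te, cons, cfg)
  expect_length(model@clusters, 1)
  expect_length(model@fallback, 0)
  out <- predict(model, featureMatrix(te))
  expect_true(all(out$routing == names(model@clusters)[1]))
  # centroid is the mean of the cluster rows
  expect_equal(model@clusters[[1]]$centroid, colMeans(featureMatrix(te)),
               tolerance = 1e-10)
})

test_that("training rows route back to their own cluster in the separated regime", {
  out <- generateTelemonitoring(syntheticConfig(
    nSubjects = 15, recordingsPerSubject = 10, nClusters = 3,
    clusterSeparation = 6, seed = 19))
  te <- out$table
  cfg <- clusterwiseConfig(grids = list(gamma = 0.05, epsilon = 0.001,
                                        cost = 3.5), minClusterSize = 10)
  model <- fitClusterwise(te, out$labels, cfg)
  pr <- predict(model, featureMatrix(te))
  fidelity <- mean(pr$routing == as.character(partitionLabels(out$labels)))
  expect_gte(fidelity, 0.99)
  # permutation equivariance
  perm <- sample(length(pr$motor))
  pr2 <- predict(model, featureMatrix(te)[perm, ])
  expect_equal(pr2$motor, pr$motor[perm], tolerance = 1e-12)
})

test_that("undersized clusters merge into the global fallback", {
  gen <- tinyTable(nSubjects = 8, recordingsPerSubject = 8, seed = 10)
  te <- gen$table
  n <- length(motorUPDRS(te))
  # cluster 2 has only 4 rows, below the minimum
  cons <- Partition(c(rep(1L, n - 4), rep(2L, 4)), k = 2L)
  cfg <- clusterwiseConfig(grids = list(gamma = 0.05, epsilon = 0.001,
                                        cost = 3.5), minClusterSize = 10)
  model <- fitClusterwise(te, cons, cfg)
  expect_length(model@clusters, 1)
  expect_gt(length(model@fallback), 0)
  # every cluster undersized -> single global model, with a warning
  tiny <- Partition(rep_len(1:8, n), k = 8L)
  expect_warning(m2 <- fitClusterwise(te, tiny, cfg), "global")
  expect_length(m2@clusters, 0)
  pr <- predict(m2, featureMatrix(te))
  expect_true(all(pr$routing == "fallback"))
})
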