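test_that("perfect and offset predictions give the expected metrics", {
  set.seed(1)
  o <- rnorm(10, 20, 5)
  m0 <- computeMetrics(o, o, m = 2)
  expect_equal(m0@rmse, 0)
  expect_equal(m0@mae, 0)
  expect_equal(m0@ia, 1)
  expect_equal(m0@pa, 1)
  expect_equal(m0@r2Adjusted, 1)

  m2 <- computeMetrics(o + 2, o, m = 1)
  expect_equal(m2@rmse, 2)
  expect_equal(m2@mae, 2)
  expect_equal(m2@pa, 1)
})

test_that("metrics match the hand-computed worked example", {
  got <- computeMetrics(c(1, 2, 3, 5), c(1, 2, 4, 4), m = 1)
  o <- oracleMetrics(c(1, 2, 3, 5), c(1, 2, 4, 4), 1)
  expect_equal(got@rmse, o$rmse, tolerance = 1e-10)
  expect_equal(got@mae, o$mae, tolerance = 1e-10)
  expect_equal(got@ia, o$ia, tolerance = 1e-10)
  expect_equal(got@pa, o$pa, tolerance = 1e-10)
  expect_equal(got@r2Adjusted, o$r2a, tolerance = 1e-10)
})

test_that("metrics validate their preconditions", {
  expect_error(computeMetrics(1:5, rep(2, 5), m = 1), "zero variance")
  expect_error(computeMetrics(1:3, 1:3, m = 3), "n > m")
  expect_error(computeMetrics(1:2, 1:2, m = 0), "n >= 3")
  expect_error(computeMetrics(1:4, 1:5, m = 1), "equal length")
})

test_that("ARI is 1 up to relabeling and matches independent implementations", {
  a <- Partition(c(1, 1, 2, 2, 3, 3))
  b <- Partition(c(3, 3, 1, 1, 2, 2))
  expect_equal(adjustedRandIndex(a, a), 1)
  expect_equal(adjustedRandIndex(a, b), 1)

  p1 <- Partition(c(1, 1, 2, 2)); p2 <- Partition(c(1, 2, 1, 2))
  expect_equal(adjustedRandIndex(p1, p2),
               bruteARI(p1@labels, p2@labels), tolerance = 1e-12)

  for (s in 1:20) {
    set.seed(500 + s)
    x <- sample(1:3, 12, replace = TRUE)
    y <- sample(1:4, 12, replace = TRUE)
    ours <- adjustedRandIndex(Partition(x, k = 3), Partition(y, k = 4))
    expect_equal(ours, bruteARI(x, y), tolerance = 1e-12)
    expect_equal(ours, mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
  }
})

smallExperimentConfig <- function(seed = 5, ...) {
  experimentConfig(
    data = syntheticConfig(nSubjects = 12, recordingsPerSubject = 10,
                           nClusters = 3, clusterSeparation = 6, seed = seed),
    ensemble = list(list(type = "em", k = 3), list(type = "em", k = 4)),
    consensusMethods = "hgpa", targetK = 3,
    grids = list(gamma = 0.07, epsilon = 0.001, cost = 3.5),
    minClusterSize = 10, scheme = "split", trainFraction = 0.7,
    seed = seed, ...)
}

test_that("the experiment report has one row per method and target", {
  res <- runExperiment(smallExperimentConfig(baselines = FALSE))
  expect_equal(nrow(res$report), 2)   # 1 method x 2 targets
  expect_setequal(res$report$target, c("motor_updrs", "total_updrs"))
  expect_true(all(res$report$method == "hgpa"))
  expect_true(all(c("ensemble_size", "composition", "method", "target",
                    "rmse", "mae", "ia", "pa", "r2_adjusted", "n") %in%
                    colnames(res$report)))
  expect_equal(unique(res$report$ensemble_size), 2)

  resB <- runExperiment(smallExperimentConfig())
  expect_equal(nrow(resB$report), 6)  # + global_svr and global_mlr
})

test_that("identical configurations reproduce identical reports", {
  r1 <- runExperiment(smallExperimentConfig())
  r2 <- runExperiment(smallExperimentConfig())
  expect_identical(r1$report, r2$report)
})

test_that("the null-value experiment imputes and reports recovery error", {
  res <- runExperiment(smallExperimentConfig(maskFraction = 0.1,
                                             baselines = FALSE))
  expect_false(is.null(res$details$imputation))
  expect_true(is.finite(res$details$imputation$rmse))
  expect_s4_class(res$details$imputationModel, "ImputationModel")
  expect_equal(nrow(res$report), 2)
})

test_that("grouped cross-validation covers every recording exactly once", {
  cfg <- smallExperimentConfig(baselines = FALSE)
  cfg$scheme <- "cv"; cfg$outerFolds <- 4
  res <- runExperiment(cfg)
  n <- cfg$data$nSubjects * cfg$data$recordingsPerSubject
  expect_equal(sort(res$details$evalIndex), seq_len(n))
  expect_equal(unique(res$report$n), n)
})
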