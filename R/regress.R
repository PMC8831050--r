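# RBF-kernel support vector regression: hyperparameter grids, 5-fold
# grid-search tuning, bootstrap ensembles of 8 SVRs, and cluster-wise
# training/prediction with nearest-centroid routing.

#' Radial basis function kernel (gamma-squared convention)
#'
#' `K(x, y) = exp(-||x - y||^2 / gamma^2)`: `gamma` is the spread of the
#' function, entering squared in the denominator. Returns a value in
#' (0, 1], equal to 1 iff `x == y`.
#'
#' @param x,y numeric vectors of equal dimension.
#' @param gamma spread parameter, > 0.
#' @return Kernel value.
#' @export
rbfKernel <- function(x, y, gamma) {
  stopIfNot(length(x) == length(y), "x and y must have equal dimension")
  stopIfNot(is.numeric(gamma) && gamma > 0, "gamma must be > 0")
  exp(-sum((x - y)^2) / gamma^2)
}

#' Hyperparameter grids for SVR tuning
#'
#' The full grids are gamma in [0.01, 0.1] step 0.005 (19 values),
#' epsilon in [0.0001, 0.002] step 0.0001 (20 values) and C in [3, 4.1]
#' step 0.005 (221 values) - 83,980 cells. The fast grid keeps every 4th
#' value per axis (5 x 5 x 56 = 1,400 cells) for desk-scale runs.
#'
#' @param type `"fast"` (default) or `"full"`.
#' @return List with numeric vectors `gamma`, `epsilon`, `cost`.
#' @export
svrGrids <- function(type = c("fast", "full")) {
  type <- match.arg(type)
  g <- list(gamma = seq(0.01, 0.1, by = 0.005),
            epsilon = seq(1e-4, 2e-3, by = 1e-4),
            cost = seq(3, 4.1, by = 0.005))
  if (type == "fast")
    g <- lapply(g, function(v) v[seq(1, length(v), by = 4)])
  g
}

#' Train one epsilon-insensitive RBF support vector regressor
#'
#' Solves the dual quadratic program of the epsilon-insensitive loss
#' through libsvm's SMO solver: dual coefficients respect the box
#' `0 <= beta, beta* <= C` and the equality `sum(beta - beta*) = 0`;
#' prediction is the kernel expansion over support points plus the bias.
#' The kernel is the gamma-squared form of [rbfKernel()], mapped
#' internally to libsvm's parameterization.
#'
#' @param features numeric matrix (>= 2 rows).
#' @param targets numeric response.
#' @param params an [SVRParams-class].
#' @param tolerance SMO termination tolerance (default 1e-3); tighten
#'   (e.g. 1e-7) when exact Karush-Kuhn-Tucker structure matters more
#'   than speed.
#' @return Object of class `"svrFit"`; use [predict()] and [svrDuals()].
#' @export
svrTrain <- function(features, targets, params, tolerance = 1e-3) {
  features <- as.matrix(features)
  stopIfNot(nrow(features) >= 2, "need >= 2 training rows")
  stopIfNot(all(is.finite(targets)), "targets must be finite")
  m <- e1071::svm(features, targets, type = "eps-regression",
                  kernel = "radial", gamma = 1 / params@gamma^2,
                  cost = params@cost, epsilon = params@epsilon,
                  scale = FALSE, fitted = FALSE, cachesize = 100,
                  tolerance = tolerance)
  structure(list(model = m, params = params, n = nrow(features)),
            class = "svrFit")
}

#' @describeIn svrTrain predictions of a single trained SVR.
#' @param object an `"svrFit"`.
#' @param newdata numeric matrix.
#' @param ... unused.
#' @method predict svrFit
#' @export
predict.svrFit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  # a flat optimum can have zero support vectors; the prediction is then
  # the bias alone, which libsvm cannot evaluate itself
  if (object$model$tot.nSV == 0)
    return(rep(-object$model$rho, nrow(newdata)))
  unname(stats::predict(object$model, newdata))
}

#' Dual solution of a trained SVR
#'
#' @param fit an object from [svrTrain()].
#' @return List with `coef` (beta - beta* per support point), `b` (bias),
#'   `supportIndex` (row indices of the support points) and `C`.
#' @export
svrDuals <- function(fit) {
  list(coef = as.numeric(fit$model$coefs), b = -fit$model$rho,
       supportIndex = fit$model$index, C = fit$params@cost)
}

#' Exhaustive grid search with k-fold cross-validation
#'
#' Evaluates every cell of the Cartesian hyperparameter grid by k-fold
#' cross-validated RMSE (folds formed by seeded shuffling) and returns
#' the minimizing parameters. Ties are broken by smaller C, then larger
#' epsilon, then smaller gamma. When `groups` is supplied (e.g. subject
#' identifiers), whole groups are assigned to folds, so no group spans
#' the tuning train/validation boundary -- repeated recordings of one
#' subject otherwise leak identity into the validation folds and bias
#' the selection toward memorization.
#'
#' @param features numeric matrix with at least `folds` rows.
#' @param targets numeric response.
#' @param grids list with `gamma`, `epsilon`, `cost` vectors (see
#'   [svrGrids()]).
#' @param folds number of cross-validation folds (default 5).
#' @param seed integer seed for fold assignment.
#' @param groups optional per-row group labels for grouped folds; with
#'   fewer distinct groups than folds, row-wise folds are used instead.
#' @return The selected [SVRParams-class], with attributes `"cvRMSE"`
#'   (the winning mean validation RMSE).
#' @export
gridSearch <- function(features, targets, grids = svrGrids("fast"),
                       folds = 5, seed = 1, groups = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  stopIfNot(n >= folds, "need at least one row per fold")
  stopIfNot(length(grids$gamma) > 0 && length(grids$epsilon) > 0 &&
              length(grids$cost) > 0, "grids must be nonempty")
  if (!is.null(groups)) {
    stopIfNot(length(groups) == n, "groups must have one label per row")
    g <- as.integer(factor(groups))
    if (length(unique(g)) < folds) groups <- NULL
  }
  foldID <- if (is.null(groups)) {
    withSeed(seed, sample(rep_len(seq_len(folds), n)))
  } else {
    nG <- length(unique(g))
    foldOfGroup <- integer(nG)
    foldOfGroup[withSeed(seed, sample(nG))] <- rep_len(seq_len(folds), nG)
    foldOfGroup[g]
  }
  splits <- lapply(seq_len(folds), function(f)
    list(train = which(foldID != f), test = which(foldID == f)))

  cells <- expand.grid(gamma = grids$gamma, epsilon = grids$epsilon,
                       cost = grids$cost)
  # tie-break order: smaller C, larger epsilon, smaller gamma
  cells <- cells[order(cells$cost, -cells$epsilon, cells$gamma), ]
  bestRMSE <- Inf; bestRow <- 1L
  for (i in seq_len(nrow(cells))) {
    p <- svrParams(cells$cost[i], cells$epsilon[i], cells$gamma[i])
    se <- 0; nv <- 0
    for (sp in splits) {
      fit <- svrTrain(features[sp$train, , drop = FALSE], targets[sp$train], p)
      pr <- predict(fit, features[sp$test, , drop = FALSE])
      se <- se + sum((pr - targets[sp$test])^2)
      nv <- nv + length(sp$test)
    }
    rmse <- sqrt(se / nv)
    if (rmse < bestRMSE - 1e-12) { bestRMSE <- rmse; bestRow <- i }
  }
  out <- svrParams(cells$cost[bestRow], cells$epsilon[bestRow],
                   cells$gamma[bestRow])
  attr(out, "cvRMSE") <- bestRMSE
  out
}

#' Train a bagged ensemble of support vector regressors
#'
#' Each member is trained on a with-replacement resample of the training
#' rows (member i uses `seed + i`); the ensemble prediction is the
#' unweighted arithmetic mean of member predictions. A degenerate
#' resample (fewer than two unique rows) is redrawn with a fresh
#' sub-seed.
#'
#' @param features numeric matrix (>= 2 rows).
#' @param targets numeric response.
#' @param params shared [SVRParams-class] for all members.
#' @param nMembers ensemble size (default 8).
#' @param seed integer base seed for the bootstrap.
#' @param bootstrap set `FALSE` to train every member on the full sample
#'   (members are then identical).
#' @return An [SVREnsemble-class].
#' @export
trainEnsemble <- function(features, targets, params, nMembers = 8,
                          seed = 1, bootstrap = TRUE) {
  features <- as.matrix(features)
  n <- nrow(features)
  stopIfNot(n >= 2, "need >= 2 training rows")
  stopIfNot(nMembers >= 1, "nMembers must be >= 1")
  members <- vector("list", nMembers)
  seeds <- integer(nMembers)
  for (i in seq_len(nMembers)) {
    s <- as.integer(seed) + i
    if (bootstrap) {
      idx <- withSeed(s, sample.int(n, n, replace = TRUE))
      tries <- 0L
      while (length(unique(idx)) < 2L && tries < 100L) {
        tries <- tries + 1L
        s <- subSeed(s, 1000L + tries)
        idx <- withSeed(s, sample.int(n, n, replace = TRUE))
      }
    } else idx <- seq_len(n)
    seeds[i] <- s
    members[[i]] <- svrTrain(features[idx, , drop = FALSE], targets[idx],
                             params)
  }
  ens <- new("SVREnsemble", members = members, params = params,
             seeds = seeds, trainRMSE = NA_real_, bootstrap = bootstrap)
  pr <- predict(ens, features)
  ens@trainRMSE <- sqrt(mean((pr - targets)^2))
  ens
}

#' @describeIn SVREnsemble-class mean of member predictions.
#' @param object an `SVREnsemble`.
#' @param newdata numeric matrix.
#' @export
setMethod("predict", "SVREnsemble", function(object, newdata) {
  newdata <- as.matrix(newdata)
  P <- vapply(object@members, function(m) predict(m, newdata),
              numeric(nrow(newdata)))
  rowMeans(matrix(P, nrow = nrow(newdata)))
})

#' Configuration for cluster-wise SVR training
#'
#' @param varianceThreshold PCA cumulative-variance retention target.
#' @param grids SVR hyperparameter grids (see [svrGrids()]).
#' @param folds grid-search cross-validation folds.
#' @param nMembers ensemble size per cluster and target.
#' @param minClusterSize clusters with fewer training rows fall back to
#'   the global model (default 25 = 5 folds x 5 rows).
#' @param tuningRows maximum rows used for the hyperparameter grid search
#'   (a seeded subsample; final ensembles always train on all cluster
#'   rows). `Inf` tunes on everything.
#' @param seed integer base seed.
#' @return A list of class `"clusterwiseConfig"`.
#' @export
clusterwiseConfig <- function(varianceThreshold = 0.95,
                              grids = svrGrids("fast"), folds = 5,
                              nMembers = 8, minClusterSize = 25,
                              tuningRows = Inf, seed = 1) {
  structure(list(varianceThreshold = varianceThreshold, grids = grids,
                 folds = folds, nMembers = nMembers,
                 minClusterSize = minClusterSize, tuningRows = tuningRows,
                 seed = as.integer(seed)),
            class = "clusterwiseConfig")
}

# fit PCA + tuned ensembles for one row subset
fitOneClusterModel <- function(X, motor, total, cfg, stream, groups = NULL) {
  basis <- fitPCA(X, cfg$varianceThreshold)
  S <- pcaTransform(X, basis)
  tuneIdx <- seq_len(nrow(S))
  if (nrow(S) > cfg$tuningRows)
    tuneIdx <- withSeed(subSeed(cfg$seed, stream), sample.int(nrow(S), cfg$tuningRows))
  tg <- if (is.null(groups)) NULL else groups[tuneIdx]
  pm <- gridSearch(S[tuneIdx, , drop = FALSE], motor[tuneIdx], cfg$grids,
                   cfg$folds, seed = subSeed(cfg$seed, stream + 1L),
                   groups = tg)
  pt <- gridSearch(S[tuneIdx, , drop = FALSE], total[tuneIdx], cfg$grids,
                   cfg$folds, seed = subSeed(cfg$seed, stream + 2L),
                   groups = tg)
  centroid <- colMeans(X)
  list(basis = basis,
       motor = trainEnsemble(S, motor, pm, cfg$nMembers,
                             seed = subSeed(cfg$seed, stream + 3L)),
       total = trainEnsemble(S, total, pt, cfg$nMembers,
                             seed = subSeed(cfg$seed, stream + 4L)),
       centroid = centroid,
       sds = pmax(apply(X, 2, stats::sd), 1e-12),
       n = nrow(X))
}

#' Fit per-cluster PCA + bagged SVR ensembles
#'
#' For every consensus cluster with at least
#' `max(folds, minClusterSize)` rows: a PCA basis is fitted on the
#' cluster's rows, hyperparameters are grid-searched by 5-fold
#' cross-validation independently for each target, and one bagged SVR
#' ensemble per target is trained on the cluster. The cluster centroid
#' (mean of its rows in imputed feature space) is stored for routing.
#' Undersized clusters are merged into a global fallback model; if every
#' cluster is undersized the result is a single global model (with a
#' warning).
#'
#' @param te a dense (imputed) [TelemonitoringExperiment-class].
#' @param consensus a [Partition-class] labeling the table's rows.
#' @param config a [clusterwiseConfig()].
#' @return A [ClusterwiseSVRModel-class].
#' @export
fitClusterwise <- function(te, consensus, config = clusterwiseConfig()) {
  stopIfNot(is.null(missingMask(te)), "impute the table before fitting")
  X <- featureMatrix(te)
  stopIfNot(length(consensus@labels) == nrow(X),
            "consensus must label the table's rows")
  motor <- motorUPDRS(te); total <- totalUPDRS(te)
  subj <- as.character(subjectID(te))   # grouped tuning folds
  minN <- max(config$folds, config$minClusterSize)

  sizes <- tabulate(consensus@labels, nbins = consensus@k)
  keep <- which(sizes >= minN)
  clusters <- list()
  for (cc in keep) {
    i <- which(consensus@labels == cc)
    clusters[[as.character(cc)]] <-
      fitOneClusterModel(X[i, , drop = FALSE], motor[i], total[i], config,
                         stream = 10L * cc, groups = subj[i])
  }
  fallback <- list()
  if (length(keep) < sum(sizes > 0)) {
    if (length(keep) == 0)
      warning("all clusters below minClusterSize; falling back to a single global model")
    fallback <- fitOneClusterModel(X, motor, total, config, stream = 9000L,
                                   groups = subj)
  }
  new("ClusterwiseSVRModel", clusters = clusters, fallback = fallback,
      minClusterSize = as.integer(config$minClusterSize))
}

#' @describeIn ClusterwiseSVRModel-class route each row to the cluster
#'   maximizing the diagonal-Gaussian log-likelihood of its centroid and
#'   per-feature SDs (in imputed feature space): squared standardized
#'   distance plus the log-determinant term `2 sum(log sd)`, the same
#'   assignment rule the EM clusterer uses, fitted by moments. For
#'   clusters of equal spread this reduces to plain nearest-centroid
#'   routing. The routed cluster's ensembles predict both targets; rows
#'   route to the global fallback only when no cluster model exists.
#'   Returns a list with `motor`, `total` and the `routing` labels for
#'   audit.
#' @param object a `ClusterwiseSVRModel`.
#' @param newdata numeric recordings-by-features matrix.
#' @export
setMethod("predict", "ClusterwiseSVRModel", function(object, newdata) {
  X <- as.matrix(newdata)
  cls <- object@clusters
  if (length(cls) == 0) {
    fb <- object@fallback
    S <- pcaTransform(X, fb$basis)
    return(list(motor = predict(fb$motor, S), total = predict(fb$total, S),
                routing = rep("fallback", nrow(X))))
  }
  cents <- do.call(rbind, lapply(cls, `[[`, "centroid"))
  if (ncol(X) != ncol(cents))
    stop("shape error: feature dimension does not match model", call. = FALSE)
  D2 <- vapply(cls, function(cl)
    rowSums(sweep(sweep(X, 2, cl$centroid), 2, cl$sds, `/`)^2) +
      2 * sum(log(cl$sds)),
    numeric(nrow(X)))
  D2 <- matrix(D2, nrow = nrow(X))
  route <- max.col(-D2, ties.method = "first")
  motor <- numeric(nrow(X)); total <- numeric(nrow(X))
  for (j in seq_along(cls)) {
    i <- which(route == j)
    if (!length(i)) next
    S <- pcaTransform(X[i, , drop = FALSE], cls[[j]]$basis)
    motor[i] <- predict(cls[[j]]$motor, S)
    total[i] <- predict(cls[[j]]$total, S)
  }
  list(motor = motor, total = total, routing = names(cls)[route])
})
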