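# Base clusterers: EM for Gaussian mixtures and the self-organizing map.
# Both return a Partition alongside the fitted model; partitions feed the
# consensus functions.

logSumExpRows <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

# per-component log-densities, n x k
gmmLogDens <- function(X, means, sds, covariances, mode) {
  n <- nrow(X); k <- nrow(means)
  out <- matrix(0, n, k)
  if (mode == "diagonal") {
    for (m in seq_len(k)) {
      v <- sds[m, ]^2
      out[, m] <- -0.5 * sum(log(2 * pi * v)) -
        0.5 * rowSums(sweep(sweep(X, 2, means[m, ])^2, 2, v, `/`))
    }
  } else {
    for (m in seq_len(k)) {
      ch <- chol(covariances[[m]])
      ctr <- sweep(X, 2, means[m, ])
      y <- ctr %*% backsolve(ch, diag(ncol(X)))
      out[, m] <- -0.5 * ncol(X) * log(2 * pi) - sum(log(diag(ch))) -
        0.5 * rowSums(y^2)
    }
  }
  out
}

kmeansPlusPlusCenters <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums(sweep(X, 2, X[centers[1], ])^2)
    for (m in 2:k) {
      p <- d2 / sum(d2)
      if (!all(is.finite(p)) || sum(d2) == 0) p <- rep(1 / n, n)
      centers[m] <- sample.int(n, 1, prob = p)
      d2 <- pmin(d2, rowSums(sweep(X, 2, X[centers[m], ])^2))
    }
  }
  X[centers, , drop = FALSE]
}

#' Fit a Gaussian mixture by expectation-maximization
#'
#' Alternates the expectation step (responsibilities: each component's
#' weighted density over the weighted-density total per row) and the
#' maximization step (responsibility-weighted means, variances and mixing
#' proportions) until the log-likelihood change falls below `tol` or
#' `maxIter` is reached. Initialization is kmeans++-style seeding;
#' `nInit` restarts are run and the best final likelihood kept. A
#' variance floor of 1e-6 times each feature's overall variance prevents
#' component collapse.
#'
#' @param X dense numeric recordings-by-features matrix.
#' @param k number of mixture components (<= rows).
#' @param seed integer RNG seed for initialization.
#' @param tol absolute log-likelihood convergence tolerance.
#' @param maxIter maximum EM iterations per restart.
#' @param covarianceMode `"diagonal"` (default, one SD per dimension) or
#'   `"full"`.
#' @param nInit number of seeded restarts.
#' @return List with `model` (a [GaussianMixtureModel-class] whose
#'   log-likelihood trace is nondecreasing) and `partition` (argmax
#'   responsibility per row, ties to the lowest component index).
#' @export
emFit <- function(X, k, seed = 1, tol = 1e-6, maxIter = 200,
                  covarianceMode = c("diagonal", "full"), nInit = 5) {
  X <- as.matrix(X)
  covarianceMode <- match.arg(covarianceMode)
  n <- nrow(X); d <- ncol(X)
  stopIfNot(k >= 1 && k <= n, "k must lie in 1..rows")
  floorV <- 1e-6 * pmax(apply(X, 2, stats::var), .Machine$double.eps)

  runOne <- function(s) {
    withSeed(s, {
      ctr <- kmeansPlusPlusCenters(X, k)
      lab <- max.col(-rowDist2(X, ctr), ties.method = "first")
      R <- matrix(0, n, k); R[cbind(seq_len(n), lab)] <- 1
      w <- rep(1 / k, k); means <- ctr
      sds <- matrix(1, k, d); covs <- vector("list", k)
      trace <- numeric(0); converged <- FALSE
      for (it in seq_len(maxIter)) {
        # M-step from current responsibilities
        Nm <- colSums(R)
        Nm[Nm < 1e-12] <- 1e-12
        w <- Nm / n
        means <- sweep(crossprod(R, X), 1, Nm, `/`)
        if (covarianceMode == "diagonal") {
          for (m in seq_len(k)) {
            v <- colSums(R[, m] * sweep(X, 2, means[m, ])^2) / Nm[m]
            sds[m, ] <- sqrt(pmax(v, floorV))
          }
        } else {
          for (m in seq_len(k)) {
            ctrd <- sweep(X, 2, means[m, ])
            S <- crossprod(ctrd * R[, m], ctrd) / Nm[m]
            covs[[m]] <- S + diag(floorV, d)
          }
        }
        # E-step and log-likelihood
        lp <- sweep(gmmLogDens(X, means, sds, covs, covarianceMode),
                    2, log(w), `+`)
        ll <- sum(logSumExpRows(lp))
        R <- exp(lp - logSumExpRows(lp))
        trace <- c(trace, ll)
        if (it > 1 && abs(trace[it] - trace[it - 1]) < tol) {
          converged <- TRUE; break
        }
      }
      list(w = w, means = means, sds = sds, covs = covs, trace = trace,
           converged = converged, R = R)
    })
  }

  fits <- lapply(seq_len(max(1L, nInit)), function(i) runOne(subSeed(seed, i)))
  best <- fits[[which.max(vapply(fits, function(f)
    f$trace[length(f$trace)], numeric(1)))]]

  model <- new("GaussianMixtureModel", k = as.integer(k), weights = best$w,
               means = best$means, sds = best$sds,
               covariances = if (covarianceMode == "full") best$covs else list(),
               covarianceMode = covarianceMode, logLikTrace = best$trace,
               converged = best$converged, varFloor = max(floorV))
  labels <- max.col(best$R, ties.method = "first")
  list(model = model,
       partition = Partition(labels, k = k, source = sprintf("EM k=%d", k)))
}

#' Responsibilities of a fitted Gaussian mixture
#'
#' Each row's posterior probability of belonging to each component: the
#' component's weighted density divided by the sum of all components'
#' weighted densities. Rows sum to one.
#'
#' @param model a [GaussianMixtureModel-class].
#' @param X numeric matrix with the model's feature dimension.
#' @return Row-stochastic n-by-k matrix.
#' @export
emResponsibilities <- function(model, X) {
  X <- as.matrix(X)
  stopIfNot(ncol(X) == ncol(model@means),
            "shape error: feature dimension does not match model")
  lp <- sweep(gmmLogDens(X, model@means, model@sds, model@covariances,
                         model@covarianceMode), 2, log(model@weights), `+`)
  exp(lp - logSumExpRows(lp))
}

#' @describeIn emResponsibilities argmax-responsibility partition for new
#'   rows (ties to the lowest component index).
#' @param features numeric matrix.
#' @export
setMethod("clusterAssign", "GaussianMixtureModel", function(model, features) {
  R <- emResponsibilities(model, features)
  Partition(max.col(R, ties.method = "first"), k = model@k,
            source = sprintf("EM k=%d (assigned)", model@k))
})

#' Train a self-organizing map
#'
#' Online training: per presented sample the best-matching node (minimum
#' Euclidean distance) and its lattice neighbors move toward the sample;
#' learning rate and Gaussian neighborhood radius decay exponentially
#' from their initial values to 0.01 across epochs. Node weights are
#' initialized by sampling data rows. Nodes that end up with no
#' best-matching rows remain as empty clusters.
#'
#' @param X dense numeric recordings-by-features matrix with at least as
#'   many rows as lattice nodes.
#' @param gridRows,gridCols lattice dimensions.
#' @param epochs training epochs (default 200); each epoch presents every
#'   sample once in seeded shuffled order.
#' @param seed integer RNG seed (weight init + presentation order).
#' @param alpha0 initial learning rate.
#' @param radius0 initial neighborhood radius; default `max(grid)/2`.
#' @return List with `model` (a [SOMModel-class] carrying the per-epoch
#'   quantization error) and `partition` (final best-matching node per
#'   row; `k` = node count).
#' @export
somFit <- function(X, gridRows, gridCols, epochs = 200, seed = 1,
                   alpha0 = 0.5, radius0 = max(gridRows, gridCols) / 2) {
  X <- as.matrix(X)
  nNodes <- gridRows * gridCols
  stopIfNot(epochs >= 1, "epochs must be >= 1")
  stopIfNot(nrow(X) >= nNodes, "need at least one row per lattice node")
  gr <- expand.grid(col = seq_len(gridCols), row = seq_len(gridRows))
  coords <- cbind(gr$row, gr$col)          # node index row-major
  latD2 <- rowDist2(coords, coords)
  final <- 0.01
  n <- nrow(X)

  withSeed(seed, {
    W <- X[sample.int(n, nNodes), , drop = FALSE]
    qe <- numeric(epochs)
    for (e in seq_len(epochs)) {
      frac <- if (epochs > 1) (e - 1) / (epochs - 1) else 1
      alpha <- alpha0 * (final / alpha0)^frac
      radius <- radius0 * (final / radius0)^frac
      h0 <- exp(-latD2 / (2 * radius^2))   # node x node neighborhood
      for (i in sample.int(n)) {
        x <- X[i, ]
        dif <- sweep(W, 2, x, `-`)
        bmu <- which.min(rowSums(dif^2))
        W <- W - (alpha * h0[, bmu]) * dif
      }
      D2 <- rowDist2(X, W)
      qe[e] <- mean(sqrt(pmax(apply(D2, 1, min), 0)))
    }
    model <- new("SOMModel", gridRows = as.integer(gridRows),
                 gridCols = as.integer(gridCols), codebook = W,
                 epochs = as.integer(epochs), quantizationError = qe,
                 radius0 = radius0, alpha0 = alpha0, seed = as.integer(seed))
    list(model = model, partition = clusterAssign(model, X))
  })
}

#' @describeIn somFit best-matching-node partition for new rows.
#' @param model a [SOMModel-class].
#' @param features numeric matrix.
#' @export
setMethod("clusterAssign", "SOMModel", function(model, features) {
  features <- as.matrix(features)
  stopIfNot(ncol(features) == ncol(model@codebook),
            "shape error: feature dimension does not match model")
  D2 <- rowDist2(features, model@codebook)
  Partition(max.col(-D2, ties.method = "first"),
            k = nrow(model@codebook),
            source = sprintf("SOM %dx%d", model@gridRows, model@gridCols))
})
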