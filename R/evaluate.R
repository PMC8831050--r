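# Evaluation metrics, clustering-agreement utilities, and the experiment
# harness chaining imputation -> base clusterings -> consensus ->
# cluster-wise PCA+SVR ensembles -> outer evaluation.

#' Regression evaluation metrics
#'
#' RMSE, MAE, Willmott's index of agreement
#' `IA = 1 - sum((P-O)^2) / sum((|P-Obar| + |O-Obar|)^2)`, prediction
#' accuracy PA (Pearson correlation of predictions and observations), and
#' adjusted R-squared `1 - (1 - PA^2)(n-1)/(n-m-1)` where `m` is the
#' predictor count. When the predictions are constant their correlation
#' with the observations is undefined; PA is reported as 0 in that case.
#'
#' @param predicted,observed numeric vectors of equal length n >= 3 with
#'   `n > m + 1`; `observed` must have nonzero variance.
#' @param m number of predictors used by the model.
#' @return A [MetricsReport-class].
#' @examples
#' computeMetrics(c(1, 2, 3, 5), c(1, 2, 4, 4), m = 1)
#' @export
computeMetrics <- function(predicted, observed, m) {
  stopIfNot(length(predicted) == length(observed),
            "predicted and observed must have equal length")
  n <- length(observed)
  stopIfNot(n >= 3, "need n >= 3 observations")
  stopIfNot(n > m + 1, "need n > m + 1 for the adjusted R-squared")
  if (stats::var(observed) == 0)
    stop("undefined metrics: observed values have zero variance", call. = FALSE)
  err <- predicted - observed
  rmse <- sqrt(sum(err^2) / n)
  mae <- sum(abs(err)) / n
  ob <- mean(observed)
  ia <- 1 - sum(err^2) / sum((abs(predicted - ob) + abs(observed - ob))^2)
  pa <- if (stats::var(predicted) == 0) 0 else stats::cor(predicted, observed)
  r2a <- 1 - (1 - pa^2) * (n - 1) / (n - m - 1)
  new("MetricsReport", rmse = rmse, mae = mae, ia = ia, pa = pa,
      r2Adjusted = r2a, n = as.integer(n), m = as.integer(m))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement computed from the contingency
#' table; equals 1 iff the partitions are identical up to relabeling.
#'
#' @param a,b [Partition-class] objects over the same rows.
#' @return Numeric scalar <= 1.
#' @export
adjustedRandIndex <- function(a, b) {
  stopIfNot(length(a@labels) == length(b@labels),
            "partitions must label the same rows")
  n <- length(a@labels)
  tab <- table(a@labels, b@labels)
  ch2 <- function(x) x * (x - 1) / 2
  sumIJ <- sum(ch2(tab))
  sumA <- sum(ch2(rowSums(tab)))
  sumB <- sum(ch2(colSums(tab)))
  expected <- sumA * sumB / ch2(n)
  denom <- (sumA + sumB) / 2 - expected
  if (denom == 0) return(1)
  (sumIJ - expected) / denom
}

#' Describe an experiment run
#'
#' @param data a [syntheticConfig()] (the table is generated) or a
#'   [TelemonitoringExperiment-class].
#' @param ensemble list of base-clusterer specs, each
#'   `list(type = "em", k = ...)` or
#'   `list(type = "som", rows = ..., cols = ...)`.
#' @param consensusMethods subset of `c("voting", "cspa", "hgpa")`.
#' @param targetK consensus cluster count; `NULL` uses the median base
#'   `k`.
#' @param maskFraction if > 0 and the table is fully observed, this
#'   fraction of feature cells is masked and then imputed (the null-value
#'   experiment); recovery error is reported.
#' @param imputeRank rank passed to [imputeSVD()] (default `"auto"`).
#' @param varianceThreshold,grids,folds,nMembers,minClusterSize,tuningRows
#'   passed to [clusterwiseConfig()].
#' @param hgpaTolerance part-size imbalance tolerance used for the HGPA
#'   consensus inside the harness (default 0.3; grouped subject splits
#'   make cluster sizes noisier than the balanced ideal).
#' @param scheme outer evaluation: `"cv"` (default, grouped k-fold
#'   cross-validation) or `"split"` (single grouped train/test split).
#' @param outerFolds folds for `scheme = "cv"` (default 10).
#' @param trainFraction train share for `scheme = "split"` (default 0.7).
#' @param groupBySubject keep all recordings of a subject on one side of
#'   every split (default TRUE; prevents subject-level leakage).
#' @param baselines also evaluate the plain baselines of a Table-4-style
#'   comparison (default TRUE): one grid-search-tuned global SVR and one
#'   global multiple linear regression, both fitted directly on the
#'   imputed features (no clustering, no bagging, no per-cluster PCA).
#' @param somEpochs epochs for SOM base clusterers (default 50).
#' @param seed integer master seed; every stage derives sub-seeds from
#'   it.
#' @return A list of class `"experimentConfig"`.
#' @export
experimentConfig <- function(data = syntheticConfig(),
                             ensemble = list(list(type = "em", k = 8),
                                             list(type = "em", k = 10),
                                             list(type = "em", k = 12),
                                             list(type = "em", k = 13)),
                             consensusMethods = c("voting", "cspa", "hgpa"),
                             targetK = NULL, maskFraction = 0,
                             imputeRank = "auto", varianceThreshold = 0.95,
                             grids = svrGrids("fast"), folds = 5,
                             nMembers = 8, minClusterSize = 25,
                             tuningRows = 200, hgpaTolerance = 0.3,
                             scheme = c("cv", "split"), outerFolds = 10,
                             trainFraction = 0.7, groupBySubject = TRUE,
                             baselines = TRUE, somEpochs = 50, seed = 1) {
  scheme <- match.arg(scheme)
  stopIfNot(all(vapply(consensusMethods, function(m)
    m %in% c("voting", "cspa", "hgpa"), logical(1))),
    "consensusMethods must be among voting, cspa, hgpa")
  structure(as.list(environment()), class = "experimentConfig")
}

# seeded grouped splits: list of train/test index pairs
outerSplits <- function(cfg, subjects, seed) {
  n <- length(subjects)
  groups <- if (cfg$groupBySubject) as.integer(factor(subjects)) else seq_len(n)
  ug <- unique(groups)
  ord <- withSeed(seed, sample(ug))
  if (cfg$scheme == "split") {
    nTrain <- round(cfg$trainFraction * length(ord))
    trainG <- ord[seq_len(max(1, min(nTrain, length(ord) - 1)))]
    list(list(train = which(groups %in% trainG),
              test = which(!groups %in% trainG)))
  } else {
    fid <- rep_len(seq_len(cfg$outerFolds), length(ord))
    lapply(seq_len(cfg$outerFolds), function(f) {
      testG <- ord[fid == f]
      list(train = which(!groups %in% testG), test = which(groups %in% testG))
    })
  }
}

fitBaseClusterers <- function(X, specs, somEpochs, seed) {
  out <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    if (sp$type == "em") {
      f <- emFit(X, k = sp$k, seed = subSeed(seed, 100L + i))
      out[[i]] <- list(model = f$model, partition = f$partition)
    } else if (sp$type == "som") {
      f <- somFit(X, sp$rows, sp$cols, epochs = somEpochs,
                  seed = subSeed(seed, 100L + i))
      out[[i]] <- list(model = f$model, partition = f$partition)
    } else stop(sprintf("unknown clusterer type '%s'", sp$type), call. = FALSE)
  }
  out
}

consensusPartition <- function(method, ensemble, seed, hgpaTolerance = 0.2) {
  switch(method,
    voting = majorityVote(ensemble),
    cspa = cspaPartition(buildCoassociation(ensemble), ensemble@targetK),
    hgpa = hgpaPartition(buildHypergraph(ensemble), ensemble@targetK,
                         imbalanceTolerance = hgpaTolerance,
                         seed = subSeed(seed, 777L)),
    stop(sprintf("unknown consensus method '%s'", method), call. = FALSE))
}

metricsRow <- function(size, comp, method, target, rep) {
  data.frame(ensemble_size = size, composition = comp, method = method,
             target = target, rmse = rep@rmse, mae = rep@mae, ia = rep@ia,
             pa = rep@pa, r2_adjusted = rep@r2Adjusted, n = rep@n,
             stringsAsFactors = FALSE)
}

#' Run a full pipeline experiment
#'
#' Executes (optionally) masking and SVD imputation, the base
#' clusterings, each requested consensus function, per-cluster PCA + SVR
#' ensemble training, and outer (grouped) evaluation, and reports the
#' evaluation metrics per consensus method and target, alongside global
#' SVR and multiple-linear-regression baselines. The run is a pure
#' function of the configuration (including its seed): identical configs
#' give identical reports.
#'
#' @param config an [experimentConfig()].
#' @return A list of class `"updrsExperiment"` with `report` (one row per
#'   method and target: ensemble_size, composition, method, target, rmse,
#'   mae, ia, pa, r2_adjusted, n) and `details` (consensus ARI against
#'   true labels when the data are synthetic, imputation recovery error
#'   when masking was involved, routing audit, seeds).
#' @export
runExperiment <- function(config) {
  stopIfNot(inherits(config, "experimentConfig"),
            "config must be an experimentConfig")
  seed <- config$seed
  truthLabels <- NULL
  if (inherits(config$data, "syntheticConfig")) {
    gen <- generateTelemonitoring(config$data)
    te <- gen$table
    truthLabels <- gen$labels
  } else te <- config$data

  details <- list(seed = seed)

  # null-value experiment: mask then impute
  if (config$maskFraction > 0 && is.null(missingMask(te)))
    te <- maskRandomEntries(te, config$maskFraction, subSeed(seed, 5L))
  if (!is.null(missingMask(te))) {
    imp <- imputeSVD(te, rankD = config$imputeRank)
    if ("truth" %in% SummarizedExperiment::assayNames(te))
      details$imputation <- imputationError(imp$table, te)
    details$imputationModel <- imp$model
    te <- imp$table
  }

  X <- featureMatrix(te)
  motor <- motorUPDRS(te); total <- totalUPDRS(te)
  splits <- outerSplits(config, subjectID(te), subSeed(seed, 9L))

  cwCfg <- clusterwiseConfig(
    varianceThreshold = config$varianceThreshold, grids = config$grids,
    folds = config$folds, nMembers = config$nMembers,
    minClusterSize = config$minClusterSize, tuningRows = config$tuningRows,
    seed = subSeed(seed, 11L))

  methods <- config$consensusMethods
  pred <- list()
  for (m in methods) pred[[m]] <- list(motor = rep(NA_real_, nrow(X)),
                                       total = rep(NA_real_, nrow(X)))
  if (config$baselines) {
    pred$global_svr <- list(motor = rep(NA_real_, nrow(X)),
                            total = rep(NA_real_, nrow(X)))
    pred$global_mlr <- list(motor = rep(NA_real_, nrow(X)),
                            total = rep(NA_real_, nrow(X)))
  }
  ari <- stats::setNames(rep(NA_real_, length(methods)), methods)
  mUsed <- stats::setNames(rep(NA_real_, length(pred)), names(pred))
  comp <- paste(vapply(config$ensemble, function(sp)
    if (sp$type == "em") sprintf("EM k=%d", sp$k)
    else sprintf("SOM %dx%d", sp$rows, sp$cols), character(1)),
    collapse = " + ")

  for (si in seq_along(splits)) {
    tr <- splits[[si]]$train; tst <- splits[[si]]$test
    if (!length(tst) || !length(tr)) next
    base <- fitBaseClusterers(X[tr, , drop = FALSE], config$ensemble,
                              config$somEpochs, subSeed(seed, 20L + si))
    parts <- lapply(base, `[[`, "partition")
    ens <- if (is.null(config$targetK)) clusterEnsemble(parts)
           else clusterEnsemble(parts, targetK = config$targetK)

    for (m in methods) {
      cons <- consensusPartition(m, ens, subSeed(seed, 30L + si),
                                 hgpaTolerance = config$hgpaTolerance)
      if (!is.null(truthLabels) && si == 1)
        ari[m] <- adjustedRandIndex(
          Partition(truthLabels@labels[tr], k = truthLabels@k), cons)
      model <- fitClusterwise(te[, tr], cons, cwCfg)
      out <- predict(model, X[tst, , drop = FALSE])
      pred[[m]]$motor[tst] <- out$motor
      pred[[m]]$total[tst] <- out$total
      if (si == 1) {
        nr <- vapply(model@clusters, function(cl) cl$basis@nRetained, integer(1))
        sz <- vapply(model@clusters, `[[`, numeric(1), "n")
        mUsed[m] <- if (length(nr)) round(sum(nr * sz) / sum(sz)) else NA_real_
        details$routing[[m]] <- table(out$routing)
      }
    }

    if (config$baselines) {
      # plain baselines: a single tuned global SVR and a global MLR on
      # the imputed features themselves
      Xtr <- X[tr, , drop = FALSE]; Xts <- X[tst, , drop = FALSE]
      subjTr <- as.character(subjectID(te))[tr]
      tune <- seq_along(tr)
      if (length(tr) > config$tuningRows)
        tune <- withSeed(subSeed(seed, 40L + si),
                         sample.int(length(tr), config$tuningRows))
      for (tgt in c("motor", "total")) {
        y <- if (tgt == "motor") motor else total
        p <- gridSearch(Xtr[tune, , drop = FALSE], y[tr][tune],
                        config$grids, config$folds,
                        seed = subSeed(seed, 50L + si),
                        groups = subjTr[tune])
        fit <- svrTrain(Xtr, y[tr], p)
        pred$global_svr[[tgt]][tst] <- predict(fit, Xts)
      }
      if (si == 1) mUsed["global_svr"] <- ncol(X)
      dtr <- as.data.frame(Xtr); dts <- as.data.frame(Xts)
      fitM <- stats::lm(y ~ ., data = cbind(y = motor[tr], dtr))
      fitT <- stats::lm(y ~ ., data = cbind(y = total[tr], dtr))
      pred$global_mlr$motor[tst] <- stats::predict(fitM, dts)
      pred$global_mlr$total[tst] <- stats::predict(fitT, dts)
      if (si == 1) mUsed["global_mlr"] <- ncol(X)
    }
  }

  evalIdx <- sort(unique(unlist(lapply(splits, `[[`, "test"))))
  report <- NULL
  for (m in names(pred)) {
    mm <- if (is.na(mUsed[m])) 1L else as.integer(mUsed[m])
    size <- if (m %in% methods) length(config$ensemble) else 1L
    cc <- if (m %in% methods) comp else m
    repM <- computeMetrics(pred[[m]]$motor[evalIdx], motor[evalIdx], mm)
    repT <- computeMetrics(pred[[m]]$total[evalIdx], total[evalIdx], mm)
    report <- rbind(report,
                    metricsRow(size, cc, m, "motor_updrs", repM),
                    metricsRow(size, cc, m, "total_updrs", repT))
  }
  details$ariTruth <- ari
  details$predictions <- pred
  details$evalIndex <- evalIdx
  structure(list(report = report, details = details, config = config),
            class = "updrsExperiment")
}

#' @export
print.updrsExperiment <- function(x, ...) {
  cat("UPDRS pipeline experiment\n")
  print(x$report, row.names = FALSE, digits = 4)
  if (!all(is.na(x$details$ariTruth))) {
    cat("consensus ARI vs true labels:\n")
    print(round(x$details$ariTruth, 3))
  }
  if (!is.null(x$details$imputation))
    cat(sprintf("imputation recovery RMSE: %.4g\n", x$details$imputation$rmse))
  invisible(x)
}
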