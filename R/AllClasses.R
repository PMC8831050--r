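#' TelemonitoringExperiment: voice features with UPDRS targets
#'
#' Container for per-recording telemonitoring data, extending
#' \linkS4class{SummarizedExperiment}. The `"features"` assay holds the
#' numeric voice measures (features in rows, recordings in columns, the
#' SummarizedExperiment convention); `colData` carries the subject
#' identifier, demographic covariates (typically `age`, `sex`,
#' `test_time`) and the two regression targets `motor_updrs` (0-108) and
#' `total_updrs` (0-176). An optional `"mask"` assay (logical) marks
#' absent feature cells and an optional `"truth"` assay retains the
#' pre-masking values so imputation recovery can be scored.
#'
#' Targets are never masked and must always be present and within scale
#' bounds; masked feature cells are stored as `NA` in the `"features"`
#' assay, a sentinel no legal voice measure can take.
#'
#' @slot clipped integer vector of recording indices whose simulated
#'   targets were clipped to the scale bounds (empty for real data).
#' @export
setClass("TelemonitoringExperiment",
  contains = "SummarizedExperiment",
  representation(clipped = "integer"),
  prototype(clipped = integer(0)))

setValidity("TelemonitoringExperiment", function(object) {
  msg <- character(0)
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  cd <- SummarizedExperiment::colData(object)
  for (col in c("subject_id", "motor_updrs", "total_updrs"))
    if (!col %in% colnames(cd)) msg <- c(msg, sprintf("colData lacks '%s'", col))
  if (length(msg)) return(msg)
  mo <- cd$motor_updrs; to <- cd$total_updrs
  if (anyNA(mo) || anyNA(to))
    msg <- c(msg, "targets must be present for every recording")
  else {
    if (any(mo < 0 | mo > 108)) msg <- c(msg, "motor_updrs outside [0, 108]")
    if (any(to < 0 | to > 176)) msg <- c(msg, "total_updrs outside [0, 176]")
  }
  if ("mask" %in% SummarizedExperiment::assayNames(object)) {
    mk <- SummarizedExperiment::assay(object, "mask")
    if (!is.logical(mk)) msg <- c(msg, "'mask' assay must be logical")
  }
  if (length(msg)) msg else TRUE
})

#' Partition: one clustering of a row set
#'
#' An assignment of every recording to one of `k` clusters; the unit the
#' consensus functions consume and produce. Labels are 1-based; clusters
#' may be empty (a self-organizing map node that attracted no rows keeps
#' its index).
#'
#' @slot labels integer vector, one label in 1..k per row.
#' @slot k integer cluster count.
#' @slot source character tag naming the producing clusterer and setting
#'   (e.g. `"EM k=8"`, `"SOM 3x3"`).
#' @export
setClass("Partition",
  representation(labels = "integer", k = "integer", source = "character"),
  prototype(source = "unknown"))

setValidity("Partition", function(object) {
  if (length(object@k) != 1L || object@k < 1L) return("k must be >= 1")
  l <- object@labels
  if (anyNA(l)) return("labels must not contain NA")
  if (length(l) && (min(l) < 1L || max(l) > object@k))
    return("labels must lie in 1..k")
  TRUE
})

#' Construct a Partition
#'
#' @param labels integer-like vector of 1-based cluster labels.
#' @param k cluster count; defaults to `max(labels)`.
#' @param source character tag identifying the producing clusterer.
#' @return A [Partition-class].
#' @export
Partition <- function(labels, k = max(labels), source = "unknown") {
  new("Partition", labels = as.integer(labels), k = as.integer(k),
      source = as.character(source)[1])
}

#' ClusterEnsemble: an ordered collection of partitions
#'
#' Partitions of the same rows produced by different base clusterers
#' (EM at several k, SOM at several map sizes), to be fused by a
#' consensus function.
#'
#' @slot partitions list of [Partition-class] over identical rows.
#' @slot targetK integer; desired consensus cluster count.
#' @export
setClass("ClusterEnsemble",
  representation(partitions = "list", targetK = "integer"))

setValidity("ClusterEnsemble", function(object) {
  ps <- object@partitions
  if (length(ps) < 2L) return("an ensemble needs >= 2 partitions")
  if (!all(vapply(ps, is, logical(1), "Partition")))
    return("all elements must be Partition objects")
  n <- length(ps[[1]]@labels)
  if (!all(vapply(ps, function(p) length(p@labels) == n, logical(1))))
    return("all partitions must label the same row set")
  if (length(object@targetK) != 1L || object@targetK < 1L)
    return("targetK must be a single positive integer")
  TRUE
})

#' Construct a ClusterEnsemble
#'
#' @param partitions list of [Partition-class] objects over the same rows.
#' @param targetK desired consensus cluster count; default is the median
#'   `k` of the member partitions (rounded to integer).
#' @return A [ClusterEnsemble-class].
#' @export
clusterEnsemble <- function(partitions,
                            targetK = round(stats::median(
                              vapply(partitions, function(p) p@k, integer(1))))) {
  new("ClusterEnsemble", partitions = partitions, targetK = as.integer(targetK))
}

#' GaussianMixtureModel: EM-fitted mixture of Gaussians
#'
#' Parameters of a Gaussian mixture fitted by expectation-maximization,
#' plus the per-iteration log-likelihood trace (nondecreasing, the
#' fundamental EM guarantee).
#'
#' @slot k integer component count.
#' @slot weights numeric mixing proportions summing to 1.
#' @slot means k-by-d matrix of component means.
#' @slot sds k-by-d matrix of per-dimension standard deviations
#'   (diagonal mode) .
#' @slot covariances list of d-by-d covariance matrices (full mode only;
#'   empty list in diagonal mode).
#' @slot covarianceMode `"diagonal"` or `"full"`.
#' @slot logLikTrace numeric per-iteration log-likelihood values.
#' @slot converged logical.
#' @slot varFloor numeric variance floor applied to prevent collapse.
#' @export
setClass("GaussianMixtureModel",
  representation(k = "integer", weights = "numeric", means = "matrix",
                 sds = "matrix", covariances = "list",
                 covarianceMode = "character", logLikTrace = "numeric",
                 converged = "logical", varFloor = "numeric"))

setValidity("GaussianMixtureModel", function(object) {
  if (abs(sum(object@weights) - 1) > 1e-9) return("weights must sum to 1")
  if (object@covarianceMode == "diagonal" && any(object@sds <= 0))
    return("sds must be strictly positive")
  ll <- object@logLikTrace
  if (length(ll) > 1 && any(diff(ll) < -1e-9 * (1 + abs(ll[-length(ll)]))))
    return("log-likelihood trace must be nondecreasing")
  TRUE
})

#' SOMModel: trained self-organizing map
#'
#' A 2-D lattice of prototype vectors trained competitively; each node
#' acts as one cluster.
#'
#' @slot gridRows,gridCols integer lattice dimensions.
#' @slot codebook (gridRows*gridCols)-by-d matrix of node weight vectors,
#'   node index running row-major over the lattice.
#' @slot epochs integer epochs run.
#' @slot quantizationError numeric per-epoch mean distance of samples to
#'   their best-matching node.
#' @slot radius0,alpha0 initial neighborhood radius and learning rate.
#' @slot seed integer seed used for weight init and sample order.
#' @export
setClass("SOMModel",
  representation(gridRows = "integer", gridCols = "integer",
                 codebook = "matrix", epochs = "integer",
                 quantizationError = "numeric", radius0 = "numeric",
                 alpha0 = "numeric", seed = "integer"))

setValidity("SOMModel", function(object) {
  if (nrow(object@codebook) != object@gridRows * object@gridCols)
    return("node count must equal gridRows * gridCols")
  if (!all(is.finite(object@codebook))) return("codebook must be finite")
  TRUE
})

#' PCABasis: fitted principal-component projection
#'
#' @slot rotation d-by-m matrix of orthonormal component vectors
#'   (columns), sign fixed so each component's largest-magnitude loading
#'   is positive.
#' @slot explainedVarianceRatio per-component variance proportions
#'   (nonincreasing, relative to total variance of all d components).
#' @slot centers per-feature means used for centering.
#' @slot nRetained integer number of components kept.
#' @export
setClass("PCABasis",
  representation(rotation = "matrix", explainedVarianceRatio = "numeric",
                 centers = "numeric", nRetained = "integer"))

setValidity("PCABasis", function(object) {
  R <- object@rotation
  if (ncol(R) != object@nRetained) return("rotation must have nRetained columns")
  G <- crossprod(R)
  if (max(abs(G - diag(ncol(R)))) > 1e-8)
    return("component vectors must be pairwise orthonormal")
  evr <- object@explainedVarianceRatio
  if (length(evr) > 1 && any(diff(evr) > 1e-12))
    return("explainedVarianceRatio must be nonincreasing")
  TRUE
})

#' ImputationModel: record of an iterative SVD imputation
#'
#' @slot rankD integer retained singular values.
#' @slot columnCenters,columnScales per-feature location/scale used in the
#'   normalization step (computed over observed entries only).
#' @slot nIterations integer iterations run.
#' @slot converged logical.
#' @slot finalDelta numeric; last iteration's maximum absolute change in
#'   imputed values (original units).
#' @export
setClass("ImputationModel",
  representation(rankD = "integer", columnCenters = "numeric",
                 columnScales = "numeric", nIterations = "integer",
                 converged = "logical", finalDelta = "numeric"))

setValidity("ImputationModel", function(object) {
  if (object@rankD < 1L) return("rankD must be >= 1")
  if (any(object@columnScales <= 0)) return("scales must be strictly positive")
  TRUE
})

#' SVRParams: hyperparameters of one RBF support vector regressor
#'
#' `gamma` is the kernel spread in the form K(x,y) = exp(-||x-y||^2 /
#' gamma^2); `C` the penalty factor; `epsilon` the insensitive-tube
#' half-width.
#'
#' @slot cost,epsilon,gamma numeric scalars (`cost` is the penalty factor C).
#' @export
setClass("SVRParams",
  representation(cost = "numeric", epsilon = "numeric", gamma = "numeric"))

setValidity("SVRParams", function(object) {
  if (object@cost <= 0) return("C must be > 0")
  if (object@epsilon < 0) return("epsilon must be >= 0")
  if (object@gamma <= 0) return("gamma must be > 0")
  TRUE
})

#' Construct SVRParams
#' @param C penalty factor (> 0).
#' @param epsilon tube half-width (>= 0).
#' @param gamma RBF spread (> 0), in the gamma^2-denominator convention.
#' @return An [SVRParams-class].
#' @export
svrParams <- function(C, epsilon, gamma)
  new("SVRParams", cost = as.numeric(C), epsilon = as.numeric(epsilon),
      gamma = as.numeric(gamma))

#' SVREnsemble: bagged ensemble of trained support vector regressors
#'
#' Members are trained on with-replacement bootstrap resamples; the
#' ensemble prediction is the unweighted mean of member predictions.
#'
#' @slot members list of fitted member models (each an e1071 svm fit).
#' @slot params the shared [SVRParams-class].
#' @slot seeds integer bootstrap seeds, one per member.
#' @slot trainRMSE numeric in-sample RMSE of the ensemble mean.
#' @slot bootstrap logical; FALSE when members were trained on the full
#'   sample (degenerate, for diagnostics).
#' @export
setClass("SVREnsemble",
  representation(members = "list", params = "SVRParams", seeds = "integer",
                 trainRMSE = "numeric", bootstrap = "logical"))

setValidity("SVREnsemble", function(object) {
  if (length(object@members) < 1L) return("ensemble needs >= 1 member")
  TRUE
})

#' ClusterwiseSVRModel: per-cluster PCA + SVR ensembles with centroid routing
#'
#' For each consensus cluster with enough training rows: a PCA basis
#' fitted on that cluster, one SVR ensemble per target (Motor, Total),
#' and the cluster centroid in imputed feature space used to route
#' unseen rows (nearest centroid). Clusters below the minimum size are
#' merged into a global fallback model.
#'
#' @slot clusters named list; each element has `basis`, `motor`, `total`,
#'   `centroid`, `n`.
#' @slot fallback list with the same structure fitted on all rows, or
#'   empty when every cluster was large enough and no routing fallback is
#'   needed.
#' @slot minClusterSize integer threshold below which clusters fall back.
#' @export
setClass("ClusterwiseSVRModel",
  representation(clusters = "list", fallback = "list",
                 minClusterSize = "integer"))

setValidity("ClusterwiseSVRModel", function(object) {
  if (length(object@clusters) == 0 && length(object@fallback) == 0)
    return("model must contain at least one cluster or a fallback")
  for (cl in object@clusters) {
    if (!all(c("basis", "motor", "total", "centroid") %in% names(cl)))
      return("each cluster needs basis, motor, total, centroid")
    if (!all(is.finite(cl$centroid))) return("centroids must be finite")
  }
  TRUE
})

#' MetricsReport: regression evaluation metrics
#'
#' RMSE and MAE in target units; IA is Willmott's index of agreement in
#' [0,1]; PA the Pearson correlation of predictions and observations;
#' adjusted R-squared penalizes by the predictor count m.
#'
#' @slot rmse,mae,ia,pa,r2Adjusted numeric scalars.
#' @slot n integer observation count.
#' @slot m integer predictor count used in the adjustment.
#' @export
setClass("MetricsReport",
  representation(rmse = "numeric", mae = "numeric", ia = "numeric",
                 pa = "numeric", r2Adjusted = "numeric", n = "integer",
                 m = "integer"))

setValidity("MetricsReport", function(object) {
  if (object@rmse < 0 || object@mae < 0) return("rmse/mae must be >= 0")
  if (object@ia < 0 || object@ia > 1 + 1e-12) return("ia must lie in [0,1]")
  if (abs(object@pa) > 1 + 1e-12) return("pa must lie in [-1,1]")
  TRUE
})

## show methods ---------------------------------------------------------

setMethod("show", "Partition", function(object) {
  cat(sprintf("Partition: %d rows, k = %d [%s]\n", length(object@labels),
              object@k, object@source))
  tab <- tabulate(object@labels, nbins = object@k)
  cat("  cluster sizes:", paste(tab, collapse = " "), "\n")
})

setMethod("show", "ClusterEnsemble", function(object) {
  cat(sprintf("ClusterEnsemble: %d partitions over %d rows, targetK = %d\n",
              length(object@partitions), length(object@partitions[[1]]@labels),
              object@targetK))
  for (p in object@partitions)
    cat(sprintf("  - %s (k = %d)\n", p@source, p@k))
})

setMethod("show", "GaussianMixtureModel", function(object) {
  cat(sprintf(
    "GaussianMixtureModel: k = %d, %s covariance, %d EM iterations (%s)\n",
    object@k, object@covarianceMode, length(object@logLikTrace),
    if (object@converged) "converged" else "max iterations"))
  cat(sprintf("  final log-likelihood: %.4f\n",
              object@logLikTrace[length(object@logLikTrace)]))
})

setMethod("show", "SOMModel", function(object) {
  cat(sprintf("SOMModel: %dx%d lattice, %d epochs, final QE %.4g\n",
              object@gridRows, object@gridCols, object@epochs,
              object@quantizationError[length(object@quantizationError)]))
})

setMethod("show", "PCABasis", function(object) {
  cat(sprintf("PCABasis: %d of %d components retained (%.1f%% variance)\n",
              object@nRetained, nrow(object@rotation),
              100 * sum(object@explainedVarianceRatio[seq_len(object@nRetained)])))
})

setMethod("show", "ImputationModel", function(object) {
  cat(sprintf(
    "ImputationModel: rank %d, %d iterations (%s), final delta %.3g\n",
    object@rankD, object@nIterations,
    if (object@converged) "converged" else "max iterations",
    object@finalDelta))
})

setMethod("show", "SVRParams", function(object) {
  cat(sprintf("SVRParams: C = %g, epsilon = %g, gamma = %g\n",
              object@cost, object@epsilon, object@gamma))
})

setMethod("show", "SVREnsemble", function(object) {
  cat(sprintf("SVREnsemble: %d members (%s), train RMSE %.4g\n",
              length(object@members),
              if (object@bootstrap) "bootstrap" else "no bootstrap",
              object@trainRMSE))
  show(object@params)
})

setMethod("show", "ClusterwiseSVRModel", function(object) {
  cat(sprintf("ClusterwiseSVRModel: %d cluster models%s\n",
              length(object@clusters),
              if (length(object@fallback)) " + global fallback" else ""))
  for (nm in names(object@clusters))
    cat(sprintf("  cluster %s: n = %d, %d PCs\n", nm,
                object@clusters[[nm]]$n,
                object@clusters[[nm]]$basis@nRetained))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(
    "MetricsReport (n = %d, m = %d)\n  RMSE %.4f  MAE %.4f  IA %.4f  PA %.4f  adj.R2 %.4f\n",
    object@n, object@m, object@rmse, object@mae, object@ia, object@pa,
    object@r2Adjusted))
})

## simple accessors -----------------------------------------------------

#' @describeIn Partition-class cluster labels.
#' @param x object.
#' @export
setMethod("partitionLabels", "Partition", function(x) x@labels)

#' @describeIn Partition-class cluster count.
#' @export
setMethod("nClusters", "Partition", function(x) x@k)

#' @describeIn GaussianMixtureModel-class component count.
#' @param x object.
#' @export
setMethod("nClusters", "GaussianMixtureModel", function(x) x@k)

#' @describeIn SOMModel-class node count (clusters may be empty).
#' @param x object.
#' @export
setMethod("nClusters", "SOMModel", function(x) x@gridRows * x@gridCols)
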