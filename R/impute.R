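#' Column-wise normalization of a feature block
#'
#' Z-scores each column using its observed entries only (masked cells are
#' `NA`): center = mean, scale = sample SD (n-1 denominator). The inverse
#' transform restores the originals to within 1e-10 relative.
#'
#' @param X numeric matrix, possibly containing `NA` for masked cells.
#' @return List with `block` (normalized matrix, `NA`s preserved),
#'   `centers`, `scales`.
#' @export
normalizeFeatures <- function(X) {
  X <- as.matrix(X)
  centers <- numeric(ncol(X)); scales <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    obs <- X[!is.na(X[, j]), j]
    stopIfNot(length(obs) >= 2,
              "column %d has fewer than 2 observed values", j)
    s <- stats::sd(obs)
    if (!is.finite(s) || s == 0)
      stop(sprintf("degenerate scale: column %d (%s) is constant", j,
                   colnames(X)[j] %||% "?"), call. = FALSE)
    centers[j] <- mean(obs); scales[j] <- s
  }
  list(block = sweep(sweep(X, 2, centers), 2, scales, `/`),
       centers = centers, scales = scales)
}

#' Invert [normalizeFeatures()]
#'
#' @param Z normalized matrix.
#' @param centers,scales as returned by [normalizeFeatures()].
#' @return Matrix in original units.
#' @export
denormalizeFeatures <- function(Z, centers, scales)
  sweep(sweep(Z, 2, scales, `*`), 2, centers, `+`)

#' Best rank-d approximation of a dense block
#'
#' Truncated singular value decomposition: the optimal approximation in
#' the least-squares sense. Approximation error is nonincreasing in
#' `rankD`.
#'
#' @param block dense numeric matrix (no `NA`).
#' @param rankD number of singular values retained, in 1..min(dim).
#' @return The rank-`rankD` approximation matrix.
#' @export
svdLowRank <- function(block, rankD) {
  block <- as.matrix(block)
  stopIfNot(!anyNA(block), "block must be fully dense")
  r <- min(dim(block))
  stopIfNot(rankD >= 1 && rankD <= r, "rankD must lie in 1..min(dim)")
  s <- svd(block, nu = rankD, nv = rankD)
  s$u %*% (s$d[seq_len(rankD)] * t(s$v))
}

#' Impute missing feature values by iterated low-rank SVD
#'
#' Missing feature cells are initialized at their column means, then the
#' block is repeatedly normalized, approximated by a truncated SVD at rank
#' `rankD`, and the masked cells replaced by the approximation, until the
#' maximum absolute change in imputed values (original units) drops below
#' `tol` or `maxIter` is reached. Observed cells are never altered.
#' `maxIter = 1` performs the literal single-pass five-step procedure.
#'
#' @param te a [TelemonitoringExperiment-class] with at least one masked
#'   feature cell.
#' @param rankD retained singular values, or `"auto"` (default): the
#'   number of singular values of the initialized normalized block above
#'   the Marchenko-Pastur noise edge `sqrt(rows) + sqrt(features)` (the
#'   largest singular value a pure unit-variance noise matrix of this
#'   shape produces), at least 1. Normalized columns have unit variance,
#'   so values above the edge carry structure and values below it are
#'   indistinguishable from noise; retaining near-noise directions makes
#'   the iteration fit observed noise and extrapolate badly into the
#'   masked cells.
#' @param maxIter maximum iterations (default 100).
#' @param tol convergence tolerance on the imputed-cell change, original
#'   units (default 1e-6).
#' @return List with `table` (dense [TelemonitoringExperiment-class]) and
#'   `model` (an [ImputationModel-class]).
#' @export
imputeSVD <- function(te, rankD = "auto", maxIter = 100, tol = 1e-6) {
  mask <- missingMask(te)
  stopIfNot(!is.null(mask) && any(mask), "table has no masked feature cell")
  X <- featureMatrix(te)
  fullCols <- which(colSums(!mask) == 0)
  if (length(fullCols))
    stop(sprintf("column %d is fully masked; cannot impute", fullCols[1]),
         call. = FALSE)

  # initialize masked cells at their column means (observed entries only)
  nrm0 <- normalizeFeatures(X)
  Xcur <- X
  Xcur[mask] <- matrix(nrm0$centers, nrow(X), ncol(X), byrow = TRUE)[mask]

  if (identical(rankD, "auto")) {
    Z0 <- normalizeFeatures(Xcur)$block
    sv <- svd(Z0, nu = 0, nv = 0)$d
    edge <- sqrt(nrow(Z0)) + sqrt(ncol(Z0))
    rankD <- max(1L, sum(sv > edge))
  }
  rankD <- as.integer(rankD)
  stopIfNot(rankD >= 1 && rankD <= min(dim(X)),
            "rankD must lie in 1..min(rows, features)")

  # iterate: normalize the current completed block, approximate at rank d,
  # replace the masked cells, denormalize; the normalization is refit each
  # pass so the completed matrix itself is the object being approximated
  delta <- Inf; iter <- 0L; converged <- FALSE
  nrm <- nrm0
  while (iter < maxIter) {
    iter <- iter + 1L
    nrm <- normalizeFeatures(Xcur)
    Zd <- svdLowRank(nrm$block, rankD)
    if (any(!is.finite(Zd)))
      stop(sprintf("numeric error: non-finite values at iteration %d", iter),
           call. = FALSE)
    filled <- denormalizeFeatures(Zd, nrm$centers, nrm$scales)
    old <- Xcur[mask]
    Xcur[mask] <- filled[mask]
    delta <- max(abs(Xcur[mask] - old))
    if (delta < tol) { converged <- TRUE; break }
  }

  Xout <- Xcur
  Xout[!mask] <- X[!mask]           # observed entries bitwise unchanged
  colnames(Xout) <- colnames(X)

  cd <- as.data.frame(SummarizedExperiment::colData(te))
  covCols <- setdiff(colnames(cd), c("subject_id", "motor_updrs", "total_updrs"))
  dense <- TelemonitoringExperiment(
    features = Xout, subjectID = cd$subject_id, motorUPDRS = cd$motor_updrs,
    totalUPDRS = cd$total_updrs,
    covariates = if (length(covCols)) cd[covCols] else NULL,
    clipped = te@clipped)
  model <- new("ImputationModel", rankD = rankD, columnCenters = nrm$centers,
               columnScales = nrm$scales, nIterations = iter,
               converged = converged, finalDelta = delta)
  list(table = dense, model = model)
}

#' Score imputation recovery against retained truth
#'
#' Compares imputed values in the masked cells with the values retained by
#' [maskRandomEntries()].
#'
#' @param imputed dense table returned by [imputeSVD()].
#' @param masked the masked table that was imputed (carries `mask` and
#'   `truth` assays).
#' @return List with `rmse`, `mae` and `maxRelative` error over masked
#'   cells.
#' @export
imputationError <- function(imputed, masked) {
  mask <- missingMask(masked)
  stopIfNot(!is.null(mask), "masked table carries no mask")
  stopIfNot("truth" %in% SummarizedExperiment::assayNames(masked),
            "masked table retains no truth assay")
  truth <- t(SummarizedExperiment::assay(masked, "truth"))[mask]
  est <- featureMatrix(imputed)[mask]
  err <- est - truth
  list(rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
       maxRelative = max(abs(err) / pmax(abs(truth), .Machine$double.eps)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
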