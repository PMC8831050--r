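#' Pearson correlation coefficient
#'
#' Thin validated wrapper around the product-moment correlation: the
#' covariance of the two sequences over the product of their standard
#' deviations. Symmetric in its arguments and bounded in [-1, 1].
#'
#' @param x,y numeric vectors of equal length >= 2, each with nonzero
#'   variance.
#' @return Correlation coefficient.
#' @export
pcc <- function(x, y) {
  stopIfNot(length(x) == length(y), "x and y must have equal length")
  stopIfNot(length(x) >= 2, "need at least 2 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: zero-variance input", call. = FALSE)
  stats::cor(x, y)
}

#' Fit a principal-component basis for feature decorrelation
#'
#' Centers the block, eigendecomposes its covariance (n-1 denominator),
#' and retains the smallest number of components whose cumulative
#' explained variance reaches `varianceThreshold`. Component signs are
#' fixed by the convention that each component's largest-magnitude loading
#' is positive, so the basis is reproducible across linear-algebra
#' backends.
#'
#' @param X dense numeric matrix with >= 2 rows.
#' @param varianceThreshold cumulative explained-variance target in
#'   (0, 1]; default 0.95.
#' @return A [PCABasis-class].
#' @export
fitPCA <- function(X, varianceThreshold = 0.95) {
  X <- as.matrix(X)
  stopIfNot(nrow(X) >= 2, "need >= 2 rows")
  stopIfNot(is.numeric(varianceThreshold) && varianceThreshold > 0 &&
              varianceThreshold <= 1,
            "varianceThreshold must lie in (0, 1]")
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  evr <- ev / sum(ev)
  m <- which(cumsum(evr) >= varianceThreshold - 1e-12)[1]
  rot <- p$rotation[, seq_len(m), drop = FALSE]
  for (j in seq_len(m)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  new("PCABasis", rotation = rot, explainedVarianceRatio = evr,
      centers = as.numeric(p$center), nRetained = as.integer(m))
}

#' Project features onto a fitted principal-component basis
#'
#' Centered orthogonal projection onto the retained components. On the
#' training block the score columns are mutually uncorrelated.
#'
#' @param X numeric matrix whose column count matches the basis.
#' @param basis a [PCABasis-class].
#' @return Score matrix with `nRetained` columns.
#' @export
pcaTransform <- function(X, basis) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(basis@rotation))
    stop(sprintf("shape error: %d features supplied, basis expects %d",
                 ncol(X), nrow(basis@rotation)), call. = FALSE)
  sweep(X, 2, basis@centers) %*% basis@rotation
}
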