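#' Construct a TelemonitoringExperiment
#'
#' Builds the central data container from a recordings-by-features matrix
#' plus per-recording annotations. Masked feature cells (if any) are held
#' as `NA` in the features assay; their true values may be retained in a
#' parallel `truth` assay for recovery scoring.
#'
#' @param features numeric recordings-by-features matrix of voice measures.
#' @param subjectID per-recording subject identifier (coerced to factor).
#' @param motorUPDRS,totalUPDRS numeric targets, in [0,108] and [0,176].
#' @param covariates optional data.frame of per-recording covariates
#'   (e.g. `age`, `sex`, `test_time`).
#' @param mask optional logical matrix of the same shape as `features`
#'   (`TRUE` = absent).
#' @param truth optional numeric matrix retaining pre-masking values.
#' @param clipped integer indices of rows whose simulated targets were
#'   clipped to scale bounds (synthetic data bookkeeping).
#' @return A [TelemonitoringExperiment-class].
#' @examples
#' te <- TelemonitoringExperiment(
#'   features = matrix(rnorm(20), 5, 4),
#'   subjectID = rep(c("a", "b"), c(3, 2)),
#'   motorUPDRS = runif(5, 10, 40), totalUPDRS = runif(5, 20, 60))
#' featureMatrix(te)
#' @export
TelemonitoringExperiment <- function(features, subjectID, motorUPDRS,
                                     totalUPDRS, covariates = NULL,
                                     mask = NULL, truth = NULL,
                                     clipped = integer(0)) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (is.null(colnames(features)))
    colnames(features) <- sprintf("feature_%02d", seq_len(ncol(features)))
  cd <- S4Vectors::DataFrame(subject_id = factor(subjectID),
                             motor_updrs = as.numeric(motorUPDRS),
                             total_updrs = as.numeric(totalUPDRS))
  if (!is.null(covariates)) {
    stopIfNot(nrow(covariates) == n, "covariates must have one row per recording")
    cd <- cbind(cd, S4Vectors::DataFrame(covariates))
  }
  assays <- list(features = t(features))
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    stopIfNot(all(dim(mask) == dim(features)),
              "mask must match the feature matrix shape")
    assays$mask <- t(mask)
  }
  if (!is.null(truth)) assays$truth <- t(as.matrix(truth))
  se <- SummarizedExperiment::SummarizedExperiment(assays = assays, colData = cd)
  colnames(se) <- sprintf("rec_%05d", seq_len(n))
  new("TelemonitoringExperiment", se, clipped = as.integer(clipped))
}

#' @describeIn TelemonitoringExperiment recordings-by-features matrix
#'   (masked cells as `NA`).
#' @param x a `TelemonitoringExperiment`.
#' @export
setMethod("featureMatrix", "TelemonitoringExperiment", function(x)
  t(SummarizedExperiment::assay(x, "features")))

#' @describeIn TelemonitoringExperiment logical mask, or `NULL` when fully
#'   observed.
#' @export
setMethod("missingMask", "TelemonitoringExperiment", function(x) {
  if ("mask" %in% SummarizedExperiment::assayNames(x))
    t(SummarizedExperiment::assay(x, "mask"))
  else NULL
})

#' @name accessors
#' @title Per-recording annotation accessors
#' @description Subject identifiers and UPDRS targets of a
#'   [TelemonitoringExperiment-class].
#' @param x a `TelemonitoringExperiment`.
#' @return `subjectID`: factor; `motorUPDRS`, `totalUPDRS`: numeric.
NULL

#' @rdname accessors
#' @export
setMethod("subjectID", "TelemonitoringExperiment", function(x)
  SummarizedExperiment::colData(x)$subject_id)

#' @rdname accessors
#' @export
setMethod("motorUPDRS", "TelemonitoringExperiment", function(x)
  SummarizedExperiment::colData(x)$motor_updrs)

#' @rdname accessors
#' @export
setMethod("totalUPDRS", "TelemonitoringExperiment", function(x)
  SummarizedExperiment::colData(x)$total_updrs)

#' Declare column roles for loading a telemonitoring CSV
#'
#' The dataset's feature names are not standardized, so the schema is
#' user-declared: which CSV columns are the subject id, covariates,
#' voice features, and the two targets.
#'
#' @param id column name of the subject identifier.
#' @param features character vector of feature column names.
#' @param motor,total target column names.
#' @param covariates optional character vector of covariate columns.
#' @param naTokens strings treated (case-insensitively) as missing in
#'   feature cells; the empty string is always included.
#' @return A list of class `"tmSchema"`.
#' @export
tmSchema <- function(id, features, motor = "motor_updrs",
                     total = "total_updrs", covariates = character(0),
                     naTokens = c("", "NA", "NaN")) {
  structure(list(id = id, features = features, motor = motor, total = total,
                 covariates = covariates,
                 naTokens = unique(c("", tolower(naTokens)))),
            class = "tmSchema")
}

#' Load a telemonitoring table from CSV
#'
#' Reads an RFC-4180 CSV with a header row, applies the declared column
#' roles, and marks empty / NA-token feature cells as missing. Row order
#' is preserved exactly.
#'
#' @param path CSV file path.
#' @param schema a [tmSchema()] declaring column roles.
#' @return A [TelemonitoringExperiment-class]; if any feature cell was
#'   missing, a `mask` assay records which.
#' @export
loadTable <- function(path, schema) {
  stopIfNot(inherits(schema, "tmSchema"), "schema must be a tmSchema")
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c(schema$id, schema$features, schema$motor, schema$total,
            schema$covariates)
  absent <- setdiff(need, colnames(raw))
  if (length(absent))
    stop(sprintf("schema error: column(s) %s not present in %s",
                 paste(sQuote(absent), collapse = ", "), path), call. = FALSE)

  parseNum <- function(col, allowNA) {
    txt <- trimws(raw[[col]])
    isna <- tolower(txt) %in% schema$naTokens
    out <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(out) & !isna)
    if (length(bad))
      stop(sprintf("parse error: non-numeric value %s in column '%s', row %d",
                   sQuote(txt[bad[1]]), col, bad[1]), call. = FALSE)
    if (!allowNA && any(isna))
      stop(sprintf("schema error: missing value in target column '%s', row %d",
                   col, which(isna)[1]), call. = FALSE)
    out[isna] <- NA_real_
    out
  }

  feat <- vapply(schema$features, parseNum, numeric(nrow(raw)), allowNA = TRUE)
  feat <- matrix(feat, nrow = nrow(raw),
                 dimnames = list(NULL, schema$features))
  mask <- is.na(feat)
  cov <- NULL
  if (length(schema$covariates)) {
    cov <- as.data.frame(lapply(schema$covariates, parseNum, allowNA = FALSE),
                         col.names = schema$covariates)
  }
  TelemonitoringExperiment(
    features = feat, subjectID = raw[[schema$id]],
    motorUPDRS = parseNum(schema$motor, allowNA = FALSE),
    totalUPDRS = parseNum(schema$total, allowNA = FALSE),
    covariates = cov,
    mask = if (any(mask)) mask else NULL)
}

#' Write a telemonitoring table to CSV
#'
#' Inverse of [loadTable()]: masked feature cells are written as empty
#' strings; numeric content round-trips at full double precision.
#'
#' @param te a [TelemonitoringExperiment-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
saveTable <- function(te, path) {
  X <- featureMatrix(te)
  cd <- as.data.frame(SummarizedExperiment::colData(te))
  covCols <- setdiff(colnames(cd), c("subject_id", "motor_updrs", "total_updrs"))
  df <- data.frame(subject_id = cd$subject_id, check.names = FALSE)
  for (cc in covCols) df[[cc]] <- cd[[cc]]
  fmt <- function(v) ifelse(is.na(v), "", formatC(v, digits = 17, format = "g"))
  for (j in seq_len(ncol(X))) df[[colnames(X)[j]]] <- fmt(X[, j])
  df$motor_updrs <- fmt(cd$motor_updrs)
  df$total_updrs <- fmt(cd$total_updrs)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Schema matching the layout written by [saveTable()]
#'
#' @param te the experiment whose layout to describe.
#' @return A [tmSchema()].
#' @export
tmSchemaOf <- function(te) {
  cd <- as.data.frame(SummarizedExperiment::colData(te))
  tmSchema(id = "subject_id", features = colnames(featureMatrix(te)),
           covariates = setdiff(colnames(cd),
                                c("subject_id", "motor_updrs", "total_updrs")))
}

#' Mask a random fraction of feature cells
#'
#' Marks exactly `round(fraction * rows * features)` feature cells as
#' missing, chosen uniformly without replacement over feature cells only
#' (targets are never masked). The original values are retained in a
#' `truth` assay so imputation recovery can be scored later.
#'
#' @param te a fully observed [TelemonitoringExperiment-class].
#' @param fraction proportion of feature cells to mask, in (0,1).
#' @param seed integer; the mask is a deterministic function of the seed.
#' @return A `TelemonitoringExperiment` with `mask` and `truth` assays.
#' @export
maskRandomEntries <- function(te, fraction, seed) {
  stopIfNot(is.numeric(fraction) && fraction > 0 && fraction < 1,
            "fraction must lie in (0,1)")
  stopIfNot(is.null(missingMask(te)),
            "table already has masked cells; unmask first")
  X <- featureMatrix(te)
  nCells <- length(X)
  nMask <- round(fraction * nCells)
  stopIfNot(nMask >= 1, "fraction too small: no cell would be masked")
  idx <- withSeed(seed, sample.int(nCells, nMask))
  truth <- X
  mask <- matrix(FALSE, nrow(X), ncol(X))
  mask[idx] <- TRUE
  X[idx] <- NA_real_
  cd <- as.data.frame(SummarizedExperiment::colData(te))
  covCols <- setdiff(colnames(cd), c("subject_id", "motor_updrs", "total_updrs"))
  TelemonitoringExperiment(
    features = X, subjectID = cd$subject_id, motorUPDRS = cd$motor_updrs,
    totalUPDRS = cd$total_updrs,
    covariates = if (length(covCols)) cd[covCols] else NULL,
    mask = mask, truth = truth, clipped = te@clipped)
}

#' Restore retained values into masked cells
#'
#' Inverse of [maskRandomEntries()]: puts the retained `truth` values back
#' into the masked cells, yielding the original fully observed table.
#'
#' @param te a masked [TelemonitoringExperiment-class] carrying a `truth`
#'   assay.
#' @return The unmasked `TelemonitoringExperiment`.
#' @export
unmaskTable <- function(te) {
  mask <- missingMask(te)
  stopIfNot(!is.null(mask), "table has no mask")
  stopIfNot("truth" %in% SummarizedExperiment::assayNames(te),
            "table retains no truth assay; cannot unmask")
  X <- featureMatrix(te)
  truth <- t(SummarizedExperiment::assay(te, "truth"))
  X[mask] <- truth[mask]
  cd <- as.data.frame(SummarizedExperiment::colData(te))
  covCols <- setdiff(colnames(cd), c("subject_id", "motor_updrs", "total_updrs"))
  TelemonitoringExperiment(
    features = X, subjectID = cd$subject_id, motorUPDRS = cd$motor_updrs,
    totalUPDRS = cd$total_updrs,
    covariates = if (length(covCols)) cd[covCols] else NULL,
    clipped = te@clipped)
}
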