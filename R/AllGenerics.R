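#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor cov cutree dist dnorm hclust lm predict prcomp
#'   quantile rbinom rnorm runif sd setNames var
#' @importFrom utils read.csv write.csv head
NULL

#' Feature matrix of a telemonitoring experiment
#'
#' Returns the voice-feature block as a recordings-by-features numeric
#' matrix (the orientation every downstream stage consumes).
#'
#' @param x A [TelemonitoringExperiment-class].
#' @return A numeric matrix with one row per recording.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Missing-value mask of a telemonitoring experiment
#'
#' @param x A [TelemonitoringExperiment-class].
#' @return A logical recordings-by-features matrix (`TRUE` = value absent),
#'   or `NULL` when the table is fully observed.
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname accessors
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))

#' @rdname accessors
#' @export
setGeneric("motorUPDRS", function(x) standardGeneric("motorUPDRS"))

#' @rdname accessors
#' @export
setGeneric("totalUPDRS", function(x) standardGeneric("totalUPDRS"))

#' Cluster labels of a partition
#'
#' @param x A [Partition-class].
#' @return Integer vector of 1-based cluster labels, one per row.
#' @export
setGeneric("partitionLabels", function(x) standardGeneric("partitionLabels"))

#' Number of clusters
#'
#' @param x A [Partition-class] or model object.
#' @return Integer cluster count.
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' Assign rows to clusters under a fitted clustering model
#'
#' For a Gaussian mixture the label is the argmax responsibility; for a
#' self-organizing map it is the best-matching lattice node. Deterministic.
#'
#' @param model A fitted [GaussianMixtureModel-class] or [SOMModel-class].
#' @param features Numeric recordings-by-features matrix, dimension matching
#'   the model.
#' @return A [Partition-class] over the rows of `features`.
#' @export
setGeneric("clusterAssign", function(model, features)
  standardGeneric("clusterAssign"))
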