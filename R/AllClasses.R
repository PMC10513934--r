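#' @import methods
#' @importFrom Matrix Matrix sparseMatrix t colSums rowSums rowMeans colMeans
#'   diag readMM writeMM drop0
NULL

#' Symmetric k-nearest-neighbour graph over cells or pseudobulks
#'
#' Holds the symmetric, non-negative sparse weight matrix \eqn{w_{ij}} used
#' for Moran's I autocorrelation, Leiden partitioning and graph diffusion.
#' The diagonal is zero and the total weight \eqn{W = \sum_{ij} w_{ij}} must
#' be positive.
#'
#' @slot weights symmetric sparse \code{dgCMatrix} of edge weights.
#' @slot k integer, number of neighbours requested at construction.
#' @slot metric character, distance metric name (currently "euclidean").
#'
#' @seealso [knnGraph()], [moransI()], [leidenPartition()]
#' @export
setClass("NeighborGraph",
  slots = c(weights = "dgCMatrix", k = "integer", metric = "character"))

setValidity("NeighborGraph", function(object) {
  w <- object@weights
  if (nrow(w) != ncol(w)) return("weight matrix must be square")
  if (any(w@x < 0)) return("edge weights must be non-negative")
  if (any(Matrix::diag(w) != 0)) return("diagonal weights must be zero")
  if (!Matrix::isSymmetric(w, tol = 1e-10)) return("weights must be symmetric")
  if (sum(w) <= 0) return("total edge weight must be positive")
  TRUE
})

#' @describeIn NeighborGraph number of nodes
#' @param object,x a \code{NeighborGraph}
#' @export
nNodes <- function(x) nrow(x@weights)

#' @describeIn NeighborGraph sparse symmetric weight matrix
#' @export
graphWeights <- function(x) x@weights

setMethod("show", "NeighborGraph", function(object) {
  w <- object@weights
  cat(sprintf("NeighborGraph: %d nodes, %d undirected edges (k=%d, %s)\n",
              nrow(w), length(w@x) / 2L, object@k, object@metric))
})

#' Pseudobulk expression profiles
#'
#' Container for cluster-by-gene aggregate expression. Two kinds are
#' supported, mirroring their distinct downstream uses:
#' \describe{
#'   \item{fine}{metacell-style profiles: per-cluster \emph{means} of
#'     log1p-normalized expression, from a very-high-resolution graph
#'     partition. Used as low-noise feature vectors for gene and state
#'     clustering.}
#'   \item{metadata}{raw counts \emph{summed} over cells sharing metadata
#'     keys (e.g. cell type x sample x sex), used for GLM-based
#'     differential expression.}
#' }
#'
#' @slot profiles numeric matrix, clusters x genes.
#' @slot sizes integer vector, number of cells per cluster.
#' @slot kind "fine" or "metadata".
#' @slot keys data.frame of per-cluster grouping metadata (may have 0 cols).
#'
#' @seealso [finePseudobulk()], [metadataPseudobulk()]
#' @export
setClass("PseudobulkMatrix",
  slots = c(profiles = "matrix", sizes = "integer", kind = "character",
            keys = "data.frame"))

setValidity("PseudobulkMatrix", function(object) {
  if (!object@kind %in% c("fine", "metadata"))
    return("kind must be 'fine' or 'metadata'")
  if (length(object@sizes) != nrow(object@profiles))
    return("one size per profile row required")
  if (any(object@sizes < 1L)) return("cluster sizes must be >= 1")
  if (nrow(object@keys) > 0 && nrow(object@keys) != nrow(object@profiles))
    return("keys must have one row per cluster")
  TRUE
})

#' @describeIn PseudobulkMatrix clusters x genes profile matrix
#' @param object,x a \code{PseudobulkMatrix}
#' @export
profiles <- function(x) x@profiles

#' @describeIn PseudobulkMatrix cells per cluster
#' @export
clusterSizes <- function(x) x@sizes

#' @describeIn PseudobulkMatrix per-cluster grouping metadata
#' @export
clusterKeys <- function(x) x@keys

setMethod("show", "PseudobulkMatrix", function(object) {
  cat(sprintf("PseudobulkMatrix (%s): %d clusters x %d genes, %d cells\n",
              object@kind, nrow(object@profiles), ncol(object@profiles),
              sum(object@sizes)))
})
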