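#' Build a union-symmetrized k-nearest-neighbour graph
#'
#' Exact Euclidean nearest neighbours computed blockwise; an undirected
#' edge of weight 1 is placed between two nodes if either lies among the
#' other's \code{k} nearest (union symmetrization). Distance ties are
#' broken deterministically by node index. Binary weights follow the
#' classical Moran's I convention; pass \code{weighted = TRUE} for
#' Gaussian-kernel weights with per-node bandwidth equal to the distance to
#' the k-th neighbour.
#'
#' @param embedding cells x d numeric matrix of coordinates.
#' @param k number of neighbours (must be < number of rows).
#' @param weighted use Gaussian kernel weights instead of binary.
#' @return a \linkS4class{NeighborGraph}.
#' @export
knnGraph <- function(embedding, k = 15L, weighted = FALSE) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (k >= n) stop("k must be smaller than the number of points",
                   call. = FALSE)
  if (!all(is.finite(embedding))) stop("non-finite coordinates",
                                       call. = FALSE)
  sq <- rowSums(embedding^2)
  block <- max(1L, floor(2e7 / n))
  nn_idx <- matrix(0L, n, k)
  nn_dist <- matrix(0, n, k)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    d2 <- outer(sq[rows], sq, "+") -
      2 * tcrossprod(embedding[rows, , drop = FALSE], embedding)
    for (j in seq_along(rows)) {
      i <- rows[j]
      di <- d2[j, ]
      di[i] <- Inf
      ord <- order(di, seq_len(n))[seq_len(k)]   # ties by node index
      nn_idx[i, ] <- ord
      nn_dist[i, ] <- sqrt(pmax(di[ord], 0))
    }
  }
  ii <- rep(seq_len(n), each = k)
  jj <- as.vector(t(nn_idx))
  if (weighted) {
    bw <- pmax(nn_dist[, k], 1e-12)
    ww <- exp(-(as.vector(t(nn_dist))^2) / (2 * bw[ii]^2))
    a <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
    at <- Matrix::t(a)
    w <- (a + at + abs(a - at)) / 2          # elementwise max kernel
  } else {
    a <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
    w <- a + Matrix::t(a)
    w@x <- rep(1, length(w@x))               # union: edge if either direction
  }
  methods::new("NeighborGraph",
               weights = methods::as(methods::as(w, "CsparseMatrix"),
                                     "generalMatrix"),
               k = as.integer(k), metric = "euclidean")
}

#' Moran's I spatial autocorrelation on a neighbour graph
#'
#' \deqn{I = \frac{N}{W} \frac{\sum_{ij} w_{ij}(x_i-\bar x)(x_j-\bar x)}
#'                            {\sum_i (x_i-\bar x)^2}}
#' with \eqn{N} nodes and total weight \eqn{W=\sum_{ij} w_{ij}}. Values lie
#' in approximately \eqn{[-1, 1]}; the null expectation is
#' \eqn{-1/(N-1)}.
#'
#' @param x numeric vector of node values (length N) or a cells x genes
#'   matrix to compute one I per column.
#' @param graph a \linkS4class{NeighborGraph} over the same nodes.
#' @return a single I, or a named vector of per-gene I for matrix input.
#' @export
moransI <- function(x, graph) {
  w <- graphWeights(graph)
  n <- nrow(w)
  W <- sum(w)
  if (is.matrix(x) || is(x, "Matrix")) {
    stopifnot(nrow(x) == n)
    dev <- as.matrix(x)
    dev <- sweep(dev, 2L, colMeans(dev))
    ss <- colSums(dev^2)
    if (any(ss == 0))
      stop("zero-variance column: autocorrelation undefined", call. = FALSE)
    num <- colSums(dev * as.matrix(w %*% dev))
    return((n / W) * num / ss)
  }
  stopifnot(length(x) == n)
  dev <- x - mean(x)
  ss <- sum(dev^2)
  if (ss == 0) stop("undefined autocorrelation for zero-variance input",
                    call. = FALSE)
  (n / W) * sum(dev * as.numeric(w %*% dev)) / ss
}

#' Moran's I conservation score of an integrated embedding
#'
#' Embedding-quality metric that needs no cell-type annotation: if an
#' embedding retains biological variation, highly variable genes should
#' vary smoothly (non-randomly) across it. The score selects \code{g}
#' batch-aware HVGs, computes each gene's Moran's I on the embedding's kNN
#' graph, and rescales the mean to [0, 1]:
#' \deqn{\mathrm{score} = \frac{\frac{1}{g}\sum_g i_g + 1}{2}.}
#'
#' Genes expressed in fewer than 3 cells are excluded from the HVG pool.
#'
#' @param sce SingleCellExperiment with \code{logcounts}.
#' @param embedding cells x d matrix (the integrated embedding).
#' @param batch_key colData column with batch labels for HVG selection.
#' @param g number of HVGs (fewer are used, with a warning, if not enough
#'   genes have positive variance).
#' @param k neighbours for the graph.
#' @return list with \code{per_gene_I} (named), \code{g}, \code{mean_I} and
#'   \code{score}.
#' @export
conservationScore <- function(sce, embedding, batch_key = "sample",
                              g = 1000L, k = 15L) {
  expr <- SummarizedExperiment::assay(sce, "logcounts")
  n_cells_expr <- Matrix::rowSums(expr > 0)
  eligible <- rownames(sce)[n_cells_expr >= 3L]
  sub <- sce[eligible, ]
  if (length(eligible) < g) {
    warning("fewer than g eligible genes; using all ", length(eligible))
    g <- length(eligible)
  }
  hvgs <- hvgBatch(sub, n_top = g, batch_key = batch_key)
  graph <- knnGraph(embedding, k = k)
  xm <- Matrix::t(SummarizedExperiment::assay(sce, "logcounts")[hvgs, ,
                                                                drop = FALSE])
  keep <- apply(as.matrix(xm), 2L, stats::sd) > 0
  I <- moransI(as.matrix(xm)[, keep, drop = FALSE], graph)
  list(per_gene_I = I, g = length(I), mean_I = mean(I),
       score = (mean(I) + 1) / 2)
}
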