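# mean silhouette width of a partition given a dense distance matrix
.meanSilhouette <- function(dm, labels) {
  n <- nrow(dm)
  ulab <- unique(labels)
  if (length(ulab) < 2L) return(-Inf)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1L) sum(dm[i, own]) / (sum(own) - 1L) else 0
    b <- min(vapply(ulab[ulab != labels[i]], function(u)
      mean(dm[i, labels == u]), 0))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 0)
  mean(s)
}

#' Leiden community detection on a neighbour graph
#'
#' Modularity-objective Leiden partitioning via igraph; deterministic for
#' a fixed seed. High resolutions (e.g. 20) yield the metacell-style fine
#' clusters used for pseudobulk profiles.
#'
#' @param graph a \linkS4class{NeighborGraph}.
#' @param resolution resolution parameter (higher = more clusters).
#' @param seed integer seed.
#' @param n_iterations Leiden refinement iterations.
#' @return integer vector of cluster labels (1-based).
#' @export
leidenPartition <- function(graph, resolution = 1, seed = 0L,
                            n_iterations = 5L) {
  w <- graphWeights(graph)
  if (nrow(w) == 0L) stop("empty graph", call. = FALSE)
  ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                            weighted = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_leiden(ig, objective_function = "modularity",
                               resolution = resolution,
                               n_iterations = n_iterations)
  as.integer(igraph::membership(cl))
}

#' Metacell-style fine pseudobulk profiles
#'
#' Per-cluster means of log1p-normalized expression; the size-weighted mean
#' of the profiles reconstructs the global mean profile exactly.
#'
#' @param norm_expr cells x genes matrix of log1p-normalized expression.
#' @param labels cluster label per cell.
#' @return a \linkS4class{PseudobulkMatrix} of kind "fine".
#' @export
finePseudobulk <- function(norm_expr, labels) {
  norm_expr <- as.matrix(norm_expr)
  stopifnot(nrow(norm_expr) == length(labels))
  lab <- as.character(labels)
  ulab <- sort(unique(lab))
  ind <- Matrix::sparseMatrix(i = match(lab, ulab), j = seq_along(lab), x = 1,
                              dims = c(length(ulab), length(lab)))
  sizes <- as.integer(Matrix::rowSums(ind))
  prof <- as.matrix(ind %*% norm_expr) / sizes
  dimnames(prof) <- list(ulab, colnames(norm_expr))
  methods::new("PseudobulkMatrix", profiles = prof, sizes = sizes,
               kind = "fine",
               keys = data.frame(cluster = ulab, stringsAsFactors = FALSE))
}

#' Metadata-based pseudobulk counts
#'
#' Raw counts summed over cells sharing a combination of metadata keys
#' (e.g. cell type x sample x sex); no log transform is applied. Total
#' counts are conserved.
#'
#' @param counts cells x genes matrix of raw counts.
#' @param group_keys data.frame of per-cell metadata columns defining the
#'   grouping.
#' @return a \linkS4class{PseudobulkMatrix} of kind "metadata" whose
#'   \code{clusterKeys} hold the unique key combinations.
#' @export
metadataPseudobulk <- function(counts, group_keys) {
  group_keys <- as.data.frame(group_keys)
  stopifnot(nrow(group_keys) == nrow(counts))
  key <- do.call(paste, c(group_keys, sep = "\r"))
  ukey <- sort(unique(key))
  ind <- Matrix::sparseMatrix(i = match(key, ukey), j = seq_along(key), x = 1,
                              dims = c(length(ukey), length(key)))
  prof <- as.matrix(ind %*% counts)
  rownames(prof) <- ukey
  colnames(prof) <- colnames(counts)
  keys <- group_keys[match(ukey, key), , drop = FALSE]
  rownames(keys) <- NULL
  methods::new("PseudobulkMatrix", profiles = prof,
               sizes = as.integer(Matrix::rowSums(ind)), kind = "metadata",
               keys = keys)
}

#' Fine-state clustering of pseudobulks on gene-program scores
#'
#' Pseudobulks are clustered hierarchically (Euclidean distance, Ward
#' linkage) on their gene-program score vectors; each cell inherits the
#' state of its pseudobulk. The dendrogram cut can be an explicit number
#' of states \code{k}, an explicit height \code{h}, a fraction of the
#' maximum merge height, or chosen automatically (\code{k = "auto"}, the
#' default) as the k in \code{2..k_max} maximizing the mean silhouette
#' width of the pseudobulk partition, a deterministic stand-in for a
#' visually selected cut.
#'
#' @param gp_scores pseudobulks x programs matrix of mean GP scores.
#' @param cell_clusters fine-pseudobulk label per cell (values must match
#'   rownames of \code{gp_scores}).
#' @param cut_height_frac fraction of the maximum merge height to cut at
#'   when \code{k} is NULL and no \code{h} is given.
#' @param k number of states, or "auto" for silhouette selection.
#' @param k_max largest k considered by the automatic selection.
#' @param h optional explicit cut height (used when \code{k} is NULL).
#' @return list with \code{state} (label per cell),
#'   \code{pseudobulk_state} (label per pseudobulk) and \code{provenance}
#'   (parameters used).
#' @export
gpStateClustering <- function(gp_scores, cell_clusters,
                              cut_height_frac = 0.7, k = "auto",
                              k_max = 10L, h = NULL) {
  gp_scores <- as.matrix(gp_scores)
  if (nrow(gp_scores) == 1L) {
    pb_state <- stats::setNames(1L, rownames(gp_scores))
  } else {
    d <- stats::dist(gp_scores)
    hc <- stats::hclust(d, method = "ward.D2")
    if (identical(k, "auto")) {
      dm <- as.matrix(d)
      ks <- 2:min(k_max, nrow(gp_scores) - 1L)
      sil <- vapply(ks, function(kk)
        .meanSilhouette(dm, stats::cutree(hc, k = kk)), 0)
      k <- ks[which.max(sil)]
      pb_state <- stats::cutree(hc, k = k)
    } else if (is.null(k)) {
      if (is.null(h)) h <- cut_height_frac * max(hc$height)
      pb_state <- stats::cutree(hc, h = h)
    } else pb_state <- stats::cutree(hc, k = k)
  }
  cl <- as.character(cell_clusters)
  stopifnot(all(cl %in% rownames(gp_scores)))
  list(state = as.integer(pb_state[cl]),
       pseudobulk_state = pb_state,
       provenance = list(linkage = "ward.D2", distance = "euclidean",
                         cut_height_frac = cut_height_frac, k = k, h = h))
}

#' Pruned inter-state connectivity on the cell graph
#'
#' PAGA-style state-graph: the observed inter-state edge weight is divided
#' by its expectation under a degree-preserving configuration-model null,
#' \eqn{E[s,t] = \mathrm{vol}_s \mathrm{vol}_t / (2m)} with vol the summed
#' degrees, clipped to [0, 1]; entries below \code{prune_threshold} are
#' zeroed.
#'
#' @param graph a \linkS4class{NeighborGraph} over cells.
#' @param states state label per cell.
#' @param prune_threshold connectivities below this are set to 0.
#' @return symmetric states x states matrix with zero diagonal.
#' @export
clusterConnectivity <- function(graph, states, prune_threshold = 0.1) {
  w <- graphWeights(graph)
  lab <- as.character(states)
  ulab <- if (is.factor(states)) levels(states) else sort(unique(lab))
  if (!all(ulab %in% lab)) stop("state with no cells", call. = FALSE)
  ind <- Matrix::sparseMatrix(i = seq_along(lab), j = match(lab, ulab), x = 1,
                              dims = c(length(lab), length(ulab)))
  obs <- as.matrix(Matrix::t(ind) %*% w %*% ind)     # summed edge weights x2
  deg <- Matrix::rowSums(w)
  vol <- as.numeric(Matrix::t(ind) %*% deg)
  m2 <- sum(w)                                       # = 2m for binary graphs
  expd <- outer(vol, vol) / m2
  conn <- pmin(obs / expd, 1)
  diag(conn) <- 0
  conn[conn < prune_threshold] <- 0
  dimnames(conn) <- list(ulab, ulab)
  conn
}

#' Weighted k-NN label transfer with an uncertainty threshold
#'
#' For each query cell the \code{k} nearest reference cells (shared
#' embedding space, Euclidean distance) vote with Gaussian-kernel weights
#' whose bandwidth is the distance to the k-th neighbour. The predicted
#' label is the argmax weighted vote; uncertainty is 1 minus the winning
#' vote share, and cells above \code{uncertainty_threshold} are labelled
#' "unassigned".
#'
#' @param ref_embedding reference cells x d matrix.
#' @param ref_labels label per reference cell.
#' @param query_embedding query cells x d matrix.
#' @param k neighbours (must be <= reference size).
#' @param uncertainty_threshold cells with uncertainty above this are
#'   unassigned (default 0.75).
#' @return data.frame with columns \code{label} and \code{uncertainty}.
#' @export
labelTransfer <- function(ref_embedding, ref_labels, query_embedding,
                          k = 15L, uncertainty_threshold = 0.75) {
  ref_embedding <- as.matrix(ref_embedding)
  query_embedding <- as.matrix(query_embedding)
  nr <- nrow(ref_embedding)
  if (k > nr) stop("k exceeds reference size", call. = FALSE)
  lab <- as.character(ref_labels)
  ulab <- sort(unique(lab))
  d2 <- outer(rowSums(query_embedding^2), rowSums(ref_embedding^2), "+") -
    2 * tcrossprod(query_embedding, ref_embedding)
  out <- t(apply(d2, 1L, function(di) {
    ord <- order(di, seq_len(nr))[seq_len(k)]
    dd <- sqrt(pmax(di[ord], 0))
    bw <- max(dd[k], 1e-12)
    wv <- exp(-dd^2 / (2 * bw^2))
    votes <- vapply(ulab, function(u) sum(wv[lab[ord] == u]), 0)
    votes <- votes / sum(votes)
    c(which.max(votes), 1 - max(votes))
  }))
  label <- ulab[out[, 1L]]
  label[out[, 2L] > uncertainty_threshold] <- "unassigned"
  data.frame(label = label, uncertainty = out[, 2L])
}
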