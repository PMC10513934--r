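#' Per-sample ambient expression profile from near-empty droplets
#'
#' Gene proportions are computed on raw counts over droplets with total
#' counts below \code{max_count} (default 100), the droplets assumed to
#' contain no cell and therefore only ambient RNA.
#'
#' @param raw_sample_counts genes x droplets matrix of raw counts for one
#'   sample, including sub-threshold droplets.
#' @param max_count droplets with total counts >= this contribute nothing.
#' @param sample sample label stored in the profile.
#' @return an \code{AmbientProfile} list: \code{sample},
#'   \code{gene_proportion} (named, sums to 1), \code{n_droplets_used},
#'   \code{max_count_threshold}.
#' @export
ambientProfile <- function(raw_sample_counts, max_count = 100,
                           sample = "sample") {
  tot <- Matrix::colSums(raw_sample_counts)
  use <- tot < max_count & tot > 0
  if (!any(use))
    stop("no droplets with fewer than ", max_count, " counts in sample ",
         sample, call. = FALSE)
  gs <- Matrix::rowSums(raw_sample_counts[, use, drop = FALSE])
  structure(list(sample = sample,
                 gene_proportion = stats::setNames(as.numeric(gs) / sum(gs),
                                                   rownames(raw_sample_counts)),
                 n_droplets_used = sum(use),
                 max_count_threshold = max_count),
            class = "AmbientProfile")
}

#' Select top ambient genes across samples
#'
#' Per sample, genes are ranked by their ambient proportion and a
#' proportion threshold is chosen so that the per-sample set has
#' approximately the target size; the reported sets are unions across
#' samples. Two nested sets are returned: a strict set of the dominant
#' ambient genes and a more permissive set.
#'
#' @param profiles list of [ambientProfile()] objects.
#' @param small_target approximate per-sample size of the strict set.
#' @param large_target approximate per-sample size of the permissive set.
#' @return list with \code{small_set} and \code{large_set} (character
#'   vectors, small_set is a subset of large_set) and \code{proportions}
#'   (genes x samples matrix of ambient proportions for the large set).
#' @export
topAmbientGenes <- function(profiles, small_target = 20L,
                            large_target = 100L) {
  stopifnot(length(profiles) >= 1L)
  if (small_target > large_target)
    stop("small_target must be <= large_target", call. = FALSE)
  n_genes <- length(profiles[[1L]]$gene_proportion)
  if (large_target > n_genes)
    stop("target exceeds number of genes", call. = FALSE)
  pick <- function(prof, target) {
    p <- sort(prof$gene_proportion, decreasing = TRUE)
    thr <- p[target]                         # proportion threshold
    names(p)[p >= thr]
  }
  small_set <- sort(unique(unlist(lapply(profiles, pick, small_target))))
  large_set <- sort(unique(c(small_set,
                             unlist(lapply(profiles, pick, large_target)))))
  prop <- sapply(profiles, function(pr) pr$gene_proportion[large_set])
  prop <- matrix(prop, nrow = length(large_set),
                 dimnames = list(large_set,
                                 vapply(profiles, `[[`, "", "sample")))
  list(small_set = small_set, large_set = large_set, proportions = prop)
}

#' Relative expression of genes across cell types
#'
#' Per gene, cluster mean expressions are maxabs-scaled across clusters
#' (divided by the largest absolute cluster mean); the relative expression
#' of the gene in a cell type is the highest scaled value over clusters
#' predominantly composed of that type (modal cell-type label > 50% of
#' members). Low values in a cell type indicate the gene's signal there is
#' likely ambient rather than endogenous.
#'
#' @param norm_expr cells x genes matrix of normalized (log1p) expression.
#' @param cluster_labels fine cluster label per cell.
#' @param celltype_labels cell-type label per cell (used to assign each
#'   cluster its predominant type).
#' @return genes x celltypes matrix with values in [0, 1]; genes with
#'   all-zero means get 0 everywhere. Attribute \code{"scaled_clusters"}
#'   carries the genes x clusters maxabs-scaled means.
#' @export
relativeExpression <- function(norm_expr, cluster_labels, celltype_labels) {
  cl <- as.character(cluster_labels)
  cls <- sort(unique(cl))
  norm_expr <- as.matrix(norm_expr)
  means <- t(vapply(cls, function(c)
    colMeans(norm_expr[cl == c, , drop = FALSE]), numeric(ncol(norm_expr))))
  # genes x clusters
  means <- t(means)
  mx <- apply(abs(means), 1L, max)
  scaled <- means / ifelse(mx > 0, mx, 1)    # all-zero genes stay 0

  modal <- vapply(cls, function(c) {
    tab <- table(celltype_labels[cl == c])
    if (max(tab) / sum(tab) > 0.5) names(tab)[which.max(tab)]
    else NA_character_
  }, "")
  types <- sort(unique(stats::na.omit(modal)))
  rel <- vapply(types, function(tp) {
    cc <- which(modal == tp)
    apply(scaled[, cc, drop = FALSE], 1L, max)
  }, numeric(nrow(scaled)))
  rel <- matrix(rel, nrow = nrow(scaled),
                dimnames = list(colnames(norm_expr), types))
  attr(rel, "scaled_clusters") <- scaled
  rel
}

#' Ambient genes unlikely to originate from a target cell type
#'
#' Ambient genes are grouped by hierarchical clustering (correlation
#' distance, average linkage) of their per-cluster relative expression
#' profiles; groups whose maximum relative expression in the target cell
#' type is below \code{cutoff} are flagged as ambient signals not produced
#' by that type.
#'
#' @param ambient_genes character vector of ambient gene names.
#' @param rel_expr output of [relativeExpression()] (the
#'   \code{"scaled_clusters"} attribute must be present).
#' @param target_celltype column of \code{rel_expr} naming the type.
#' @param cutoff relative-expression cutoff (default 0.5).
#' @param k number of groups; default \code{max(2, ceiling(n/5))}.
#' @return character vector of flagged genes (possibly empty).
#' @export
nonCelltypeAmbientGenes <- function(ambient_genes, rel_expr,
                                    target_celltype, cutoff = 0.5,
                                    k = NULL) {
  ambient_genes <- intersect(ambient_genes, rownames(rel_expr))
  if (length(ambient_genes) == 0L) return(character(0))
  if (cutoff <= 0) return(character(0))
  scaled <- attr(rel_expr, "scaled_clusters")[ambient_genes, , drop = FALSE]
  n <- length(ambient_genes)
  if (is.null(k)) k <- max(2L, ceiling(n / 5))
  k <- min(k, n)
  grp <- if (n == 1L) 1L else {
    cm <- suppressWarnings(stats::cor(t(scaled)))
    cm[!is.finite(cm)] <- 0
    stats::cutree(stats::hclust(stats::as.dist(1 - cm), method = "average"),
                  k = k)
  }
  rel_t <- rel_expr[ambient_genes, target_celltype]
  flagged <- unlist(lapply(split(ambient_genes, grp), function(g)
    if (max(rel_t[g]) < cutoff) g else character(0)))
  sort(unname(flagged))
}
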