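#' Sparsity-bias-corrected Moran's I
#'
#' Genes detected in few cells are biased toward low Moran's I, which
#' would make lowly expressed genes systematically less likely to be
#' selected as variable. The correction estimates the baseline sparsity
#' trend from genes that are likely not truly variable and reports
#' residuals from that trend:
#' \enumerate{
#'   \item genes detected in at least \code{high_expr_cutoff} (a fraction
#'     of cells, or an absolute cell count if > 1) are excluded from the
#'     baseline, as very widely expressed genes deviate upward;
#'   \item remaining genes are split into \code{n_bins} equal-frequency
#'     bins by number of expressing cells and the \code{per_bin} lowest-I
#'     genes of each bin form the baseline set;
#'   \item an OLS regression of I on log10(cells expressing) is fitted on
#'     the baseline set (a lowess fit is available via
#'     \code{method = "lowess"});
#'   \item corrected I = I minus the fitted baseline, for every gene.
#' }
#'
#' @param I named numeric vector of per-gene Moran's I.
#' @param n_expressed named vector, cells expressing each gene (same
#'   genes).
#' @param high_expr_cutoff fraction of cells (default 0.40) or absolute
#'   count above which genes are excluded from baseline fitting.
#' @param n_cells total cell count, needed when \code{high_expr_cutoff}
#'   is a fraction.
#' @param n_bins equal-frequency bins over n_expressed.
#' @param per_bin lowest-I genes taken per bin.
#' @param method "ols" (default) or "lowess".
#' @param lowess_f lowess smoother span (only for method = "lowess").
#' @return data.frame with gene, I, n_expressed, corrected_I,
#'   used_in_baseline.
#' @export
correctedMoransI <- function(I, n_expressed, high_expr_cutoff = 0.40,
                             n_cells = NULL, n_bins = 20L, per_bin = 5L,
                             method = c("ols", "lowess"), lowess_f = 2 / 3) {
  method <- match.arg(method)
  stopifnot(length(I) == length(n_expressed))
  genes <- names(I)
  if (is.null(genes)) genes <- sprintf("g%d", seq_along(I))
  cutoff_cells <- if (high_expr_cutoff <= 1) {
    if (is.null(n_cells))
      stop("n_cells required for a fractional high_expr_cutoff",
           call. = FALSE)
    high_expr_cutoff * n_cells
  } else high_expr_cutoff

  eligible <- which(n_expressed < cutoff_cells)
  if (length(eligible) < 2L)
    stop("too few genes below high_expr_cutoff to fit a baseline",
         call. = FALSE)
  if (length(eligible) < n_bins * per_bin) {
    per_bin <- max(1L, floor(length(eligible) / n_bins))
    warning("reducing per_bin to ", per_bin, " for ", length(eligible),
            " eligible genes")
  }
  bins <- .equalFreqBins(n_expressed[eligible], n_bins)
  baseline <- unlist(lapply(split(eligible, bins), function(idx)
    idx[order(I[idx], idx)][seq_len(min(per_bin, length(idx)))]))

  lx <- log10(pmax(n_expressed, 1))
  if (method == "ols") {
    fit <- stats::lm(I[baseline] ~ lx[baseline])
    fitted_all <- stats::coef(fit)[1L] + stats::coef(fit)[2L] * lx
  } else {
    lo <- stats::lowess(lx[baseline], I[baseline], f = lowess_f)
    fitted_all <- stats::approx(lo$x, lo$y, xout = lx, rule = 2)$y
  }
  data.frame(gene = genes, I = as.numeric(I),
             n_expressed = as.numeric(n_expressed),
             corrected_I = as.numeric(I - fitted_all),
             used_in_baseline = seq_along(I) %in% baseline,
             stringsAsFactors = FALSE)
}

#' Cluster selected genes into coexpression programs
#'
#' Genes are clustered on their fine-pseudobulk expression profiles
#' (distance 1 - Pearson r, average linkage); the dendrogram cut yields
#' disjoint gene programs, and programs smaller than \code{min_size} are
#' dropped.
#'
#' @param genes character vector of selected genes (e.g. top corrected
#'   Moran's I).
#' @param pb a fine \linkS4class{PseudobulkMatrix} containing the genes.
#' @param cut_height_frac cut at this fraction of the max merge height.
#' @param k optional number of programs (overrides the height cut).
#' @param min_size programs smaller than this are dropped (default 5).
#' @return named list of \code{GeneProgram} lists (id, genes); programs
#'   are pairwise disjoint.
#' @export
clusterGenePrograms <- function(genes, pb, cut_height_frac = 0.5, k = NULL,
                                min_size = 5L) {
  stopifnot(length(genes) >= 2L)
  prof <- profiles(pb)[, genes, drop = FALSE]
  cm <- suppressWarnings(stats::cor(prof))
  cm[!is.finite(cm)] <- 0
  d <- stats::as.dist(1 - cm)
  if (max(d) == 0) {
    grp <- stats::setNames(rep(1L, length(genes)), genes)
  } else {
    hc <- stats::hclust(d, method = "average")
    grp <- if (is.null(k))
      stats::cutree(hc, h = cut_height_frac * max(hc$height))
    else stats::cutree(hc, k = k)
  }
  progs <- split(genes, grp)
  progs <- progs[lengths(progs) >= min_size]
  if (length(progs) == 0L) return(list())
  stats::setNames(lapply(seq_along(progs), function(i)
    list(id = sprintf("GP%d", i), genes = unname(progs[[i]]))),
    sprintf("GP%d", seq_along(progs)))
}

#' Score cells for a gene set against bin-matched controls
#'
#' The per-cell score is the mean expression over the set minus the mean
#' over control genes drawn (seeded) from the same mean-expression bins as
#' the set members, excluding the members themselves (up to
#' \code{ctrl_per_bin} controls per occupied bin).
#'
#' @param norm_expr cells x genes matrix of log1p-normalized expression.
#' @param gene_set character vector; genes missing from the matrix are
#'   dropped with a message.
#' @param n_ctrl_bins number of equal-frequency mean-expression bins.
#' @param ctrl_per_bin control genes sampled per occupied bin.
#' @param seed integer seed for the control draw.
#' @return numeric vector of per-cell scores.
#' @export
scoreGeneSet <- function(norm_expr, gene_set, n_ctrl_bins = 25L,
                         ctrl_per_bin = 50L, seed = 0L) {
  norm_expr <- as.matrix(norm_expr)
  all_genes <- colnames(norm_expr)
  missing <- setdiff(gene_set, all_genes)
  gene_set <- intersect(gene_set, all_genes)
  if (length(gene_set) == 0L)
    stop("gene set has no overlap with measured genes", call. = FALSE)
  if (length(missing)) message(length(missing),
                               " gene(s) missing from matrix, dropped")
  mu <- colMeans(norm_expr)
  bins <- .equalFreqBins(mu, n_ctrl_bins)
  set_bins <- unique(bins[match(gene_set, all_genes)])
  set.seed(seed)
  ctrl <- unlist(lapply(set_bins, function(b) {
    cand <- setdiff(all_genes[bins == b], gene_set)
    if (length(cand) <= ctrl_per_bin) cand
    else sample(cand, ctrl_per_bin)
  }))
  if (length(ctrl) == 0L)
    stop("no control genes available outside the set", call. = FALSE)
  rowMeans(norm_expr[, gene_set, drop = FALSE]) -
    rowMeans(norm_expr[, ctrl, drop = FALSE])
}

#' Winsorized min-max normalization of per-cell scores
#'
#' Rescales scores to [0, 1] where the scaling range is the min/max after
#' removing the \code{n_trim} highest and lowest cells; values outside the
#' range are clipped. With 2*n_trim or more cells absent, falls back to a
#' plain min-max with a warning. Constant scores map to 0.5.
#'
#' @param scores numeric vector.
#' @param n_trim cells trimmed from each tail to set the range.
#' @return numeric vector in [0, 1].
#' @export
minmaxWinsorized <- function(scores, n_trim = 20L) {
  n <- length(scores)
  if (stats::sd(scores) == 0 || n == 1L) return(rep(0.5, n))
  if (n > 2L * n_trim) {
    s <- sort(scores)
    lo <- s[n_trim + 1L]
    hi <- s[n - n_trim]
  } else {
    warning("too few cells for winsorizing; plain min-max used")
    lo <- min(scores)
    hi <- max(scores)
  }
  if (hi == lo) return(rep(0.5, n))
  pmin(pmax((scores - lo) / (hi - lo), 0), 1)
}

#' Gene groups variable in every healthy sample
#'
#' Per sample, bias-corrected Moran's I is computed on the sample's own
#' embedding graph (baseline excludes genes expressed in at least
#' \code{min_expr_frac} of the sample's cells); genes above the
#' corrected-I threshold in ALL samples are retained. Retained genes are
#' clustered with the distance defined as the maximum over samples of the
#' per-sample correlation distance on fine pseudobulks, so a group must be
#' coexpressed in every sample.
#'
#' @param per_sample list, one element per sample, each a list with
#'   \code{expr} (cells x genes log1p-normalized matrix) and
#'   \code{embedding} (cells x d matrix).
#' @param min_expr_frac baseline exclusion threshold (default 0.30).
#' @param corrected_I_min per-sample threshold on corrected I.
#' @param k graph neighbours per sample.
#' @param fine_resolution Leiden resolution for per-sample pseudobulks.
#' @param cut_height absolute correlation-distance cut for the final gene
#'   grouping: genes in a group must reach 1 - cut_height Pearson r on
#'   the pseudobulks of every sample (default 0.4).
#' @param min_size groups smaller than this are dropped.
#' @param seed seed for the per-sample Leiden partitions.
#' @return named list of gene groups (character vectors); empty, with a
#'   warning, if no gene passes in all samples.
#' @export
conservedVariableGeneGroups <- function(per_sample, min_expr_frac = 0.30,
                                        corrected_I_min = 0.1, k = 15L,
                                        fine_resolution = 10,
                                        cut_height = 0.4,
                                        min_size = 5L, seed = 0L) {
  stopifnot(length(per_sample) >= 2L)
  genes <- colnames(per_sample[[1L]]$expr)
  pass <- rep(TRUE, length(genes))
  dists <- NULL
  for (si in seq_along(per_sample)) {
    expr <- as.matrix(per_sample[[si]]$expr)
    stopifnot(identical(colnames(expr), genes))
    graph <- knnGraph(per_sample[[si]]$embedding, k = k)
    n_expr <- colSums(expr > 0)
    ok <- n_expr >= 3L & apply(expr, 2L, stats::sd) > 0
    I <- rep(NA_real_, length(genes))
    I[ok] <- moransI(expr[, ok, drop = FALSE], graph)
    cm <- correctedMoransI(I[ok], n_expr[ok],
                           high_expr_cutoff = min_expr_frac,
                           n_cells = nrow(expr))
    ci <- rep(-Inf, length(genes))
    ci[ok] <- cm$corrected_I
    pass <- pass & ci >= corrected_I_min

    part <- leidenPartition(graph, resolution = fine_resolution,
                            seed = seed + si)
    prof <- profiles(finePseudobulk(expr, part))
    cmat <- suppressWarnings(stats::cor(prof))
    cmat[!is.finite(cmat)] <- 0
    d <- 1 - cmat
    dists <- if (is.null(dists)) d else pmax(dists, d)
  }
  sel <- genes[pass]
  if (length(sel) < 2L) {
    warning("no gene passes the corrected-I threshold in all samples")
    return(list())
  }
  hc <- stats::hclust(stats::as.dist(dists[sel, sel]), method = "average")
  grp <- stats::cutree(hc, h = cut_height)
  groups <- split(sel, grp)
  groups <- groups[lengths(groups) >= min_size]
  stats::setNames(groups, sprintf("group%d", seq_along(groups)))
}

#' Variance explained by gene-program scores via PC regression
#'
#' PCs are computed from the supplied expression matrix; each PC's scores
#' are regressed on the GP score matrix and the total explained variance
#' is \eqn{\sum_k R^2_k \cdot \mathrm{varratio}_k}. Significance comes
#' from an empirical null of size-matched random gene groups scored with
#' [scoreGeneSet()] and run through the same regression:
#' \eqn{p = (1 + \#\{null \ge obs\}) / (1 + n_{rand})} (one-sided).
#'
#' @param expr cells x genes log1p-normalized matrix (HVG-subset).
#' @param gp_scores cells x programs matrix of per-cell GP scores.
#' @param gene_sets optional named list of the GP gene sets, needed for the
#'   random-group null (sizes are matched per program).
#' @param n_pcs number of principal components.
#' @param n_rand random repetitions for the null (0 skips it).
#' @param seed seed controlling the random gene draws.
#' @return list with \code{total_ev}, \code{per_pc_r2},
#'   \code{var_ratio}, \code{per_gp_ev} (leave-one-in EV per program),
#'   \code{null_ev} and \code{empirical_p}.
#' @export
explainedVariance <- function(expr, gp_scores, gene_sets = NULL,
                              n_pcs = 50L, n_rand = 0L, seed = 0L) {
  expr <- as.matrix(expr)
  gp_scores <- as.matrix(gp_scores)
  n_pcs <- min(n_pcs, ncol(expr), nrow(expr) - 1L)
  pca <- stats::prcomp(expr, center = TRUE, scale. = FALSE, rank. = n_pcs)
  var_ratio <- pca$sdev[seq_len(n_pcs)]^2 / sum(pca$sdev^2)

  qr_scores <- function(S) {
    qrS <- qr(cbind(1, S))
    if (qrS$rank < ncol(S) + 1L)
      warning("collinear GP scores; redundant columns dropped in fit")
    qrS
  }
  r2_of <- function(S) {
    qrS <- qr_scores(S)
    vapply(seq_len(n_pcs), function(kk) {
      y <- pca$x[, kk]
      res <- qr.resid(qrS, y)
      1 - sum(res^2) / sum((y - mean(y))^2)
    }, 0)
  }
  per_pc_r2 <- r2_of(gp_scores)
  total_ev <- sum(per_pc_r2 * var_ratio)
  per_gp_ev <- vapply(seq_len(ncol(gp_scores)), function(j)
    sum(r2_of(gp_scores[, j, drop = FALSE]) * var_ratio), 0)
  names(per_gp_ev) <- colnames(gp_scores)

  null_ev <- numeric(0)
  if (n_rand > 0L) {
    if (is.null(gene_sets))
      stop("gene_sets needed for the random-group null", call. = FALSE)
    sizes <- lengths(gene_sets)
    all_genes <- colnames(expr)
    null_ev <- vapply(seq_len(n_rand), function(r) {
      S <- vapply(seq_along(sizes), function(j) {
        set.seed(seed * 10000L + r * 100L + j)
        rnd <- sample(all_genes, sizes[j])
        scoreGeneSet(expr, rnd, seed = seed + r)
      }, numeric(nrow(expr)))
      sum(r2_of(S) * var_ratio)
    }, 0)
  }
  list(total_ev = total_ev, per_pc_r2 = per_pc_r2, var_ratio = var_ratio,
       per_gp_ev = per_gp_ev, null_ev = null_ev,
       empirical_p = if (n_rand > 0L)
         (1 + sum(null_ev >= total_ev)) / (1 + n_rand) else NA_real_)
}
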