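#' Quality-control thresholds for cell filtering
#'
#' @param min_genes minimum number of expressed genes per cell.
#' @param min_counts minimum total counts per cell.
#' @param max_counts maximum total counts per cell (outlier rule).
#' @param max_mito_frac maximum mitochondrial count fraction.
#' @param mito_gene_prefix gene-name prefix identifying mitochondrial genes.
#' @return a \code{QCThresholds} list.
#' @export
qcThresholds <- function(min_genes = 200L, min_counts = 500L,
                         max_counts = Inf, max_mito_frac = 0.2,
                         mito_gene_prefix = "mt-") {
  if (min_counts > max_counts) stop("min_counts must be <= max_counts",
                                    call. = FALSE)
  .assertProportion(max_mito_frac, "max_mito_frac")
  structure(list(min_genes = min_genes, min_counts = min_counts,
                 max_counts = max_counts, max_mito_frac = max_mito_frac,
                 mito_gene_prefix = mito_gene_prefix),
            class = "QCThresholds")
}

#' Filter cells on QC rules
#'
#' Removes cells with too few expressed genes, too few or too many total
#' counts, or too high a mitochondrial proportion. Barcodes flagged as
#' empty droplets in the colData (column \code{is_empty}) are kept out of
#' the cell set but their raw counts remain available upstream for ambient
#' profiling; doublet flags (\code{is_doublet}) are also removed here when
#' present.
#'
#' @param sce a SingleCellExperiment with a \code{counts} assay.
#' @param thresholds a [qcThresholds()] object.
#' @return list with \code{sce} (filtered) and \code{report} (data.frame of
#'   per-rule removal counts).
#' @export
filterCells <- function(sce, thresholds = qcThresholds()) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  tot <- Matrix::colSums(counts)
  ngene <- Matrix::colSums(counts > 0)
  mito <- startsWith(rownames(counts), thresholds$mito_gene_prefix)
  mfrac <- if (any(mito)) Matrix::colSums(counts[mito, , drop = FALSE]) /
    pmax(tot, 1) else rep(0, ncol(counts))

  cd <- SummarizedExperiment::colData(sce)
  flagged <- rep(FALSE, ncol(counts))
  if ("is_empty" %in% colnames(cd)) flagged <- flagged | cd$is_empty
  if ("is_doublet" %in% colnames(cd)) flagged <- flagged | cd$is_doublet

  fail_genes <- ngene < thresholds$min_genes
  fail_min <- tot < thresholds$min_counts
  fail_max <- tot > thresholds$max_counts
  fail_mito <- mfrac > thresholds$max_mito_frac
  keep <- !(fail_genes | fail_min | fail_max | fail_mito | flagged)
  if (!any(keep))
    stop("all cells removed by QC; thresholds: min_genes=",
         thresholds$min_genes, " min_counts=", thresholds$min_counts,
         call. = FALSE)
  report <- data.frame(
    rule = c("min_genes", "min_counts", "max_counts", "max_mito_frac",
             "flagged_empty_or_doublet", "kept"),
    n = c(sum(fail_genes), sum(fail_min), sum(fail_max), sum(fail_mito),
          sum(flagged), sum(keep)))
  list(sce = sce[, keep], report = report)
}

#' Per-sample normalization and log1p transform
#'
#' Size factors are computed per sample and mean-centred to 1 within each
#' sample, then each cell's counts are divided by its size factor and
#' log(x + 1)-transformed into the \code{logcounts} assay.
#'
#' \describe{
#'   \item{total}{size factor proportional to the cell's total count; after
#'     division every cell's total equals the sample mean total (the scale
#'     is set by mean-centring the factors).}
#'   \item{median_ratio}{median across genes of the ratio of the cell's
#'     counts to the sample's mean expression profile (computed over genes
#'     detected in the cell), a droplet-friendly median-of-ratios.}
#' }
#'
#' @param sce SingleCellExperiment with \code{counts}; colData must contain
#'   a \code{sample} column (a single implicit sample is assumed otherwise).
#' @param method "total" (default) or "median_ratio".
#' @return the SingleCellExperiment with a \code{logcounts} assay and a
#'   \code{sizeFactor} colData column.
#' @export
normalizeLog1p <- function(sce, method = c("total", "median_ratio")) {
  method <- match.arg(method)
  counts <- SummarizedExperiment::assay(sce, "counts")
  tot <- Matrix::colSums(counts)
  if (any(tot == 0))
    stop("zero-count cells present; run filterCells first", call. = FALSE)
  cd <- SummarizedExperiment::colData(sce)
  samp <- if ("sample" %in% colnames(cd)) as.character(cd$sample)
          else rep("sample1", ncol(counts))
  sf <- numeric(ncol(counts))
  for (s in unique(samp)) {
    idx <- which(samp == s)
    if (method == "total") {
      f <- tot[idx]
    } else {
      ref <- Matrix::rowMeans(counts[, idx, drop = FALSE])
      sub <- as.matrix(counts[, idx, drop = FALSE])
      f <- vapply(seq_along(idx), function(j) {
        det <- sub[, j] > 0 & ref > 0
        stats::median(sub[det, j] / ref[det])
      }, 0)
    }
    sf[idx] <- f / mean(f)                   # mean-centred to 1 per sample
  }
  norm <- sweep(as.matrix(counts), 2L, sf, "/")
  SummarizedExperiment::assay(sce, "logcounts") <-
    Matrix::Matrix(log1p(norm), sparse = TRUE)
  sce$sizeFactor <- sf
  sce
}

# per-batch normalized dispersion: genes ranked by z-scored dispersion
# (var/mean of de-logged normalized expression) within 20 equal-frequency
# mean bins; returns rank per gene (1 = most variable)
.batchDispersionRank <- function(expr, n_bins = 20L) {
  x <- expm1(expr)                           # cells x genes dense
  mu <- colMeans(x)
  v <- apply(x, 2L, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- .equalFreqBins(mu, n_bins)
  z <- numeric(length(disp))
  for (b in unique(bins)) {
    i <- bins == b
    s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  z[disp == 0] <- -Inf                       # constant genes rank last
  order_idx <- order(-z, seq_along(z))       # ties broken by gene index
  rk <- integer(length(z))
  rk[order_idx] <- seq_along(z)
  rk
}

#' Batch-aware highly variable gene selection
#'
#' Within each batch, genes are ranked by normalized dispersion
#' (variance/mean of de-logged normalized expression, z-scored within 20
#' equal-frequency mean-expression bins). The final list orders genes by
#' the number of batches in which they fall in that batch's top
#' \code{n_top}, breaking ties by median rank across batches and then gene
#' index, and returns the first \code{n_top}.
#'
#' @param sce SingleCellExperiment with \code{logcounts}.
#' @param n_top number of genes to return.
#' @param batch_key colData column naming the batch (default "sample").
#' @return character vector of gene names, ordered by selection priority.
#' @export
hvgBatch <- function(sce, n_top = 2000L, batch_key = "sample") {
  expr <- SummarizedExperiment::assay(sce, "logcounts")
  genes <- rownames(sce)
  if (n_top > length(genes)) {
    warning("n_top exceeds gene count; returning all genes")
    n_top <- length(genes)
  }
  cd <- SummarizedExperiment::colData(sce)
  batch <- if (batch_key %in% colnames(cd)) as.character(cd[[batch_key]])
           else rep("batch1", ncol(sce))
  ranks <- sapply(unique(batch), function(b) {
    idx <- which(batch == b)
    if (length(idx) < 2L) stop("batch ", b, " has < 2 cells", call. = FALSE)
    .batchDispersionRank(t(as.matrix(expr[, idx, drop = FALSE])))
  })
  ranks <- matrix(ranks, nrow = length(genes))
  in_top <- rowSums(ranks <= n_top)
  med_rank <- apply(ranks, 1L, stats::median)
  genes[order(-in_top, med_rank, seq_along(genes))][seq_len(n_top)]
}
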