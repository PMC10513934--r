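#' Two-sided Welch's t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom.
#' Variances are floored at 1e-12 (flagged as degenerate when the floor
#' engages) so that constant groups yield a defined statistic rather than
#' NaN.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @return list: \code{t}, \code{df}, \code{p} (two-sided),
#'   \code{degenerate}.
#' @export
welchT <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  va <- stats::var(a)
  vb <- stats::var(b)
  degenerate <- va < 1e-12 || vb < 1e-12
  va <- max(va, 1e-12)
  vb <- max(vb, 1e-12)
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1L) +
                 (vb / length(b))^2 / (length(b) - 1L))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       degenerate = degenerate)
}

# vectorized Welch over genes given group summaries
.welchVec <- function(m1, v1, n1, m2, v2, n2) {
  v1 <- pmax(v1, 1e-12)
  v2 <- pmax(v2, 1e-12)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone, capped at 1), via
#' \code{stats::p.adjust}.
#'
#' @param pvals numeric vector of p-values in [0, 1]; NaN is an error.
#' @return adjusted p-values, same order as input.
#' @export
bhFdr <- function(pvals) {
  if (any(is.na(pvals))) stop("NA/NaN p-values", call. = FALSE)
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0,1]",
                                       call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

# scanpy-convention log2 fold change between mean log1p expressions
.lfcFromLogMeans <- function(m1, m2)
  log2((expm1(m1) + 1e-9) / (expm1(m2) + 1e-9))

#' Signed minimal log fold change across comparisons
#'
#' Reporting convention for marker tables: when the logFCs of a gene's
#' comparisons contain both negative and positive values, 0 is reported;
#' otherwise the logFC of smallest absolute value, with its sign.
#'
#' @param lfc numeric vector of per-comparison log fold changes.
#' @return a single number.
#' @export
signedMinLfc <- function(lfc) {
  if (any(lfc > 0) && any(lfc < 0)) return(0)
  lfc[which.min(abs(lfc))]
}
.signedMinLfc <- signedMinLfc

#' Cross-dataset conserved state markers
#'
#' Cell groups are state x dataset combinations; a dataset is included for
#' a state only if at least \code{min_sample_frac} of the cells of one of
#' its samples fall in that state. For every group, each gene is Welch
#' tested against every other group except those of the same state (BH
#' across genes per comparison). A gene is a marker of a state iff it is
#' significantly upregulated (FDR < \code{fdr_max}, logFC >
#' \code{min_lfc}) in ALL of the state's datasets against ALL compared
#' groups; markers are ranked by their highest minimal logFC and genes
#' whose relative expression in the cell type falls below
#' \code{rel_expr_min} are removed as likely ambient.
#'
#' @param norm_expr cells x genes matrix of log1p-normalized expression.
#' @param states state label per cell.
#' @param datasets dataset label per cell.
#' @param samples sample label per cell (for the representation rule).
#' @param rel_expr optional named vector of relative expression of each
#'   gene in the cell type under study (from [relativeExpression()]).
#' @param fdr_max FDR threshold per comparison (default 0.1).
#' @param min_lfc logFC threshold per comparison (default 0).
#' @param rel_expr_min relative-expression filter (default 0.7).
#' @param min_sample_frac dataset-representation rule (default 0.1).
#' @return data.frame (gene, state, max_fdr, signed_min_lfc, min_lfc)
#'   sorted within state by decreasing minimal logFC.
#' @export
conservedStateMarkers <- function(norm_expr, states, datasets, samples,
                                  rel_expr = NULL, fdr_max = 0.1,
                                  min_lfc = 0, rel_expr_min = 0.7,
                                  min_sample_frac = 0.1) {
  norm_expr <- as.matrix(norm_expr)
  st <- as.character(states)
  ds <- as.character(datasets)
  sm <- as.character(samples)
  genes <- colnames(norm_expr)

  # representation rule: (state, dataset) kept if any sample of the
  # dataset has >= min_sample_frac of its cells in the state
  keep_sd <- list()
  for (d in unique(ds)) for (s in unique(st)) {
    fr <- vapply(unique(sm[ds == d]), function(ss)
      mean(st[sm == ss] == s), 0)
    if (any(fr >= min_sample_frac)) keep_sd[[paste(s, d, sep = "|")]] <-
      c(state = s, dataset = d)
  }
  grp_tab <- do.call(rbind, lapply(keep_sd, function(x)
    data.frame(state = x[["state"]], dataset = x[["dataset"]])))
  if (is.null(grp_tab)) stop("no state/dataset group passes representation",
                             call. = FALSE)
  skipped <- setdiff(unique(st), grp_tab$state)
  if (length(skipped))
    warning("states without represented datasets skipped: ",
            paste(skipped, collapse = ", "))

  grp_id <- paste(st, ds, sep = "|")
  stat_of <- function(id) {
    idx <- grp_id == id
    x <- norm_expr[idx, , drop = FALSE]
    list(m = colMeans(x), v = apply(x, 2L, stats::var), n = sum(idx))
  }
  ids <- paste(grp_tab$state, grp_tab$dataset, sep = "|")
  stats_by <- lapply(stats::setNames(ids, ids), stat_of)

  out <- list()
  for (s in unique(grp_tab$state)) {
    own <- ids[grp_tab$state == s]
    others <- ids[grp_tab$state != s]
    if (length(others) == 0L) next
    pass <- matrix(TRUE, length(genes), 1L)
    fdrs <- NULL
    lfcs <- NULL
    for (g1 in own) for (g2 in others) {
      s1 <- stats_by[[g1]]
      s2 <- stats_by[[g2]]
      wt <- .welchVec(s1$m, s1$v, s1$n, s2$m, s2$v, s2$n)
      fdr <- bhFdr(wt$p)
      lfc <- .lfcFromLogMeans(s1$m, s2$m)
      pass <- pass & (fdr < fdr_max & lfc > min_lfc)
      fdrs <- cbind(fdrs, fdr)
      lfcs <- cbind(lfcs, lfc)
    }
    sel <- which(pass)
    if (length(sel) == 0L) next
    df <- data.frame(gene = genes[sel], state = s,
                     max_fdr = apply(fdrs[sel, , drop = FALSE], 1L, max),
                     signed_min_lfc = apply(lfcs[sel, , drop = FALSE], 1L,
                                            .signedMinLfc),
                     min_lfc = apply(lfcs[sel, , drop = FALSE], 1L, min),
                     stringsAsFactors = FALSE)
    out[[s]] <- df[order(-df$min_lfc), ]
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(data.frame(gene = character(0),
                                      state = character(0),
                                      max_fdr = numeric(0),
                                      signed_min_lfc = numeric(0),
                                      min_lfc = numeric(0)))
  if (!is.null(rel_expr))
    res <- res[res$gene %in% names(rel_expr)[rel_expr >= rel_expr_min], ]
  rownames(res) <- NULL
  res
}

#' Differential expression along the disease process
#'
#' NB-GLM Wald test of a linear effect of the continuous disease-process
#' covariate on raw counts, with size factors as exposure and optional
#' dataset covariates when pooling. Genes expressed in fewer than
#' \code{min_expr_frac} of the cells of both condition groups are never
#' tested. DEGs require FDR < \code{fdr_max}, |logFC| > \code{min_abs_lfc}
#' (binary log of the process coefficient) and relative expression in the
#' cell type above \code{rel_expr_min} (genes below are likely ambient);
#' degenerate fits are excluded.
#'
#' @param counts genes x cells raw counts.
#' @param process disease-process value per cell (from [processScore()]).
#' @param condition "healthy"/"diseased" per cell (expression filter).
#' @param size_factors per-cell size factors.
#' @param datasets optional dataset label per cell, used as covariate.
#' @param rel_expr optional named relative-expression vector.
#' @param min_expr_frac expression filter (default 0.05).
#' @param fdr_max DEG FDR threshold (default 0.05).
#' @param min_abs_lfc DEG |logFC| threshold (default 1).
#' @param rel_expr_min DEG relative-expression threshold (default 0.2).
#' @return data.frame per tested gene with NB-GLM columns plus
#'   \code{rel_expr_ok} and \code{deg}.
#' @export
trajectoryDge <- function(counts, process, condition, size_factors,
                          datasets = NULL, rel_expr = NULL,
                          min_expr_frac = 0.05, fdr_max = 0.05,
                          min_abs_lfc = 1, rel_expr_min = 0.2) {
  counts <- as.matrix(counts)
  h <- condition == "healthy"
  frac_h <- Matrix::rowSums(counts[, h, drop = FALSE] > 0) / max(sum(h), 1L)
  frac_d <- Matrix::rowSums(counts[, !h, drop = FALSE] > 0) /
    max(sum(!h), 1L)
  tested <- frac_h >= min_expr_frac | frac_d >= min_expr_frac
  X <- stats::model.matrix(
    if (is.null(datasets) || length(unique(datasets)) < 2L) ~process
    else ~process + factor(datasets))
  res <- nbGlmWald(counts[tested, , drop = FALSE], X,
                   size_factors = size_factors, test_coef = "process")
  ok <- if (is.null(rel_expr)) rep(TRUE, nrow(res))
        else rel_expr[res$gene] > rel_expr_min
  res$rel_expr_ok <- as.logical(ok)
  res$deg <- !res$degenerate & res$fdr < fdr_max &
    abs(res$lfc) > min_abs_lfc & res$rel_expr_ok
  res
}

#' One-versus-rest cell-type markers from metadata pseudobulks
#'
#' A joint NB-GLM with cell-type factors (plus sample-level covariates
#' such as sex when present) is fitted per gene on metadata pseudobulks;
#' each cell type is compared against every other via Wald contrasts and a
#' gene is a marker only when it passes FDR < \code{fdr_max} and logFC >
#' \code{min_lfc} against ALL other cell types. The reported
#' \code{max_fdr} is the maximum adjusted p across compared types, and the
#' logFC follows the signed-minimum convention (0 when comparisons
#' disagree in sign).
#'
#' @param pb a metadata \linkS4class{PseudobulkMatrix}; \code{clusterKeys}
#'   must contain a \code{cell_type} column and may contain \code{sex}.
#' @param fdr_max FDR threshold (default 0.05).
#' @param min_lfc logFC threshold (default 1.5).
#' @param min_total genes with fewer summed counts are not tested.
#' @param size_factors optional per-pseudobulk exposure; defaults to the
#'   pseudobulk total counts scaled to mean 1.
#' @return data.frame (gene, cell_type, max_fdr, signed_min_lfc, min_lfc).
#' @export
pairwiseCelltypeMarkers <- function(pb, fdr_max = 0.05, min_lfc = 1.5,
                                    min_total = 10, size_factors = NULL) {
  keys <- clusterKeys(pb)
  stopifnot("cell_type" %in% colnames(keys))
  counts <- t(profiles(pb))                   # genes x pseudobulks
  ct <- as.character(keys$cell_type)
  tab <- table(ct)
  usable <- names(tab)[tab >= 2L]
  if (length(usable) < 2L) stop("need >= 2 cell types with >= 2 pseudobulks",
                                call. = FALSE)
  keep_pb <- ct %in% usable
  counts <- counts[, keep_pb, drop = FALSE]
  keys <- keys[keep_pb, , drop = FALSE]
  ct <- ct[keep_pb]
  sf <- if (is.null(size_factors)) colSums(counts) else
    size_factors[keep_pb]
  sf <- sf / mean(sf)

  tested <- rowSums(counts) >= min_total
  counts <- counts[tested, , drop = FALSE]
  ctf <- factor(ct)
  fml <- if ("sex" %in% colnames(keys) && length(unique(keys$sex)) > 1L)
    ~0 + ctf + factor(keys$sex) else ~0 + ctf
  X <- stats::model.matrix(fml)

  lev <- levels(ctf)
  pairs <- expand.grid(a = seq_along(lev), b = seq_along(lev))
  pairs <- pairs[pairs$a != pairs$b, ]
  L <- matrix(0, nrow(pairs), ncol(X))
  for (r in seq_len(nrow(pairs))) {
    L[r, pairs$a[r]] <- 1
    L[r, pairs$b[r]] <- -1
  }
  cres <- nbGlmContrasts(counts, X, L, size_factors = sf)

  out <- list()
  for (t_idx in seq_along(lev)) {
    rows <- which(pairs$a == t_idx)
    fdrs <- sapply(rows, function(r) cres[[r]]$fdr)
    lfcs <- sapply(rows, function(r) cres[[r]]$lfc)
    degn <- sapply(rows, function(r) cres[[r]]$degenerate)
    fdrs <- matrix(fdrs, ncol = length(rows))
    lfcs <- matrix(lfcs, ncol = length(rows))
    degn <- matrix(degn, ncol = length(rows))
    is_marker <- rowSums(fdrs < fdr_max & lfcs > min_lfc & !degn) ==
      length(rows)
    sel <- which(is_marker)
    if (!length(sel)) next
    out[[lev[t_idx]]] <- data.frame(
      gene = cres[[1L]]$gene[sel], cell_type = lev[t_idx],
      max_fdr = apply(fdrs[sel, , drop = FALSE], 1L, max),
      signed_min_lfc = apply(lfcs[sel, , drop = FALSE], 1L, .signedMinLfc),
      min_lfc = apply(lfcs[sel, , drop = FALSE], 1L, min),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(gene = character(0),
                                      cell_type = character(0),
                                      max_fdr = numeric(0),
                                      signed_min_lfc = numeric(0),
                                      min_lfc = numeric(0))
  rownames(res) <- NULL
  res
}

#' Group DEGs by pseudobulk coexpression and score cells
#'
#' Up- and downregulated genes are separately hierarchically clustered on
#' their fine-pseudobulk profiles (correlation distance, average linkage);
#' each resulting group is scored per cell with [scoreGeneSet()] followed
#' by [minmaxWinsorized()].
#'
#' @param degs data.frame with columns \code{gene} and \code{lfc}.
#' @param pb fine \linkS4class{PseudobulkMatrix} containing the genes.
#' @param norm_expr cells x genes matrix for scoring.
#' @param cut_height_frac dendrogram cut fraction.
#' @param seed seed for control-gene draws in scoring.
#' @param ... further arguments passed to [scoreGeneSet()].
#' @return list with \code{groups} (named list of gene vectors, names
#'   "up1", "down1", ...) and \code{scores} (cells x groups matrix in
#'   [0, 1]).
#' @export
clusterDegGroups <- function(degs, pb, norm_expr, cut_height_frac = 0.5,
                             seed = 0L, ...) {
  groups <- list()
  for (dir in c("up", "down")) {
    g <- degs$gene[if (dir == "up") degs$lfc > 0 else degs$lfc < 0]
    if (length(g) == 0L) next
    if (length(g) < 2L) {
      groups[[paste0(dir, 1L)]] <- g
      next
    }
    prof <- profiles(pb)[, g, drop = FALSE]
    cm <- suppressWarnings(stats::cor(prof))
    cm[!is.finite(cm)] <- 0
    d <- stats::as.dist(1 - cm)
    grp <- if (max(d) == 0) rep(1L, length(g)) else {
      hc <- stats::hclust(d, method = "average")
      stats::cutree(hc, h = cut_height_frac * max(hc$height))
    }
    sp <- split(g, grp)
    for (i in seq_along(sp)) groups[[paste0(dir, i)]] <- unname(sp[[i]])
  }
  scores <- vapply(groups, function(g)
    minmaxWinsorized(scoreGeneSet(norm_expr, g, seed = seed, ...)),
    numeric(nrow(norm_expr)))
  if (length(groups))
    scores <- matrix(scores, nrow = nrow(norm_expr),
                     dimnames = list(rownames(norm_expr), names(groups)))
  list(groups = groups, scores = scores)
}

#' Condition-response genes conserved across datasets
#'
#' Per dataset, genes failing the expression rule (detected in fewer than
#' \code{min_expr_frac} of both condition groups) are not counted as
#' tested; selected genes pass FDR < \code{fdr_max} and logFC >
#' \code{min_lfc} in at least \code{ceiling(min_frac_datasets * n)} of the
#' datasets.
#'
#' @param per_dataset_dge list of data.frames, one per dataset, each with
#'   columns gene, fdr, lfc and optionally \code{tested} (logical; TRUE
#'   assumed when absent).
#' @param fdr_max FDR threshold per dataset (default 0.25).
#' @param min_lfc logFC threshold per dataset (default 0.5).
#' @param min_frac_datasets fraction of datasets required (default 0.5).
#' @return character vector of selected genes.
#' @export
conservedConditionGenes <- function(per_dataset_dge, fdr_max = 0.25,
                                    min_lfc = 0.5,
                                    min_frac_datasets = 0.5) {
  stopifnot(length(per_dataset_dge) >= 1L)
  need <- ceiling(min_frac_datasets * length(per_dataset_dge))
  counts <- list()
  for (df in per_dataset_dge) {
    tested <- if ("tested" %in% colnames(df)) df$tested else TRUE
    pass <- df$gene[tested & df$fdr < fdr_max & df$lfc > min_lfc]
    for (g in pass) counts[[g]] <- (counts[[g]] %||% 0L) + 1L
  }
  sort(names(counts)[unlist(counts) >= need])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mann-Whitney comparison of two score distributions
#'
#' Two-sided Mann-Whitney U test on the cell level (exact for small
#' untied samples, normal approximation with tie correction otherwise, via
#' \code{stats::wilcox.test}) with a natural-log effect between the
#' distribution medians, \eqn{\ln(\mathrm{median}_a / \mathrm{median}_b)}.
#' Non-positive medians make the log-ratio undefined; the effect is then
#' NA with \code{effect_defined = FALSE}.
#'
#' @param a,b numeric score vectors (a is conventionally the diseased
#'   group so positive effects mean higher scores in disease).
#' @return list: \code{U}, \code{p}, \code{effect_ln_median_ratio},
#'   \code{effect_defined}.
#' @export
scoreCompare <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty group", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(a, b))
  ma <- stats::median(a)
  mb <- stats::median(b)
  defined <- ma > 0 && mb > 0
  list(U = unname(wt$statistic), p = wt$p.value,
       effect_ln_median_ratio = if (defined) log(ma / mb) else NA_real_,
       effect_defined = defined)
}

#' Hypergeometric gene-set enrichment
#'
#' Each set is intersected with the background, size-filtered to
#' [\code{min_size}, \code{max_size}], tested with a one-sided
#' hypergeometric p on the overlap with the query, and BH-adjusted across
#' the retained sets.
#'
#' @param query_genes character vector (must be contained in background).
#' @param gene_sets named list of character vectors (e.g. from
#'   [readGmt()]).
#' @param background character vector of all considered genes.
#' @param fdr_max significance threshold recorded in the output.
#' @param min_size,max_size set-size filter after background
#'   intersection.
#' @return data.frame (set, set_size, overlap, p, fdr, significant),
#'   sorted by p.
#' @export
hypergeomEnrichment <- function(query_genes, gene_sets, background,
                                fdr_max = 0.25, min_size = 5L,
                                max_size = 500L) {
  if (length(background) == 0L) stop("empty background", call. = FALSE)
  stopifnot(all(query_genes %in% background))
  sets <- lapply(gene_sets, intersect, background)
  keep <- lengths(sets) >= min_size & lengths(sets) <= max_size
  sets <- sets[keep]
  if (length(sets) == 0L)
    return(data.frame(set = character(0), set_size = integer(0),
                      overlap = integer(0), p = numeric(0), fdr = numeric(0),
                      significant = logical(0)))
  N <- length(unique(background))
  q <- length(query_genes)
  ov <- vapply(sets, function(s) length(intersect(s, query_genes)), 0L)
  p <- vapply(seq_along(sets), function(i)
    stats::phyper(ov[i] - 1L, lengths(sets)[i], N - lengths(sets)[i], q,
                  lower.tail = FALSE), 0)
  out <- data.frame(set = names(sets), set_size = lengths(sets),
                    overlap = ov, p = p, fdr = bhFdr(p),
                    stringsAsFactors = FALSE)
  out$significant <- out$fdr < fdr_max
  out[order(out$p), ]
}

#' Test whether markers translate across datasets
#'
#' Per dataset, a one-sided Welch t-test (greater in the target group) is
#' run for each marker; a marker "translates" iff it is significant at
#' \code{alpha} in every dataset where the target group is present.
#' Datasets lacking the group are skipped and noted. The log2 fold change
#' between de-logged group means is reported per dataset.
#'
#' @param expr cells x genes log1p-normalized matrix.
#' @param group_mask logical per cell, TRUE for the target group.
#' @param datasets dataset label per cell.
#' @param markers character vector of genes to test.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame (gene, n_datasets_tested, n_significant,
#'   translates, min_lfc) plus attribute "skipped_datasets".
#' @export
markerTranslationTest <- function(expr, group_mask, datasets, markers,
                                  alpha = 0.05) {
  expr <- as.matrix(expr)
  markers <- intersect(markers, colnames(expr))
  ds <- as.character(datasets)
  skipped <- character(0)
  per_ds <- list()
  for (d in unique(ds)) {
    in_d <- ds == d
    tgt <- in_d & group_mask
    rest <- in_d & !group_mask
    if (sum(tgt) < 2L || sum(rest) < 2L) {
      skipped <- c(skipped, d)
      next
    }
    x1 <- expr[tgt, markers, drop = FALSE]
    x2 <- expr[rest, markers, drop = FALSE]
    wt <- .welchVec(colMeans(x1), apply(x1, 2L, stats::var), nrow(x1),
                    colMeans(x2), apply(x2, 2L, stats::var), nrow(x2))
    per_ds[[d]] <- data.frame(
      gene = markers,
      p_greater = stats::pt(-wt$t, wt$df, lower.tail = TRUE),
      lfc = .lfcFromLogMeans(colMeans(x1), colMeans(x2)))
  }
  if (length(per_ds) == 0L) stop("target group absent from every dataset",
                                 call. = FALSE)
  sig <- sapply(per_ds, function(df) df$p_greater < alpha)
  lfc <- sapply(per_ds, function(df) df$lfc)
  sig <- matrix(sig, nrow = length(markers))
  lfc <- matrix(lfc, nrow = length(markers))
  out <- data.frame(gene = markers,
                    n_datasets_tested = ncol(sig),
                    n_significant = rowSums(sig),
                    translates = rowSums(sig) == ncol(sig),
                    min_lfc = apply(lfc, 1L, min))
  attr(out, "skipped_datasets") <- skipped
  out
}
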