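#' Pipeline configuration
#'
#' Collects every stage's parameters around one global seed. Unknown
#' parameter names are rejected so typos cannot silently fall back to
#' defaults. The configuration (plus the seed) is serialized into the
#' provenance header of every output file.
#'
#' @param ... named overrides of the defaults listed below.
#' @return a \code{PipelineConfig} list.
#' @export
pipelineConfig <- function(...) {
  defaults <- list(
    synthetic = NULL,          # syntheticConfig(); NULL = default generator
    input_dir = NULL,          # read an MTX bundle instead of simulating
    seed = 1L,
    qc = qcThresholds(),
    norm_method = "total",
    hvg_n_top = 2000L,
    embed_dims = 15L,
    knn_k = 15L,
    conservation_g = 1000L,
    embed_center_batches = TRUE,
    ambient_small_target = 20L,
    ambient_large_target = 100L,
    ambient_cluster_resolution = 2,
    ambient_rel_cutoff = 0.5,
    target_celltype = "beta",
    fine_resolution = 20,
    gp_top_k = 300L,
    gp_cut_height_frac = 0.5,
    gp_high_expr_cutoff = 0.40,
    state_cut_height_frac = 0.7,
    connectivity_prune = 0.1,
    diffusion_steps = 3L,
    dge_fdr = 0.05,
    dge_min_abs_lfc = 1,
    dge_rel_expr_min = 0.2,
    marker_fdr = 0.1,
    marker_rel_expr_min = 0.7,
    enrich_fdr = 0.25)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, over)
  class(cfg) <- "PipelineConfig"
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

# flat named list of scalar config values for provenance headers
.cfgFlat <- function(cfg) {
  keep <- vapply(cfg, function(v)
    is.atomic(v) && length(v) == 1L && !is.null(v), TRUE)
  cfg[keep]
}

#' Run the full atlas analysis pipeline
#'
#' Executes simulate/read, QC, normalization, ambient-gene detection,
#' embedding + Moran's I conservation, gene-program discovery, fine-state
#' definition, disease-process scoring, trajectory differential
#' expression, conserved state markers and gene-set enrichment on one
#' dataset collection, writing every numeric output as a
#' provenance-stamped TSV under \code{out_dir}. With identical config and
#' seed, the run is deterministic.
#'
#' The embedding is a PCA of the batch-aware HVGs with per-dataset
#' centring of the PC scores, a lightweight linear stand-in for a trained
#' integration that removes additive batch displacement while keeping
#' within-dataset geometry. Beta-cell analyses (programs, states, trajectory,
#' markers) run on cells annotated with the configured target cell type.
#'
#' @param config a [pipelineConfig()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a report list with the main objects and summary
#'   metrics (conservation score, state/condition purity table, DEG
#'   counts, file paths).
#' @export
runPipeline <- function(config = pipelineConfig(), out_dir = tempfile("islet")) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!is.null(config$input_dir) && !dir.exists(config$input_dir))
    stop("input_dir does not exist: ", config$input_dir, call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  prov <- .cfgFlat(config)
  paths <- list()
  emit <- function(df, name, params = list()) {
    p <- file.path(out_dir, paste0(name, ".tsv"))
    writeProvenancedTsv(df, p, params = c(.cfgFlat(config), params),
                        seed = seed)
    paths[[name]] <<- p
    p
  }

  # --- simulate / read --------------------------------------------------
  truth <- NULL
  raw <- .stage("input", {
    if (is.null(config$input_dir)) {
      sc <- config$synthetic
      if (is.null(sc)) sc <- syntheticConfig(seed = seed)
      atl <- generateAtlas(sc)
      truth <- atl$truth
      atl$sce
    } else readExpression(config$input_dir)
  })

  # --- ambient profiles (raw data, incl. empty droplets) ---------------
  ambient <- .stage("ambient", {
    cd <- SummarizedExperiment::colData(raw)
    profs <- lapply(unique(cd$sample), function(s)
      ambientProfile(SummarizedExperiment::assay(raw, "counts")[,
        cd$sample == s, drop = FALSE], sample = s))
    topAmbientGenes(profs, config$ambient_small_target,
                    config$ambient_large_target)
  })
  emit(data.frame(gene = rownames(ambient$proportions),
                  in_small_set = rownames(ambient$proportions) %in%
                    ambient$small_set,
                  ambient$proportions, check.names = FALSE),
       "ambient_genes")

  # --- qc + normalize ---------------------------------------------------
  qc <- .stage("qc", filterCells(raw, config$qc))
  emit(qc$report, "qc_report")
  sce <- .stage("normalize", normalizeLog1p(qc$sce, config$norm_method))

  # --- embedding + conservation ----------------------------------------
  hvgs <- .stage("hvg", hvgBatch(sce, config$hvg_n_top))
  center_batches <- function(scores, batch) {
    if (!config$embed_center_batches) return(scores)
    for (b in unique(batch)) {
      i <- batch == b
      scores[i, ] <- sweep(scores[i, , drop = FALSE], 2L,
                           colMeans(scores[i, , drop = FALSE]))
    }
    scores
  }
  emb <- .stage("embed", {
    x <- t(as.matrix(SummarizedExperiment::assay(sce, "logcounts")[hvgs, ]))
    sc <- stats::prcomp(x, center = TRUE, scale. = FALSE,
                        rank. = config$embed_dims)$x
    if ("dataset" %in% colnames(SummarizedExperiment::colData(sce)))
      sc <- center_batches(sc, sce$dataset)
    sc
  })
  cons <- .stage("integrate-eval",
                 conservationScore(sce, emb, g = config$conservation_g,
                                   k = config$knn_k))
  emit(data.frame(gene = names(cons$per_gene_I), I = cons$per_gene_I),
       "conservation_per_gene")
  emit(data.frame(metric = c("mean_I", "score"),
                  value = c(cons$mean_I, cons$score)), "conservation")

  # --- relative expression / non-target-type ambient genes --------------
  logc <- t(as.matrix(SummarizedExperiment::assay(sce, "logcounts")))
  graph_all <- .stage("graph", knnGraph(emb, k = config$knn_k))
  relex <- .stage("relative-expression", {
    fine_cl <- leidenPartition(graph_all,
                               resolution = config$ambient_cluster_resolution,
                               seed = seed)
    ct <- if ("cell_type" %in% colnames(SummarizedExperiment::colData(sce)))
      sce$cell_type else as.character(fine_cl)
    relativeExpression(logc, fine_cl, ct)
  })
  has_target <- config$target_celltype %in% colnames(relex)
  non_ct_amb <- .stage("ambient-nontarget",
    if (has_target)
      nonCelltypeAmbientGenes(ambient$small_set, relex,
                              config$target_celltype,
                              cutoff = config$ambient_rel_cutoff)
    else character(0))
  # relative expression of each gene in the target type; without an
  # annotation the best value across cluster groups is used
  rel_target <- if (has_target) relex[, config$target_celltype]
                else apply(relex, 1L, max)

  # --- target-celltype subset -------------------------------------------
  is_tgt <- if ("cell_type" %in% colnames(SummarizedExperiment::colData(sce)))
    sce$cell_type == config$target_celltype else rep(TRUE, ncol(sce))
  sce_b <- sce[, which(is_tgt)]
  logc_b <- logc[is_tgt, , drop = FALSE]
  emb_b <- .stage("embed-target", {
    xb <- t(as.matrix(SummarizedExperiment::assay(sce_b, "logcounts")[hvgs, ]))
    sc <- stats::prcomp(xb, center = TRUE, scale. = FALSE,
                        rank. = config$embed_dims)$x
    if ("dataset" %in% colnames(SummarizedExperiment::colData(sce_b)))
      sc <- center_batches(sc, sce_b$dataset)
    sc
  })
  graph_b <- .stage("graph-target", knnGraph(emb_b, k = config$knn_k))
  fine_b <- .stage("fine-pseudobulk", {
    part <- leidenPartition(graph_b, resolution = config$fine_resolution,
                            seed = seed)
    list(labels = part, pb = finePseudobulk(logc_b, part))
  })

  # --- gene programs ----------------------------------------------------
  gp <- .stage("programs", {
    n_expr <- colSums(logc_b > 0)
    cand <- setdiff(colnames(logc_b)[n_expr >= max(3L, 0.01 * nrow(logc_b))],
                    non_ct_amb)
    cand <- cand[apply(logc_b[, cand, drop = FALSE], 2L, stats::sd) > 0]
    I <- moransI(logc_b[, cand, drop = FALSE], graph_b)
    cm <- correctedMoransI(I, n_expr[cand],
                           high_expr_cutoff = config$gp_high_expr_cutoff,
                           n_cells = nrow(logc_b))
    sel <- cm$gene[order(-cm$corrected_I)][seq_len(
      min(config$gp_top_k, nrow(cm)))]
    progs <- clusterGenePrograms(sel, fine_b$pb,
                                 cut_height_frac = config$gp_cut_height_frac)
    list(corrected = cm, programs = progs)
  })
  emit(gp$corrected, "corrected_morans_i")
  writeGmt(lapply(gp$programs, `[[`, "genes"),
           file.path(out_dir, "gene_programs.gmt"))
  paths$gene_programs <- file.path(out_dir, "gene_programs.gmt")

  # --- GP scores and fine states ---------------------------------------
  states <- .stage("states", {
    gs <- vapply(gp$programs, function(p)
      scoreGeneSet(logc_b, p$genes, seed = seed), numeric(nrow(logc_b)))
    gs <- matrix(gs, nrow = nrow(logc_b),
                 dimnames = list(NULL, names(gp$programs)))
    pb_scores <- rowsum(gs, fine_b$labels)
    sz <- table(fine_b$labels)
    pb_scores <- pb_scores / as.numeric(sz[rownames(pb_scores)])
    st <- gpStateClustering(pb_scores, fine_b$labels,
                            cut_height_frac = config$state_cut_height_frac)
    conn <- clusterConnectivity(graph_b, st$state,
                                prune_threshold = config$connectivity_prune)
    list(gp_scores = gs, partition = st, connectivity = conn)
  })
  emit(data.frame(barcode = colnames(sce_b),
                  fine_pseudobulk = fine_b$labels,
                  fine_state = states$partition$state), "states")
  emit(as.data.frame(states$connectivity), "state_connectivity")

  # --- disease process ---------------------------------------------------
  proc <- .stage("trajectory", {
    cdb <- SummarizedExperiment::colData(sce_b)
    dens <- lapply(unique(cdb$dataset), function(d) {
      ind <- ifelse(cdb$dataset == d, as.character(cdb$condition), "other")
      dd <- conditionDensity(graph_b, ind, t_steps = config$diffusion_steps)
      dd[, c("healthy", "diseased"), drop = FALSE]
    })
    names(dens) <- unique(cdb$dataset)
    processScore(dens)
  })
  emit(data.frame(barcode = colnames(sce_b), process_healthy = proc$score),
       "process_score")

  # --- trajectory DGE ----------------------------------------------------
  dge <- .stage("dge", {
    cdb <- SummarizedExperiment::colData(sce_b)
    trajectoryDge(as.matrix(SummarizedExperiment::assay(sce_b, "counts")),
                  process = 1 - proc$score,
                  condition = as.character(cdb$condition),
                  size_factors = cdb$sizeFactor,
                  datasets = as.character(cdb$dataset),
                  rel_expr = rel_target,
                  fdr_max = config$dge_fdr,
                  min_abs_lfc = config$dge_min_abs_lfc,
                  rel_expr_min = config$dge_rel_expr_min)
  })
  emit(dge, "trajectory_dge")

  # --- conserved state markers -------------------------------------------
  markers <- .stage("markers", {
    cdb <- SummarizedExperiment::colData(sce_b)
    conservedStateMarkers(logc_b, states$partition$state, cdb$dataset,
                          cdb$sample, rel_expr = rel_target,
                          fdr_max = config$marker_fdr,
                          rel_expr_min = config$marker_rel_expr_min)
  })
  emit(markers, "state_markers")

  # --- enrichment of DEGs against the discovered programs ----------------
  enrich <- .stage("enrich", {
    degs_up <- dge$gene[dge$deg & dge$lfc > 0]
    hypergeomEnrichment(degs_up, lapply(gp$programs, `[[`, "genes"),
                        background = dge$gene, fdr_max = config$enrich_fdr)
  })
  emit(enrich, "enrichment")

  # --- summary -----------------------------------------------------------
  cdb <- SummarizedExperiment::colData(sce_b)
  purity <- vapply(split(as.character(cdb$condition),
                         states$partition$state),
                   function(x) max(table(x)) / length(x), 0)
  report <- list(
    sce = sce, truth = truth, embedding = emb, conservation = cons,
    ambient = ambient, non_target_ambient = non_ct_amb,
    relative_expression = relex, target_cells = colnames(sce_b),
    fine_pseudobulk = fine_b, programs = gp$programs,
    corrected_morans_i = gp$corrected, states = states,
    process_score = proc$score, trajectory_dge = dge, markers = markers,
    enrichment = enrich,
    state_condition_purity = purity,
    frac_states_pure = mean(purity >= 0.8),
    n_deg = sum(dge$deg), paths = paths)
  invisible(report)
}
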