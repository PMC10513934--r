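#' Configuration for the synthetic islet atlas generator
#'
#' Defines a multi-dataset, multi-sample droplet scRNA-seq experiment with
#' complete ground truth: discrete endocrine-like cell types plus a
#' beta-like continuum carrying a healthy-to-diseased gradient, planted
#' coexpression programs, planted state and type markers, per-sample
#' ambient contamination dominated by a few hormone-like driver genes,
#' empty droplets, doublets and Y-linked sex genes.
#'
#' The defaults describe the study conditions every stage is validated
#' under: 3 datasets x 2 samples x 1,000 cells (~6,000 cells), 2,000 genes,
#' 5 planted programs and 4 beta-cell states.
#'
#' @param n_datasets number of datasets (batches with their own offsets).
#' @param samples_per_dataset samples per dataset; within each dataset the
#'   first half of the samples is "healthy", the rest "diseased" (or pass
#'   \code{disease_conditions} explicitly, one label per sample).
#' @param cells_per_sample real cells per sample (before doublets).
#' @param n_genes total genes.
#' @param n_celltypes discrete cell types; the first is the beta-like type
#'   that carries the disease continuum.
#' @param n_programs planted coexpression programs (gene modules); must be
#'   <= 9 so each program gets a dedicated latent factor in d = 10.
#' @param program_size_range (min, max) genes per program.
#' @param n_state_markers marker genes planted per beta-cell state.
#' @param disease_conditions optional character vector, one of
#'   "healthy"/"diseased" per sample (length n_datasets*samples_per_dataset).
#' @param ambient_fraction fraction of each cell's counts drawn from the
#'   sample ambient profile, in [0, 1).
#' @param n_ambient_driver_genes hormone-like genes dominating the ambient
#'   profile (expressed in the alpha-like type, boosted in ambience).
#' @param batch_sd log-scale SD of per-gene dataset offsets.
#' @param doublet_rate fraction of extra barcodes that are doublets.
#' @param n_empty_droplets empty droplets per sample (< 100 counts each).
#' @param dispersion NB dispersion: scalar location of the per-gene
#'   log-normal dispersion draw, or a length-n_genes vector.
#' @param seed integer seed; fully determines the output.
#'
#' @return a \code{SyntheticConfig} list.
#' @examples
#' cfg <- syntheticConfig(n_datasets = 2, cells_per_sample = 100,
#'                        n_genes = 300, seed = 1)
#' @export
syntheticConfig <- function(n_datasets = 3L, samples_per_dataset = 2L,
                            cells_per_sample = 1000L, n_genes = 2000L,
                            n_celltypes = 4L, n_programs = 5L,
                            program_size_range = c(20L, 40L),
                            n_state_markers = 10L,
                            disease_conditions = NULL,
                            ambient_fraction = 0.1,
                            n_ambient_driver_genes = 20L,
                            batch_sd = 0.3, doublet_rate = 0.03,
                            n_empty_droplets = 300L, dispersion = 0.3,
                            seed = 1L) {
  cfg <- list(
    n_datasets = .assertCount(n_datasets, "n_datasets"),
    samples_per_dataset = .assertCount(samples_per_dataset, "samples_per_dataset"),
    cells_per_sample = .assertCount(cells_per_sample, "cells_per_sample"),
    n_genes = .assertCount(n_genes, "n_genes"),
    n_celltypes = .assertCount(n_celltypes, "n_celltypes"),
    n_programs = .assertCount(n_programs, "n_programs"),
    program_size_range = as.integer(program_size_range),
    n_state_markers = .assertCount(n_state_markers, "n_state_markers"),
    disease_conditions = disease_conditions,
    ambient_fraction = .assertProportion(ambient_fraction, "ambient_fraction",
                                         open_upper = TRUE),
    n_ambient_driver_genes = .assertCount(n_ambient_driver_genes,
                                          "n_ambient_driver_genes"),
    batch_sd = as.numeric(batch_sd),
    doublet_rate = .assertProportion(doublet_rate, "doublet_rate"),
    n_empty_droplets = .assertCount(n_empty_droplets, "n_empty_droplets", 0L),
    dispersion = dispersion,
    seed = .assertCount(seed, "seed", 0L))
  n_samples <- cfg$n_datasets * cfg$samples_per_dataset
  if (is.null(cfg$disease_conditions)) {
    per_ds <- rep(c("healthy", "diseased"),
                  c(ceiling(cfg$samples_per_dataset / 2),
                    floor(cfg$samples_per_dataset / 2)))
    cfg$disease_conditions <- rep(per_ds, cfg$n_datasets)
  }
  stopifnot(length(cfg$disease_conditions) == n_samples,
            all(cfg$disease_conditions %in% c("healthy", "diseased")))
  if (cfg$ambient_fraction + cfg$doublet_rate >= 1)
    stop("ambient_fraction + doublet_rate must be < 1", call. = FALSE)
  if (cfg$n_programs > 9L)
    stop("at most 9 programs fit the 10-dimensional latent space", call. = FALSE)
  if (length(cfg$program_size_range) != 2L ||
      cfg$program_size_range[1L] > cfg$program_size_range[2L])
    stop("program_size_range must be (min, max)", call. = FALSE)
  if (cfg$n_programs * cfg$program_size_range[2L] > cfg$n_genes)
    stop("program sizes exceed n_genes", call. = FALSE)
  class(cfg) <- "SyntheticConfig"
  cfg
}

# per-state program activity means (n_states x n_programs): the first
# min(n_states, n_programs) programs are specific to one state each,
# extra programs span two states, so no two column patterns are collinear
.stateActivity <- function(n_states, n_programs) {
  A <- matrix(0, n_states, n_programs)
  for (p in seq_len(n_programs)) {
    if (p <= n_states) {
      A[p, p] <- 2
    } else {
      s1 <- ((p - n_states - 1L) %% n_states) + 1L
      s2 <- (s1 %% n_states) + 1L
      A[c(s1, s2), p] <- 1
    }
  }
  A
}

#' Generate a synthetic multi-dataset islet atlas with ground truth
#'
#' Counts are negative-binomial draws around
#' \eqn{\mu = \ell_c \cdot \mathrm{softmax}_g(\eta_{gc})}, where the
#' log-rate \eqn{\eta} combines a gene baseline, cell-type effects, program
#' loadings on dedicated latent factors, a disease-gradient axis restricted
#' to beta-like cells of diseased samples, Y-linked sex effects, and
#' per-dataset log-normal batch offsets. Each cell's expected profile is
#' then mixed with its sample's ambient profile at rate
#' \code{ambient_fraction}; doublets are sums of two random cell count
#' vectors and empty droplets are small multinomial draws (< 100 counts)
#' from the ambient profile alone.
#'
#' Beta cells of diseased samples carry a latent \code{disease_process} in
#' (0, 1]; those with process < 0.1 remain in healthy-like states so the
#' gradient is continuous across conditions, the remainder split into two
#' diseased states at process 0.6. Healthy-sample beta cells and all
#' non-beta cells have process 0.
#'
#' @param config a [syntheticConfig()] object.
#' @return list with elements \code{sce} (a
#'   \linkS4class{SingleCellExperiment} with the \code{counts} assay and
#'   colData columns barcode, sample, dataset, condition, sex, cell_type,
#'   is_doublet, is_empty) and \code{truth} (list: cell_type, state,
#'   disease_process, program_membership, marker_genes, type_markers,
#'   ambient_genes, disease_genes, sex_genes, mito_genes, latent,
#'   is_doublet, is_empty).
#' @examples
#' atl <- generateAtlas(syntheticConfig(n_datasets = 1, cells_per_sample = 60,
#'                                      n_genes = 250, n_empty_droplets = 40,
#'                                      seed = 7))
#' table(atl$truth$cell_type[!atl$truth$is_empty])
#' @export
generateAtlas <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  G <- config$n_genes
  n_types <- config$n_celltypes
  n_prog <- config$n_programs
  n_states <- 4L
  d <- 10L

  gene_ids <- sprintf("gene%04d", seq_len(G))

  # --- gene architecture ------------------------------------------------
  used <- integer(0)
  take <- function(n) {
    pool <- setdiff(seq_len(G), used)
    if (length(pool) < n) stop("gene architecture exceeds n_genes", call. = FALSE)
    sel <- pool[seq_len(n)]
    used <<- c(used, sel)
    sel
  }
  drivers <- take(config$n_ambient_driver_genes)   # hormone-like, alpha-biased
  prog_sizes <- sample(seq(config$program_size_range[1L],
                           config$program_size_range[2L]), n_prog,
                       replace = TRUE)
  prog_genes <- lapply(prog_sizes, take)
  type_markers <- lapply(seq_len(n_types), function(t) take(10L))
  state_markers <- lapply(seq_len(n_states), function(s)
    take(config$n_state_markers))
  disease_up <- take(15L)
  disease_dn <- take(15L)
  sex_genes <- take(3L)
  mito_genes <- take(5L)
  gene_ids[sex_genes] <- c("Ddx3y", "Uty", "Eif2s3y")
  gene_ids[mito_genes] <- sprintf("mt-gene%d", seq_len(5L))

  base <- stats::rnorm(G, 0, 1)
  base[drivers] <- stats::rnorm(length(drivers), 2.5, 0.3)  # uniformly abundant hormones
  base[mito_genes] <- base[mito_genes] + 2

  # per-type additive log effects (genes x types); type 1 = beta-like,
  # type 2 = alpha-like carrying the hormone drivers
  M_type <- matrix(stats::rnorm(G * n_types, 0, 0.2), G, n_types)
  for (t in seq_len(n_types)) M_type[type_markers[[t]], t] <-
    M_type[type_markers[[t]], t] + 3
  if (n_types >= 2L) {
    M_type[drivers, 2L] <- M_type[drivers, 2L] + 4
    M_type[drivers, -2L] <- M_type[drivers, -2L] - 2
  }

  # program loadings (genes x programs), positive within the module
  P_load <- matrix(0, G, n_prog)
  for (p in seq_len(n_prog)) P_load[prog_genes[[p]], p] <-
    stats::runif(length(prog_genes[[p]]), 0.8, 1.2)

  M_state <- matrix(0, G, n_states)
  for (s in seq_len(n_states)) M_state[state_markers[[s]], s] <- 2

  dis_load <- numeric(G)
  dis_load[disease_up] <- 1
  dis_load[disease_dn] <- -1

  batch <- matrix(stats::rnorm(G * config$n_datasets, 0, config$batch_sd),
                  G, config$n_datasets)

  phi <- if (length(config$dispersion) == G) pmax(config$dispersion, 1e-8)
         else pmax(stats::rlnorm(G, log(config$dispersion), 0.5), 1e-8)

  A_state <- .stateActivity(n_states, n_prog)
  type_labels <- c("beta", "alpha", "delta", "gamma",
                   sprintf("type%d", seq_len(max(0L, n_types - 4L))))[seq_len(n_types)]
  type_prob <- c(0.4, rep(0.6 / (n_types - 1L), n_types - 1L))
  if (n_types == 1L) type_prob <- 1

  n_samples <- config$n_datasets * config$samples_per_dataset
  sample_ids <- sprintf("ds%d_s%d",
                        rep(seq_len(config$n_datasets),
                            each = config$samples_per_dataset),
                        rep(seq_len(config$samples_per_dataset),
                            config$n_datasets))
  sample_ds <- rep(seq_len(config$n_datasets),
                   each = config$samples_per_dataset)
  sample_cond <- config$disease_conditions
  sample_sex <- rep_len(c("male", "female"), n_samples)

  counts_list <- vector("list", n_samples)
  cd_list <- vector("list", n_samples)
  truth_list <- vector("list", n_samples)

  for (si in seq_len(n_samples)) {
    nc <- config$cells_per_sample
    ds <- sample_ds[si]
    diseased <- sample_cond[si] == "diseased"

    type <- sample.int(n_types, nc, replace = TRUE, prob = type_prob)
    dp <- numeric(nc)
    state <- integer(nc)                       # 0 = non-beta
    is_beta <- type == 1L
    if (diseased) {
      dp[is_beta] <- stats::runif(sum(is_beta), 1e-3, 1)
      state[is_beta] <- ifelse(dp[is_beta] < 0.1,
                               1L + (dp[is_beta] > 0.05),
                               ifelse(dp[is_beta] < 0.6, 3L, 4L))
    } else {
      state[is_beta] <- sample(1:2, sum(is_beta), replace = TRUE)
    }
    dp[!is_beta] <- 0

    act <- matrix(stats::rnorm(nc * n_prog, 0, 0.5), nc, n_prog)
    act[is_beta, ] <- act[is_beta, ] + A_state[state[is_beta], , drop = FALSE]

    eta <- base + M_type[, type, drop = FALSE] +
      P_load %*% t(act) + outer(dis_load, dp) + batch[, ds]
    beta_cells <- which(is_beta)
    if (length(beta_cells))
      eta[, beta_cells] <- eta[, beta_cells] +
        M_state[, state[beta_cells], drop = FALSE]
    if (sample_sex[si] == "female") eta[sex_genes, ] <- -30

    # softmax per cell
    eta <- sweep(eta, 2L, apply(eta, 2L, max))
    pm <- exp(eta)
    pm <- sweep(pm, 2L, colSums(pm), "/")

    amb <- rowMeans(pm)
    amb[drivers] <- amb[drivers] * 25
    amb <- amb / sum(amb)

    lib <- pmax(stats::rlnorm(nc, log(5000), 0.25), 1000)
    af <- config$ambient_fraction
    mu <- sweep((1 - af) * pm + af * amb, 2L, lib, "*")
    cnt <- matrix(stats::rnbinom(G * nc, mu = mu, size = 1 / phi), G, nc)

    n_dbl <- round(config$doublet_rate * nc)
    if (n_dbl > 0) {
      i1 <- sample.int(nc, n_dbl, replace = TRUE)
      i2 <- sample.int(nc, n_dbl, replace = TRUE)
      cnt <- cbind(cnt, cnt[, i1, drop = FALSE] + cnt[, i2, drop = FALSE])
    } else i1 <- integer(0)

    n_emp <- config$n_empty_droplets
    if (n_emp > 0) {
      tot <- pmin(stats::rpois(n_emp, 30), 99L)
      emp <- vapply(tot, function(tt)
        as.integer(stats::rmultinom(1L, tt, amb)), integer(G))
      cnt <- cbind(cnt, emp)
    }

    nb <- ncol(cnt)
    bc <- sprintf("%s_bc%05d", sample_ids[si], seq_len(nb))
    is_dbl <- c(rep(FALSE, nc), rep(TRUE, n_dbl), rep(FALSE, n_emp))
    is_emp <- c(rep(FALSE, nc + n_dbl), rep(TRUE, n_emp))
    ctype <- c(type_labels[type],
               if (n_dbl) type_labels[type[i1]],
               rep(NA_character_, n_emp))
    cstate <- c(ifelse(state > 0L, sprintf("state%d", state), NA),
                rep(NA_character_, n_dbl + n_emp))
    cdp <- c(dp, if (n_dbl) dp[i1], rep(NA_real_, n_emp))

    lat <- matrix(0, nb, d)
    lat[seq_len(nc), seq_len(n_prog)] <- act
    lat[seq_len(nc), n_prog + 1L] <- 3 * dp
    lat[seq_len(nc), n_prog + 2L] <- 3 * (type %% 4L)
    counts_list[[si]] <- cnt
    cd_list[[si]] <- data.frame(
      barcode = bc, sample = sample_ids[si],
      dataset = sprintf("dataset%d", ds), condition = sample_cond[si],
      sex = sample_sex[si], cell_type = ctype,
      is_doublet = is_dbl, is_empty = is_emp,
      stringsAsFactors = FALSE)
    truth_list[[si]] <- list(state = cstate, dp = cdp, latent = lat)
  }

  counts <- do.call(cbind, counts_list)
  cd <- do.call(rbind, cd_list)
  rownames(counts) <- gene_ids
  colnames(counts) <- cd$barcode

  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
    colData = S4Vectors::DataFrame(cd, row.names = cd$barcode))

  prog_membership <- stats::setNames(
    rep(sprintf("GP%d", seq_len(n_prog)), lengths(prog_genes)),
    gene_ids[unlist(prog_genes)])

  truth <- list(
    cell_type = cd$cell_type,
    state = unlist(lapply(truth_list, `[[`, "state")),
    disease_process = unlist(lapply(truth_list, `[[`, "dp")),
    program_membership = prog_membership,
    program_genes = stats::setNames(lapply(prog_genes, function(i) gene_ids[i]),
                                    sprintf("GP%d", seq_len(n_prog))),
    marker_genes = stats::setNames(lapply(state_markers, function(i) gene_ids[i]),
                                   sprintf("state%d", seq_len(n_states))),
    type_markers = stats::setNames(lapply(type_markers, function(i) gene_ids[i]),
                                   type_labels),
    ambient_genes = gene_ids[drivers],
    disease_genes = stats::setNames(c(rep(1, length(disease_up)),
                                      rep(-1, length(disease_dn))),
                                    gene_ids[c(disease_up, disease_dn)]),
    sex_genes = gene_ids[sex_genes],
    mito_genes = gene_ids[mito_genes],
    latent = do.call(rbind, lapply(truth_list, `[[`, "latent")),
    is_doublet = cd$is_doublet,
    is_empty = cd$is_empty)
  rownames(truth$latent) <- cd$barcode
  list(sce = sce, truth = truth)
}

#' Write a synthetic atlas as a CellRanger-style MTX bundle
#'
#' One sub-directory per sample containing \code{matrix.mtx} (genes as
#' rows), \code{features.tsv} and \code{barcodes.tsv}, plus a top-level
#' \code{metadata.tsv} (barcode, sample, dataset, condition, sex) and
#' \code{truth.json}. A round-trip through [readExpression()] reproduces
#' the sparse matrices exactly.
#'
#' @param atlas list as returned by [generateAtlas()] (elements sce, truth).
#' @param dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return invisibly, the directory.
#' @export
writeSynthetic <- function(atlas, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
    stop("directory ", dir, " is not empty; set overwrite = TRUE",
         call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sce <- atlas$sce
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  counts <- SummarizedExperiment::assay(sce, "counts")
  for (s in unique(cd$sample)) {
    sub <- file.path(dir, s)
    dir.create(sub, showWarnings = FALSE)
    idx <- which(cd$sample == s)
    Matrix::writeMM(methods::as(counts[, idx, drop = FALSE], "generalMatrix"),
                    file.path(sub, "matrix.mtx"))
    utils::write.table(
      data.frame(id = rownames(counts), name = rownames(counts),
                 type = "Gene Expression"),
      file.path(sub, "features.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    writeLines(cd$barcode[idx], file.path(sub, "barcodes.tsv"))
  }
  utils::write.table(cd[, c("barcode", "sample", "dataset", "condition", "sex")],
                     file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- atlas$truth
  truth$latent <- NULL                       # large; kept in memory only
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
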