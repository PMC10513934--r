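# shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

# small atlas for fast module-level checks
smallAtlas <- function() {
  if (is.null(.fixtures$small)) {
    atl <- generateAtlas(syntheticConfig(
      n_datasets = 2, samples_per_dataset = 2, cells_per_sample = 150,
      n_genes = 400, n_empty_droplets = 80, seed = 42))
    f <- filterCells(atl$sce, qcThresholds())
    sce <- normalizeLog1p(f$sce)
    .fixtures$small <- list(raw = atl$sce, truth = atl$truth, sce = sce)
  }
  .fixtures$small
}

# study-scale atlas (3 datasets x 2 samples x 1000 cells, 2000 genes)
fixtureAtlas <- function() {
  if (is.null(.fixtures$atlas)) {
    atl <- generateAtlas(syntheticConfig(seed = 101))
    f <- filterCells(atl$sce, qcThresholds())
    sce <- normalizeLog1p(f$sce)
    .fixtures$atlas <- list(raw = atl$sce, truth = atl$truth, sce = sce)
  }
  .fixtures$atlas
}

# full default pipeline run on the study-scale atlas
fixturePipeline <- function() {
  if (is.null(.fixtures$pipe)) {
    .fixtures$pipe <- runPipeline(pipelineConfig(seed = 101),
                                  out_dir = file.path(tempdir(),
                                                      "pipe_fixture"))
  }
  .fixtures$pipe
}

adjustedRandIndex <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# dense double-loop Moran's I oracle
moransIOracle <- function(x, W) {
  n <- length(x)
  xb <- mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * (x[i] - xb) * (x[j] - xb)
  (n / sum(W)) * num / sum((x - xb)^2)
}

# path graph as a NeighborGraph
pathGraph <- function(n) {
  i <- seq_len(n - 1L)
  w <- Matrix::sparseMatrix(i = c(i, i + 1L), j = c(i + 1L, i), x = 1,
                            dims = c(n, n))
  methods::new("NeighborGraph",
               weights = methods::as(w, "CsparseMatrix"),
               k = 1L, metric = "euclidean")
}

# graph from a dense symmetric zero-diagonal adjacency matrix
graphFromAdjacency <- function(W) {
  methods::new("NeighborGraph",
               weights = methods::as(methods::as(Matrix::Matrix(W,
                 sparse = TRUE), "CsparseMatrix"), "generalMatrix"),
               k = 1L, metric = "euclidean")
}

# brute-force BH step-up oracle
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- numeric(n)
  prev <- 1
  for (k in seq_len(n)) {
    i <- o[k]
    rank_i <- n - k + 1L
    val <- min(prev, p[i] * n / rank_i)
    adj[k] <- val
    prev <- val
  }
  pmin(adj[ro], 1)
}
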