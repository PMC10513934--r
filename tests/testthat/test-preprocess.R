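mkSce <- function(counts, sample = NULL) {
  cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  if (!is.null(sample)) cd$sample <- sample
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
    colData = cd)
}

test_that("filterCells applies each QC rule", {
  counts <- matrix(1L, 10, 5,
                   dimnames = list(c(sprintf("mt-g%d", 1:2),
                                     sprintf("g%d", 1:8)),
                                   sprintf("c%d", 1:5)))
  counts[1:2, ] <- 0L                        # no mito baseline
  counts[1, 2] <- 10L                        # c2: 10 mito of 18 total
  counts[6:10, 3] <- 0L                      # c3 expresses 3 genes
  sce <- mkSce(counts)
  # mito fraction 10/18 > 0.5 removes cell 2 only
  f <- filterCells(sce, qcThresholds(min_genes = 0, min_counts = 0,
                                     max_mito_frac = 0.5))
  expect_false("c2" %in% colnames(f$sce))
  expect_identical(ncol(f$sce), 4L)
  # vacuous thresholds remove nothing
  f2 <- filterCells(sce, qcThresholds(min_genes = 0, min_counts = 0,
                                      max_counts = Inf, max_mito_frac = 1))
  expect_identical(ncol(f2$sce), 5L)
  # min_genes = 5 drops the 2-gene cell, 4 remain
  f3 <- filterCells(sce, qcThresholds(min_genes = 5, min_counts = 0,
                                      max_mito_frac = 1))
  expect_identical(ncol(f3$sce), 4L)
  expect_true("kept" %in% f3$report$rule)
  # removing everything is an error with diagnostics
  expect_error(filterCells(sce, qcThresholds(min_counts = 1e9)),
               "all cells removed")
})

test_that("normalization centres size factors and equalizes totals", {
  counts <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(2, 4, 6))
  rownames(counts) <- sprintf("g%d", 1:3)
  sce <- normalizeLog1p(mkSce(counts))
  expect_equal(sce$sizeFactor[1], sce$sizeFactor[2])
  # identical cells after centring within the single implicit sample
  expect_equal(unname(sce$sizeFactor), c(0.75, 0.75, 1.5))
  # count 0 -> normalized log value 0
  logc <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
  counts2 <- cbind(a = c(0, 5), b = c(3, 3))
  rownames(counts2) <- c("g1", "g2")
  l2 <- as.matrix(SummarizedExperiment::assay(
    normalizeLog1p(mkSce(counts2)), "logcounts"))
  expect_identical(l2["g1", "a"], 0)
  # after division all totals in a sample are equal
  norm_tot <- colSums(expm1(logc))
  expect_equal(unname(norm_tot[1]), unname(norm_tot[3]))
})

test_that("zero-count cells are rejected by normalization", {
  counts <- cbind(a = c(1, 2), b = c(0, 0))
  rownames(counts) <- c("g1", "g2")
  expect_error(normalizeLog1p(mkSce(counts)), "zero-count")
})

test_that("normalization commutes with cell permutation", {
  fx <- smallAtlas()
  sce <- fx$sce
  raw <- fx$raw[, colnames(sce)]
  perm <- sample(ncol(raw))
  n1 <- normalizeLog1p(raw)
  n2 <- normalizeLog1p(raw[, perm])
  expect_equal(
    as.matrix(SummarizedExperiment::assay(n1, "logcounts"))[, perm],
    as.matrix(SummarizedExperiment::assay(n2, "logcounts")))
})

test_that("median-of-ratios size factors track depth", {
  counts <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
  rownames(counts) <- sprintf("g%d", 1:3)
  sce <- normalizeLog1p(mkSce(counts), method = "median_ratio")
  expect_equal(unname(sce$sizeFactor), c(2 / 3, 4 / 3))
})

test_that("hvgBatch ranks structure above constants, deterministically", {
  set.seed(3)
  n <- 120
  counts <- matrix(rpois(n * 50, 5), 50, n,
                   dimnames = list(sprintf("g%02d", 1:50),
                                   sprintf("c%03d", 1:n)))
  counts[1, ] <- 5L                                  # constant gene
  counts[2, ] <- ifelse(seq_len(n) %% 2 == 0, 40L, 0L)  # bimodal gene
  sce <- normalizeLog1p(mkSce(counts, sample = rep(c("s1", "s2"),
                                                   each = n / 2)))
  h <- hvgBatch(sce, n_top = 10)
  expect_length(h, 10L)
  expect_true("g02" %in% h)
  expect_false("g01" %in% h)
  expect_identical(h, hvgBatch(sce, n_top = 10))
  # single batch degenerates to per-batch ranking
  sce1 <- normalizeLog1p(mkSce(counts))
  expect_length(hvgBatch(sce1, n_top = 10), 10L)
  # n_top beyond the panel returns everything with a warning
  expect_warning(hall <- hvgBatch(sce, n_top = 100), "exceeds")
  expect_length(hall, 50L)
})

test_that("a planted bimodal gene survives selection from a null panel", {
  set.seed(11)
  n <- 300
  ngene <- 2000
  counts <- matrix(rpois(n * ngene, 3), ngene, n,
                   dimnames = list(sprintf("g%04d", seq_len(ngene)),
                                   sprintf("c%03d", seq_len(n))))
  counts[1, ] <- ifelse(runif(n) < 0.5, 30L, 0L)
  sce <- normalizeLog1p(mkSce(counts, sample = rep(c("s1", "s2"),
                                                   each = n / 2)))
  expect_true("g0001" %in% hvgBatch(sce, n_top = 400))
})
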