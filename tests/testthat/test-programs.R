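test_that("corrected Moran's I is the residual from the baseline fit", {
  # baseline genes exactly on a line: residuals are zero
  n_exp <- round(10^seq(1, 3, length.out = 100))
  I <- 0.02 + 0.1 * log10(n_exp)
  cm <- correctedMoransI(I, n_exp, high_expr_cutoff = 1e9, n_bins = 10,
                         per_bin = 10)
  expect_true(all(abs(cm$corrected_I) < 1e-10))
  # a gene above the fitted line has positive corrected I
  I2 <- c(I, 0.02 + 0.1 * log10(500) + 0.3)
  cm2 <- correctedMoransI(I2, c(n_exp, 500), high_expr_cutoff = 1e9,
                          n_bins = 10, per_bin = 10)
  expect_gt(cm2$corrected_I[101], 0.25)
  # order invariance and determinism
  perm <- sample(101)
  cm3 <- correctedMoransI(I2[perm], c(n_exp, 500)[perm],
                          high_expr_cutoff = 1e9, n_bins = 10,
                          per_bin = 10)
  expect_equal(cm3$corrected_I, cm2$corrected_I[perm], tolerance = 1e-12)
  # too few eligible genes shrinks per_bin with a warning
  expect_warning(correctedMoransI(I[1:30], n_exp[1:30],
                                  high_expr_cutoff = 1e9, n_bins = 20,
                                  per_bin = 5), "reducing per_bin")
})

test_that("gene-program clustering groups coexpressed profiles", {
  set.seed(12)
  base <- matrix(rnorm(40 * 2), 40, 2)
  prof <- cbind(base[, 1] + rnorm(40, 0, 0.05),
                base[, 1] + rnorm(40, 0, 0.05),
                base[, 1] + rnorm(40, 0, 0.05),
                base[, 2] + rnorm(40, 0, 0.05),
                base[, 2] + rnorm(40, 0, 0.05),
                base[, 2] + rnorm(40, 0, 0.05))
  colnames(prof) <- sprintf("g%d", 1:6)
  pb <- methods::new("PseudobulkMatrix", profiles = prof,
                     sizes = rep(1L, 40), kind = "fine",
                     keys = data.frame(cluster = as.character(1:40)))
  progs <- clusterGenePrograms(colnames(prof), pb, min_size = 2)
  expect_length(progs, 2L)
  members <- lapply(progs, `[[`, "genes")
  expect_true(any(vapply(members, setequal, TRUE, c("g1", "g2", "g3"))))
  # duplicated profiles always co-assign
  prof2 <- cbind(prof, g7 = prof[, 1])
  pb2 <- methods::new("PseudobulkMatrix", profiles = prof2,
                      sizes = rep(1L, 40), kind = "fine",
                      keys = data.frame(cluster = as.character(1:40)))
  progs2 <- clusterGenePrograms(colnames(prof2), pb2, min_size = 2)
  in_same <- vapply(progs2, function(p)
    all(c("g1", "g7") %in% p$genes) || !any(c("g1", "g7") %in% p$genes),
    TRUE)
  expect_true(all(in_same))
  # cutting above the max merge height yields a single program
  progs1 <- clusterGenePrograms(colnames(prof), pb, cut_height_frac = 1.01,
                                min_size = 2)
  expect_length(progs1, 1L)
  expect_length(progs1[[1]]$genes, 6L)
})

test_that("gene-set scores subtract bin-matched controls", {
  # set genes constant c, control candidates constant d in the same bin
  n <- 30
  x <- cbind(s1 = rep(5, n), s2 = rep(5, n),
             c1 = rep(2, n), c2 = rep(2, n))
  sc <- scoreGeneSet(x, c("s1", "s2"), n_ctrl_bins = 1, seed = 1)
  expect_equal(sc, rep(3, n))
  # same seed reproduces, different seed may differ
  set.seed(13)
  xx <- matrix(rnorm(50 * 40, 5, 1), 50, 40,
               dimnames = list(NULL, sprintf("g%02d", 1:40)))
  s1 <- scoreGeneSet(xx, c("g01", "g05"), seed = 3)
  expect_identical(s1, scoreGeneSet(xx, c("g01", "g05"), seed = 3))
  # on exchangeable null data the mean score is near zero
  set.seed(14)
  null <- matrix(rnorm(200 * 100, 0, 1), 200, 100,
                 dimnames = list(NULL, sprintf("g%03d", 1:100)))
  sc0 <- scoreGeneSet(null, sprintf("g%03d", 1:10), seed = 5)
  se <- sd(sc0) / sqrt(length(sc0))
  expect_lt(abs(mean(sc0)), 3 * se + 0.05)
  expect_error(scoreGeneSet(xx, "absent"), "no overlap")
})

test_that("winsorized min-max scaling follows the trimmed range", {
  sc <- minmaxWinsorized(0:99, n_trim = 20)
  expect_equal(sc[21], 0)          # raw 20 -> 0
  expect_equal(sc[80], 1)          # raw 79 -> 1
  expect_equal(sc[1], 0)           # raw 0 clipped to 0
  expect_equal(minmaxWinsorized(c(0:99, 49.5), n_trim = 20)[101], 0.5)
  # monotone within the scaling range
  expect_true(all(diff(sc[22:79]) > 0))
  expect_equal(minmaxWinsorized(rep(4, 50)), rep(0.5, 50))
  expect_warning(small <- minmaxWinsorized(1:10, n_trim = 20), "min-max")
  expect_equal(range(small), c(0, 1))
})

# sparse count-based sample with an optional shared and private program;
# background genes are lowly detected so they can anchor the correction
# baseline (detection below the 30% rule)
mkVarSample <- function(shared_on, private_on, seed, n = 250) {
  set.seed(seed)
  u <- seq(0, 10, length.out = n)
  emb <- cbind(u, rnorm(n, 0, 0.1))
  expr <- sapply(1:60, function(j) {
    lam <- if (j <= 6 && shared_on) 2 * exp(sin(u))
    else if (j >= 7 && j <= 12 && private_on) 2 * exp(cos(u))
    else 0.25
    log1p(rpois(n, lam))
  })
  colnames(expr) <- sprintf("g%02d", 1:60)
  list(expr = expr, embedding = emb)
}

test_that("conserved variable gene groups demand support in all samples", {
  samples <- list(mkVarSample(TRUE, TRUE, 1), mkVarSample(TRUE, FALSE, 2),
                  mkVarSample(TRUE, FALSE, 3))
  grp <- suppressWarnings(conservedVariableGeneGroups(
    samples, corrected_I_min = 0.1, fine_resolution = 5, min_size = 3))
  all_genes <- unlist(grp)
  # the program shared by every sample comes back as one group
  expect_true(any(vapply(grp, function(g)
    all(sprintf("g%02d", 1:6) %in% g), TRUE)))
  # the program present in only one of three samples is excluded
  expect_false(any(sprintf("g%02d", 7:12) %in% all_genes))
})

test_that("identical samples reduce to single-sample grouping", {
  s <- mkVarSample(TRUE, FALSE, 15, n = 200)
  grp <- suppressWarnings(conservedVariableGeneGroups(
    list(s, s), corrected_I_min = 0.1, fine_resolution = 5, min_size = 3))
  expect_true(any(vapply(grp, function(g)
    all(sprintf("g%02d", 1:6) %in% g), TRUE)))
})

test_that("explained variance is exact for a PC1 score and bounded", {
  set.seed(16)
  expr <- matrix(rnorm(150 * 40), 150, 40,
                 dimnames = list(NULL, sprintf("g%02d", 1:40)))
  pca <- stats::prcomp(expr, rank. = 10)
  ev <- explainedVariance(expr, pca$x[, 1, drop = FALSE], n_pcs = 10)
  expect_equal(ev$total_ev, pca$sdev[1]^2 / sum(pca$sdev^2),
               tolerance = 1e-8)
  expect_true(ev$total_ev >= 0 && ev$total_ev <= sum(ev$var_ratio))
  # collinear scores are flagged
  expect_warning(explainedVariance(expr, cbind(pca$x[, 1], pca$x[, 1]),
                                   n_pcs = 5), "collinear")
})
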