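test_that("Welch test matches its closed form and symmetries", {
  r <- welchT(c(1, 2, 3), c(3, 4, 5))
  expect_equal(r$t, -2.449, tolerance = 1e-3)
  expect_equal(r$df, 4.0, tolerance = 1e-3)
  # identical groups: t = 0, p = 1
  ri <- welchT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ri$t, 0)
  expect_equal(ri$p, 1)
  # swapping groups negates t, keeps p
  rs <- welchT(c(3, 4, 5), c(1, 2, 3))
  expect_equal(rs$t, -r$t)
  expect_equal(rs$p, r$p)
  # agrees with stats::t.test where defined
  set.seed(30)
  a <- rnorm(12); b <- rnorm(15, 0.5)
  tt <- stats::t.test(a, b)
  rw <- welchT(a, b)
  expect_equal(rw$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(rw$p, tt$p.value, tolerance = 1e-10)
  expect_error(welchT(1, c(1, 2)), "at least 2")
})

test_that("Welch p-values are uniform under the null", {
  set.seed(31)
  p <- replicate(5000, welchT(rnorm(10), rnorm(10))$p)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("BH adjustment matches hand-derived cases", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(0.2), 0.2)
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  expect_error(bhFdr(c(0.1, NA)), "NA")
  expect_error(bhFdr(c(0.1, 1.2)), "lie in")
})

test_that("signed minimal logFC reports 0 on sign conflicts", {
  expect_identical(signedMinLfc(c(0.5, -0.2)), 0)
  expect_identical(signedMinLfc(c(0.5, 0.2, 1.4)), 0.2)
  expect_identical(signedMinLfc(c(-0.5, -0.2)), -0.2)
})

test_that("conserved state markers demand support in every dataset", {
  set.seed(32)
  n_per <- 40
  mk_block <- function(state, ds, up1, up2) {
    x <- matrix(rnorm(n_per * 4, 1, 0.3), n_per, 4)
    if (up1) x[, 1] <- x[, 1] + 2
    if (up2) x[, 2] <- x[, 2] + 2
    x
  }
  blocks <- list(
    mk_block("s1", "d1", TRUE, TRUE), mk_block("s1", "d2", TRUE, FALSE),
    mk_block("s2", "d1", FALSE, FALSE), mk_block("s2", "d2", FALSE, FALSE))
  expr <- do.call(rbind, blocks)
  colnames(expr) <- c("conserved", "d1only", "flat1", "flat2")
  st <- rep(c("s1", "s1", "s2", "s2"), each = n_per)
  ds <- rep(c("d1", "d2", "d1", "d2"), each = n_per)
  sm <- paste0(st, "_", ds)
  mk <- conservedStateMarkers(expr, st, ds, sm)
  s1 <- mk$gene[mk$state == "s1"]
  expect_true("conserved" %in% s1)
  # up in dataset 1 only: excluded by the all-datasets rule
  expect_false("d1only" %in% s1)
  # relative-expression filter removes low-relative genes
  rel <- c(conserved = 0.1, d1only = 0.9, flat1 = 0.9, flat2 = 0.9)
  mk2 <- conservedStateMarkers(expr, st, ds, sm, rel_expr = rel)
  expect_false("conserved" %in% mk2$gene)
})

test_that("planted state markers are recovered across three datasets", {
  fx <- fixtureAtlas()
  sce <- fx$sce
  truth <- fx$truth
  st <- truth$state[match(colnames(sce), rownames(truth$latent))]
  isb <- sce$cell_type == "beta"
  logc <- t(as.matrix(
    SummarizedExperiment::assay(sce, "logcounts")[, isb]))
  mk <- conservedStateMarkers(logc, st[isb], sce$dataset[isb],
                              sce$sample[isb])
  planted <- unlist(truth$marker_genes)
  state_specific <- c(planted, unlist(truth$program_genes[1:4]),
                      names(truth$disease_genes))
  expect_gte(mean(planted %in% mk$gene), 0.8)            # recall
  expect_gte(mean(mk$gene %in% state_specific), 0.8)     # precision
})

test_that("pairwise cell-type markers require wins against all types", {
  set.seed(33)
  types <- rep(c("alpha", "beta", "delta"), each = 6)
  samples <- rep(sprintf("s%d", 1:6), 3)
  base <- exp(rnorm(18, log(200), 0.1))
  bg <- t(sapply(1:50, function(i)
    rnbinom(18, mu = base * exp(rnorm(1, 0, 0.2)), size = 20)))
  rownames(bg) <- sprintf("bg%02d", 1:50)
  counts <- rbind(
    betaOnly = rnbinom(18, mu = base * ifelse(types == "beta", 20, 1),
                       size = 20),
    twoTypes = rnbinom(18, mu = base * ifelse(types %in% c("alpha", "beta"),
                                              20, 1), size = 20),
    flat = rnbinom(18, mu = base, size = 20),
    bg)
  pb <- methods::new("PseudobulkMatrix", profiles = t(counts),
                     sizes = rep(1L, 18), kind = "metadata",
                     keys = data.frame(cell_type = types, sample = samples))
  mk <- pairwiseCelltypeMarkers(pb, size_factors = base)
  expect_identical(mk$gene[mk$cell_type == "beta"], "betaOnly")
  # a gene high in two types is a marker of neither
  expect_false("twoTypes" %in% mk$gene)
  expect_true(all(mk$max_fdr < 0.05))
})

test_that("DEG groups split by direction and score into [0, 1]", {
  set.seed(34)
  n_pb <- 30
  prof <- cbind(u1 = sin(1:n_pb) + rnorm(n_pb, 0, 0.05),
                u2 = sin(1:n_pb) + rnorm(n_pb, 0, 0.05),
                u3 = cos(1:n_pb) + rnorm(n_pb, 0, 0.05),
                u4 = cos(1:n_pb) + rnorm(n_pb, 0, 0.05),
                d1 = seq(1, 2, length.out = n_pb))
  pb <- methods::new("PseudobulkMatrix", profiles = prof,
                     sizes = rep(1L, n_pb), kind = "fine",
                     keys = data.frame(cluster = as.character(1:n_pb)))
  degs <- data.frame(gene = colnames(prof), lfc = c(2, 2, 1.5, 1.5, -2))
  expr <- matrix(rnorm(100 * 5, 2), 100, 5,
                 dimnames = list(NULL, colnames(prof)))
  expr <- cbind(expr, matrix(rnorm(100 * 20, 2), 100, 20,
                             dimnames = list(NULL, sprintf("bg%02d", 1:20))))
  res <- clusterDegGroups(degs, pb, expr, cut_height_frac = 0.5, seed = 1,
                          n_ctrl_bins = 5)
  up_groups <- res$groups[startsWith(names(res$groups), "up")]
  expect_length(up_groups, 2L)
  expect_true(any(vapply(up_groups, setequal, TRUE, c("u1", "u2"))))
  expect_identical(res$groups$down1, "d1")
  expect_true(all(res$scores >= 0 & res$scores <= 1))
})

test_that("conserved condition genes follow the at-least-half rule", {
  dge <- function(...) data.frame(...)
  per <- list(
    dge(gene = c("a", "b", "c"), fdr = c(0.01, 0.01, 0.01),
        lfc = c(1, 1, 1), tested = c(TRUE, TRUE, FALSE)),
    dge(gene = c("a", "b", "c"), fdr = c(0.01, 0.5, 0.5),
        lfc = c(1, 1, 1), tested = TRUE),
    dge(gene = c("a", "b", "c"), fdr = c(0.5, 0.5, 0.5),
        lfc = c(1, 1, 1), tested = TRUE),
    dge(gene = c("a", "b", "c"), fdr = c(0.5, 0.5, 0.01),
        lfc = c(1, 1, 1), tested = TRUE))
  res <- conservedConditionGenes(per)
  expect_true("a" %in% res)       # passes in 2 of 4
  expect_false("b" %in% res)      # passes in 1 of 4
  # gene c passes in datasets 1 (untested there) and 4 -> counts once
  expect_false("c" %in% res)
})

test_that("Mann-Whitney comparison is exact for small untied samples", {
  r <- scoreCompare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$U), 0)
  expect_equal(r$p, 0.1)
  expect_equal(scoreCompare(c(2, 2, 2, 2), c(1, 1, 1, 1))$effect_ln_median_ratio,
               log(2))
  same <- scoreCompare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1)
  neg <- scoreCompare(c(-3, -1, 0), c(1, 2, 3))
  expect_false(neg$effect_defined)
  expect_error(scoreCompare(numeric(0), 1), "empty")
})

test_that("hypergeometric enrichment matches combinatorial counts", {
  bg <- sprintf("g%02d", 1:20)
  sets <- list(hit = bg[1:5], big = sprintf("x%03d", 1:600),
               small = bg[1:3])
  res <- hypergeomEnrichment(bg[1:5], sets, bg, min_size = 5,
                             max_size = 500)
  expect_identical(res$set, "hit")           # size filters drop the others
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  # zero overlap cannot be enriched
  res0 <- hypergeomEnrichment(bg[6:10], list(hit = bg[1:5]), bg)
  expect_equal(res0$p, 1)
  expect_error(hypergeomEnrichment("g01", list(a = "g01"), character(0)),
               "empty background")
})

test_that("marker translation needs significance in every dataset", {
  set.seed(35)
  n <- 40
  expr1 <- cbind(both = c(rnorm(n, 3), rnorm(n, 1)),
                 oneds = c(rnorm(n, 3), rnorm(n, 1)))
  expr2 <- cbind(both = c(rnorm(n, 3), rnorm(n, 1)),
                 oneds = c(rnorm(n, 2), rnorm(n, 2)))
  expr <- rbind(expr1, expr2)
  grp <- rep(c(TRUE, FALSE, TRUE, FALSE), each = n)
  ds <- rep(c("d1", "d2"), each = 2 * n)
  res <- markerTranslationTest(expr, grp, ds, c("both", "oneds"))
  expect_true(res$translates[res$gene == "both"])
  expect_false(res$translates[res$gene == "oneds"])
  expect_identical(res$n_datasets_tested, rep(2L, 2))
})
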