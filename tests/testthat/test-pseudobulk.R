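test_that("Leiden partitions are seeded and respect components", {
  w <- matrix(0, 8, 8)
  w[1:4, 1:4] <- 1; w[5:8, 5:8] <- 1; diag(w) <- 0
  g <- graphFromAdjacency(w)
  l1 <- leidenPartition(g, resolution = 1, seed = 3)
  l2 <- leidenPartition(g, resolution = 1, seed = 3)
  expect_identical(l1, l2)
  # disconnected cliques never merge
  expect_identical(length(unique(l1[1:4])), 1L)
  expect_identical(length(unique(l1[5:8])), 1L)
  expect_false(l1[1] == l1[5])
})

test_that("Leiden refines well-separated blobs purely", {
  set.seed(8)
  emb <- rbind(matrix(rnorm(100, 0, 0.2), 50),
               matrix(rnorm(100, 10, 0.2), 50))
  g <- knnGraph(emb, 10)
  part <- leidenPartition(g, resolution = 1, seed = 1)
  blob <- rep(1:2, each = 50)
  purity <- vapply(split(blob, part), function(x)
    max(table(x)) / length(x), 0)
  expect_true(all(purity == 1))
})

test_that("fine pseudobulks are means that reconstruct the global mean", {
  set.seed(9)
  x <- matrix(rnorm(200), 20, 10,
              dimnames = list(NULL, sprintf("g%d", 1:10)))
  lab <- sample(c("a", "b", "c"), 20, replace = TRUE)
  pb <- finePseudobulk(x, lab)
  expect_s4_class(pb, "PseudobulkMatrix")
  expect_equal(
    colSums(profiles(pb) * clusterSizes(pb)) / sum(clusterSizes(pb)),
    colMeans(x), tolerance = 1e-12)
  # cluster of identical cells reproduces the cell
  xx <- rbind(x, x[1, ], x[1, ])
  pbi <- finePseudobulk(xx, c(lab, "dup", "dup"))
  expect_equal(unname(profiles(pbi)["dup", ]), unname(x[1, ]))
  # singleton cluster equals the cell exactly
  pbs <- finePseudobulk(x, c("s", rep("rest", 19)))
  expect_equal(unname(profiles(pbs)["s", ]), unname(x[1, ]))
})

test_that("metadata pseudobulks sum counts without transformation", {
  counts <- rbind(c(1, 2, 0), c(0, 1, 1), c(5, 0, 2))
  colnames(counts) <- sprintf("g%d", 1:3)
  keys <- data.frame(grp = c("a", "a", "b"))
  pb <- metadataPseudobulk(counts, keys)
  expect_equal(unname(profiles(pb)[1, ]), c(1, 3, 1))
  expect_equal(sum(profiles(pb)), sum(counts), tolerance = 1e-12)
  # one group per cell is the identity
  pbi <- metadataPseudobulk(counts, data.frame(grp = c("x", "y", "z")))
  expect_equal(unname(profiles(pbi)), unname(counts))
})

test_that("state clustering inherits labels and honours explicit cuts", {
  gp <- rbind(a = c(0, 0), b = c(0, 0.001), c = c(5, 5), d = c(5, 5.001))
  colnames(gp) <- c("GP1", "GP2")
  cells <- c("a", "a", "b", "c", "d", "d")
  st <- gpStateClustering(gp, cells, k = 2)
  expect_length(st$state, 6L)
  # duplicated-feature pseudobulks co-cluster
  expect_identical(st$pseudobulk_state[["a"]], st$pseudobulk_state[["b"]])
  expect_identical(st$pseudobulk_state[["c"]], st$pseudobulk_state[["d"]])
  expect_false(st$pseudobulk_state[["a"]] == st$pseudobulk_state[["c"]])
  # cut at height 0: one state per distinct pseudobulk
  st0 <- gpStateClustering(gp, cells, k = NULL, h = 0)
  expect_identical(length(unique(st0$pseudobulk_state)), 4L)
  # single pseudobulk collapses to one state
  st1 <- gpStateClustering(gp[1, , drop = FALSE], rep("a", 3))
  expect_identical(unique(st1$state), 1L)
})

test_that("connectivity is symmetric, pruned monotonically, null-scaled", {
  w <- matrix(0, 9, 9)
  w[1:3, 1:3] <- 1; w[4:6, 4:6] <- 1; w[7:9, 7:9] <- 1
  w[3, 4] <- w[4, 3] <- 1                     # one bridge between s1, s2
  diag(w) <- 0
  g <- graphFromAdjacency(w)
  st <- rep(c("s1", "s2", "s3"), each = 3)
  conn <- clusterConnectivity(g, st, prune_threshold = 0)
  expect_equal(conn, t(conn))
  expect_true(all(diag(conn) == 0))
  # s3 is a separate component: zero connectivity to both
  expect_equal(conn["s3", "s1"], 0)
  expect_equal(conn["s3", "s2"], 0)
  expect_gt(conn["s1", "s2"], 0)
  # raising the prune threshold never adds edges
  conn_hi <- clusterConnectivity(g, st, prune_threshold = 0.9)
  expect_true(all((conn_hi > 0) <= (conn > 0)))
  expect_error(clusterConnectivity(g, factor(st, levels = c(unique(st),
                                                            "ghost"))),
               "no cells")
})

test_that("label transfer votes with kernel weights and abstains", {
  # all neighbours share a label: certainty
  ref <- rbind(matrix(rnorm(20, 0, 0.1), 10), matrix(rnorm(20, 8, 0.1), 10))
  lab <- rep(c("x", "y"), each = 10)
  res <- labelTransfer(ref, lab, rbind(c(0, 0), c(8, 8)), k = 5)
  expect_identical(res$label, c("x", "y"))
  expect_equal(res$uncertainty, c(0, 0))
  # uniform votes over 5 labels: uncertainty 0.8 -> unassigned
  theta <- 2 * pi * (0:4) / 5
  ref5 <- cbind(cos(theta), sin(theta))
  res5 <- labelTransfer(ref5, letters[1:5], rbind(c(0, 0)), k = 5)
  expect_equal(res5$uncertainty, 0.8, tolerance = 1e-9)
  expect_identical(res5$label, "unassigned")
  expect_error(labelTransfer(ref5, letters[1:5], rbind(c(0, 0)), k = 9),
               "exceeds")
})

test_that("centroid queries recover their cluster label", {
  set.seed(10)
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6))
  ref <- do.call(rbind, lapply(1:3, function(i)
    sweep(matrix(rnorm(60, 0, 0.4), 30), 2, centers[i, ], "+")))
  lab <- rep(c("a", "b", "c"), each = 30)
  res <- labelTransfer(ref, lab, centers, k = 15)
  expect_identical(res$label, c("a", "b", "c"))
})
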