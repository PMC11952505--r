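test_that("graph_cluster separates well-separated blobs deterministically", {
  set.seed(1)
  emb <- rbind(matrix(rnorm(80 * 3), 80, 3),
               matrix(rnorm(80 * 3, mean = 20), 80, 3))
  truth <- rep(1:2, each = 80)
  cl <- graph_cluster(emb, k = 15, resolution = 0.5, seed = 1)
  # the two blobs never share a cluster
  expect_equal(length(intersect(unique(cl[truth == 1]), unique(cl[truth == 2]))), 0)
  expect_identical(cl, graph_cluster(emb, k = 15, resolution = 0.5, seed = 1))
  expect_error(graph_cluster(emb, k = 0), "positive")
  expect_error(graph_cluster(emb, k = 160), "smaller")
})

test_that("higher resolution never yields fewer clusters on a fixed graph", {
  set.seed(2)
  emb <- matrix(rnorm(200 * 4), 200, 4)
  ks <- vapply(c(0.1, 0.5, 1, 2),
               function(r) length(unique(graph_cluster(emb, k = 15,
                                                       resolution = r, seed = 1))),
               numeric(1))
  expect_true(all(diff(ks) >= 0))
})

test_that("marker_compartments assigns planted compartments", {
  set.seed(3)
  n <- 90
  genes <- c(unlist(compartment_markers(), use.names = FALSE),
             sprintf("g%02d", 1:20))
  m <- matrix(rpois(n * length(genes), 3), n, length(genes),
              dimnames = list(sprintf("c%03d", 1:n), genes))
  comp <- rep(c("epithelial", "immune", "stromal"), each = 30)
  for (cp in unique(comp)) {
    m[comp == cp, compartment_markers()[[cp]]] <-
      m[comp == cp, compartment_markers()[[cp]]] + 30
  }
  b <- toy_bundle(m)
  clusters <- rep(1:3, each = 30)
  res <- marker_compartments(b, clusters)
  expect_identical(res$clusters$compartment, c("epithelial", "immune", "stromal"))
  expect_identical(res$cell_compartment, comp)
  expect_false(any(res$clusters$tie))

  # a panel with no measured genes warns; all-absent panels abort
  panels <- c(compartment_markers(), list(ghost = "NOPE1"))
  expect_warning(marker_compartments(b, clusters, panels), "ghost")
  expect_error(marker_compartments(b, clusters, list(x = "NOPE1")), "no panel gene")
})

test_that("consensus_relabel votes, tie-breaks and is idempotent", {
  votes <- tibble::tibble(
    cell_id = c("c1", "c2", "c3", "c4"),
    s1 = c("T", "B", NA, "Mac"),
    s2 = c("T", "Mac", "B", "T"),
    s3 = c("B", "Mac", "B", "B"),
    cluster_compartment = c(NA, NA, NA, "T"))
  res <- consensus_relabel(votes, c("s1", "s2", "s3"))
  # c1: T wins 2-1; c2: Mac wins 2-1; c3: B (newly annotated);
  # c4: three-way tie, broken by cluster compartment
  expect_identical(res$labels$final, c("T", "Mac", "B", "T"))
  expect_equal(res$n_newly_annotated, 1)
  expect_equal(res$n_relabeled, 2)  # c2 and c4 differ from s1

  # idempotence: final labels fed back as the sole source change nothing
  again <- consensus_relabel(
    tibble::tibble(cell_id = votes$cell_id, s1 = res$labels$final), "s1")
  expect_identical(again$labels$final, res$labels$final)
  expect_equal(again$n_relabeled, 0)

  # unresolved tie falls back to lexicographic order
  tie <- consensus_relabel(tibble::tibble(cell_id = "c1", a = "Z", b = "A"),
                           c("a", "b"))
  expect_identical(tie$labels$final, "A")
})

test_that("donor_entropy_filter matches its closed form", {
  clusters <- c(rep("k1", 10), rep("k2", 10))
  donors <- c(rep("d1", 7), rep("d2", 2), rep("d3", 1),  # H = 0.8018 nats
              rep("dX", 10))                              # single donor
  res <- donor_entropy_filter(clusters, donors, threshold = 0.3)
  h <- -(0.7 * log(0.7) + 0.2 * log(0.2) + 0.1 * log(0.1))
  expect_equal(res$entropy[res$cluster == "k1"], h / log(3), tolerance = 1e-10)
  expect_equal(res$entropy[res$cluster == "k1"], 0.7298, tolerance = 1e-4)
  expect_false(res$donor_specific[res$cluster == "k1"])
  expect_equal(res$entropy[res$cluster == "k2"], 0)
  expect_true(res$donor_specific[res$cluster == "k2"])
  expect_equal(res$n_donors, c(3L, 1L))
})

test_that("stratified_markers matches wilcox.test in the single-batch case", {
  set.seed(4)
  n <- 60
  m <- matrix(rpois(n * 10, 5), n, 10,
              dimnames = list(NULL, sprintf("g%02d", 1:10)))
  m[1:30, 3] <- m[1:30, 3] + rpois(30, 6)
  b <- toy_bundle(m)
  clusters <- rep(c(1, 2), each = 30)
  res <- stratified_markers(b, clusters)

  norm <- as.matrix(lognormalize(b))
  wt <- wilcox.test(norm[1:30, 3], norm[31:60, 3], exact = FALSE,
                    correct = FALSE)
  got <- res[res$cluster == 1 & res$gene == "g03", ]
  expect_equal(unname(got$p), wt$p.value, tolerance = 1e-10)
  expect_gt(got$z, 0)
  expect_equal(got$gene, res$gene[res$cluster == 1][1])  # top-ranked marker
})

test_that("stratified_markers ignores purely batch-driven shifts", {
  set.seed(5)
  n <- 120
  m <- matrix(rpois(n * 8, 5), n, 8,
              dimnames = list(NULL, sprintf("g%02d", 1:8)))
  batch <- rep(c("b1", "b2"), each = 60)
  m[batch == "b2", 5] <- m[batch == "b2", 5] + 20  # batch-confounded gene
  clusters <- rep(rep(c(1, 2), each = 30), 2)      # clusters balanced in batch
  b <- toy_bundle(m, batch = batch)
  res <- stratified_markers(b, clusters)
  expect_gt(min(res$p[res$gene == "g05"]), 0.01)

  expect_error(stratified_markers(b, rep(1, n)), ">= 2 clusters")
  expect_warning(stratified_markers(b, c(rep(1, n - 1), 2), min_cells = 5),
                 "skipped")
})

test_that("nearest_centroid_label is rank-based and flags degenerate queries", {
  set.seed(6)
  panel <- matrix(rnorm(3 * 40), 3, 40,
                  dimnames = list(c("LumA", "Basal", "Her2"),
                                  sprintf("g%02d", 1:40)))
  q <- panel["Basal", ] + rnorm(40, sd = 0.2)
  res <- nearest_centroid_label(q, panel)
  expect_equal(unname(res$label), "Basal")
  # monotone-transform invariance (Spearman)
  res2 <- nearest_centroid_label(exp(q), panel)
  expect_equal(res2$correlation, res$correlation)
  expect_equal(unname(res2$label), "Basal")

  flat <- setNames(rep(1, 40), colnames(panel))
  expect_equal(unname(nearest_centroid_label(flat, panel)$label), "unassigned")
  expect_error(nearest_centroid_label(q[1:3], panel), "shared genes")
})
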