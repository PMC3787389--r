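test_that("descriptor-mode features are presence/absence of first selections", {
  traces <- list(OrA = descriptor_multiset(sprintf("d%02d", 1:20)),
                 OrB = descriptor_multiset(sprintf("d%02d", 1:20)),
                 OrC = descriptor_multiset(sprintf("d%02d", 11:30)),
                 OrD = descriptor_multiset(sprintf("d%02d", 31:50)))
  m <- receptor_feature_matrix("descriptor", traces = traces)
  expect_identical(m["OrA", ], m["OrB", ])
  # 10 of 20 descriptors shared: 20 differing coordinates
  expect_equal(sum((m["OrA", ] - m["OrC", ])^2), 20)
  # disjoint selections: 40 differing coordinates
  expect_equal(sum((m["OrA", ] - m["OrD", ])^2), 40)

  # duplicates collapse to presence; short traces warn
  short <- list(OrE = descriptor_multiset(c("d01", "d01", "d02")))
  expect_warning(ms <- receptor_feature_matrix("descriptor", traces = short),
                 "only 3")
  expect_equal(sum(ms), 2)
})

test_that("overlap-mode features are pairwise top-list overlap percentages", {
  preds <- list(OrA = sprintf("L%03d", 1:50),
                OrB = sprintf("L%03d", 26:75),
                OrC = sprintf("L%03d", 101:150))
  m <- receptor_feature_matrix("overlap", predictions = preds)
  expect_equal(diag(m), c(OrA = 100, OrB = 100, OrC = 100))
  expect_equal(m["OrA", "OrB"], 50)
  expect_equal(m["OrA", "OrC"], 0)
  expect_equal(m, t(m))
})

test_that("receptor clustering follows complete linkage", {
  # planted pairwise distances {AB:1, AC:10, BC:~10}: A,B merge first and
  # C joins at the maximum pairwise distance (complete linkage)
  f <- rbind(A = c(0, 0), B = c(1, 0), C = c(5.5, sqrt(100 - 5.5^2)))
  colnames(f) <- c("f1", "f2")
  d <- as.matrix(dist(f))
  expect_equal(d["A", "B"], 1, tolerance = 1e-9)
  expect_equal(d["A", "C"], 10, tolerance = 1e-9)

  tree <- cluster_receptors(f, mode = "activity")
  hc <- tree$hclust
  expect_equal(hc$height[1], 1, tolerance = 1e-9)
  expect_equal(hc$height[2], max(d["A", "C"], d["B", "C"]), tolerance = 1e-9)

  # two receptors: a single merge at their Euclidean distance
  t2 <- cluster_receptors(f[1:2, ])
  expect_equal(t2$hclust$height, 1, tolerance = 1e-9)

  # duplicate rows merge at height zero
  t3 <- cluster_receptors(rbind(A = c(1, 2), B = c(1, 2), C = c(9, 9)))
  expect_equal(min(t3$hclust$height), 0)

  expect_error(cluster_receptors(f[1, , drop = FALSE]), "at least 2")
})

test_that("tree topology is invariant to receptor input order", {
  set.seed(81)
  f <- matrix(rnorm(24), 6, 4,
              dimnames = list(sprintf("Or%d", 1:6), sprintf("f%d", 1:4)))
  t1 <- cluster_receptors(f)
  t2 <- cluster_receptors(f[sample(6), ])
  expect_equal(t1$hclust$height, t2$hclust$height)
  expect_identical(t1$hclust$labels, t2$hclust$labels)
  f2 <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(t1, f2)
  phy <- ape::read.tree(f2)
  expect_setequal(phy$tip.label, rownames(f))
})

test_that("interaction networks merge known and predicted evidence", {
  empty <- build_network()
  expect_equal(igraph::ecount(empty$graph), 0)

  known <- matrix(c(80, 50, 10), ncol = 1,
                  dimnames = list(c("c1", "c2", "c3"), "OrA"))
  net <- build_network(known, list(OrA = c("c1", "c2", "c3")))
  e <- igraph::as_data_frame(net$graph)
  expect_equal(nrow(e), 3)
  # response of exactly 50 spikes/s is not a known interaction
  expect_identical(sort(e$evidence), c("known", "predicted", "predicted"))
  expect_identical(e$evidence[e$to == "c1" | e$from == "c1"], "known")

  # edge count = known + predicted-not-already-known
  net2 <- build_network(known, list(OrA = c("c1", "c4")))
  expect_equal(igraph::ecount(net2$graph), 2)

  clash <- matrix(100, 1, 1, dimnames = list("OrA", "OrA"))
  expect_error(build_network(clash, list(OrA = "c9")), "overlap")
})

test_that("networks export to SIF and GraphML", {
  known <- matrix(c(80, 10), ncol = 1, dimnames = list(c("c1", "c2"), "OrA"))
  net <- build_network(known, list(OrA = "c2"))
  sif <- withr::local_tempfile(fileext = ".sif")
  write_network_sif(net, sif)
  lines <- sort(readLines(sif))
  expect_identical(lines, c("OrA\tknown\tc1", "OrA\tpredicted\tc2"))

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), 2)
  expect_setequal(igraph::E(g)$evidence, c("known", "predicted"))
})
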