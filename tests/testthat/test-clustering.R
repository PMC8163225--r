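test_that("complete linkage follows the manual agglomeration of a 2x2 block design", {
  D <- matrix(10, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                        c("A", "B", "C", "D")))
  diag(D) <- 0
  D["A", "B"] <- D["B", "A"] <- 1
  D["C", "D"] <- D["D", "C"] <- 1
  tree <- complete_linkage(D)
  expect_equal(sort(tree$height), c(1, 1, 10))
  a <- cut_tree(tree, 2)
  expect_equal(assignment_partition(a),
               canon_partition(list(c("A", "B"), c("C", "D"))))
  # stable numbering: cluster 1 holds the smallest id
  expect_equal(unname(a["A"]), 1L)
})

test_that("degenerate trees behave at the boundaries", {
  D2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- complete_linkage(D2)
  expect_equal(t2$height, 3)
  # duplicate points merge at height zero
  D3 <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(min(complete_linkage(D3)$height), 0)
  # malformed inputs
  Dneg <- D2; Dneg[1, 2] <- -1
  expect_error(complete_linkage(Dneg), "negative|symmetric")
  Dasym <- D2; Dasym[1, 2] <- 4
  expect_error(complete_linkage(Dasym), "symmetric")
})

test_that("complete linkage matches a step-by-step max-linkage oracle", {
  set.seed(41)
  for (draw in 1:15) {
    n <- sample(4:7, 1)
    pts <- matrix(runif(n * 2) * 10, n)
    D <- as.matrix(dist(pts))
    dimnames(D) <- list(letters[1:n], letters[1:n])
    tree <- complete_linkage(D)
    oracle <- brute_complete_linkage(D)
    expect_equal(sort(tree$height), sort(oracle$heights), tolerance = 1e-10)
    for (k in seq_len(n - 1)) {
      got <- assignment_partition(cut_tree(tree, n - k))
      want <- canon_partition(oracle$partitions[[k]])
      expect_equal(got, want)
    }
  }
})

test_that("cutting at k refines the cut at k-1", {
  set.seed(17)
  D <- as.matrix(dist(matrix(runif(20), 10)))
  dimnames(D) <- list(letters[1:10], letters[1:10])
  tree <- complete_linkage(D)
  expect_equal(unique(cut_tree(tree, 1)), 1L)
  expect_equal(sort(unname(cut_tree(tree, 10))), 1:10)
  for (k in 2:10) {
    fine <- cut_tree(tree, k)
    coarse <- cut_tree(tree, k - 1)
    for (cl in unique(fine)) {
      members <- names(fine)[fine == cl]
      expect_length(unique(coarse[members]), 1L)
    }
  }
  expect_error(cut_tree(tree, 0), "between 1")
  expect_error(cut_tree(tree, 11), "between 1")
})

test_that("module reports summarize members, pathways and cohesion", {
  out <- generate_toy_network(toy_network_design(), seed = 11)
  g <- carbon_filter(suppressWarnings(remove_side_compounds(out$graph)))
  dm <- path_distance_matrix(g, names(out$labels))
  tree <- complete_linkage(dm)
  a <- cut_tree(tree, 5)
  rep5 <- module_report(a, dm, graph = g, tree = tree)
  expect_equal(nrow(rep5$modules), 5L)
  expect_equal(sum(rep5$modules$size), length(out$labels))
  # planted modules recovered
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(a[names(out$labels)], out$labels)
  expect_gte(ari, 0.8)
  # each recovered module is dominated by a single planted pathway
  expect_true(all(!grepl(";", rep5$modules$dominant_pathways)))

  # singleton module has mean within-distance 0 by convention
  single <- cut_tree(tree, length(out$labels))
  rep1 <- module_report(single, dm)
  expect_true(all(rep1$modules$mean_within_distance == 0))
})

test_that("structurally identical modules get identical summaries", {
  # two planted 3-chains, mutually disconnected
  g <- compound_graph(
    data.frame(id = c("a1", "a2", "a3", "b1", "b2", "b3"),
               pathways = rep(c("PA", "PB"), each = 3)),
    data.frame(from = c("a1", "a2", "b1", "b2"),
               to = c("a2", "a3", "b2", "b3"), carbon = TRUE))
  dm <- path_distance_matrix(g, g$nodes$id)
  tree <- complete_linkage(dm)
  a <- cut_tree(tree, 2)
  rep2 <- module_report(a, dm, graph = g, tree = tree)
  expect_equal(rep2$modules$size, c(3L, 3L))
  expect_equal(rep2$modules$mean_within_distance[1],
               rep2$modules$mean_within_distance[2])
})

test_that("modules spanning disconnected pairs trigger a warning", {
  g <- compound_graph(data.frame(id = c("A", "B", "C", "D")),
                      data.frame(from = "A", to = "B", carbon = TRUE))
  dm <- path_distance_matrix(g, c("A", "B", "C", "D"))
  tree <- complete_linkage(dm)
  expect_warning(module_report(cut_tree(tree, 1), dm), "sentinel")
})

test_that("the silhouette profile covers the requested range with valid widths", {
  skip_if_not_installed("cluster")
  out <- generate_toy_network(toy_network_design(), seed = 11)
  g <- carbon_filter(suppressWarnings(remove_side_compounds(out$graph)))
  dm <- path_distance_matrix(g, names(out$labels))
  tree <- complete_linkage(dm)
  prof <- silhouette_profile(tree, dm, 2:8)
  expect_equal(prof$k, 2:8)
  expect_true(all(is.finite(prof$mean_silhouette)))
  expect_true(all(abs(prof$mean_silhouette) <= 1))
  # the planted five-module structure is well separated
  expect_gt(prof$mean_silhouette[prof$k == 5], 0.25)
})
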