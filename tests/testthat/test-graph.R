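test_that("graph construction merges parallel edges and rejects dangling ones", {
  g <- compound_graph(
    data.frame(id = c("A", "B", "C")),
    data.frame(from = c("A", "B", "B", "A"), to = c("B", "C", "C", "A"),
               reaction = c("R1", "R2", "R3", "R4"),
               carbon = c(TRUE, FALSE, TRUE, TRUE)))
  expect_equal(nrow(g$nodes), 3L)
  expect_equal(nrow(g$edges), 2L)          # B-C merged, A-A self-loop dropped
  bc <- g$edges[g$edges$from == "B", ]
  expect_true(bc$carbon)                   # OR over merged reactions
  expect_equal(bc$reaction, "R2;R3")
  expect_error(
    compound_graph(data.frame(id = "A"),
                   data.frame(from = "A", to = "Z", carbon = TRUE)),
    "unknown node")
})

test_that("node and edge tables round-trip through delimited files", {
  dir <- withr::local_tempdir()
  g <- chain_graph(c("A", "B", "C"))
  write_compound_graph(g, file.path(dir, "nodes.tsv"),
                       file.path(dir, "edges.tsv"))
  back <- read_compound_graph(file.path(dir, "nodes.tsv"),
                              file.path(dir, "edges.tsv"))
  expect_equal(back$nodes$id, g$nodes$id)
  expect_equal(back$edges[c("from", "to", "carbon")],
               g$edges[c("from", "to", "carbon")])
})

test_that("compartment collapse merges copies and deletes transport loops", {
  g <- compound_graph(
    data.frame(id = c("atp_c", "atp_m"), pathways = c("P1", "P2")),
    data.frame(from = "atp_c", to = "atp_m", carbon = FALSE))
  cg <- collapse_compartments(g)
  expect_equal(cg$nodes$id, "atp")
  expect_equal(nrow(cg$edges), 0L)
  expect_setequal(strsplit(cg$nodes$pathways, ";")[[1]], c("P1", "P2"))

  # duplicated reactions across compartments collapse into one edge
  g2 <- compound_graph(
    data.frame(id = c("glc_c", "g6p_c", "glc_m", "g6p_m")),
    data.frame(from = c("glc_c", "glc_m"), to = c("g6p_c", "g6p_m"),
               carbon = TRUE))
  cg2 <- collapse_compartments(g2)
  expect_setequal(cg2$nodes$id, c("glc", "g6p"))
  expect_equal(nrow(cg2$edges), 1L)

  # no suffixes: identity
  g3 <- chain_graph(c("alpha", "beta"))
  expect_equal(collapse_compartments(g3)$nodes$id, g3$nodes$id)
  expect_error(collapse_compartments(
    compound_graph(data.frame(id = "_c"), NULL)), "whole id")
})

test_that("side-compound removal deletes nodes with their incident edges", {
  star <- compound_graph(
    data.frame(id = c("hub", paste0("m", 1:10))),
    data.frame(from = "hub", to = paste0("m", 1:10), carbon = TRUE))
  out <- remove_side_compounds(star, "hub")
  expect_equal(nrow(out$nodes), 10L)
  expect_equal(nrow(out$edges), 0L)
  expect_equal(remove_side_compounds(star, character(0))$edges, star$edges)
  expect_warning(remove_side_compounds(star, c("hub", "ghost")), "ghost")
})

test_that("the carbon filter deletes exactly the non-transfer edges", {
  ids <- c("A", "B", "C", "D")
  g <- compound_graph(
    data.frame(id = ids),
    data.frame(from = c("A", "B", "C"), to = c("B", "C", "D"),
               carbon = c(TRUE, FALSE, TRUE)))
  out <- carbon_filter(g)
  expect_equal(nrow(out$edges), 2L)
  expect_equal(nrow(out$nodes), 4L)        # isolated nodes retained
  all_true <- carbon_filter(chain_graph())
  expect_equal(all_true$edges, chain_graph()$edges)
  g_na <- compound_graph(data.frame(id = c("A", "B")),
                         data.frame(from = "A", to = "B"))
  expect_error(carbon_filter(g_na), "no carbon-transfer flag")
})

test_that("filtering and side-compound removal commute", {
  out <- generate_toy_network(toy_network_design(), seed = 4)
  side <- c("h2o", "co2")
  g1 <- carbon_filter(remove_side_compounds(out$graph, side))
  g2 <- remove_side_compounds(carbon_filter(out$graph), side)
  expect_equal(g1$nodes, g2$nodes)
  expect_equal(g1$edges, g2$edges)
})

test_that("lightest paths minimize the squared-degree sum with endpoints included", {
  # chain A-B-C: degrees 1,2,1 -> cost 1+4+1
  g <- chain_graph(c("A", "B", "C"))
  p <- lightest_path(g, "A", "C")
  expect_equal(p$path, c("A", "B", "C"))
  expect_equal(p$cost, 6)
  # self-distance convention
  self <- lightest_path(g, "B", "B")
  expect_equal(self$cost, 0)
  expect_equal(self$path, "B")
  # hub avoidance: A-B-C vs A-H-C with H also serving D and E
  g2 <- compound_graph(
    data.frame(id = c("A", "B", "C", "H", "D", "E")),
    data.frame(from = c("A", "A", "B", "H", "H", "H"),
               to = c("B", "H", "C", "C", "D", "E"), carbon = TRUE))
  p2 <- lightest_path(g2, "A", "C")
  expect_equal(p2$path, c("A", "B", "C"))
  expect_equal(p2$cost, 4 + 4 + 4)
  # disconnection is a result, not an exception
  g3 <- compound_graph(data.frame(id = c("A", "B")), NULL)
  p3 <- lightest_path(g3, "A", "B")
  expect_false(p3$found)
  expect_equal(p3$cost, Inf)
})

test_that("lightest paths match brute-force enumeration on random small graphs", {
  set.seed(77)
  for (draw in 1:40) {
    g <- random_small_graph()
    ids <- g$nodes$id
    src <- sample(ids, 1)
    for (to in setdiff(ids, src)) {
      got <- lightest_path(g, src, to)
      want <- brute_lightest(g, src, to)
      expect_equal(got$cost, want$cost)
      if (is.finite(want$cost)) expect_equal(got$path, want$path)
    }
  }
})

test_that("lightest-path costs agree with an independent igraph computation", {
  skip_if_not_installed("igraph")
  set.seed(99)
  for (draw in 1:10) {
    g <- random_small_graph(n = 8, p_edge = 0.5)
    if (nrow(g$edges) == 0) next
    deg <- graph_degrees(g)
    w <- as.numeric(deg)^2
    names(w) <- names(deg)
    ig <- igraph::graph_from_data_frame(g$edges[, c("from", "to")],
                                        directed = FALSE,
                                        vertices = g$nodes$id)
    # node-weighted cost as edge weights (w(u)+w(v))/2 plus endpoint halves
    ew <- (w[igraph::as_edgelist(ig)[, 1]] + w[igraph::as_edgelist(ig)[, 2]]) / 2
    D <- igraph::distances(ig, weights = ew)
    for (i in 1:3) {
      uv <- sample(g$nodes$id, 2)
      ref <- D[uv[1], uv[2]] + w[uv[1]] / 2 + w[uv[2]] / 2
      got <- lightest_path(g, uv[1], uv[2])$cost
      if (is.infinite(D[uv[1], uv[2]])) expect_equal(got, Inf)
      else expect_equal(got, unname(ref))
    }
  }
})

test_that("path costs satisfy the hub-discounted triangle bound", {
  set.seed(55)
  for (draw in 1:10) {
    g <- random_small_graph(n = 7, p_edge = 0.5)
    ids <- g$nodes$id
    w <- as.numeric(graph_degrees(g))^2
    names(w) <- ids
    for (trip in 1:5) {
      uvw <- sample(ids, 3)
      c_uv <- lightest_path(g, uvw[1], uvw[2])$cost
      c_vw <- lightest_path(g, uvw[2], uvw[3])$cost
      c_uw <- lightest_path(g, uvw[1], uvw[3])$cost
      if (is.finite(c_uv) && is.finite(c_vw))
        expect_lte(c_uw, c_uv + c_vw - w[[uvw[2]]] + 1e-9)
    }
  }
})

test_that("path degrees are those of the graph after filtering", {
  # with side compound S attached to B, the A->C route through H is lighter;
  # after removing S the tie resolves to the lexicographically smaller route
  g <- compound_graph(
    data.frame(id = c("A", "B", "C", "H", "S")),
    data.frame(from = c("A", "B", "A", "H", "S"),
               to = c("B", "C", "H", "C", "B"), carbon = TRUE))
  expect_equal(lightest_path(g, "A", "C")$path, c("A", "H", "C"))
  g2 <- remove_side_compounds(g, "S")
  expect_equal(lightest_path(g2, "A", "C")$path, c("A", "B", "C"))
})

test_that("subnetwork extraction unions pairwise lightest paths", {
  ch <- chain_graph(c("A", "B", "C", "D", "E"))
  sub <- extract_subnetwork(ch, c("A", "C", "E"))
  expect_setequal(sub$nodes$id, c("A", "B", "C", "D", "E"))
  expect_equal(nrow(sub$edges), 4L)
  expect_setequal(sub$nodes$role[sub$nodes$id %in% c("A", "C", "E")], "seed")
  expect_setequal(sub$nodes$role[sub$nodes$id %in% c("B", "D")],
                  "intermediate")
  # degenerate seed sets
  one <- extract_subnetwork(ch, "B")
  expect_equal(one$nodes$id, "B")
  two <- extract_subnetwork(ch, c("A", "B"))
  expect_equal(nrow(two$edges), 1L)
  expect_error(extract_subnetwork(ch, character(0)), "empty seed")
  # disconnected pairs are skipped, not fatal
  g <- compound_graph(data.frame(id = c("A", "B")), NULL)
  sub2 <- extract_subnetwork(g, c("A", "B"))
  expect_length(attr(sub2, "skipped_pairs"), 1L)
})

test_that("distance matrices are symmetric, zero-diagonal and oracle-exact", {
  ch <- chain_graph(c("A", "B", "C", "D", "E", "F"))
  D <- path_distance_matrix(ch, c("A", "C", "E"))
  expect_equal(unname(diag(unclass(D))), c(0, 0, 0))
  expect_true(isSymmetric(unclass(D)))
  # monotone in chain separation
  expect_lt(D["A", "C"], D["A", "E"])
  # brute-force equality on a random 6-node graph
  set.seed(12)
  g <- random_small_graph(n = 6, p_edge = 0.6)
  ids <- g$nodes$id
  D2 <- path_distance_matrix(g, ids)
  for (i in 1:5) for (j in (i + 1):6) {
    want <- brute_lightest(g, ids[i], ids[j])$cost
    if (is.finite(want)) expect_equal(unclass(D2)[i, j], want)
  }
})

test_that("disconnected pairs receive the sentinel policy", {
  g <- compound_graph(data.frame(id = c("A", "B", "C", "D")),
                      data.frame(from = "A", to = "B", carbon = TRUE))
  D <- path_distance_matrix(g, c("A", "B", "C", "D"))
  finite_max <- unclass(D)["A", "B"]
  expect_equal(unclass(D)["C", "D"], 2 * finite_max)
  expect_gt(nrow(attr(D, "disconnected_pairs")), 0)
  # fully disconnected: the configured fallback applies everywhere
  g0 <- compound_graph(data.frame(id = c("A", "B", "C")), NULL)
  D0 <- path_distance_matrix(g0, c("A", "B", "C"), fallback = 7)
  off <- unclass(D0)[upper.tri(D0)]
  expect_true(all(off == 7))
  expect_equal(nrow(attr(D0, "disconnected_pairs")), 3L)
})
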