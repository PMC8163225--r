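# Independent oracles used across the suite. These deliberately use only
# brute-force enumeration / direct recomputation, never the package's own
# search or clustering code paths.

# all simple paths between two nodes by DFS; returns the minimum
# squared-degree-sum cost (Inf if disconnected) and the best path under the
# (cost, hops, lexicographic) ordering
brute_lightest <- function(graph, from, to) {
  deg <- graph_degrees(graph)
  w <- as.numeric(deg)^2
  names(w) <- names(deg)
  adj <- list()
  for (id in graph$nodes$id) adj[[id]] <- character(0)
  if (nrow(graph$edges)) {
    for (i in seq_len(nrow(graph$edges))) {
      u <- graph$edges$from[i]; v <- graph$edges$to[i]
      adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
    }
  }
  if (from == to) return(list(cost = 0, path = from))
  best <- list(cost = Inf, path = character(0))
  recurse <- function(node, visited, cost) {
    if (node == to) {
      cand <- list(cost = cost, path = visited)
      if (cand$cost < best$cost ||
          (cand$cost == best$cost &&
           (length(cand$path) < length(best$path) ||
            (length(cand$path) == length(best$path) &&
             paste(cand$path, collapse = "\r") <
             paste(best$path, collapse = "\r")))))
        best <<- cand
      return(invisible())
    }
    for (nb in adj[[node]]) {
      if (nb %in% visited) next
      recurse(nb, c(visited, nb), cost + w[[nb]])
    }
  }
  recurse(from, from, w[[from]])
  best
}

# a random small compound graph for path-property tests
random_small_graph <- function(n = sample(3:8, 1), p_edge = 0.4) {
  ids <- LETTERS[seq_len(n)]
  pairs <- t(combn(ids, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  edges <- if (any(keep))
    data.frame(from = pairs[keep, 1], to = pairs[keep, 2], carbon = TRUE,
               stringsAsFactors = FALSE)
  else NULL
  compound_graph(data.frame(id = ids, stringsAsFactors = FALSE), edges)
}

# exhaustive right-tail hypergeometric probability: enumerate every draw of
# n elements from the universe and count overlaps >= k_obs
brute_ora_p <- function(universe, pathway_members, selected) {
  n <- length(selected)
  k_obs <- length(intersect(selected, pathway_members))
  draws <- combn(universe, n)
  hits <- apply(draws, 2, function(d)
    length(intersect(d, pathway_members)) >= k_obs)
  mean(hits)
}

# direct max-linkage agglomeration: recompute every inter-cluster maximum
# at each step; returns merge heights and the partition after each merge
brute_complete_linkage <- function(D) {
  labels <- rownames(D)
  clusters <- as.list(labels)
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq((i + 1L), length(clusters))) {
        d <- max(D[clusters[[i]], clusters[[j]]])
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    merged <- c(clusters[[i]], clusters[[j]])
    clusters <- c(clusters[-c(i, j)], list(merged))
    heights <- c(heights, best[1])
    partitions[[length(partitions) + 1L]] <- lapply(clusters, sort)
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a partition for comparison: sorted list of sorted groups
canon_partition <- function(groups) {
  groups <- unname(lapply(groups, function(g) sort(unname(g))))
  groups[order(vapply(groups, `[`, character(1), 1L))]
}

# partition induced by a named assignment vector
assignment_partition <- function(a) canon_partition(split(names(a), a))
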