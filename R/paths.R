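# adjacency list of a compound_graph: named list id -> character vector of
# neighbours (sorted, so tie-breaking is reproducible)
adjacency_list <- function(graph) {
  ids <- graph$nodes$id
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(adj)) adj[[i]] <- character(0)
  if (nrow(graph$edges)) {
    for (i in seq_len(nrow(graph$edges))) {
      u <- graph$edges$from[i]; v <- graph$edges$to[i]
      adj[[u]] <- c(adj[[u]], v)
      adj[[v]] <- c(adj[[v]], u)
    }
    adj <- lapply(adj, function(x) sort(unique(x)))
  }
  adj
}

# Dijkstra over node weights w(v) = degree(v)^2: the cost of a path is the
# sum of w over its nodes, endpoints included. Entering node v costs w(v);
# w(source) is added once at the start. Labels are (cost, hops, path);
# ties resolved by fewer hops, then the lexicographically smallest node
# sequence. Returns per-node cost and path from the source.
dijkstra_squared_degree <- function(adj, w, source) {
  ids <- names(adj)
  n <- length(ids)
  cost <- stats::setNames(rep(Inf, n), ids)
  hops <- stats::setNames(rep(Inf, n), ids)
  pkey <- stats::setNames(rep(NA_character_, n), ids)   # path as "\r"-joined key
  done <- stats::setNames(rep(FALSE, n), ids)
  cost[source] <- w[source]
  hops[source] <- 1
  pkey[source] <- source

  better <- function(c1, h1, k1, c2, h2, k2) {
    if (c1 != c2) return(c1 < c2)
    if (h1 != h2) return(h1 < h2)
    !is.na(k1) && (is.na(k2) || k1 < k2)
  }

  repeat {
    # pick the unfinished node with the smallest (cost, hops, path) label
    cand <- which(!done & is.finite(cost))
    if (length(cand) == 0L) break
    u <- names(cand)[1L]
    for (v in names(cand)[-1L]) {
      if (better(cost[v], hops[v], pkey[v], cost[u], hops[u], pkey[u])) u <- v
    }
    done[u] <- TRUE
    for (v in adj[[u]]) {
      if (done[v]) next
      nc <- cost[u] + w[v]
      nh <- hops[u] + 1
      nk <- paste(pkey[u], v, sep = "\r")
      if (better(nc, nh, nk, cost[v], hops[v], pkey[v])) {
        cost[v] <- nc; hops[v] <- nh; pkey[v] <- nk
      }
    }
  }
  list(cost = cost,
       path = lapply(pkey, function(k)
         if (is.na(k)) character(0) else strsplit(k, "\r", fixed = TRUE)[[1L]]))
}

#' Lightest path between two metabolites
#'
#' Finds the path minimizing the sum of squared node degrees over all
#' nodes of the path, endpoints included. Weighting each node by its
#' squared degree steers routes away from ubiquitous hub compounds and
#' toward biochemically informative chains, which plain shortest paths do
#' not. Degrees are those of the graph as passed in — i.e. *after* any
#' compartment collapse, side-compound removal and carbon filtering.
#' Ties are broken by fewer nodes, then by the lexicographically smallest
#' node sequence; the self-distance is 0 by convention.
#'
#' @param graph a [compound_graph()].
#' @param from,to node ids.
#' @return an object of class `"lightest_path"`: list with `path`
#'   (character vector of node ids, empty if disconnected), `cost` (sum of
#'   squared degrees, `Inf` if disconnected, 0 for `from == to`) and
#'   `found` (logical).
#' @examples
#' g <- compound_graph(data.frame(id = c("A", "B", "C")),
#'                     data.frame(from = c("A", "B"), to = c("B", "C"),
#'                                carbon = TRUE))
#' lightest_path(g, "A", "C")   # cost 1 + 4 + 1 = 6
#' @export
lightest_path <- function(graph, from, to) {
  stopifnot(inherits(graph, "compound_graph"))
  ids <- graph$nodes$id
  if (!from %in% ids) stop("unknown node id: ", from)
  if (!to %in% ids) stop("unknown node id: ", to)
  if (from == to)
    return(structure(list(path = from, cost = 0, found = TRUE),
                     class = "lightest_path"))
  w <- as.numeric(graph_degrees(graph))^2
  names(w) <- ids
  res <- dijkstra_squared_degree(adjacency_list(graph), w, from)
  if (!is.finite(res$cost[to]))
    return(structure(list(path = character(0), cost = Inf, found = FALSE),
                     class = "lightest_path"))
  structure(list(path = res$path[[to]], cost = unname(res$cost[to]),
                 found = TRUE), class = "lightest_path")
}

#' @export
print.lightest_path <- function(x, ...) {
  if (!x$found) cat("<lightest_path> disconnected\n")
  else cat(sprintf("<lightest_path> %s (cost %g)\n",
                   paste(x$path, collapse = " - "), x$cost))
  invisible(x)
}

#' Extract a subnetwork spanned by lightest paths between seeds
#'
#' Returns the union of the lightest paths over all unordered seed pairs:
#' the usual way to place a set of metabolites of interest (e.g. markers
#' of significantly over-represented pathways) into their metabolic
#' context, revealing hubs, modules and bridges. Disconnected pairs are
#' skipped and recorded. Seeds and intermediate (path-only) nodes are
#' flagged distinctly in the result's node table (`role` column).
#'
#' @param graph a [compound_graph()].
#' @param seeds character vector of node ids (non-empty, all present).
#' @return a [compound_graph()] whose edges are exactly those used by at
#'   least one returned path; skipped (disconnected) pairs are attached as
#'   the `"skipped_pairs"` attribute.
#' @export
extract_subnetwork <- function(graph, seeds) {
  stopifnot(inherits(graph, "compound_graph"))
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0L) stop("empty seed set")
  missing <- setdiff(seeds, graph$nodes$id)
  if (length(missing))
    stop("seed id(s) not in graph: ", paste(missing, collapse = ", "))

  w <- as.numeric(graph_degrees(graph))^2
  names(w) <- graph$nodes$id
  adj <- adjacency_list(graph)

  used_nodes <- seeds
  used_edges <- character(0)
  skipped <- list()
  if (length(seeds) > 1L) {
    for (i in seq_len(length(seeds) - 1L)) {
      res <- dijkstra_squared_degree(adj, w, seeds[i])
      for (j in seq((i + 1L), length(seeds))) {
        p <- res$path[[seeds[j]]]
        if (length(p) == 0L) {
          skipped[[length(skipped) + 1L]] <- c(seeds[i], seeds[j])
          next
        }
        used_nodes <- c(used_nodes, p)
        if (length(p) > 1L)
          used_edges <- c(used_edges,
                          paste(pmin(p[-length(p)], p[-1L]),
                                pmax(p[-length(p)], p[-1L]), sep = "\r"))
      }
    }
  }
  used_nodes <- unique(used_nodes)
  nodes <- graph$nodes[graph$nodes$id %in% used_nodes, , drop = FALSE]
  nodes$role <- ifelse(nodes$id %in% seeds, "seed", "intermediate")
  edges <- graph$edges
  ekey <- paste(edges$from, edges$to, sep = "\r")
  edges <- edges[ekey %in% unique(used_edges), , drop = FALSE]
  out <- compound_graph(nodes[, c("id", "name", "pathways", "side",
                                  "external_ids")], edges, graph$pathways)
  out$nodes$role <- nodes$role[match(out$nodes$id, nodes$id)]
  attr(out, "skipped_pairs") <- skipped
  out
}

#' Pairwise lightest-path distance matrix
#'
#' Square symmetric matrix of lightest-path costs over a metabolite
#' subset, intended to be computed on the carbon-filtered,
#' side-compound-free graph and handed to [complete_linkage()].
#' Disconnected pairs receive the sentinel `2 * max(finite entries)` —
#' under complete linkage this forces disconnected components to merge
#' last — and are flagged in the `"disconnected_pairs"` attribute. If no
#' pair is connected the configured `fallback` sentinel is used instead.
#'
#' @param graph a [compound_graph()].
#' @param subset character vector of at least two node ids.
#' @param fallback sentinel used when no finite off-diagonal entry exists.
#' @return an object of classes `"path_distance_matrix"` and `matrix`.
#' @export
path_distance_matrix <- function(graph, subset, fallback = 1) {
  stopifnot(inherits(graph, "compound_graph"))
  subset <- as.character(subset)
  if (length(subset) < 2L) stop("'subset' must contain at least two nodes")
  if (anyDuplicated(subset)) stop("'subset' contains duplicated ids")
  missing <- setdiff(subset, graph$nodes$id)
  if (length(missing))
    stop("subset node(s) not in graph: ", paste(missing, collapse = ", "))

  w <- as.numeric(graph_degrees(graph))^2
  names(w) <- graph$nodes$id
  adj <- adjacency_list(graph)
  n <- length(subset)
  D <- matrix(0, n, n, dimnames = list(subset, subset))
  for (i in seq_len(n - 1L)) {
    res <- dijkstra_squared_degree(adj, w, subset[i])
    for (j in seq((i + 1L), n)) {
      D[i, j] <- D[j, i] <- unname(res$cost[subset[j]])
    }
  }
  disc <- which(!is.finite(D) & upper.tri(D), arr.ind = TRUE)
  if (nrow(disc)) {
    finite <- D[is.finite(D) & upper.tri(D)]
    sentinel <- if (length(finite) && max(finite) > 0) 2 * max(finite)
                else fallback
    pairs <- data.frame(from = subset[disc[, 1L]], to = subset[disc[, 2L]],
                        stringsAsFactors = FALSE)
    D[!is.finite(D)] <- sentinel
    attr(D, "disconnected_pairs") <- pairs
    attr(D, "sentinel") <- sentinel
  } else {
    attr(D, "disconnected_pairs") <- data.frame(from = character(0),
                                                to = character(0))
    attr(D, "sentinel") <- NA_real_
  }
  class(D) <- c("path_distance_matrix", class(D))
  D
}

#' @export
print.path_distance_matrix <- function(x, ...) {
  cat(sprintf("<path_distance_matrix> %d x %d (%d disconnected pair(s))\n",
              nrow(x), ncol(x), nrow(attr(x, "disconnected_pairs"))))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  invisible(x)
}
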