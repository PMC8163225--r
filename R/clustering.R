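#' Complete-linkage clustering of a path distance matrix
#'
#' Agglomerative hierarchical clustering with inter-cluster distance equal
#' to the maximum pairwise distance. Complete linkage favours compact
#' clusters and avoids the chaining effect that would blur metabolic
#' modules. Leaves are ordered lexicographically by id before
#' agglomeration so that ties resolve deterministically toward the
#' smallest leaf id. Sentinel distances of disconnected pairs (see
#' [path_distance_matrix()]) participate as ordinary values, which forces
#' disconnected components to merge last.
#'
#' @param dm a symmetric non-negative matrix with zero diagonal, typically
#'   a [path_distance_matrix()].
#' @return an object of classes `"module_tree"` and `"hclust"` (merge
#'   list, heights, labels), with the input matrix attached as the
#'   `"distance_matrix"` attribute.
#' @export
complete_linkage <- function(dm) {
  D <- unclass(dm)
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("'dm' must be a square matrix")
  if (is.null(rownames(D)))
    dimnames(D) <- list(paste0("n", seq_len(nrow(D))),
                        paste0("n", seq_len(nrow(D))))
  if (any(D < 0)) stop("'dm' has negative entries")
  if (max(abs(D - t(D))) > 1e-8) stop("'dm' is not symmetric")
  if (any(diag(D) != 0)) stop("'dm' must have a zero diagonal")
  ord <- order(rownames(D))
  D <- D[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(D), method = "complete")
  class(hc) <- c("module_tree", "hclust")
  attr(hc, "distance_matrix") <- dm
  hc
}

#' @export
print.module_tree <- function(x, ...) {
  cat(sprintf("<module_tree> complete-linkage tree over %d leaves (merge heights %.3g .. %.3g)\n",
              length(x$labels), min(x$height), max(x$height)))
  invisible(x)
}

#' Cut a module tree into k clusters
#'
#' Cuts the dendrogram below the (n-k+1)-th merge. Cluster numbers are
#' stabilised so that cluster 1 contains the lexicographically smallest
#' leaf id, cluster 2 the smallest id not in cluster 1, and so on —
#' independent of the agglomeration order.
#'
#' @param tree a [complete_linkage()] tree.
#' @param k number of clusters, between 1 and the number of leaves.
#' @return named integer vector of cluster assignments.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels)
  k <- as.integer(k)
  if (k < 1L || k > n)
    stop("'k' must lie between 1 and the number of leaves (", n, ")")
  raw <- stats::cutree(tree, k = k)
  # renumber clusters by their smallest member id
  first <- vapply(split(names(raw), raw), function(m) min(m), character(1))
  relabel <- stats::setNames(rank(first), names(first))
  out <- as.integer(relabel[as.character(raw)])
  names(out) <- names(raw)
  out[order(names(out))]
}

#' Summarize metabolic modules
#'
#' Per-module report: members, dominant pathway annotations, and mean
#' within-module lightest-path distance (0 for singletons by convention).
#' A warning is emitted when a module spans a disconnected pair, i.e. its
#' cohesion rests on sentinel distances. The dendrogram leaf order is
#' returned for heatmap display of the distance matrix.
#'
#' @param assignment cluster assignment from [cut_tree()].
#' @param dm the [path_distance_matrix()] the tree was built on.
#' @param graph optional [compound_graph()] providing names and pathway
#'   annotations.
#' @param tree optional [complete_linkage()] tree; supplies the heatmap
#'   leaf order.
#' @return an object of class `"module_report"`: list with `modules`
#'   (data frame `module`, `size`, `members`, `dominant_pathways`,
#'   `mean_within_distance`), `assignment`, and `leaf_order`.
#' @export
module_report <- function(assignment, dm, graph = NULL, tree = NULL) {
  ids <- names(assignment)
  if (is.null(ids)) stop("'assignment' must be a named vector")
  D <- unclass(dm)
  if (!all(ids %in% rownames(D)))
    stop("assignment names must all appear in the distance matrix")
  disc <- attr(dm, "disconnected_pairs")
  rows <- lapply(sort(unique(assignment)), function(m) {
    members <- sort(ids[assignment == m])
    wd <- if (length(members) < 2L) 0 else {
      sub <- D[members, members]
      mean(sub[upper.tri(sub)])
    }
    if (!is.null(disc) && nrow(disc)) {
      spans <- any(disc$from %in% members & disc$to %in% members)
      if (spans)
        warning("module ", m, " spans disconnected pair(s); ",
                "its cohesion rests on sentinel distances")
    }
    dom <- ""
    if (!is.null(graph)) {
      pw <- unlist(strsplit(
        graph$nodes$pathways[graph$nodes$id %in% members], ";"))
      pw <- pw[nzchar(pw)]
      if (length(pw)) {
        tab <- sort(table(pw), decreasing = TRUE)
        dom <- paste(names(tab)[tab == max(tab)], collapse = ";")
      }
    }
    data.frame(module = m, size = length(members),
               members = paste(members, collapse = ";"),
               dominant_pathways = dom,
               mean_within_distance = wd,
               stringsAsFactors = FALSE)
  })
  leaf_order <- if (!is.null(tree)) tree$labels[tree$order] else sort(ids)
  structure(list(modules = do.call(rbind, rows),
                 assignment = assignment,
                 leaf_order = leaf_order),
            class = "module_report")
}

#' @export
print.module_report <- function(x, ...) {
  cat("<module_report>", nrow(x$modules), "module(s)\n")
  print(x$modules[, c("module", "size", "dominant_pathways",
                      "mean_within_distance")], row.names = FALSE)
  invisible(x)
}

#' Mean silhouette width over a range of cluster counts
#'
#' Guidance for choosing k when the dendrogram alone is ambiguous: for
#' each candidate k the tree is cut and the average silhouette width over
#' all leaves is reported (larger is better-separated).
#'
#' @param tree a [complete_linkage()] tree.
#' @param dm the distance matrix the tree was built on.
#' @param k_range candidate cluster counts (default 2..10, truncated to
#'   n - 1).
#' @return data frame with columns `k`, `mean_silhouette`.
#' @export
silhouette_profile <- function(tree, dm, k_range = 2:10) {
  if (!requireNamespace("cluster", quietly = TRUE))
    stop("the 'cluster' package is required for silhouette profiles")
  D <- unclass(dm)
  k_range <- k_range[k_range >= 2L & k_range < nrow(D)]
  rows <- lapply(k_range, function(k) {
    a <- cut_tree(tree, k)
    a <- a[rownames(D)]
    sil <- cluster::silhouette(a, stats::as.dist(D))
    data.frame(k = k, mean_silhouette = mean(sil[, "sil_width"]))
  })
  do.call(rbind, rows)
}
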