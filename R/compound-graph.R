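#' Construct a compound graph
#'
#' A compound graph has metabolites as nodes, with two nodes connected
#' when they are substrate and product of the same reaction. Edges are
#' undirected and carry the reaction id and a carbon-transfer flag (does
#' at least one carbon atom pass between the two metabolites in that
#' reaction, per precomputed atom mappings). Parallel edges contributed by
#' distinct reactions are merged; the merged edge transfers carbon if any
#' contributing reaction does. Self-loops are dropped.
#'
#' @param nodes data frame with columns `id` (unique), and optionally
#'   `name`, `pathways` (semicolon-separated pathway ids), `side`
#'   (logical side-compound flag), `external_ids` (semicolon-separated).
#' @param edges data frame with columns `from`, `to`, and optionally
#'   `reaction`, `carbon` (logical carbon-transfer flag).
#' @param pathways optional named character vector, pathway id -> display
#'   name.
#' @return an object of class `"compound_graph"`.
#' @seealso [read_compound_graph()], [collapse_compartments()],
#'   [remove_side_compounds()], [carbon_filter()], [lightest_path()]
#' @export
compound_graph <- function(nodes, edges, pathways = NULL) {
  if (!is.data.frame(nodes) || !"id" %in% names(nodes))
    stop("'nodes' must be a data frame with an 'id' column")
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id))
    stop("duplicate node ids: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  if (is.null(nodes$name)) nodes$name <- nodes$id
  if (is.null(nodes$pathways)) nodes$pathways <- ""
  if (is.null(nodes$side)) nodes$side <- FALSE
  if (is.null(nodes$external_ids)) nodes$external_ids <- ""
  nodes$pathways[is.na(nodes$pathways)] <- ""
  nodes$external_ids[is.na(nodes$external_ids)] <- ""
  nodes <- nodes[, c("id", "name", "pathways", "side", "external_ids")]

  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(from = character(0), to = character(0),
                        reaction = character(0), carbon = logical(0),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("from", "to") %in% names(edges)))
      stop("'edges' must have 'from' and 'to' columns")
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    if (is.null(edges$reaction)) edges$reaction <- paste0("R", seq_len(nrow(edges)))
    if (is.null(edges$carbon)) edges$carbon <- NA
    edges$carbon <- as.logical(edges$carbon)
    missing_ep <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(missing_ep)) {
      bad <- which(edges$from %in% missing_ep | edges$to %in% missing_ep)[1L]
      stop(sprintf("edge %d (%s - %s, reaction %s) references unknown node(s): %s",
                   bad, edges$from[bad], edges$to[bad], edges$reaction[bad],
                   paste(missing_ep, collapse = ", ")))
    }
    edges <- edges[edges$from != edges$to, , drop = FALSE]   # drop self-loops
    if (nrow(edges)) {
      a <- pmin(edges$from, edges$to)
      b <- pmax(edges$from, edges$to)
      key <- paste(a, b, sep = "\r")
      agg_rxn <- tapply(edges$reaction, key,
                        function(r) paste(unique(r), collapse = ";"))
      agg_carbon <- tapply(edges$carbon, key, function(x) {
        if (all(is.na(x))) NA else any(x, na.rm = TRUE)
      })
      u <- !duplicated(key)
      edges <- data.frame(from = a[u], to = b[u],
                          reaction = unname(agg_rxn[key[u]]),
                          carbon = unname(agg_carbon[key[u]]),
                          stringsAsFactors = FALSE)
      edges <- edges[order(edges$from, edges$to), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  structure(list(nodes = nodes, edges = edges,
                 pathways = pathways), class = "compound_graph")
}

#' @export
print.compound_graph <- function(x, ...) {
  npw <- length(unique(unlist(strsplit(x$nodes$pathways[nzchar(x$nodes$pathways)], ";"))))
  cat(sprintf("<compound_graph> %d metabolites, %d edges, %d pathways (%d side compounds)\n",
              nrow(x$nodes), nrow(x$edges), npw, sum(x$nodes$side)))
  invisible(x)
}

#' Node degrees of a compound graph
#'
#' @param graph a [compound_graph()].
#' @return named integer vector of degrees (isolated nodes have 0).
#' @export
graph_degrees <- function(graph) {
  stopifnot(inherits(graph, "compound_graph"))
  d <- stats::setNames(integer(nrow(graph$nodes)), graph$nodes$id)
  if (nrow(graph$edges)) {
    tab <- table(c(graph$edges$from, graph$edges$to))
    d[names(tab)] <- as.integer(tab)
  }
  d
}

#' Pathway membership sets of a compound graph
#'
#' @param graph a [compound_graph()].
#' @param include_side include side compounds in the sets (default TRUE).
#' @return named list, pathway id -> character vector of node ids.
#' @export
pathway_sets <- function(graph, include_side = TRUE) {
  stopifnot(inherits(graph, "compound_graph"))
  nodes <- graph$nodes
  if (!include_side) nodes <- nodes[!nodes$side, , drop = FALSE]
  pw <- strsplit(nodes$pathways, ";")
  keep <- lengths(pw) > 0L
  df <- data.frame(id = rep(nodes$id[keep], lengths(pw[keep])),
                   pw = unlist(pw[keep]), stringsAsFactors = FALSE)
  df <- df[nzchar(df$pw), , drop = FALSE]
  split(df$id, df$pw)
}

#' Read a compound graph from node and edge tables
#'
#' Native tab-delimited schema: a nodes file with columns `id`, and
#' optionally `name`, `pathways` (semicolon-separated), `side`,
#' `external_ids`; and an edges file with columns `from`, `to`, and
#' optionally `reaction`, `carbon`. Dangling edge endpoints are a parse
#' error naming the record.
#'
#' @param nodes_file,edges_file file paths.
#' @return a [compound_graph()].
#' @export
read_compound_graph <- function(nodes_file, edges_file) {
  nodes <- utils::read.delim(nodes_file, stringsAsFactors = FALSE,
                             colClasses = "character")
  if (!is.null(nodes$side)) nodes$side <- as.logical(nodes$side)
  edges <- utils::read.delim(edges_file, stringsAsFactors = FALSE,
                             colClasses = "character")
  if (!is.null(edges$carbon)) edges$carbon <- as.logical(edges$carbon)
  compound_graph(nodes, edges)
}

#' Write a compound graph as node and edge tables
#'
#' @param graph a [compound_graph()].
#' @param nodes_file,edges_file output file paths.
#' @return invisibly, the two paths.
#' @export
write_compound_graph <- function(graph, nodes_file, edges_file) {
  stopifnot(inherits(graph, "compound_graph"))
  utils::write.table(graph$nodes, nodes_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(graph$edges, edges_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(nodes_file, edges_file))
}

#' Collapse compartment-specific metabolite copies
#'
#' Genome-scale reconstructions keep one node per metabolite per cellular
#' compartment; for plasma metabolomics this distinction is irrelevant, so
#' nodes whose ids differ only by a trailing compartment suffix are merged
#' into a single node. Edges are re-targeted; self-loops created by the
#' merge (transport reactions) are deleted; parallel edges are merged;
#' pathway memberships and external ids are unioned.
#'
#' @param graph a [compound_graph()].
#' @param pattern regular expression for the compartment suffix (default:
#'   a final underscore plus one or two alphanumerics, e.g. `"_c"`,
#'   `"_m"`).
#' @return a [compound_graph()] with one node per stripped id.
#' @export
collapse_compartments <- function(graph, pattern = "_[a-z0-9]{1,2}$") {
  stopifnot(inherits(graph, "compound_graph"))
  nodes <- graph$nodes
  stripped <- sub(pattern, "", nodes$id)
  if (any(!nzchar(stripped)))
    stop("compartment pattern matches the whole id for: ",
         paste(nodes$id[!nzchar(stripped)], collapse = ", "))
  union_field <- function(x) {
    v <- unique(unlist(strsplit(x[nzchar(x)], ";")))
    paste(v, collapse = ";")
  }
  merged <- do.call(rbind, lapply(split(seq_len(nrow(nodes)), stripped),
    function(ix) {
      data.frame(id = stripped[ix[1L]],
                 name = sub(pattern, "", nodes$name[ix[1L]]),
                 pathways = union_field(nodes$pathways[ix]),
                 side = any(nodes$side[ix]),
                 external_ids = union_field(nodes$external_ids[ix]),
                 stringsAsFactors = FALSE)
    }))
  lut <- stats::setNames(stripped, nodes$id)
  edges <- graph$edges
  if (nrow(edges)) {
    edges$from <- unname(lut[edges$from])
    edges$to <- unname(lut[edges$to])
  }
  compound_graph(merged, edges, graph$pathways)
}

#' Default side-compound list
#'
#' Ubiquitous auxiliary metabolites (water, carbon dioxide, redox and
#' energy cofactors, phosphate carriers and their deoxy counterparts) that
#' create biologically meaningless shortcuts in compound graphs. The list
#' ships as a plain-text file under `extdata` and is meant to be
#' overridden or extended per analysis.
#'
#' @return character vector of node ids.
#' @export
default_side_compounds <- function() {
  path <- system.file("extdata", "side_compounds.txt", package = "netpca")
  readLines(path)
}

#' Remove side compounds from a compound graph
#'
#' Deletes the listed nodes and their incident edges. Unknown ids are
#' ignored with a warning so that one generic list can serve several
#' networks.
#'
#' @param graph a [compound_graph()].
#' @param side_list character vector of node ids; defaults to
#'   [default_side_compounds()].
#' @return a [compound_graph()].
#' @export
remove_side_compounds <- function(graph, side_list = default_side_compounds()) {
  stopifnot(inherits(graph, "compound_graph"))
  unknown <- setdiff(side_list, graph$nodes$id)
  if (length(unknown))
    warning("side compound id(s) not in graph (ignored): ",
            paste(unknown, collapse = ", "))
  drop <- intersect(side_list, graph$nodes$id)
  nodes <- graph$nodes[!graph$nodes$id %in% drop, , drop = FALSE]
  edges <- graph$edges[!(graph$edges$from %in% drop |
                         graph$edges$to %in% drop), , drop = FALSE]
  compound_graph(nodes, edges, graph$pathways)
}

#' Keep only carbon-transfer edges
#'
#' Deletes every edge whose carbon-transfer flag is `FALSE`; edges without
#' a flag are an error. Nodes are retained even when isolated, so the node
#' set (and hence the enrichment universe) is unchanged.
#'
#' @param graph a [compound_graph()] with carbon flags on every edge.
#' @return a [compound_graph()].
#' @export
carbon_filter <- function(graph) {
  stopifnot(inherits(graph, "compound_graph"))
  edges <- graph$edges
  if (nrow(edges) && anyNA(edges$carbon)) {
    bad <- which(is.na(edges$carbon))[1L]
    stop(sprintf("edge %s - %s (reaction %s) has no carbon-transfer flag",
                 edges$from[bad], edges$to[bad], edges$reaction[bad]))
  }
  compound_graph(graph$nodes, edges[which(edges$carbon), , drop = FALSE],
                 graph$pathways)
}

#' Induced subgraph on a node subset
#'
#' @param graph a [compound_graph()].
#' @param ids node ids to keep.
#' @return a [compound_graph()] restricted to `ids` and the edges between
#'   them.
#' @export
induced_subgraph <- function(graph, ids) {
  stopifnot(inherits(graph, "compound_graph"))
  missing <- setdiff(ids, graph$nodes$id)
  if (length(missing))
    stop("node id(s) not in graph: ", paste(missing, collapse = ", "))
  nodes <- graph$nodes[graph$nodes$id %in% ids, , drop = FALSE]
  edges <- graph$edges[graph$edges$from %in% ids &
                       graph$edges$to %in% ids, , drop = FALSE]
  compound_graph(nodes, edges, graph$pathways)
}
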