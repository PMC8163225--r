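#' Design for a toy pathway-annotated metabolic network
#'
#' Stand-in for genome-scale network structure at test scale: pathways
#' wired as chains (or cycles) of carbon-transfer edges, a few
#' carbon-transfer bridges between consecutive pathways, high-degree side
#' compounds attached across pathways, and a fraction of extra edges that
#' carry no carbon (pruned by [carbon_filter()]). Pathway membership is
#' the planted module truth for clustering validation.
#'
#' @param n_pathways number of pathways.
#' @param mets_per_pathway metabolites per pathway.
#' @param wiring `"chain"` or `"cycle"` within-pathway topology.
#' @param n_bridges carbon-transfer edges between consecutive pathways.
#' @param n_side number of side compounds.
#' @param side_degree edges attached to each side compound; must be at
#'   least `mets_per_pathway` so side compounds are the top hubs.
#' @param noncarbon_frac extra non-carbon edges as a fraction of the
#'   carbon edge count.
#' @param metabolite_ids optional character vector of node ids to use for
#'   the pathway metabolites (length `n_pathways * mets_per_pathway`);
#'   handy for aligning network nodes with cohort variable ids.
#' @return an object of class `"network_design"`.
#' @seealso [generate_toy_network()]
#' @export
toy_network_design <- function(n_pathways = 5L, mets_per_pathway = 8L,
                               wiring = c("chain", "cycle"),
                               n_bridges = 4L, n_side = 2L,
                               side_degree = 20L, noncarbon_frac = 0.15,
                               metabolite_ids = NULL) {
  wiring <- match.arg(wiring)
  if (n_pathways < 1L || mets_per_pathway < 2L || n_side < 0L)
    stop("counts must be positive (and at least 2 metabolites per pathway)")
  if (n_side > 0L && side_degree < mets_per_pathway)
    stop("'side_degree' must be >= 'mets_per_pathway' so side compounds are hubs")
  if (!is.null(metabolite_ids) &&
      length(metabolite_ids) != n_pathways * mets_per_pathway)
    stop("'metabolite_ids' must have length n_pathways * mets_per_pathway")
  structure(list(n_pathways = as.integer(n_pathways),
                 mets_per_pathway = as.integer(mets_per_pathway),
                 wiring = wiring, n_bridges = as.integer(n_bridges),
                 n_side = as.integer(n_side),
                 side_degree = as.integer(side_degree),
                 noncarbon_frac = noncarbon_frac,
                 metabolite_ids = metabolite_ids),
            class = "network_design")
}

#' Generate a toy compound graph with planted modules
#'
#' @param design a [toy_network_design()].
#' @param seed integer seed.
#' @return list with elements `graph` (a [compound_graph()]), `labels`
#'   (named character vector, metabolite id -> planted pathway id; side
#'   compounds excluded), and `counts` (declared node/edge bookkeeping:
#'   `n_nodes`, `n_edges`, `n_carbon_edges`, `n_noncarbon_edges`).
#' @export
generate_toy_network <- function(design = toy_network_design(), seed = 1L) {
  stopifnot(inherits(design, "network_design"))
  set.seed(as.integer(seed))
  P <- design$n_pathways; M <- design$mets_per_pathway
  ids <- design$metabolite_ids
  if (is.null(ids))
    ids <- as.vector(outer(seq_len(M), seq_len(P),
                           function(i, p) sprintf("pw%d_m%d", p, i)))
  pw_of <- rep(sprintf("PW%d", seq_len(P)), each = M)
  names(pw_of) <- ids

  edges <- list()
  add_edge <- function(u, v, carbon, rxn) {
    edges[[length(edges) + 1L]] <<- data.frame(
      from = u, to = v, reaction = rxn, carbon = carbon,
      stringsAsFactors = FALSE)
  }
  rxn <- 0L
  nxt <- function() { rxn <<- rxn + 1L; sprintf("R%04d", rxn) }

  for (p in seq_len(P)) {
    mem <- ids[pw_of == sprintf("PW%d", p)]
    for (i in seq_len(M - 1L)) add_edge(mem[i], mem[i + 1L], TRUE, nxt())
    if (design$wiring == "cycle") add_edge(mem[M], mem[1L], TRUE, nxt())
  }
  existing <- vapply(edges, function(e) paste(min(e$from, e$to),
                                              max(e$from, e$to)), character(1))
  # bridges between consecutive pathways (carbon-transfer): the end product
  # of pathway p feeds the first metabolite of pathway p+1; further bridges
  # beyond P-1 are drawn at random (re-drawn on duplicates so the declared
  # edge count matches the merged graph)
  if (P > 1L && design$n_bridges > 0L) {
    for (k in seq_len(design$n_bridges)) {
      p <- 1L + (k - 1L) %% (P - 1L)
      mem_p <- ids[pw_of == sprintf("PW%d", p)]
      mem_q <- ids[pw_of == sprintf("PW%d", p + 1L)]
      if (k <= P - 1L) {
        u <- mem_p[length(mem_p)]; v <- mem_q[1L]
        key <- paste(min(u, v), max(u, v))
      } else {
        repeat {
          u <- sample(mem_p, 1L); v <- sample(mem_q, 1L)
          key <- paste(min(u, v), max(u, v))
          if (!key %in% existing) break
        }
      }
      existing <- c(existing, key)
      add_edge(u, v, TRUE, nxt())
    }
  }
  n_carbon <- length(edges)

  # extra non-carbon edges between random non-adjacent metabolite pairs
  n_nc <- round(design$noncarbon_frac * n_carbon)
  tries <- 0L; added <- 0L
  while (added < n_nc && tries < 50L * n_nc) {
    tries <- tries + 1L
    uv <- sample(ids, 2L)
    key <- paste(min(uv), max(uv))
    if (key %in% existing) next
    existing <- c(existing, key)
    add_edge(uv[1L], uv[2L], FALSE, nxt())
    added <- added + 1L
  }
  n_nc <- added

  # side compounds: high-degree hubs attached across pathways, named after
  # real currency metabolites so the shipped default side list covers them
  currency <- c("h2o", "co2", "nad", "atp", "adp", "amp", "nadh", "coa",
                "pi", "nadp")
  side_ids <- if (design$n_side > 0L) {
    if (design$n_side <= length(currency)) currency[seq_len(design$n_side)]
    else c(currency, sprintf("cofactor%d",
                             seq_len(design$n_side - length(currency))))
  } else character(0)
  n_side_edges <- 0L
  for (s in side_ids) {
    att <- sample(ids, design$side_degree)
    for (v in att) add_edge(s, v, TRUE, nxt())
    n_side_edges <- n_side_edges + design$side_degree
  }

  nodes <- data.frame(
    id = c(ids, side_ids),
    name = c(ids, side_ids),
    pathways = c(pw_of, rep("currency", length(side_ids))),
    side = c(rep(FALSE, length(ids)), rep(TRUE, length(side_ids))),
    external_ids = "",
    stringsAsFactors = FALSE)
  pw_names <- stats::setNames(sprintf("Pathway %d", seq_len(P)),
                              sprintf("PW%d", seq_len(P)))
  graph <- compound_graph(nodes, do.call(rbind, edges), pw_names)
  list(graph = graph,
       labels = pw_of,
       counts = list(n_nodes = length(ids) + length(side_ids),
                     n_edges = n_carbon + n_nc + n_side_edges,
                     n_carbon_edges = n_carbon + n_side_edges,
                     n_noncarbon_edges = n_nc))
}
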