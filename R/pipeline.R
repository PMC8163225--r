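#' Assemble and validate a pipeline configuration
#'
#' Configuration for [run_pipeline()]. Inputs may be given as file paths
#' (matrix manifest, network node/edge tables, side-compound list) or
#' directly as in-memory objects ([data_network()], [compound_graph()],
#' character vector).
#'
#' @param network a [data_network()] or the path to a matrix manifest
#'   (see [read_matrix_manifest()]).
#' @param graph a [compound_graph()] or a length-2 character vector
#'   `c(nodes_file, edges_file)`.
#' @param side_compounds character vector of side-compound ids, or a file
#'   path (one id per line); defaults to [default_side_compounds()].
#' @param ncomp number of NetPCA components (default 2).
#' @param tol,max_iter NetPCA convergence settings.
#' @param seed seed echoed into the run log and used for any randomized
#'   initialization.
#' @param marker_threshold percent-of-variable-variance threshold for
#'   marker selection (default 20, in `[0, 100]`).
#' @param marker_component component whose markers feed the enrichment
#'   and network stages (default 1: the severity axis; treatment-specific
#'   axes are usually not a biological process to enrich on).
#' @param alpha ORA significance level on BH q-values (default 0.05).
#' @param k number of metabolic modules for the final tree cut.
#' @param widen_seeds if `TRUE`, subnetwork seeds are all mapped markers;
#'   default `FALSE` restricts seeds to markers of significant pathways.
#' @param output_dir directory for the report bundle (default: a fresh
#'   temporary directory).
#' @return an object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(network, graph,
                            side_compounds = default_side_compounds(),
                            ncomp = 2L, tol = 1e-9, max_iter = 500L,
                            seed = 1L, marker_threshold = 20,
                            marker_component = 1L, alpha = 0.05, k = 5L,
                            widen_seeds = FALSE,
                            output_dir = tempfile("netpca_run_")) {
  if (marker_threshold < 0 || marker_threshold > 100)
    stop("'marker_threshold' must lie in [0, 100]")
  if (alpha <= 0 || alpha > 1) stop("'alpha' must lie in (0, 1]")
  if (ncomp < 1L) stop("'ncomp' must be at least 1")
  if (k < 1L) stop("'k' must be at least 1")
  if (is.character(network)) {
    if (!file.exists(network)) stop("manifest not found: ", network)
  } else stopifnot(inherits(network, "data_network"))
  if (is.character(graph)) {
    if (length(graph) != 2L || !all(file.exists(graph)))
      stop("'graph' must be a compound_graph or c(nodes_file, edges_file)")
  } else stopifnot(inherits(graph, "compound_graph"))
  if (is.character(side_compounds) && length(side_compounds) == 1L &&
      file.exists(side_compounds))
    side_compounds <- readLines(side_compounds)
  structure(list(network = network, graph = graph,
                 side_compounds = side_compounds, ncomp = as.integer(ncomp),
                 tol = tol, max_iter = as.integer(max_iter),
                 seed = as.integer(seed), marker_threshold = marker_threshold,
                 marker_component = as.integer(marker_component),
                 alpha = alpha, k = as.integer(k),
                 widen_seeds = isTRUE(widen_seeds),
                 output_dir = output_dir),
            class = "pipeline_config")
}

# run one pipeline stage; failures abort with a stage-tagged condition
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(structure(class = c("pipeline_error", "error", "condition"),
                   list(message = sprintf("[stage %s] %s", stage,
                                          conditionMessage(e)),
                        call = NULL, stage = stage)))
  })
}

#' Run the integrative workflow end to end
#'
#' Executes: load and validate the data network; unit-variance scaling and
#' NetPCA fit; block-influence and per-variable explained-variance
#' decompositions; marker selection on the configured component; identifier
#' mapping onto the metabolic network; pathway over-representation
#' analysis (universe = all metabolites after compartment collapse);
#' graph preparation (compartment collapse, side-compound removal,
#' carbon-transfer filtering); subnetwork extraction seeded by mapped
#' markers of significant pathways; the lightest-path distance matrix over
#' the seeds; complete-linkage clustering cut into `k` metabolic modules.
#' All tables plus a run log (package version, seed, parameter echo) are
#' written to the configured output directory. Any stage failure aborts
#' with a `"pipeline_error"` condition naming the stage.
#'
#' When no pathway reaches significance (and `widen_seeds` is `FALSE`),
#' or fewer than two usable seeds remain, the network stages are skipped
#' with a logged notice and the bundle omits the clustering elements.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the report bundle: a list with elements `model`,
#'   `influence`, `variable_variance`, `markers`, `mapping`, `ora`,
#'   `prepared_graph`, `subnetwork`, `distance_matrix`, `tree`,
#'   `assignment`, `modules`, `log`, `output_dir` (later elements may be
#'   absent when the network stages were skipped).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- character(0)
  note <- function(...) logf <<- c(logf, sprintf(...))
  note("netpca version %s", as.character(utils::packageVersion("netpca")))
  note("seed %d", config$seed)
  note("parameters: ncomp=%d tol=%g marker_threshold=%g component=%d alpha=%g k=%d",
       config$ncomp, config$tol, config$marker_threshold,
       config$marker_component, config$alpha, config$k)

  network <- run_stage("load_network", {
    if (is.character(config$network)) read_matrix_manifest(config$network)
    else config$network
  })
  graph <- run_stage("load_graph", {
    if (is.character(config$graph))
      read_compound_graph(config$graph[1L], config$graph[2L])
    else config$graph
  })

  model <- run_stage("netpca", netpca(network, ncomp = config$ncomp,
                                      scale = TRUE, tol = config$tol,
                                      max_iter = config$max_iter,
                                      seed = config$seed))
  note("component variance: %s",
       paste(sprintf("%.2f%%", model$component_variance), collapse = ", "))
  influence <- run_stage("block_influence", block_influence(model))
  vartab <- run_stage("variable_variance", variable_explained_variance(model))
  markers <- run_stage("select_markers",
                       select_markers(vartab, config$marker_component,
                                      config$marker_threshold))
  note("%d marker(s) at >= %g%% on component %d", length(markers),
       config$marker_threshold, config$marker_component)

  collapsed <- run_stage("collapse_compartments", collapse_compartments(graph))
  mapping <- run_stage("map_identifiers", map_identifiers(markers, collapsed))
  note("mapping rate %.1f%%", mapping$mapping_rate)
  universe <- collapsed$nodes$id
  pw_sets <- pathway_sets(collapsed)
  ora_res <- run_stage("ora", ora(mapping$mapped$node_id, universe, pw_sets))
  sig <- ora_res$pathway[ora_res$q_value <= config$alpha]
  note("%d significant pathway(s) at q <= %g", length(sig), config$alpha)

  prepared <- run_stage("prepare_graph", {
    g <- remove_side_compounds(collapsed, config$side_compounds)
    carbon_filter(g)
  })

  bundle <- list(model = model, influence = influence,
                 variable_variance = vartab, markers = markers,
                 mapping = mapping, ora = ora_res,
                 prepared_graph = prepared, config = config)

  seeds <- if (config$widen_seeds) mapping$mapped$node_id else {
    sig_members <- unique(unlist(pw_sets[sig], use.names = FALSE))
    intersect(mapping$mapped$node_id, sig_members)
  }
  seeds <- intersect(seeds, prepared$nodes$id)
  if (length(seeds) < 2L) {
    note("network stages skipped: %d usable seed(s)", length(seeds))
  } else {
    bundle$subnetwork <- run_stage("extract_subnetwork",
                                   extract_subnetwork(prepared, seeds))
    bundle$distance_matrix <- run_stage("path_distance_matrix",
                                        path_distance_matrix(prepared, seeds))
    bundle$tree <- run_stage("complete_linkage",
                             complete_linkage(bundle$distance_matrix))
    kk <- min(config$k, length(seeds))
    bundle$assignment <- run_stage("cut_tree", cut_tree(bundle$tree, kk))
    bundle$modules <- run_stage("module_report",
      module_report(bundle$assignment, bundle$distance_matrix,
                    graph = prepared, tree = bundle$tree))
    note("%d module(s) over %d seed metabolites", kk, length(seeds))
  }

  run_stage("write_outputs", {
    d <- config$output_dir
    export_netpca(model, d)
    writeLines(markers, file.path(d, "markers.txt"))
    utils::write.table(mapping$mapped, file.path(d, "mapping.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_ora_report(ora_res, file.path(d, "ora.tsv"))
    if (!is.null(bundle$subnetwork))
      write_compound_graph(bundle$subnetwork,
                           file.path(d, "subnetwork_nodes.tsv"),
                           file.path(d, "subnetwork_edges.tsv"))
    if (!is.null(bundle$distance_matrix))
      utils::write.table(
        data.frame(id = rownames(bundle$distance_matrix),
                   unclass(bundle$distance_matrix), check.names = FALSE),
        file.path(d, "distance_matrix.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(bundle$tree))
      utils::write.table(
        data.frame(step = seq_along(bundle$tree$height),
                   height = bundle$tree$height),
        file.path(d, "merge_heights.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(bundle$assignment))
      utils::write.table(
        data.frame(id = names(bundle$assignment),
                   module = bundle$assignment),
        file.path(d, "module_assignment.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(bundle$modules))
      utils::write.table(bundle$modules$modules,
                         file.path(d, "module_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(logf, file.path(d, "run_log.txt"))
  })
  bundle$log <- logf
  bundle$output_dir <- config$output_dir
  class(bundle) <- "pipeline_bundle"
  invisible(bundle)
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat("<pipeline_bundle>\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  cat("  outputs:", x$output_dir, "\n")
  invisible(x)
}

#' Render the standard figures of a pipeline run
#'
#' Writes (1) the NetPCA score plot of the two first global components
#' coloured by row class, (2) the over-representation bar chart of
#' -log10(q) per pathway with the 5 percent significance threshold drawn
#' at 1.301, and (3) the lightest-path distance heatmap ordered by the
#' dendrogram (darker = shorter reaction path). The heatmap is skipped
#' with a notice when the bundle carries no clustering.
#'
#' @param bundle a [run_pipeline()] bundle.
#' @param dir output directory (default: the bundle's).
#' @param width,height device size in pixels.
#' @return character vector of the files written.
#' @export
make_figures <- function(bundle, dir = bundle$output_dir,
                         width = 900, height = 700) {
  for (el in c("model", "ora"))
    if (is.null(bundle[[el]])) stop("bundle is missing element '", el, "'")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  f <- file.path(dir, "score_plot.png")
  grDevices::png(f, width, height)
  plot(bundle$model, main = "NetPCA global components")
  grDevices::dev.off()
  files <- c(files, f)

  f <- file.path(dir, "ora_barchart.png")
  grDevices::png(f, width, height)
  oo <- bundle$ora[order(bundle$ora$neg_log10_q), ]
  graphics::par(mar = c(4, 10, 2, 1))
  graphics::barplot(oo$neg_log10_q, names.arg = oo$pathway, horiz = TRUE,
                    las = 1, col = "steelblue",
                    xlab = expression(-log[10] ~ "(BH q-value)"),
                    main = "Pathway over-representation")
  graphics::abline(v = neg_log10(bundle$config$alpha), col = "red", lty = 2)
  grDevices::dev.off()
  files <- c(files, f)

  if (is.null(bundle$tree) || is.null(bundle$distance_matrix)) {
    message("heatmap skipped: bundle carries no clustering")
  } else {
    f <- file.path(dir, "distance_heatmap.png")
    grDevices::png(f, width, height)
    ord <- bundle$modules$leaf_order
    D <- unclass(bundle$distance_matrix)[ord, ord]
    graphics::image(seq_len(nrow(D)), seq_len(ncol(D)),
                    -D[, rev(seq_len(ncol(D)))],
                    col = grDevices::gray.colors(64), axes = FALSE,
                    xlab = "", ylab = "",
                    main = "Reaction-path distances (dendrogram order)")
    graphics::axis(1, seq_len(nrow(D)), rownames(D), las = 2, cex.axis = 0.6)
    graphics::axis(2, seq_len(ncol(D)), rev(colnames(D)), las = 2,
                   cex.axis = 0.6)
    grDevices::dev.off()
    files <- c(files, f)
  }
  files
}
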