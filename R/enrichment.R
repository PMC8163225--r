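#' Normalize a metabolite identifier for matching
#'
#' Case-folds, trims whitespace and strips a trailing compartment suffix
#' (by default one or two alphanumeric characters after a final
#' underscore, e.g. `"ATP_c"` to `"atp"`).
#'
#' @param x character vector of identifiers.
#' @param compartment_pattern regular expression for the suffix to strip.
#' @return normalized character vector.
#' @export
normalize_identifier <- function(x, compartment_pattern = "_[a-z0-9]{1,2}$") {
  x <- tolower(trimws(as.character(x)))
  stripped <- sub(compartment_pattern, "", x)
  ifelse(nzchar(stripped), stripped, x)
}

#' Map query metabolites onto a compound graph
#'
#' Deterministic exact matching of query identifiers against the network's
#' node identifier fields after normalization (case-fold, trim, strip
#' compartment suffix on both sides). Identifier types are tried in a
#' fixed priority order — node id, then display name, then external
#' database ids — and the first hit wins.
#'
#' @param queries either a character vector of query ids, or a data frame
#'   with a `query_id` column plus any of `id`, `name`, `external_ids`
#'   (semicolon-separated) identifier columns. Query ids must be unique.
#' @param graph a [compound_graph()].
#' @param compartment_pattern suffix-stripping pattern, as in
#'   [normalize_identifier()].
#' @return an object of class `"mapping_result"`: list with `mapped`
#'   (data frame `query_id`, `node_id`), `unmapped` (character vector) and
#'   `mapping_rate` (percent of queries mapped).
#' @export
map_identifiers <- function(queries, graph,
                            compartment_pattern = "_[a-z0-9]{1,2}$") {
  stopifnot(inherits(graph, "compound_graph"))
  if (is.character(queries))
    queries <- data.frame(query_id = queries, id = queries,
                          stringsAsFactors = FALSE)
  if (!is.data.frame(queries) || !"query_id" %in% names(queries))
    stop("'queries' must be a character vector or a data frame with a query_id column")
  if (nrow(queries) == 0L)
    stop("empty query list: mapping rate is undefined")
  if (anyDuplicated(queries$query_id))
    stop("duplicate query ids: ",
         paste(unique(queries$query_id[duplicated(queries$query_id)]),
               collapse = ", "))

  nodes <- graph$nodes
  norm <- function(x) normalize_identifier(x, compartment_pattern)
  # lookup tables per identifier type, in priority order
  lut_id <- stats::setNames(nodes$id, norm(nodes$id))
  lut_name <- stats::setNames(nodes$id, norm(nodes$name))
  ext <- strsplit(ifelse(is.na(nodes$external_ids), "", nodes$external_ids), ";")
  lut_ext <- stats::setNames(rep(nodes$id, lengths(ext)),
                             norm(unlist(ext)))
  luts <- list(lut_id, lut_name, lut_ext)
  qcols <- intersect(c("id", "name", "external_ids"), names(queries))
  if (length(qcols) == 0L) qcols <- "query_id"

  hit <- rep(NA_character_, nrow(queries))
  for (lut in luts) {
    lut <- lut[!duplicated(names(lut)) & nzchar(names(lut))]
    for (qc in qcols) {
      keys <- norm(queries[[qc]])
      miss <- is.na(hit)
      found <- miss & keys %in% names(lut)
      hit[found] <- lut[keys[found]]
    }
  }
  mapped <- data.frame(query_id = queries$query_id[!is.na(hit)],
                       node_id = hit[!is.na(hit)],
                       stringsAsFactors = FALSE)
  structure(list(mapped = mapped,
                 unmapped = queries$query_id[is.na(hit)],
                 mapping_rate = 100 * nrow(mapped) / nrow(queries)),
            class = "mapping_result")
}

#' @export
print.mapping_result <- function(x, ...) {
  n <- nrow(x$mapped) + length(x$unmapped)
  cat(sprintf("<mapping_result> %d of %d queries mapped (%.1f%%)\n",
              nrow(x$mapped), n, x$mapping_rate))
  invisible(x)
}

#' Pathway over-representation analysis
#'
#' Right-tailed hypergeometric test (equivalently the right-tailed Fisher
#' exact test) of whether the selected metabolites contain more members of
#' each pathway than expected by chance when drawing from the universe.
#' For a pathway with \eqn{K} mappable members in a universe of size
#' \eqn{N}, of which \eqn{k} fall among the \eqn{n} selected,
#' \eqn{p = P(X \ge k)} for \eqn{X} hypergeometric. Pathways with no
#' member in the universe are skipped; Benjamini-Hochberg q-values are
#' computed across all tested pathways.
#'
#' @param selected character vector of selected node ids (must be a subset
#'   of `universe`).
#' @param universe character vector of background node ids (typically all
#'   metabolites of the network after compartment collapse).
#' @param pathways named list, pathway id -> character vector of node ids.
#' @return an object of classes `"ora_result"` and `data.frame`, sorted by
#'   q then p then pathway id, with columns `pathway`, `K` (pathway size
#'   within the universe), `k` (overlap with the selection), `p_value`,
#'   `q_value`, `neg_log10_q` (3-decimal display value).
#' @export
ora <- function(selected, universe, pathways) {
  selected <- unique(as.character(selected))
  universe <- unique(as.character(universe))
  extra <- setdiff(selected, universe)
  if (length(extra))
    stop("selected ids outside the universe: ", paste(extra, collapse = ", "))
  if (!is.list(pathways) || is.null(names(pathways)))
    stop("'pathways' must be a named list of node-id sets")
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(pathways), function(pw) {
    members <- intersect(unique(as.character(pathways[[pw]])), universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(members, selected))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, K = K, k = k, p_value = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    stop("no pathway has any member in the universe")
  res <- do.call(rbind, rows)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res$neg_log10_q <- neg_log10(res$q_value)
  res <- res[order(res$q_value, res$p_value, res$pathway), ]
  rownames(res) <- NULL
  class(res) <- c("ora_result", class(res))
  res
}

#' Minus log10 of a p-value or threshold
#'
#' Display transform used in over-representation bar charts; the 5 percent
#' significance threshold maps to 1.301. Values are rounded to 3 decimals
#' for reporting, so significance at q <= 0.05 corresponds exactly to a
#' displayed value >= 1.301.
#'
#' @param p numeric vector in `(0, 1]`.
#' @return `round(-log10(p), 3)`.
#' @export
neg_log10 <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("'p' must lie in (0, 1]")
  round(-log10(p), 3L)
}

#' Write an over-representation report
#'
#' @param result an [ora()] result.
#' @param path output file (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_ora_report <- function(result, path) {
  stopifnot(inherits(result, "ora_result"))
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
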