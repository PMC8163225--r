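#' Relative block influences of a NetPCA model
#'
#' Decomposes each component's variance over the matrices of the network:
#' the influence of matrix \eqn{(g,b)} on component \eqn{a} is
#' \deqn{\frac{\|t_{ga} p_{ba}'\|_F^2}{\sum_{(g',b')} \|t_{g'a} p_{b'a}'\|_F^2}
#'   \times 100,}
#' i.e. the share of the component's fitted sum of squares carried by that
#' matrix. Influences sum to 100 within each component, which gives an
#' objective reading of which cohort/assay combinations drive each global
#' trend.
#'
#' @param model a [netpca()] fit.
#' @param components integer vector of components to report (default all).
#' @return data frame with columns `row_class`, `col_class`, `component`,
#'   `influence` (percent).
#' @export
block_influence <- function(model, components = seq_len(model$ncomp)) {
  stopifnot(inherits(model, "netpca"))
  components <- as.integer(components)
  if (any(components < 1L | components > model$ncomp))
    stop("component index out of range (model has ", model$ncomp, ")")
  net <- model$network
  rc <- vapply(net$matrices, `[[`, character(1), "row_class")
  cc <- vapply(net$matrices, `[[`, character(1), "col_class")
  out <- do.call(rbind, lapply(components, function(a) {
    ss <- mapply(function(g, b)
      sum(model$scores[[g]][, a]^2) * sum(model$loadings[[b]][, a]^2),
      rc, cc)
    data.frame(row_class = rc, col_class = cc, component = a,
               influence = 100 * ss / sum(ss),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out
}

#' Per-variable explained variance across components
#'
#' The metabolite-centric reading of a NetPCA model: for variable \eqn{v}
#' of column class \eqn{b}, the percent of that variable's total (scaled)
#' variance explained by component \eqn{a} is
#' \deqn{\frac{\sum_g \|t_{ga}\|^2 \, p_{bav}^2}
#'   {\sum_g \sum_i X_{gb}[i,v]^2} \times 100,}
#' with the denominator taken over the unit-variance-scaled matrices the
#' model was fitted to. The cumulative column is the running sum over
#' components; ranking variables by their percent on a component of
#' interest gives a direct extraction of the corresponding biological
#' trend (see [select_markers()]).
#'
#' @param model a [netpca()] fit.
#' @return data frame with columns `var_id`, `col_class`, `component`,
#'   `percent`, `cumulative`.
#' @export
variable_explained_variance <- function(model) {
  stopifnot(inherits(model, "netpca"))
  net <- model$network
  rc <- vapply(net$matrices, `[[`, character(1), "row_class")
  cc <- vapply(net$matrices, `[[`, character(1), "col_class")
  out <- list()
  for (b in names(model$loadings)) {
    vars <- rownames(model$loadings[[b]])
    # denominator: total squared intensity of each variable over its block
    denom <- 0
    score_ss <- matrix(0, 1L, model$ncomp)
    for (i in which(cc == b)) {
      g <- rc[i]
      denom <- denom + colSums(net$matrices[[i]]$values^2)
      score_ss <- score_ss + colSums(model$scores[[g]]^2)
    }
    P2 <- model$loadings[[b]]^2                      # n_var x ncomp
    pct <- sweep(P2, 2L, drop(score_ss), "*")        # numerator
    pct <- sweep(pct, 1L, denom, "/") * 100
    pct[denom == 0, ] <- 0
    out[[b]] <- data.frame(
      var_id = rep(vars, model$ncomp),
      col_class = b,
      component = rep(seq_len(model$ncomp), each = length(vars)),
      percent = as.vector(pct),
      cumulative = as.vector(t(apply(pct, 1L, cumsum))),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("variable_variance", class(res))
  res
}

#' Select marker variables by explained-variance threshold
#'
#' Returns the variables accounting for at least `threshold` percent of
#' their own total variance on the requested component, the rule used to
#' shortlist metabolites tracking a trend of interest. The default 20
#' percent threshold is inclusive (a variable at exactly 20.0 is
#' selected). Results are ordered by descending percent, ties broken by
#' variable id.
#'
#' @param table output of [variable_explained_variance()].
#' @param component component of interest (default 1).
#' @param threshold percent threshold in `[0, 100]`; default 20.
#' @return character vector of variable ids.
#' @export
select_markers <- function(table, component = 1L, threshold = 20) {
  if (!is.data.frame(table) ||
      !all(c("var_id", "component", "percent") %in% names(table)))
    stop("'table' must be the output of variable_explained_variance()")
  if (length(threshold) != 1L || threshold < 0 || threshold > 100)
    stop("'threshold' must lie in [0, 100]")
  sub <- table[table$component == as.integer(component) &
               table$percent >= threshold, c("var_id", "percent")]
  sub <- sub[order(-sub$percent, sub$var_id), ]
  sub$var_id
}

# error-check helper: a variable id must exist in an explained-variance table
assert_known_variable <- function(table, var_id) {
  if (!var_id %in% table$var_id)
    stop("unknown variable id: ", var_id)
  invisible(TRUE)
}

#' Export a fitted NetPCA model as delimited tables
#'
#' Writes scores (one file per row class), loadings (one file per column
#' class), component variances, the block-influence table and the
#' per-variable explained-variance table to a directory.
#'
#' @param model a [netpca()] fit.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
export_netpca <- function(model, dir) {
  stopifnot(inherits(model, "netpca"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wt <- function(df, fn) {
    p <- file.path(dir, fn)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  for (g in names(model$scores)) {
    s <- model$scores[[g]]
    df <- data.frame(obs_id = rownames(s), s, check.names = FALSE)
    colnames(df)[-1L] <- paste0("PC", seq_len(ncol(s)))
    paths <- c(paths, wt(df, paste0("scores_", gsub("[^A-Za-z0-9_-]", "_", g), ".tsv")))
  }
  for (b in names(model$loadings)) {
    L <- model$loadings[[b]]
    df <- data.frame(var_id = rownames(L), L, check.names = FALSE)
    colnames(df)[-1L] <- paste0("PC", seq_len(ncol(L)))
    paths <- c(paths, wt(df, paste0("loadings_", gsub("[^A-Za-z0-9_-]", "_", b), ".tsv")))
  }
  paths <- c(paths,
    wt(data.frame(component = seq_len(model$ncomp),
                  percent_variance = model$component_variance),
       "component_variance.tsv"),
    wt(block_influence(model), "block_influence.tsv"),
    wt(variable_explained_variance(model), "variable_explained_variance.tsv"))
  invisible(paths)
}
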