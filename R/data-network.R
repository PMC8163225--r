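#' Construct a data matrix node
#'
#' A `data_matrix` is one observations-by-variables intensity table tagged
#' with a *row class* (the observation set it belongs to, e.g. a
#' cohort-timepoint such as `"preHD"`) and a *column class* (the variable
#' block, e.g. an LC-MS setup such as `"RPLC+"`). Matrices sharing a row
#' class must carry identical observation identifiers in identical order;
#' matrices sharing a column class must carry identical variable
#' identifiers. These tags are what [data_network()] turns into links.
#'
#' @param values numeric matrix, observations in rows, variables in columns.
#'   No missing values are allowed: impute or drop upstream (see
#'   [qc_ratio_filter()] and [loess_normalize()]).
#' @param row_class single string labelling the observation set.
#' @param col_class single string labelling the variable block.
#' @param obs_ids,var_ids identifiers; default to the dimnames of `values`.
#' @return an object of class `"data_matrix"`.
#' @seealso [data_network()], [uv_scale()]
#' @export
data_matrix <- function(values, row_class, col_class,
                        obs_ids = rownames(values),
                        var_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("'values' must have at least one row and one column")
  if (anyNA(values))
    stop("missing values are not supported; impute or drop during preprocessing")
  if (!is.character(row_class) || length(row_class) != 1L || !nzchar(row_class))
    stop("'row_class' must be a non-empty string")
  if (!is.character(col_class) || length(col_class) != 1L || !nzchar(col_class))
    stop("'col_class' must be a non-empty string")
  if (is.null(obs_ids)) obs_ids <- paste0("obs", seq_len(nrow(values)))
  if (is.null(var_ids)) var_ids <- paste0("var", seq_len(ncol(values)))
  obs_ids <- as.character(obs_ids); var_ids <- as.character(var_ids)
  if (length(obs_ids) != nrow(values) || anyDuplicated(obs_ids))
    stop("'obs_ids' must be unique and match nrow(values)")
  if (length(var_ids) != ncol(values) || anyDuplicated(var_ids))
    stop("'var_ids' must be unique and match ncol(values)")
  dimnames(values) <- list(obs_ids, var_ids)
  structure(list(values = values, row_class = row_class,
                 col_class = col_class),
            class = "data_matrix")
}

#' @export
print.data_matrix <- function(x, ...) {
  cat(sprintf("<data_matrix> %s / %s: %d observations x %d variables\n",
              x$row_class, x$col_class, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.data_matrix <- function(x) dim(x$values)

#' Assemble a network of linked data matrices
#'
#' Builds the incidence structure over a list of [data_matrix()] objects:
#' every pair of matrices with the same row class is joined by a
#' *shared-rows* link, every pair with the same column class by a
#' *shared-columns* link. Those links are the constraints that [netpca()]
#' enforces (common scores per row class, common loadings per column
#' class). Validation fails loudly on identifier or dimension mismatches
#' within a class and on duplicated (row class, column class) positions; a
#' disconnected network is legal but reported with a warning because the
#' components then decompose independently.
#'
#' @param matrices list of [data_matrix()] objects (at least one).
#' @return an object of class `"data_network"` with elements
#'   `matrices` (named `"row_class.col_class"`), `row_classes`,
#'   `col_classes`, and `incidence` — a square integer matrix over the
#'   matrices with 0 = no link, 1 = shared rows, 2 = shared columns.
#' @examples
#' m1 <- data_matrix(matrix(rnorm(12), 3), "grpA", "block1")
#' m2 <- data_matrix(matrix(rnorm(12), 3, dimnames = dimnames(m1$values)),
#'                   "grpA", "block2")
#' net <- data_network(list(m1, m2))
#' net
#' @export
data_network <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 1L)
    stop("'matrices' must be a non-empty list of data_matrix objects")
  if (!all(vapply(matrices, inherits, logical(1), "data_matrix")))
    stop("every element of 'matrices' must be a data_matrix")

  rc <- vapply(matrices, `[[`, character(1), "row_class")
  cc <- vapply(matrices, `[[`, character(1), "col_class")
  key <- paste(rc, cc, sep = ".")
  if (anyDuplicated(key))
    stop("duplicate (row_class, col_class) position(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  names(matrices) <- key

  n <- length(matrices)
  # identifier consistency within each class
  for (g in unique(rc)) {
    idx <- which(rc == g)
    ref <- rownames(matrices[[idx[1L]]]$values)
    for (i in idx[-1L]) {
      if (!identical(rownames(matrices[[i]]$values), ref))
        stop(sprintf("observation ids differ within row_class '%s': %s vs %s",
                     g, key[idx[1L]], key[i]))
    }
  }
  for (b in unique(cc)) {
    idx <- which(cc == b)
    ref <- colnames(matrices[[idx[1L]]]$values)
    for (i in idx[-1L]) {
      if (!identical(colnames(matrices[[i]]$values), ref))
        stop(sprintf("variable ids differ within col_class '%s': %s vs %s",
                     b, key[idx[1L]], key[i]))
    }
  }

  incidence <- matrix(0L, n, n, dimnames = list(key, key))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (rc[i] == rc[j]) incidence[i, j] <- 1L
    else if (cc[i] == cc[j]) incidence[i, j] <- 2L
  }

  net <- structure(list(matrices = matrices,
                        row_classes = unique(rc),
                        col_classes = unique(cc),
                        incidence = incidence),
                   class = "data_network")
  nc <- n_connected_components(incidence > 0L)
  if (nc > 1L)
    warning(sprintf("data network has %d disconnected components; %s",
                    nc, "components decompose independently"))
  net
}

# connected components of a logical adjacency matrix (BFS)
n_connected_components <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(0L)
  seen <- rep(FALSE, n)
  comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  comps
}

#' @export
print.data_network <- function(x, ...) {
  cat(sprintf("<data_network> %d matrices, %d row classes, %d column classes\n",
              length(x$matrices), length(x$row_classes), length(x$col_classes)))
  cat(sprintf("  %d shared-row links, %d shared-column links\n",
              sum(x$incidence == 1L) / 2L, sum(x$incidence == 2L) / 2L))
  invisible(x)
}

#' @export
length.data_network <- function(x) length(x$matrices)

# stack all matrices of one column class (rows = all observations of that block)
stack_col_class <- function(network, b) {
  mats <- network$matrices[vapply(network$matrices, `[[`, character(1),
                                  "col_class") == b]
  do.call(rbind, lapply(mats, `[[`, "values"))
}

#' Unit-variance scale a data network
#'
#' Centers and scales every variable to mean 0 and sample (n-1) standard
#' deviation 1, where the statistics are computed over the vertical
#' concatenation of *all* matrices sharing that variable's column class —
#' across groups and timepoints, never per matrix. Per-matrix centering
#' would erase between-group mean differences, which are exactly what the
#' leading component of a [netpca()] fit is meant to capture.
#'
#' @param network a [data_network()].
#' @param drop_constant if `TRUE`, zero-variance variables are dropped from
#'   every matrix of their column class; if `FALSE` (default) they raise an
#'   error listing the offending ids.
#' @param tol variance below which a variable counts as constant.
#' @return list with elements `network` (the scaled [data_network()]) and
#'   `scaling` (class `"uv_scaling"`: per column class, a data frame of
#'   `var_id`, `mean`, `sd`, computed on the input).
#' @export
uv_scale <- function(network, drop_constant = FALSE, tol = 1e-12) {
  stopifnot(inherits(network, "data_network"))
  scaling <- list()
  mats <- network$matrices
  cc <- vapply(mats, `[[`, character(1), "col_class")
  for (b in network$col_classes) {
    big <- stack_col_class(network, b)
    mu <- colMeans(big)
    sdv <- apply(big, 2L, stats::sd)
    bad <- which(sdv < sqrt(tol) | !is.finite(sdv))
    if (length(bad)) {
      if (!drop_constant)
        stop("zero-variance variable(s) in col_class '", b, "': ",
             paste(colnames(big)[bad], collapse = ", "),
             " (set drop_constant = TRUE to remove them)")
      mu <- mu[-bad]; sdv <- sdv[-bad]
    }
    keep <- names(mu)
    if (length(keep) == 0L)
      stop("all variables of col_class '", b, "' are constant")
    for (i in which(cc == b)) {
      v <- mats[[i]]$values[, keep, drop = FALSE]
      mats[[i]]$values <- sweep(sweep(v, 2L, mu, "-"), 2L, sdv, "/")
    }
    scaling[[b]] <- data.frame(var_id = keep, mean = unname(mu),
                               sd = unname(sdv), stringsAsFactors = FALSE)
  }
  scaled <- network
  scaled$matrices <- mats
  class(scaling) <- "uv_scaling"
  list(network = scaled, scaling = scaling)
}

#' @export
print.uv_scaling <- function(x, ...) {
  cat("<uv_scaling> per-variable mean/sd for",
      length(x), "column class(es)\n")
  invisible(x)
}

#' Read a data network from a matrix manifest
#'
#' The manifest is a tab-delimited file with columns `path`, `row_class`,
#' `col_class`; each `path` (relative to the manifest's directory unless
#' absolute) is a delimited table whose first column holds observation ids
#' and whose header row holds variable ids. Comma- and tab-separated files
#' are recognised by extension (`.csv` vs anything else).
#'
#' @param manifest path to the manifest file.
#' @return a [data_network()].
#' @export
read_matrix_manifest <- function(manifest) {
  man <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  need <- c("path", "row_class", "col_class")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(manifest)
  mats <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    if (!file.exists(p)) stop("matrix file not found: ", man$path[i])
    sep <- if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t"
    tab <- utils::read.table(p, header = TRUE, sep = sep, row.names = 1L,
                             check.names = FALSE, stringsAsFactors = FALSE)
    data_matrix(as.matrix(tab), man$row_class[i], man$col_class[i])
  })
  data_network(mats)
}

#' Write a data network as delimited matrices plus a manifest
#'
#' @param network a [data_network()].
#' @param dir output directory (created if needed).
#' @param sep field separator for the matrix files (default tab).
#' @return the manifest path, invisibly.
#' @export
write_data_network <- function(network, dir, sep = "\t") {
  stopifnot(inherits(network, "data_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(names(network$matrices), function(k) {
    m <- network$matrices[[k]]
    fn <- paste0(gsub("[^A-Za-z0-9_.-]", "_", k), ".tsv")
    df <- data.frame(obs_id = rownames(m$values), m$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, fn), sep = sep, quote = FALSE,
                       row.names = FALSE)
    data.frame(path = fn, row_class = m$row_class, col_class = m$col_class,
               stringsAsFactors = FALSE)
  })
  man <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.tsv")
  utils::write.table(man, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mp)
}
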