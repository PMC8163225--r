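#' @export
print.netpca <- function(x, digits = 3L, ...) {
  cat(sprintf("NetPCA model: %d component(s) over %d matrices (%d row classes x %d column classes)\n",
              x$ncomp, length(x$network$matrices),
              length(x$scores), length(x$loadings)))
  cv <- round(x$component_variance, digits)
  cat("Percent of total network variance per component:\n")
  print(stats::setNames(cv, paste0("PC", seq_along(cv))))
  if (!all(x$converged))
    cat("Note: component(s)", paste(which(!x$converged), collapse = ", "),
        "did not reach the convergence tolerance.\n")
  invisible(x)
}

#' Summarize a NetPCA model
#'
#' Reports per-component explained variance and the block-influence
#' decomposition (percent of each component's variance attributable to each
#' matrix of the network).
#'
#' @param object a [netpca()] fit.
#' @param ... unused.
#' @return an object of class `"summary.netpca"`.
#' @export
summary.netpca <- function(object, ...) {
  structure(list(
    ncomp = object$ncomp,
    component_variance = object$component_variance,
    cumulative_variance = cumsum(object$component_variance),
    influence = block_influence(object),
    iterations = object$iterations,
    converged = object$converged
  ), class = "summary.netpca")
}

#' @export
print.summary.netpca <- function(x, digits = 2L, ...) {
  cat("NetPCA model summary\n")
  tab <- rbind(`% variance` = x$component_variance,
               `% cumulative` = x$cumulative_variance)
  colnames(tab) <- paste0("PC", seq_len(x$ncomp))
  print(round(tab, digits))
  cat("\nRelative block influences (% of component variance per matrix):\n")
  inf <- x$influence
  for (a in seq_len(x$ncomp)) {
    sub <- inf[inf$component == a, ]
    wide <- stats::xtabs(influence ~ row_class + col_class, data = sub)
    cat(sprintf("\nComponent %d:\n", a))
    print(round(unclass(wide), digits))
  }
  invisible(x)
}

#' Extract NetPCA loadings
#'
#' @param object a [netpca()] fit.
#' @param ... unused.
#' @return matrix of loadings with one row per variable (stacked over
#'   column classes, row names are variable ids) and one column per
#'   component; the column class of each variable is attached as the
#'   `"col_class"` attribute.
#' @export
coef.netpca <- function(object, ...) {
  out <- do.call(rbind, object$loadings)
  rownames(out) <- unlist(lapply(object$loadings, rownames), use.names = FALSE)
  colnames(out) <- paste0("PC", seq_len(object$ncomp))
  attr(out, "col_class") <- rep(names(object$loadings),
                                vapply(object$loadings, nrow, integer(1)))
  out
}

#' Project new observations onto a fitted NetPCA model
#'
#' New observations must provide intensity matrices for (a subset of) the
#' model's column classes, with identical variable ids. The stored
#' unit-variance scaling is applied before projection; scores are the
#' least-squares projections \eqn{t = \sum_b X_b p_b / \sum_b \|p_b\|^2}
#' over the supplied blocks.
#'
#' @param object a [netpca()] fit.
#' @param newdata either a [data_network()] (scores are returned per row
#'   class) or a named list of numeric matrices keyed by column class.
#' @param ... unused.
#' @return a matrix of scores (observations x components), or a named list
#'   of such matrices when `newdata` is a network.
#' @export
predict.netpca <- function(object, newdata, ...) {
  if (inherits(newdata, "data_network")) {
    out <- lapply(newdata$row_classes, function(g) {
      mats <- newdata$matrices[vapply(newdata$matrices, `[[`, character(1),
                                      "row_class") == g]
      blocks <- lapply(mats, `[[`, "values")
      names(blocks) <- vapply(mats, `[[`, character(1), "col_class")
      predict(object, blocks)
    })
    names(out) <- newdata$row_classes
    return(out)
  }
  if (!is.list(newdata) || is.null(names(newdata)))
    stop("'newdata' must be a data_network or a named list of matrices keyed by column class")
  unknown <- setdiff(names(newdata), names(object$loadings))
  if (length(unknown))
    stop("unknown column class(es): ", paste(unknown, collapse = ", "))
  nr <- unique(vapply(newdata, nrow, integer(1)))
  if (length(nr) != 1L)
    stop("all blocks must have the same number of rows")
  num <- matrix(0, nr, object$ncomp)
  den <- numeric(object$ncomp)
  for (b in names(newdata)) {
    X <- as.matrix(newdata[[b]])
    L <- object$loadings[[b]]
    if (ncol(X) != nrow(L) || !identical(colnames(X), rownames(L)))
      stop("variables of block '", b, "' do not match the model")
    if (!is.null(object$scaling)) {
      st <- object$scaling[[b]]
      X <- sweep(sweep(X, 2L, st$mean, "-"), 2L, st$sd, "/")
    }
    num <- num + X %*% L
    den <- den + colSums(L^2)
  }
  out <- sweep(num, 2L, den, "/")
  colnames(out) <- paste0("PC", seq_len(object$ncomp))
  out
}

#' @export
fitted.netpca <- function(object, ...) {
  net <- object$network
  out <- lapply(net$matrices, function(m) {
    T <- object$scores[[m$row_class]]
    P <- object$loadings[[m$col_class]]
    tcrossprod(T, P)
  })
  names(out) <- names(net$matrices)
  out
}

#' @export
residuals.netpca <- function(object, ...) {
  fit <- fitted(object)
  out <- lapply(names(fit), function(k)
    object$network$matrices[[k]]$values - fit[[k]])
  names(out) <- names(fit)
  out
}

#' Score plot of a NetPCA model
#'
#' Scatter plot of two global components with observations coloured by row
#' class, the standard way to read group separation off the model.
#'
#' @param x a [netpca()] fit.
#' @param components length-2 integer vector of components to display.
#' @param col optional named vector of colours per row class.
#' @param legend_pos position keyword for the legend, or `NA` to suppress.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.netpca <- function(x, components = c(1L, 2L), col = NULL,
                        legend_pos = "topright", ...) {
  if (length(components) != 2L || any(components > x$ncomp))
    stop("'components' must name two fitted components")
  G <- names(x$scores)
  if (is.null(col))
    col <- stats::setNames(grDevices::hcl.colors(length(G), "Dark 3"), G)
  a <- components[1L]; b <- components[2L]
  xs <- unlist(lapply(x$scores, function(s) s[, a]), use.names = FALSE)
  ys <- unlist(lapply(x$scores, function(s) s[, b]), use.names = FALSE)
  grp <- rep(G, vapply(x$scores, nrow, integer(1)))
  graphics::plot(xs, ys, col = col[grp], pch = 19,
       xlab = sprintf("PC%d (%.1f%%)", a, x$component_variance[a]),
       ylab = sprintf("PC%d (%.1f%%)", b, x$component_variance[b]), ...)
  graphics::abline(h = 0, v = 0, col = "grey80", lty = 3L)
  if (!is.na(legend_pos))
    graphics::legend(legend_pos, legend = G, col = col[G], pch = 19,
                     cex = 0.7, bty = "n")
  invisible(x)
}
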