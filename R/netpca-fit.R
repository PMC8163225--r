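#' Fit a network principal component analysis model
#'
#' Extracts global principal components from a [data_network()]: a
#' collection of observations-by-variables matrices whose shared-row and
#' shared-column links become constraints of the decomposition. Every
#' matrix \eqn{X_{gb}} (row class \eqn{g}, column class \eqn{b}) is
#' approximated, component by component, as the rank-one product
#' \eqn{t_g p_b'} of a score vector common to all matrices of its row
#' class and a loading vector common to all matrices of its column class.
#' Component \eqn{a} minimizes
#' \deqn{\sum_{(g,b)} \| X_{gb} - t_{ga} p_{ba}' \|_F^2}
#' subject to unit Euclidean norm of the concatenated loading vector, via
#' alternating least squares:
#' \deqn{t_g \leftarrow \sum_b X_{gb} p_b \Big/ \sum_b \|p_b\|^2, \qquad
#'       p_b \leftarrow \sum_g X_{gb}' t_g \Big/ \sum_g \|t_g\|^2,}
#' followed by global renormalization of the concatenated \eqn{p}. After
#' convergence each matrix is deflated by its fitted rank-one term and the
#' next component is extracted from the residuals. On a single-matrix
#' network the procedure reduces exactly to ordinary PCA (truncated SVD).
#'
#' Scores carry the variance (loadings are unit-norm overall), which makes
#' the per-matrix variance decomposition of [block_influence()]
#' well-defined. Each component is sign-fixed so that the loading entry of
#' largest magnitude is positive.
#'
#' @param network a [data_network()]. Validated on construction.
#' @param ncomp number of components to extract. Must not exceed the
#'   smallest per-row-class observation count nor the total variable count.
#' @param scale if `TRUE` (default) the network is unit-variance scaled
#'   with [uv_scale()] before fitting; the scaling is stored in the model
#'   and reapplied by [predict.netpca()].
#' @param tol convergence tolerance on the relative change of the
#'   least-squares objective between alternations.
#' @param max_iter maximum alternations per component; non-convergence
#'   yields a warning with iteration diagnostics and a usable model.
#' @param init `"svd"` (default) initializes each block loading from the
#'   leading right singular vector of the row-wise concatenation of its
#'   column class; `"random"` draws standard normal loadings.
#' @param seed integer seed used only when `init = "random"`.
#' @param drop_constant passed to [uv_scale()].
#' @return an object of class `"netpca"`:
#' \describe{
#'   \item{scores}{named list, row class -> (observations x ncomp) matrix.}
#'   \item{loadings}{named list, column class -> (variables x ncomp) matrix;
#'     the concatenation over column classes of each column has norm 1.}
#'   \item{component_variance}{percent of total network variance per
#'     component.}
#'   \item{total_variance}{sum of squared entries of the (scaled) network.}
#'   \item{network}{the scaled network the model was fitted to.}
#'   \item{scaling}{the [uv_scale()] state, or `NULL` if `scale = FALSE`.}
#'   \item{iterations, converged}{per-component ALS diagnostics.}
#' }
#' @seealso [block_influence()], [variable_explained_variance()],
#'   [select_markers()], [plot.netpca()]
#' @examples
#' sim <- generate_cohort(ckd_design(), seed = 42)
#' fit <- netpca(sim$network, ncomp = 2)
#' fit
#' @export
netpca <- function(network, ncomp = 2L, scale = TRUE, tol = 1e-9,
                   max_iter = 500L, init = c("svd", "random"), seed = NULL,
                   drop_constant = FALSE) {
  stopifnot(inherits(network, "data_network"))
  init <- match.arg(init)
  if (length(network$matrices) == 0L) stop("empty network")
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L) stop("'ncomp' must be at least 1")

  scaling <- NULL
  if (scale) {
    sc <- uv_scale(network, drop_constant = drop_constant)
    network <- sc$network
    scaling <- sc$scaling
  }

  mats <- lapply(network$matrices, `[[`, "values")
  rc <- vapply(network$matrices, `[[`, character(1), "row_class")
  cc <- vapply(network$matrices, `[[`, character(1), "col_class")
  G <- network$row_classes
  B <- network$col_classes
  n_obs <- vapply(G, function(g) nrow(mats[[which(rc == g)[1L]]]), integer(1))
  n_var <- vapply(B, function(b) ncol(mats[[which(cc == b)[1L]]]), integer(1))
  if (ncomp > min(n_obs))
    stop("'ncomp' exceeds the smallest row-class observation count (",
         min(n_obs), ")")
  if (ncomp > sum(n_var))
    stop("'ncomp' exceeds the total variable count (", sum(n_var), ")")

  total_ss <- sum(vapply(mats, function(m) sum(m^2), numeric(1)))
  if (total_ss == 0) stop("network is identically zero; nothing to fit")

  # blocks present for each row class / row classes present for each block
  b_of_g <- lapply(G, function(g) cc[rc == g])
  g_of_b <- lapply(B, function(b) rc[cc == b])
  names(b_of_g) <- G; names(g_of_b) <- B
  idx <- function(g, b) which(rc == g & cc == b)

  scores <- lapply(G, function(g) matrix(0, n_obs[[g]], ncomp,
    dimnames = list(rownames(mats[[which(rc == g)[1L]]]), NULL)))
  loadings <- lapply(B, function(b) matrix(0, n_var[[b]], ncomp,
    dimnames = list(colnames(mats[[which(cc == b)[1L]]]), NULL)))
  names(scores) <- G; names(loadings) <- B

  comp_ss <- numeric(ncomp)
  iters <- integer(ncomp)
  conv <- logical(ncomp)
  if (init == "random") {
    if (!is.null(seed)) set.seed(as.integer(seed))
  }

  for (a in seq_len(ncomp)) {
    # initial block loadings
    p <- lapply(B, function(b) {
      big <- do.call(rbind, mats[cc == b])
      if (init == "svd") {
        v <- svd(big, nu = 0L, nv = 1L)$v[, 1L]
      } else {
        v <- stats::rnorm(ncol(big))
      }
      v
    })
    names(p) <- B
    pn <- sqrt(sum(unlist(p)^2))
    p <- lapply(p, `/`, pn)

    obj_prev <- Inf
    t_g <- NULL
    for (it in seq_len(max_iter)) {
      # score update per row class (given the unit-norm loadings)
      t_raw <- lapply(G, function(g) {
        num <- 0; den <- 0
        for (b in b_of_g[[g]]) {
          num <- num + mats[[idx(g, b)]] %*% p[[b]]
          den <- den + sum(p[[b]]^2)
        }
        drop(num) / den
      })
      names(t_raw) <- G
      # loading update per column class, then global renormalization with
      # the norm pushed into the scores. Deflating with this (score,
      # loading) pair makes the concatenated residual exactly orthogonal
      # to the scores, so the variance bookkeeping identity and the
      # component orthogonality hold to machine precision rather than to
      # the convergence tolerance.
      p_raw <- lapply(B, function(b) {
        num <- 0; den <- 0
        for (g in g_of_b[[b]]) {
          num <- num + drop(crossprod(mats[[idx(g, b)]], t_raw[[g]]))
          den <- den + sum(t_raw[[g]]^2)
        }
        num / den
      })
      names(p_raw) <- B
      pn <- sqrt(sum(unlist(p_raw)^2))
      if (pn == 0) break
      p <- lapply(p_raw, `/`, pn)
      t_g <- lapply(t_raw, `*`, pn)

      obj <- 0
      for (g in G) for (b in b_of_g[[g]]) {
        X <- mats[[idx(g, b)]]
        obj <- obj + sum(X^2) - 2 * sum((X %*% p[[b]]) * t_g[[g]]) +
          sum(t_g[[g]]^2) * sum(p[[b]]^2)
      }
      # converged when the objective stalls in relative terms, or is
      # negligible against the total sum of squares (exact fit)
      if ((is.finite(obj_prev) &&
           abs(obj_prev - obj) <= tol * max(obj_prev, .Machine$double.eps)) ||
          obj <= tol * total_ss) {
        iters[a] <- it; conv[a] <- TRUE
        break
      }
      obj_prev <- obj
      iters[a] <- it
    }
    if (!conv[a])
      warning(sprintf(
        "component %d: ALS did not converge in %d iterations (last objective %.6g)",
        a, max_iter, obj_prev))

    # sign convention: largest-magnitude loading entry positive
    pall <- unlist(p)
    if (pall[which.max(abs(pall))] < 0) {
      p <- lapply(p, `-`)
      t_g <- lapply(t_g, `-`)
    }

    fitted_ss <- 0
    for (g in G) {
      pb2 <- sum(vapply(b_of_g[[g]], function(b) sum(p[[b]]^2), numeric(1)))
      fitted_ss <- fitted_ss + sum(t_g[[g]]^2) * pb2
    }
    comp_ss[a] <- fitted_ss

    for (g in G) for (b in b_of_g[[g]]) {
      i <- idx(g, b)
      mats[[i]] <- mats[[i]] - tcrossprod(t_g[[g]], p[[b]])
    }
    for (g in G) scores[[g]][, a] <- t_g[[g]]
    for (b in B) loadings[[b]][, a] <- p[[b]]
  }

  structure(list(
    scores = scores,
    loadings = loadings,
    component_variance = 100 * comp_ss / total_ss,
    component_ss = comp_ss,
    total_variance = total_ss,
    ncomp = ncomp,
    network = network,
    scaling = scaling,
    iterations = iters,
    converged = conv,
    call = match.call()
  ), class = "netpca")
}
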