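test_that("a single-matrix network reduces to the truncated SVD", {
  set.seed(10)
  X <- matrix(rnorm(200), 20, 10)
  net <- data_network(list(data_matrix(X, "g", "b")))
  fit <- netpca(net, ncomp = 3, scale = FALSE, tol = 1e-13, max_iter = 2000)
  sv <- svd(X)
  # component variances match the singular values
  expect_equal(fit$component_variance, 100 * sv$d[1:3]^2 / sum(X^2),
               tolerance = 1e-8)
  # rank-3 reconstruction error matches the truncated SVD
  rec <- fit$scores$g %*% t(fit$loadings$b)
  rec_svd <- sv$u[, 1:3] %*% diag(sv$d[1:3]) %*% t(sv$v[, 1:3])
  expect_equal(sum((X - rec)^2), sum((X - rec_svd)^2), tolerance = 1e-8)
  # leading triplet agrees up to a simultaneous sign flip
  s <- sign(sum(fit$loadings$b[, 1] * sv$v[, 1]))
  expect_equal(fit$loadings$b[, 1], s * sv$v[, 1], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(fit$scores$g[, 1], s * sv$u[, 1] * sv$d[1], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("a noiseless rank-1 network is recovered exactly", {
  fx <- rank1_network()
  fit <- netpca(fx$network, ncomp = 1, scale = FALSE, tol = 1e-13)
  expect_equal(fit$component_variance[1], 100, tolerance = 1e-8)
  # loadings proportional to the planted p, scores to the planted t
  p_hat <- unlist(lapply(names(fx$p), function(b) fit$loadings[[b]][, 1]))
  p_true <- unlist(fx$p)
  expect_equal(abs(cor(p_hat, p_true)), 1, tolerance = 1e-8)
  for (g in names(fx$t))
    expect_equal(abs(cor(fit$scores[[g]][, 1], fx$t[[g]])), 1,
                 tolerance = 1e-8)
})

test_that("the concatenated loading has unit norm and variance books balance", {
  net <- tiny_network()
  sc <- uv_scale(net)$network
  total_before <- sum(vapply(sc$matrices, function(m) sum(m$values^2),
                             numeric(1)))
  fit <- netpca(net, ncomp = 3, tol = 1e-13, max_iter = 2000)
  for (a in seq_len(fit$ncomp)) {
    p <- unlist(lapply(fit$loadings, function(L) L[, a]))
    expect_equal(sum(p^2), 1, tolerance = 1e-10)
  }
  res <- residuals(fit)
  residual_after <- sum(vapply(res, function(m) sum(m^2), numeric(1)))
  expect_equal(total_before, residual_after + sum(fit$component_ss),
               tolerance = 1e-8)
  expect_true(all(fit$component_variance >= 0))
  expect_lte(sum(fit$component_variance), 100 + 1e-8)
})

test_that("successive concatenated score vectors are orthogonal", {
  net <- tiny_network(seed = 7)
  fit <- netpca(net, ncomp = 3, tol = 1e-14, max_iter = 5000)
  S <- do.call(rbind, fit$scores)
  G <- crossprod(S)
  off <- abs(G[upper.tri(G)])
  expect_lt(max(off / diag(G)[1]), 1e-8)
})

test_that("row- and column-class relabeling permutes outputs without changing values", {
  net <- tiny_network(seed = 2)
  fit <- netpca(net, ncomp = 2, tol = 1e-12)
  relabeled <- data_network(lapply(unname(net$matrices), function(m)
    data_matrix(m$values, paste0("z_", m$row_class),
                paste0("z_", m$col_class))))
  fit2 <- netpca(relabeled, ncomp = 2, tol = 1e-12)
  for (g in names(fit$scores))
    expect_equal(fit2$scores[[paste0("z_", g)]], fit$scores[[g]],
                 tolerance = 1e-10)
  for (b in names(fit$loadings))
    expect_equal(fit2$loadings[[paste0("z_", b)]], fit$loadings[[b]],
                 tolerance = 1e-10)
  expect_equal(fit2$component_variance, fit$component_variance,
               tolerance = 1e-10)
})

test_that("random initialization is seed-deterministic", {
  net <- tiny_network(seed = 4)
  f1 <- netpca(net, ncomp = 2, init = "random", seed = 123)
  f2 <- netpca(net, ncomp = 2, init = "random", seed = 123)
  expect_identical(f1$scores, f2$scores)
  expect_identical(f1$loadings, f2$loadings)
})

test_that("sign convention puts the largest loading entry positive", {
  net <- tiny_network(seed = 5)
  fit <- netpca(net, ncomp = 2)
  for (a in 1:2) {
    p <- unlist(lapply(fit$loadings, function(L) L[, a]))
    expect_gt(p[which.max(abs(p))], 0)
  }
})

test_that("preconditions are enforced", {
  net <- tiny_network()
  expect_error(netpca(net, ncomp = 50), "observation count|variable count")
  m <- data_matrix(matrix(0, 3, 2), "g", "b")
  expect_error(netpca(data_network(list(m)), scale = FALSE),
               "identically zero")
})

test_that("projection of the training data reproduces component-1 scores", {
  fx <- rank1_network()
  fit <- netpca(fx$network, ncomp = 1, scale = FALSE, tol = 1e-13)
  proj <- predict(fit, fx$network)
  for (g in names(fit$scores))
    expect_equal(proj[[g]][, 1], fit$scores[[g]][, 1], tolerance = 1e-8,
                 ignore_attr = TRUE)
})
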