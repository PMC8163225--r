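test_that("the CKD cohort design reproduces the study structure", {
  d <- ckd_design()
  expect_equal(nrow(d$row_classes), 10L)
  expect_equal(nrow(d$row_classes) * length(d$blocks), 40L)
  expect_equal(sum(d$row_classes$n), 393L)
  expect_equal(unname(d$blocks), c(88L, 38L, 27L, 65L))
  expect_equal(sum(d$blocks), 218L)
  # timepoint counts per cohort: 1, 1, 2, 3, 3
  expect_equal(as.integer(table(d$row_classes$group)[c("CTRL", "ICKD", "HD",
                                                       "KG", "DV")]),
               c(1L, 1L, 2L, 3L, 3L))
})

test_that("the generated cohort passes validation with the expected link count", {
  sim <- generate_cohort(ckd_design(), seed = 42)
  net <- sim$network
  expect_s3_class(net, "data_network")
  expect_length(net$matrices, 40L)
  # 4 column classes link C(10,2)=45 pairs each, 10 row classes C(4,2)=6:
  # 4*45 + 10*6 = 240 undirected links
  expect_equal(sum(net$incidence > 0) / 2, 240)
  expect_equal(sum(net$incidence == 2L) / 2, 180)
  expect_equal(sum(net$incidence == 1L) / 2, 60)
})

test_that("cohort generation is deterministic in the seed", {
  s1 <- generate_cohort(ckd_design(), seed = 5)
  s2 <- generate_cohort(ckd_design(), seed = 5)
  for (k in names(s1$network$matrices))
    expect_identical(s1$network$matrices[[k]]$values,
                     s2$network$matrices[[k]]$values)
  expect_identical(s1$truth, s2$truth)
})

test_that("zero effect amplitudes leave only noise-level structure", {
  null_design <- ckd_design(severity_levels = c(CTRL = 0),
                            secondary_levels = c(postHD = 0),
                            severity_sd = 0, secondary_sd = 0)
  sim <- generate_cohort(null_design, seed = 42)
  fit <- netpca(sim$network, ncomp = 1)
  # reference: a pure-noise network of the same shape
  noise_design <- ckd_design(severity_levels = c(CTRL = 0),
                             secondary_levels = c(postHD = 0),
                             severity_sd = 0, secondary_sd = 0,
                             severity_frac = 0)
  ref <- netpca(generate_cohort(noise_design, seed = 43)$network, ncomp = 1)
  expect_lt(abs(fit$component_variance[1] - ref$component_variance[1]),
            0.5 * ref$component_variance[1])
  # nothing like the planted-signal fits: component 1 explains only a few %
  expect_lt(fit$component_variance[1], 5)
})

test_that("planted severity and dialysis axes are recovered end to end", {
  sim <- generate_cohort(ckd_design(), seed = 42)
  fit <- netpca(sim$network, ncomp = 2)
  sc1 <- unlist(lapply(names(fit$scores), function(g) fit$scores[[g]][, 1]))
  truth <- unlist(sim$truth$severity[names(fit$scores)])
  expect_gte(abs(cor(sc1, truth)), 0.9)
  # postHD matrices jointly dominate component-2 block influence
  inf <- block_influence(fit, 2)
  per_class <- tapply(inf$influence, inf$row_class, sum)
  expect_equal(names(which.max(per_class)), "postHD")
})

test_that("null variables stay below the marker threshold", {
  sim <- generate_cohort(ckd_design(), seed = 42)
  fit <- netpca(sim$network, ncomp = 2)
  ev <- variable_explained_variance(fit)
  null_vars <- setdiff(unique(ev$var_id),
                       c(sim$truth$severity_vars, sim$truth$secondary_vars))
  pc1 <- ev$percent[ev$component == 1 & ev$var_id %in% null_vars]
  expect_true(all(pc1 < 20))
})

test_that("toy network bookkeeping matches the realized graph", {
  d <- toy_network_design(n_pathways = 5, mets_per_pathway = 6, n_side = 2)
  out <- generate_toy_network(d, seed = 11)
  expect_equal(out$counts$n_nodes, 32L)  # 5*6 + 2
  expect_equal(nrow(out$graph$nodes), out$counts$n_nodes)
  expect_equal(nrow(out$graph$edges), out$counts$n_edges)
  expect_equal(sum(out$graph$edges$carbon), out$counts$n_carbon_edges)
  expect_length(out$labels, 30L)
})

test_that("zero non-carbon fraction makes the carbon filter an identity", {
  d <- toy_network_design(noncarbon_frac = 0)
  out <- generate_toy_network(d, seed = 2)
  filtered <- carbon_filter(out$graph)
  expect_equal(filtered$edges, out$graph$edges)
})

test_that("the default side list strictly lowers the maximum degree", {
  out <- generate_toy_network(toy_network_design(), seed = 11)
  before <- max(graph_degrees(out$graph))
  after <- max(graph_degrees(
    suppressWarnings(remove_side_compounds(out$graph))))
  expect_lt(after, before)
})

test_that("feature-run generation is reproducible and structurally sound", {
  r1 <- generate_feature_run(seed = 7)
  r2 <- generate_feature_run(seed = 7)
  expect_identical(r1$intensities, r2$intensities)
  expect_true(all(table(r1$meta$batch[r1$meta$role == "QC"]) >= 2))
})
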