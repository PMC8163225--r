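# small shared fixtures, built in code

# a tiny two-row-class, two-block network with consistent identifiers
tiny_network <- function(seed = 1) {
  set.seed(seed)
  mk <- function(g, b, n, p) {
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(paste0(g, seq_len(n)), paste0(b, seq_len(p))))
    data_matrix(X, g, b)
  }
  data_network(list(mk("gA", "b1", 5, 4), mk("gA", "b2", 5, 3),
                    mk("gB", "b1", 6, 4), mk("gB", "b2", 6, 3)))
}

# a noiseless rank-1 network X(g,b) = t(g) p(b)'
rank1_network <- function(seed = 3) {
  set.seed(seed)
  t_g <- list(gA = stats::rnorm(7), gB = stats::rnorm(5))
  p_b <- list(b1 = stats::rnorm(4), b2 = stats::rnorm(6))
  mats <- list()
  for (g in names(t_g)) for (b in names(p_b)) {
    X <- outer(t_g[[g]], p_b[[b]])
    dimnames(X) <- list(paste0(g, seq_along(t_g[[g]])),
                        paste0(b, seq_along(p_b[[b]])))
    mats[[paste(g, b)]] <- data_matrix(X, g, b)
  }
  list(network = data_network(unname(mats)), t = t_g, p = p_b)
}

# chain compound graph A - B - ... with unit carbon flags
chain_graph <- function(ids = c("A", "B", "C", "D", "E")) {
  n <- length(ids)
  compound_graph(data.frame(id = ids, stringsAsFactors = FALSE),
                 data.frame(from = ids[-n], to = ids[-1L], carbon = TRUE,
                            stringsAsFactors = FALSE))
}

# a small manually scripted feature run: three QC/dQC pairs in one batch
# with features engineered against the ratio-filter rules
ratio_filter_run <- function() {
  meta <- data.frame(
    sample_id = paste0("inj", 1:9),
    role = c("QC", "dQC", "sample", "sample", "QC", "dQC", "sample",
             "QC", "dQC"),
    batch = 1L, order = 1:9, stringsAsFactors = FALSE)
  qc_rows <- meta$role == "QC"
  dqc_rows <- meta$role == "dQC"
  X <- matrix(100, 9, 4, dimnames = list(NULL, c("good", "high_ratio",
                                                 "wobbly", "low_ratio")))
  X[dqc_rows, "good"] <- 50                      # ratio 0.5, RSD 0
  X[dqc_rows, "high_ratio"] <- 90                # ratio 0.9 -> window fail
  X[dqc_rows, "wobbly"] <- c(20, 50, 80)         # median 0.5, RSD 60%
  X[dqc_rows, "low_ratio"] <- 15                 # ratio 0.15 -> window fail
  feature_run(meta, X)
}
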