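three_nets <- function() {
  list(make_net("nc1-m1,nc1-m2,nc2-m3,nc3-m4", condition_label = "relapse"),
       make_net("nc1-m1,nc2-m3,nc2-m4,nc4-m5", condition_label = "remission"),
       make_net("nc1-m1,nc3-m4,nc2-m4,nc5-m6", condition_label = "control"))
}

test_that("edge Venn partitions match the set-algebra oracle and conserve", {
  nets <- three_nets()
  v <- edge_intersections(nets[[1]], nets[[2]], nets[[3]])
  keys <- lapply(nets, function(n) paste(n$edges$ncrna, n$edges$mrna))
  expect_equal(unclass(v$regions),
               unclass(oracle_venn_regions(keys[[1]], keys[[2]], keys[[3]])))
  expect_equal(sum(v$regions), v$n_union)
  # triple region is inside every pairwise intersection
  expect_lte(v$n_triple, length(intersect(keys[[1]], keys[[2]])))
  expect_lte(v$n_triple, length(intersect(keys[[1]], keys[[3]])))
  # identical networks: everything in the triple region
  vid <- edge_intersections(nets[[1]], nets[[1]], nets[[1]])
  expect_equal(unname(vid$regions["111"]), nrow(nets[[1]]$edges))
  expect_equal(vid$triple_pct, 100)
  # pairwise-disjoint networks: only exclusive regions populated
  d1 <- make_net("nc1-m1"); d2 <- make_net("nc2-m2"); d3 <- make_net("nc3-m3")
  vd <- edge_intersections(d1, d2, d3)
  expect_equal(unname(vd$regions[c("100", "010", "001")]), c(1L, 1L, 1L))
  expect_equal(sum(vd$regions[c("110", "101", "011", "111")]), 0L)
})

test_that("node Venn shows overlap >> edge overlap on rewired cohorts", {
  nets <- three_nets()
  nv <- node_intersections(nets[[1]], nets[[2]], nets[[3]])
  expect_equal(sum(nv$regions), nv$n_union)
  # one empty network zeroes its regions
  e <- ncx_network(data.frame(ncrna = character(), mrna = character(),
                              r = numeric()))
  v0 <- node_intersections(nets[[1]], nets[[2]], e)
  expect_equal(sum(v0$regions[c("001", "101", "011", "111")]), 0L)
  # simulated rewired cohort: same panel, rewired edges
  ch <- generate_cohort(test_sim_config(rewire_fraction = 0.8, seed = 71))
  mat <- preprocess(ch$matrix)
  cn <- lapply(c("relapse", "remission", "control"),
               function(cond) build_condition_network(mat, cond, 0.01))
  ev <- edge_intersections(cn[[1]], cn[[2]], cn[[3]])
  nv2 <- node_intersections(cn[[1]], cn[[2]], cn[[3]])
  expect_gt(nv2$triple_pct, 5 * ev$triple_pct)
})

test_that("status-independent core is the triple intersection", {
  nets <- three_nets()
  core <- status_independent_core(nets[[1]], nets[[2]], nets[[3]])
  expect_identical(paste(core$edges$ncrna, core$edges$mrna), "nc1 m1")
  # core is a subset of each input
  for (n in nets)
    expect_true(all(edge_keys(core) %in% edge_keys(n)))
  # identical networks: core = the network; disjoint: empty
  expect_identical(
    status_independent_core(nets[[1]], nets[[1]], nets[[1]])$edges,
    nets[[1]]$edges)
  expect_identical(nrow(status_independent_core(
    make_net("nc1-m1"), make_net("nc2-m2"), make_net("nc3-m3"))$edges), 0L)
})

test_that("disease-specific network = (relapse & remission) \\ controls", {
  rel <- make_net("nc1-m1,nc1-m2,nc2-m3,nc2-m4", condition_label = "relapse")
  rem <- make_net("nc1-m1,nc1-m2,nc2-m4,nc5-m5", condition_label = "remission")
  ctl <- make_net("nc1-m2,nc9-m9", condition_label = "control")
  dn <- disease_specific_network(rel, rem, ctl)
  # oracle: set algebra on keys
  k <- function(n) paste(n$edges$ncrna, n$edges$mrna)
  expect_setequal(k(dn), setdiff(intersect(k(rel), k(rem)), k(ctl)))
  expect_length(intersect(edge_keys(dn), edge_keys(ctl)), 0)
  # controls superset -> empty; controls empty -> intersection
  expect_identical(nrow(disease_specific_network(rel, rem, rel)$edges), 0L)
  e <- ncx_network(data.frame(ncrna = character(), mrna = character(),
                              r = numeric()))
  expect_setequal(k(disease_specific_network(rel, rem, e)),
                  intersect(k(rel), k(rem)))
})

test_that("largest component follows the stated tie-breaks", {
  # connected network -> itself
  con <- make_net("nc1-m1,nc1-m2")
  expect_identical(largest_component(con)$edges, con$edges)
  # 3-node vs 2-node components
  two <- make_net("nc1-m1,nc1-m2,nc9-m9")
  expect_setequal(network_nodes(largest_component(two)),
                  c("nc1", "m1", "m2"))
  # node-count tie broken by edge count: C4 (4 nodes 4 edges) vs path (4,3)
  tie <- ncx_network(data.frame(
    ncrna = c("a1", "a1", "a2", "a2", "b1", "b1", "b2"),
    mrna = c("x1", "x2", "x1", "x2", "y1", "y2", "y2"),
    r = -0.5))
  expect_setequal(network_nodes(largest_component(tie)),
                  c("a1", "a2", "x1", "x2"))
  # full tie broken by lexicographically smallest node id
  tie2 <- make_net("b1-y1,a1-x1")
  expect_setequal(network_nodes(largest_component(tie2)), c("a1", "x1"))
  # 30-node random forest vs BFS-labeling oracle
  set.seed(81)
  for (seed in 1:3) {
    net <- random_net(6, 18, 14, seed = seed + 100)
    mem <- oracle_components(net$edges)
    best <- names(which.max(table(mem)))
    expect_setequal(network_nodes(largest_component(net)),
                    names(mem)[mem == as.integer(best)])
  }
  expect_error(largest_component(ncx_network(data.frame(
    ncrna = character(), mrna = character(), r = numeric()))), "empty")
})

fake_summary <- function(...) {
  v <- list(...)
  structure(list(n_connected_components = v[[1]],
                 network_centralization = v[[2]],
                 characteristic_path_length = v[[3]],
                 average_degree = v[[4]], network_heterogeneity = v[[5]],
                 powerlaw_exponent = v[[6]], n_nodes = 10L, n_edges = 12L,
                 size = 22L), class = "ncx_topology")
}

test_that("descriptor PCA matches an eigendecomposition oracle", {
  s <- list(fake_summary(1, 0.2, 2.5, 3.1, 1.2, -1.3),
            fake_summary(3, 0.4, 3.0, 2.2, 1.5, -1.6),
            fake_summary(2, 0.1, 2.2, 4.0, 0.9, -1.1))
  p <- topology_pca(s)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-12)
  # oracle: project standardized matrix on covariance eigenvectors
  x <- t(vapply(s, function(z) unlist(z[1:6]), numeric(6)))
  z <- scale(x)
  eig <- eigen(stats::cov(z))
  proj <- z %*% eig$vectors
  for (j in seq_len(ncol(p$coordinates)))
    expect_equal(abs(unname(p$coordinates[, j])), abs(unname(proj[, j])),
                 tolerance = 1e-8)
  # two networks -> one axis with all the variance
  p2 <- topology_pca(s[1:2])
  expect_equal(p2$variance_fraction[1], 1, tolerance = 1e-12)
  # identical pair is coincident in the projection
  p3 <- topology_pca(list(s[[1]], s[[1]], s[[2]]))
  expect_equal(p3$coordinates[1, ], p3$coordinates[2, ], tolerance = 1e-10)
  expect_error(topology_pca(s[1]), "at least 2")
  # constant descriptor dropped with a warning
  s2 <- lapply(s, function(z) { z$n_connected_components <- 2; z })
  expect_warning(topology_pca(s2), "n_connected_components")
})

test_that("distribution correlations match per-pair brute force", {
  nets <- three_nets()
  dc <- distribution_correlations(nets[[1]], nets[[2]], nets[[3]])
  for (m in dc) {
    expect_equal(diag(m), setNames(rep(1, 3), colnames(m)))
    expect_equal(m, t(m))
  }
  # brute force one off-diagonal entry of the degree matrix
  h1 <- degree_distribution(nets[[1]]); h2 <- degree_distribution(nets[[2]])
  bins <- sort(union(h1$degree, h2$degree))
  a <- h1$count[match(bins, h1$degree)]; a[is.na(a)] <- 0
  b <- h2$count[match(bins, h2$degree)]; b[is.na(b)] <- 0
  expect_equal(dc$degree["relapse", "remission"], oracle_pearson(a, b),
               tolerance = 1e-12)
  # identical networks correlate at exactly 1
  dci <- distribution_correlations(nets[[1]], nets[[1]], nets[[3]])
  expect_equal(unname(dci$degree[1, 2]), 1)
  # engineered anti-monotone histograms correlate negatively
  expect_lt(oracle_pearson(c(10, 5, 1), c(1, 5, 10)), 0)
})
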