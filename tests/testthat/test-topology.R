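test_that("degree distribution satisfies its identities", {
  # single edge and star
  expect_equal(degree_distribution(make_net("nc1-m1")),
               data.frame(degree = 1L, count = 2L))
  star <- make_net("nc1-m1,nc1-m2,nc1-m3,nc1-m4")
  expect_equal(degree_distribution(star),
               data.frame(degree = c(1L, 4L), count = c(4L, 1L)))
  # 8-node toy vs brute-force tally; degree-sum identity on random nets
  for (seed in 1:4) {
    net <- random_net(3, 5, 7, seed)
    h <- degree_distribution(net)
    tally <- table(table(c(net$edges$ncrna, net$edges$mrna)))
    expect_equal(h$count, as.integer(tally))
    expect_equal(sum(h$degree * h$count), 2 * nrow(net$edges))
    expect_equal(sum(h$count), length(network_nodes(net)))
  }
  expect_error(degree_distribution(ncx_network(
    data.frame(ncrna = character(), mrna = character(), r = numeric()))),
    "empty")
})

test_that("fit_power_law recovers planted exponents", {
  # exactly generated histogram with exponent -1.5
  x <- 1:50
  hist <- data.frame(degree = x, count = round(1000 * x^-1.5))
  fit <- fit_power_law(hist)
  expect_lt(abs(fit$b - (-1.5)), 0.02)
  expect_gt(fit$fit_correlation, 0.999)
  expect_gt(fit$a, 0)
  # flat histogram: slope ~ 0
  flat <- fit_power_law(data.frame(degree = 1:10, count = rep(5L, 10)))
  expect_lt(abs(flat$b), 1e-10)
  # a star has only 2 distinct degrees
  expect_error(fit_power_law(degree_distribution(
    make_net("nc1-m1,nc1-m2,nc1-m3"))), "3 distinct")
})

test_that("betweenness matches trivial closed forms", {
  path <- make_net("nc1-m1,nc2-m1")      # path a-b-c, center m1
  b <- betweenness_centrality(path)
  expect_equal(unname(b["m1"]), 1)
  expect_equal(unname(b[c("nc1", "nc2")]), c(0, 0))
  star <- make_net("nc1-m1,nc1-m2,nc1-m3,nc1-m4,nc1-m5")
  bs <- betweenness_centrality(star)
  expect_equal(unname(bs["nc1"]), 1)
  expect_true(all(bs[paste0("m", 1:5)] == 0))
})

test_that("betweenness and path stats match exhaustive oracles", {
  for (seed in 1:3) {
    net <- random_net(4, 8, 16, seed)   # 12 nodes max
    expect_equal(betweenness_centrality(net)[names(oracle_betweenness(net$edges))],
                 oracle_betweenness(net$edges), tolerance = 1e-12)
    sp <- shortest_path_stats(net)
    osp <- oracle_path_stats(net$edges)
    expect_equal(sp$mean, osp$mean, tolerance = 1e-12)
    expect_equal(sp$hist$count, as.integer(osp$table))
  }
})

test_that("shortest-path trivial cases", {
  one <- shortest_path_stats(make_net("nc1-m1"))
  expect_equal(one$hist, data.frame(length = 1L, count = 1L))
  expect_equal(one$mean, 1)
  p3 <- shortest_path_stats(make_net("nc1-m1,nc2-m1"))
  expect_equal(p3$hist, data.frame(length = c(1L, 2L), count = c(2L, 1L)))
  expect_equal(p3$mean, 4 / 3)
})

test_that("combined centrality is the exact product of its factors", {
  star <- make_net("nc1-m1,nc1-m2,nc1-m3,nc1-m4")
  ct <- combined_centrality(star)
  expect_equal(ct$combined[ct$node == "nc1"], 4)   # betweenness 1 x outdeg 4
  expect_true(all(ct$combined[ct$class == "mRNA"] == 0))
  iso <- make_net("nc1-m1")
  expect_true(all(combined_centrality(iso)$combined == 0))
  for (seed in 1:3) {
    net <- random_net(4, 6, 10, seed)
    ct <- combined_centrality(net)
    btw <- betweenness_centrality(net)
    deg <- table(net$edges$ncrna)
    for (i in seq_len(nrow(ct))) {
      expected <- if (ct$class[i] == "ncRNA")
        btw[ct$node[i]] * deg[[ct$node[i]]] else 0
      expect_equal(ct$combined[i], unname(expected), tolerance = 1e-12)
    }
  }
})

test_that("hub extraction is strict, ncRNA-only, and scales as 2.5%", {
  # one dominant ncRNA among 40
  edges <- data.frame(ncrna = c(rep("hub", 30), paste0("nc", 1:39)),
                      mrna = c(paste0("m", 1:30), paste0("q", 1:39)),
                      r = -0.5)
  ct <- combined_centrality(ncx_network(edges))
  hubs <- top_central_ncrnas(ct)
  expect_identical(hubs$node, "hub")
  expect_true(all(hubs$class == "ncRNA"))
  # all-equal combined values: strict inequality selects nothing
  flat <- combined_centrality(make_net("nc1-m1,nc2-m2,nc3-m3"))
  expect_identical(nrow(top_central_ncrnas(flat)), 0L)
  # 612 simulated ncRNA centralities -> about 15 hubs (2.5%)
  set.seed(61)
  ct2 <- data.frame(node = sprintf("nc%03d", 1:612), class = "ncRNA",
                    outdegree = 1L, betweenness = 0,
                    combined = rexp(612), stringsAsFactors = FALSE)
  n_hubs <- nrow(top_central_ncrnas(ct2, 97.5))
  expect_true(abs(n_hubs - 15) <= 1)
})

test_that("core subnetwork keeps exactly hub-incident edges", {
  net <- make_net("nc1-m1,nc1-m2,nc2-m2,nc2-m3,nc3-m4")
  # hubs = all nodes -> the network itself
  all_core <- core_subnetwork(net, network_nodes(net))
  expect_identical(all_core$edges, net$edges)
  # a single isolated star center -> that star
  expect_identical(core_subnetwork(net, "nc3")$edges$mrna, "m4")
  # two overlapping stars: union of their edges, nc2-m3 via hub nc2
  core <- core_subnetwork(net, c("nc1", "nc2"))
  expect_setequal(paste(core$edges$ncrna, core$edges$mrna),
                  c("nc1 m1", "nc1 m2", "nc2 m2", "nc2 m3"))
  expect_error(core_subnetwork(net, "ghost"), "unknown hub")
})

test_that("descriptors match hand computation for a k=4 star", {
  star <- make_net("nc1-m1,nc1-m2,nc1-m3,nc1-m4")
  # two distinct degrees -> power-law NA warning is expected here
  expect_warning(d <- descriptors(star), "power-law")
  # degrees (4,1,1,1,1): mean 1.6, population variance 1.44
  expect_equal(d$average_degree, 1.6)
  expect_equal(d$network_heterogeneity, sqrt(1.44) / 1.6)
  expect_equal(d$network_centralization, 1)   # stars are maximally central
  expect_equal(d$n_connected_components, 1L)
  expect_equal(d$size, d$n_nodes + d$n_edges)
})

test_that("a ring is fully regular: centralization and heterogeneity 0", {
  # even cycle alternating ncRNA/mRNA (synthetic regular fixture)
  n <- 6
  edges <- data.frame(
    ncrna = paste0("nc", c(1, 1, 2, 2, 3, 3)),
    mrna = paste0("m", c(1, 3, 1, 2, 2, 3)), r = -0.5)
  d <- suppressWarnings(descriptors(ncx_network(edges)))
  expect_equal(d$network_centralization, 0)
  expect_equal(d$network_heterogeneity, 0)
  expect_true(is.na(d$powerlaw_exponent))   # single distinct degree
})

test_that("simulated cohorts yield coexpression-range exponents", {
  exps <- vapply(1:3, function(seed) {
    ch <- generate_cohort(test_sim_config(seed = seed, n_regulators = 40,
                                          n_ncrna = 60, n_mrna = 400))
    net <- build_condition_network(preprocess(ch$matrix), "global", 5e-4)
    descriptors(net)$powerlaw_exponent
  }, 1)
  expect_true(all(exps > -2 & exps < -1))
})
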