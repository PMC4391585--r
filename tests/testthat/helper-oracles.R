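# Independent brute-force oracles for graph quantities, used only on small
# fixtures (<= ~12 nodes). They share no code with the package's paths.

# adjacency list from an edge data frame (columns ncrna, mrna)
oracle_adj <- function(edges) {
  nodes <- sort(unique(c(edges$ncrna, edges$mrna)))
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$ncrna[i]; b <- edges$mrna[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# BFS distances from a source; unreachable = Inf
oracle_bfs <- function(adj, src) {
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[src] <- 0
  frontier <- src
  while (length(frontier)) {
    nxt <- character()
    for (v in frontier) for (w in adj[[v]])
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        nxt <- c(nxt, w)
      }
    frontier <- unique(nxt)
  }
  dist
}

# connected components by repeated BFS; returns membership named vector
oracle_components <- function(edges) {
  adj <- oracle_adj(edges)
  mem <- stats::setNames(rep(NA_integer_, length(adj)), names(adj))
  k <- 0
  for (v in names(adj)) {
    if (!is.na(mem[v])) next
    k <- k + 1
    mem[names(which(is.finite(oracle_bfs(adj, v))))] <- k
  }
  mem
}

# enumerate all shortest paths between two nodes (list of node vectors)
oracle_all_shortest_paths <- function(adj, s, t) {
  dist <- oracle_bfs(adj, s)
  if (is.infinite(dist[t])) return(list())
  walk <- function(v) {
    if (v == s) return(list(s))
    preds <- Filter(function(u) dist[u] == dist[v] - 1 && v %in% adj[[u]],
                    names(adj))
    out <- list()
    for (u in preds)
      for (p in walk(u)) out <- c(out, list(c(p, v)))
    out
  }
  walk(t)
}

# betweenness with per-component (n-1)(n-2)/2 normalization, by exhaustive
# shortest-path enumeration
oracle_betweenness <- function(edges) {
  adj <- oracle_adj(edges)
  nodes <- names(adj)
  raw <- stats::setNames(rep(0, length(nodes)), nodes)
  for (i in seq_along(nodes)) for (j in seq_along(nodes)) {
    if (i >= j) next
    paths <- oracle_all_shortest_paths(adj, nodes[i], nodes[j])
    if (!length(paths)) next
    for (p in paths) {
      inner <- setdiff(p, c(nodes[i], nodes[j]))
      raw[inner] <- raw[inner] + 1 / length(paths)
    }
  }
  mem <- oracle_components(edges)
  csize <- table(mem)
  denom <- as.numeric((csize[mem] - 1) * (csize[mem] - 2) / 2)
  stats::setNames(as.numeric(ifelse(denom > 0, raw / denom, 0)), nodes)
}

# mean and histogram of finite shortest-path lengths over unordered pairs
oracle_path_stats <- function(edges) {
  adj <- oracle_adj(edges)
  nodes <- names(adj)
  lens <- c()
  for (i in seq_along(nodes)) {
    d <- oracle_bfs(adj, nodes[i])
    lens <- c(lens, d[nodes[-seq_len(i)]])
  }
  lens <- lens[is.finite(lens)]
  list(mean = mean(lens), table = table(lens))
}

# 7-region Venn by direct set algebra on key vectors
oracle_venn_regions <- function(a, b, c) {
  only <- function(x, y, z) length(setdiff(setdiff(x, y), z))
  c("100" = only(a, b, c), "010" = only(b, a, c), "001" = only(c, a, b),
    "110" = length(setdiff(intersect(a, b), c)),
    "101" = length(setdiff(intersect(a, c), b)),
    "011" = length(setdiff(intersect(b, c), a)),
    "111" = length(intersect(intersect(a, b), c)))
}

# textbook Pearson correlation, computed from first principles
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# geometric mean of per-column ranks for a score matrix (genes x columns);
# direction "down": rank 1 = most negative score
oracle_rank_product <- function(scores, direction = c("down", "up")) {
  direction <- match.arg(direction)
  rk <- apply(scores, 2, function(col) {
    r <- rank(col, ties.method = "average")
    if (direction == "up") r <- length(col) + 1 - r
    r
  })
  apply(rk, 1, function(r) prod(r)^(1 / length(r)))
}

# convenience: bipartite network from a terse edge string "nc1-m1,nc2-m1"
make_net <- function(edge_str, r = -0.5, condition_label = "derived") {
  pairs <- strsplit(strsplit(edge_str, ",")[[1]], "-")
  edges <- data.frame(ncrna = vapply(pairs, `[`, "", 1),
                      mrna = vapply(pairs, `[`, "", 2),
                      r = r, stringsAsFactors = FALSE)
  ncx_network(edges, sign = if (all(r < 0)) "negative" else "positive",
              condition_label = condition_label)
}

# deterministic random bipartite network for property tests
random_net <- function(n_nc, n_m, n_edges, seed) {
  set.seed(seed)
  all_pairs <- expand.grid(ncrna = sprintf("nc%02d", seq_len(n_nc)),
                           mrna = sprintf("m%02d", seq_len(n_m)),
                           stringsAsFactors = FALSE)
  pick <- all_pairs[sample(nrow(all_pairs), n_edges), ]
  pick$r <- -runif(n_edges, 0.4, 0.9)
  ncx_network(pick, sign = "negative")
}

# small standard cohort config for tests (kept small for runtime)
test_sim_config <- function(...) {
  defaults <- list(n_patients = 20, n_controls = 20, n_ncrna = 50,
                   n_mrna = 300, n_regulators = 30, target_exponent = 2,
                   max_targets = 30, effect_beta = 1, noise_sd = 0.5,
                   rewire_fraction = 0.5, n_de_ncrna = 5,
                   n_de_remission = 5, de_shift = 2, patient_sd = 0.2,
                   seed = 1L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
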