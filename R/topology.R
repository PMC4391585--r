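#' Degree distribution of a network
#'
#' @param net a non-empty \code{ncx_network}.
#' @return Data frame with columns \code{degree} (integer >= 1) and
#'   \code{count}; counts sum to the node count and
#'   \code{sum(degree * count) == 2 * n_edges}.
#' @export
degree_distribution <- function(net) {
  stopifnot(inherits(net, "ncx_network"))
  if (!nrow(net$edges)) stop("empty network")
  deg <- node_degrees(net)
  tab <- table(deg)
  data.frame(degree = as.integer(names(tab)), count = as.integer(tab))
}

# per-node incident edge counts, named by node id
node_degrees <- function(net) {
  c(table(net$edges$ncrna), table(net$edges$mrna))
}

#' Fit a power law to a degree histogram by log-log least squares
#'
#' Ordinary least squares of log10(count) on log10(degree) over the nonzero
#' bins of the raw integer-degree histogram (no logarithmic binning, no
#' maximum-likelihood tail fit): the fitted curve is y = a * x^b and the fit
#' quality is the magnitude of the regression's Pearson correlation. This is
#' the classic reporting style for scale-free coexpression networks, whose
#' exponent typically lies in (-2, -1).
#'
#' @param hist data frame with columns \code{degree}, \code{count} (as from
#'   \code{\link{degree_distribution}}).
#' @return List of class \code{ncx_powerlaw}: \code{a} (coefficient > 0),
#'   \code{b} (exponent), \code{fit_correlation} in [0, 1].
#' @export
fit_power_law <- function(hist) {
  hist <- hist[hist$count > 0, , drop = FALSE]
  if (nrow(hist) < 3)
    stop("power-law fit needs at least 3 distinct degrees with nonzero counts")
  lx <- log10(hist$degree)
  ly <- log10(hist$count)
  fit <- stats::lm(ly ~ lx)
  b <- unname(stats::coef(fit)[2])
  a <- 10^unname(stats::coef(fit)[1])
  fc <- if (stats::sd(ly) == 0) 1 else abs(stats::cor(lx, ly))
  structure(list(a = a, b = b, fit_correlation = fc),
            class = "ncx_powerlaw")
}

#' @export
print.ncx_powerlaw <- function(x, ...) {
  cat(sprintf("power law: y = %.2f * x^%.3f (|R| = %.3f)\n",
              x$a, x$b, x$fit_correlation))
  invisible(x)
}

#' Betweenness centrality, Cytoscape-normalized
#'
#' Undirected, unweighted shortest-path betweenness, normalized per
#' connected component by (n_c - 1)(n_c - 2)/2 where n_c is the component's
#' node count, the NetworkAnalyzer convention under which values lie in
#' [0, 1] (the center of a star scores 1, leaves 0). Nodes in components of
#' fewer than 3 nodes score 0.
#'
#' @param net a non-empty \code{ncx_network}.
#' @return Named numeric vector of betweenness values in [0, 1].
#' @export
betweenness_centrality <- function(net) {
  stopifnot(inherits(net, "ncx_network"))
  if (!nrow(net$edges)) stop("empty network")
  g <- as_igraph(net)
  raw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  comp <- igraph::components(g)
  csize <- comp$csize[comp$membership]
  denom <- (csize - 1) * (csize - 2) / 2
  out <- ifelse(denom > 0, raw / denom, 0)
  stats::setNames(out, igraph::V(g)$name)
}

#' Combined centrality table (betweenness x outdegree)
#'
#' The outdegree of an ncRNA is its incident edge count (the number of mRNAs
#' it targets); mRNA nodes are assigned outdegree 0, so only ncRNAs can
#' score. Combined centrality is the exact product of normalized betweenness
#' and outdegree: it is high for ncRNAs that both target many genes and sit
#' on many shortest paths.
#'
#' @param net a non-empty \code{ncx_network}.
#' @return Data frame with columns \code{node}, \code{class},
#'   \code{outdegree}, \code{betweenness}, \code{combined}, sorted by
#'   combined centrality descending (ties by node id).
#' @export
combined_centrality <- function(net) {
  stopifnot(inherits(net, "ncx_network"))
  if (!nrow(net$edges)) stop("empty network")
  btw <- betweenness_centrality(net)
  nodes <- names(btw)
  nc <- nodes %in% net$edges$ncrna
  deg <- node_degrees(net)[nodes]
  outdeg <- ifelse(nc, deg, 0L)
  tab <- data.frame(node = nodes,
                    class = ifelse(nc, "ncRNA", "mRNA"),
                    outdegree = as.integer(outdeg),
                    betweenness = unname(btw),
                    combined = unname(btw * outdeg),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$combined, tab$node), ]
  rownames(tab) <- NULL
  tab
}

#' Extract hub ncRNAs above a combined-centrality percentile
#'
#' Hubs are the ncRNA nodes whose combined centrality strictly exceeds the
#' given percentile of the combined-centrality values of the ncRNA nodes
#' present in the network. The percentile is taken over ncRNAs only: with
#' the default 97.5 this selects about 2.5 percent of the network's ncRNAs.
#'
#' @param centrality a table from \code{\link{combined_centrality}}.
#' @param percentile hub percentile (default 97.5).
#' @return The hub rows of the centrality table, sorted by combined
#'   centrality descending, with the cutoff in attribute \code{cutoff}.
#' @export
top_central_ncrnas <- function(centrality, percentile = 97.5) {
  stopifnot(is.data.frame(centrality), nrow(centrality) > 0)
  ncr <- centrality[centrality$class == "ncRNA", , drop = FALSE]
  cutoff <- stats::quantile(ncr$combined, probs = percentile / 100,
                            names = FALSE)
  hubs <- ncr[ncr$combined > cutoff, , drop = FALSE]
  hubs <- hubs[order(-hubs$combined, hubs$node), ]
  rownames(hubs) <- NULL
  attr(hubs, "cutoff") <- cutoff
  hubs
}

#' Core subnetwork: hubs plus their first neighbors
#'
#' The subnetwork on the hubs and their first neighbors, keeping only the
#' edges incident to a hub. Edges between two non-hub nodes are excluded:
#' the neighborhood union defines the core, not the full induced subgraph.
#'
#' @param net an \code{ncx_network}.
#' @param hubs character vector of hub node ids (must belong to the
#'   network).
#' @return The core \code{ncx_network}.
#' @export
core_subnetwork <- function(net, hubs) {
  stopifnot(inherits(net, "ncx_network"))
  hubs <- as.character(hubs)
  unknown <- setdiff(hubs, network_nodes(net))
  if (length(unknown))
    stop("unknown hub id(s): ", paste(unknown, collapse = ", "))
  keep <- net$edges$ncrna %in% hubs | net$edges$mrna %in% hubs
  ncx_network(net$edges[keep, , drop = FALSE], sign = net$sign,
              condition_label = "derived")
}

#' Shortest-path length distribution and characteristic path length
#'
#' All-pairs shortest path lengths over connected, unordered node pairs;
#' the mean is the characteristic path length.
#'
#' @param net a non-empty \code{ncx_network}.
#' @return List: \code{hist} (data frame \code{length}, \code{count}),
#'   \code{mean} (characteristic path length).
#' @export
shortest_path_stats <- function(net) {
  stopifnot(inherits(net, "ncx_network"))
  if (!nrow(net$edges)) stop("empty network")
  d <- igraph::distances(as_igraph(net))
  d <- d[upper.tri(d)]
  d <- d[is.finite(d)]
  tab <- table(d)
  list(hist = data.frame(length = as.integer(names(tab)),
                         count = as.integer(tab)),
       mean = mean(d))
}

#' Network descriptor summary
#'
#' Assembles the six descriptors used to compare network architectures --
#' connected-component count, network centralization, characteristic path
#' length, average degree, network heterogeneity, power-law exponent --
#' plus node/edge counts and size (nodes + edges).
#'
#' Centralization is (n/(n-2)) * (max_degree/(n-1) - density) with density
#' 2E/(n(n-1)); heterogeneity is the coefficient of variation of the degree
#' distribution, sqrt(population variance)/mean (the NetworkAnalyzer
#' definitions).
#'
#' @param net a non-empty \code{ncx_network}.
#' @return List of class \code{ncx_topology} with fields
#'   \code{n_connected_components}, \code{network_centralization},
#'   \code{characteristic_path_length}, \code{average_degree},
#'   \code{network_heterogeneity}, \code{powerlaw_exponent},
#'   \code{n_nodes}, \code{n_edges}, \code{size}.
#' @export
descriptors <- function(net) {
  stopifnot(inherits(net, "ncx_network"))
  if (!nrow(net$edges)) stop("empty network")
  deg <- as.numeric(node_degrees(net))
  n <- length(deg)
  e <- nrow(net$edges)
  density <- 2 * e / (n * (n - 1))
  centralization <- if (n > 2) (n / (n - 2)) * (max(deg) / (n - 1) - density)
                    else 0
  varpop <- mean(deg^2) - mean(deg)^2
  # regular-ish graphs (< 3 distinct degrees) have no meaningful power-law
  # fit; report NA rather than failing the whole summary
  pl <- tryCatch(fit_power_law(degree_distribution(net)),
                 error = function(e) {
                   warning("power-law fit unavailable: ", conditionMessage(e))
                   list(b = NA_real_)
                 })
  structure(list(
    n_connected_components = igraph::components(as_igraph(net))$no,
    network_centralization = centralization,
    characteristic_path_length = shortest_path_stats(net)$mean,
    average_degree = 2 * e / n,
    network_heterogeneity = sqrt(varpop) / mean(deg),
    powerlaw_exponent = pl$b,
    n_nodes = n, n_edges = e, size = n + e),
    class = "ncx_topology")
}

#' @export
print.ncx_topology <- function(x, ...) {
  cat(sprintf(paste0(
    "network topology: %d nodes, %d edges (size %d)\n",
    "  components %d | centralization %.4f | char. path length %.3f\n",
    "  avg degree %.3f | heterogeneity %.3f | power-law exponent %.3f\n"),
    x$n_nodes, x$n_edges, x$size, x$n_connected_components,
    x$network_centralization, x$characteristic_path_length,
    x$average_degree, x$network_heterogeneity, x$powerlaw_exponent))
  invisible(x)
}
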