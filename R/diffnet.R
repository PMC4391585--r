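# 7-region partition shared by edge/node Venn counting.
# keys: list of three character vectors (already canonical & unique).
venn_partition <- function(keys, labels) {
  stopifnot(length(keys) == 3)
  a <- keys[[1]]; b <- keys[[2]]; c <- keys[[3]]
  un <- unique(c(a, b, c))
  inA <- un %in% a; inB <- un %in% b; inC <- un %in% c
  region <- paste0(ifelse(inA, "1", "0"), ifelse(inB, "1", "0"),
                   ifelse(inC, "1", "0"))
  counts <- c("100" = sum(region == "100"), "010" = sum(region == "010"),
              "001" = sum(region == "001"), "110" = sum(region == "110"),
              "101" = sum(region == "101"), "011" = sum(region == "011"),
              "111" = sum(region == "111"))
  pair_jaccard <- matrix(1, 3, 3, dimnames = list(labels, labels))
  pair_frac <- matrix(1, 3, 3, dimnames = list(labels, labels))
  sets <- list(a, b, c)
  for (i in 1:2) for (j in (i + 1):3) {
    shared <- length(intersect(sets[[i]], sets[[j]]))
    uni <- length(union(sets[[i]], sets[[j]]))
    pair_jaccard[i, j] <- pair_jaccard[j, i] <-
      if (uni > 0) shared / uni else NA_real_
    # per-network fraction: shared relative to the smaller set
    mn <- min(length(sets[[i]]), length(sets[[j]]))
    pair_frac[i, j] <- pair_frac[j, i] <-
      if (mn > 0) shared / mn else NA_real_
  }
  structure(list(
    regions = counts,
    n_union = length(un),
    n_triple = unname(counts["111"]),
    triple_pct = if (length(un)) 100 * unname(counts["111"]) / length(un)
                 else NA_real_,
    pairwise_jaccard = pair_jaccard,
    pairwise_min_fraction = pair_frac,
    labels = labels,
    members = split(un, factor(region, levels = names(counts)))),
    class = "ncx_venn")
}

#' @export
print.ncx_venn <- function(x, ...) {
  cat("3-set Venn partition (", paste(x$labels, collapse = " / "), ")\n",
      sep = "")
  print(x$regions)
  cat(sprintf("union %d, triple-shared %d (%.2f%%)\n",
              x$n_union, x$n_triple, x$triple_pct))
  invisible(x)
}

#' Edge-wise 3-set Venn partition of three networks
#'
#' Edge identity is the unordered (ncRNA, mRNA) pair; the correlation value
#' is ignored. Reports the exact 7-region partition, the triple-shared
#' fraction of the edge union as a percentage, and pairwise shared
#' proportions under both the Jaccard (shared/union-of-pair) and the
#' smaller-network-fraction conventions.
#'
#' @param net1,net2,net3 three \code{ncx_network}s over consistent gene ids.
#' @return An \code{ncx_venn} object: region counts (named by membership
#'   pattern \code{"101"} = in nets 1 and 3 only), union and triple counts,
#'   \code{triple_pct}, pairwise proportion matrices and region members.
#' @export
edge_intersections <- function(net1, net2, net3) {
  nets <- list(net1, net2, net3)
  stopifnot(all(vapply(nets, inherits, TRUE, "ncx_network")))
  venn_partition(lapply(nets, edge_keys),
                 vapply(nets, function(n) n$condition_label, ""))
}

#' Node-wise 3-set Venn partition of three networks
#'
#' As \code{\link{edge_intersections}} with node identity. Condition-specific
#' coexpression networks typically share most of their nodes while sharing
#' very few edges -- rewiring changes who is connected to whom, not who is
#' present.
#'
#' @inheritParams edge_intersections
#' @return An \code{ncx_venn} object.
#' @export
node_intersections <- function(net1, net2, net3) {
  nets <- list(net1, net2, net3)
  stopifnot(all(vapply(nets, inherits, TRUE, "ncx_network")))
  venn_partition(lapply(nets, network_nodes),
                 vapply(nets, function(n) n$condition_label, ""))
}

# edges of `net` whose keys are in `keys`; r values from `net`
subset_edges <- function(net, keys) {
  net$edges[edge_keys(net) %in% keys, , drop = FALSE]
}

#' Status-independent core network
#'
#' The network wired by exactly the edges present in all three condition
#' networks: the coexpression backbone that persists irrespective of
#' disease status. Correlation values are taken from the first network.
#'
#' @inheritParams edge_intersections
#' @return An \code{ncx_network} (possibly empty) with the largest connected
#'   component attached as attribute \code{largest_component}.
#' @export
status_independent_core <- function(net1, net2, net3) {
  keys <- intersect(intersect(edge_keys(net1), edge_keys(net2)),
                    edge_keys(net3))
  core <- ncx_network(subset_edges(net1, keys), sign = net1$sign,
                      condition_label = "derived")
  attr(core, "largest_component") <-
    if (nrow(core$edges)) largest_component(core) else NULL
  core
}

#' Disease-specific network
#'
#' The edges shared by the relapse and remission networks but absent from
#' the controls network: coexpression links tied to the disease itself
#' rather than to its acute phase or to healthy physiology.
#'
#' @param relapse,remission,controls \code{ncx_network}s for the three
#'   conditions.
#' @return An \code{ncx_network} sharing zero edges with \code{controls},
#'   with the largest component attached as attribute
#'   \code{largest_component}.
#' @export
disease_specific_network <- function(relapse, remission, controls) {
  keys <- setdiff(intersect(edge_keys(relapse), edge_keys(remission)),
                  edge_keys(controls))
  net <- ncx_network(subset_edges(relapse, keys), sign = relapse$sign,
                     condition_label = "derived")
  stopifnot(length(intersect(edge_keys(net), edge_keys(controls))) == 0)
  attr(net, "largest_component") <-
    if (nrow(net$edges)) largest_component(net) else NULL
  net
}

#' Largest connected component of a network
#'
#' The component maximizing node count; ties are broken by edge count, then
#' by the lexicographically smallest node id.
#'
#' @param net a non-empty \code{ncx_network}.
#' @return The component as an \code{ncx_network}.
#' @export
largest_component <- function(net) {
  stopifnot(inherits(net, "ncx_network"))
  if (!nrow(net$edges)) stop("empty network")
  g <- as_igraph(net)
  comp <- igraph::components(g)
  mem <- comp$membership
  # edge counts per component (edges stay within components)
  ec <- table(mem[net$edges$ncrna])
  stats_tab <- data.frame(id = seq_len(comp$no),
                          nodes = comp$csize,
                          edges = as.integer(ec[as.character(seq_len(comp$no))]))
  stats_tab$minnode <- vapply(seq_len(comp$no), function(i)
    min(names(mem)[mem == i]), "")
  stats_tab <- stats_tab[order(-stats_tab$nodes, -stats_tab$edges,
                               stats_tab$minnode), ]
  keep_nodes <- names(mem)[mem == stats_tab$id[1]]
  ncx_network(net$edges[net$edges$ncrna %in% keep_nodes, , drop = FALSE],
              sign = net$sign, condition_label = "derived")
}

#' PCA on network descriptor summaries
#'
#' Standardizes the six topology descriptors across networks (zero mean,
#' unit sd per descriptor; descriptors have incommensurate units) and
#' projects the networks on the principal axes. Constant descriptors are
#' dropped with a warning.
#'
#' @param summaries list of \code{ncx_topology} objects (>= 2), optionally
#'   named.
#' @return List: \code{coordinates} (networks x components),
#'   \code{variance_fraction} per component, \code{dropped} descriptor
#'   names.
#' @export
topology_pca <- function(summaries) {
  if (length(summaries) < 2) stop("PCA needs at least 2 networks")
  stopifnot(all(vapply(summaries, inherits, TRUE, "ncx_topology")))
  fields <- c("n_connected_components", "network_centralization",
              "characteristic_path_length", "average_degree",
              "network_heterogeneity", "powerlaw_exponent")
  x <- t(vapply(summaries, function(s) unlist(s[fields]),
                numeric(length(fields))))
  colnames(x) <- fields
  if (!is.null(names(summaries))) rownames(x) <- names(summaries)
  sds <- apply(x, 2, stats::sd)
  bad <- is.na(sds) | sds == 0
  dropped <- colnames(x)[bad]
  if (length(dropped))
    warning("constant or undefined descriptor(s) dropped: ",
            paste(dropped, collapse = ", "))
  x <- x[, !bad, drop = FALSE]
  if (!ncol(x)) stop("all descriptors constant")
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  vf <- p$sdev^2 / sum(p$sdev^2)
  list(coordinates = p$x, variance_fraction = vf, dropped = dropped)
}

#' Pairwise correlations between degree and path-length distributions
#'
#' Aligns each pair of histograms on the union of observed bins (missing
#' bins count 0) and computes the Pearson correlation: near-1 values mean
#' the networks share an architecture even when they share few edges.
#'
#' @inheritParams edge_intersections
#' @return List of two 3x3 symmetric unit-diagonal matrices:
#'   \code{degree} and \code{path_length}. Entries are NA when a histogram
#'   is degenerate (single bin).
#' @export
distribution_correlations <- function(net1, net2, net3) {
  nets <- list(net1, net2, net3)
  stopifnot(all(vapply(nets, inherits, TRUE, "ncx_network")))
  labels <- vapply(nets, function(n) n$condition_label, "")
  deg_h <- lapply(nets, function(n) {
    h <- degree_distribution(n); stats::setNames(h$count, h$degree)
  })
  spl_h <- lapply(nets, function(n) {
    h <- shortest_path_stats(n)$hist; stats::setNames(h$count, h$length)
  })
  list(degree = histogram_cor_matrix(deg_h, labels),
       path_length = histogram_cor_matrix(spl_h, labels))
}

# Pearson R between aligned histograms, all pairs
histogram_cor_matrix <- function(hists, labels) {
  m <- diag(1, length(hists))
  dimnames(m) <- list(labels, labels)
  for (i in seq_along(hists)) for (j in seq_along(hists)) {
    if (i >= j) next
    bins <- sort(unique(as.integer(c(names(hists[[i]]), names(hists[[j]])))))
    a <- ifelse(is.na(hists[[i]][as.character(bins)]), 0,
                hists[[i]][as.character(bins)])
    b <- ifelse(is.na(hists[[j]][as.character(bins)]), 0,
                hists[[j]][as.character(bins)])
    r <- if (length(bins) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("degenerate histogram; correlation undefined")
      NA_real_
    } else stats::cor(a, b)
    m[i, j] <- m[j, i] <- r
  }
  m
}
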