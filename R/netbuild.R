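#' Bipartite ncRNA-mRNA coexpression network
#'
#' The only edge type any network in this package contains: an undirected
#' edge between one ncRNA and one mRNA carrying a Pearson correlation.
#' Intra-class (mRNA-mRNA, ncRNA-ncRNA) correlations never enter.
#'
#' @param edges data frame with columns \code{ncrna}, \code{mrna}, \code{r}.
#' @param sign \code{"negative"} or \code{"positive"}; all \code{r} must
#'   agree with it. Use \code{"derived"} sign-free networks via
#'   \code{sign = NA} only internally.
#' @param condition_label one of \code{"global"}, \code{"relapse"},
#'   \code{"remission"}, \code{"control"}, \code{"derived"}.
#' @return An object of class \code{ncx_network}.
#' @export
ncx_network <- function(edges, sign = "negative", condition_label = "derived") {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("ncrna", "mrna", "r") %in% names(edges)))
    stop("`edges` needs columns ncrna, mrna, r")
  edges <- edges[, c("ncrna", "mrna", "r")]
  edges$ncrna <- as.character(edges$ncrna)
  edges$mrna <- as.character(edges$mrna)
  if (anyDuplicated(paste(edges$ncrna, edges$mrna, sep = "\r")))
    stop("duplicate edges")
  if (!is.na(sign)) {
    if (!sign %in% c("negative", "positive")) stop("invalid sign")
    ok <- if (sign == "negative") all(edges$r < 0) else all(edges$r > 0)
    if (!ok) stop("edge correlations disagree with sign = ", sign)
  }
  if (nrow(edges))
    edges <- edges[order(edges$ncrna, edges$mrna), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, sign = sign,
                 condition_label = condition_label),
            class = "ncx_network")
}

#' @export
print.ncx_network <- function(x, ...) {
  cat(sprintf("ncx_network [%s, %s]: %d nodes (%d ncRNA, %d mRNA), %d edges\n",
              x$condition_label, x$sign,
              length(network_nodes(x)), length(unique(x$edges$ncrna)),
              length(unique(x$edges$mrna)), nrow(x$edges)))
  invisible(x)
}

#' Node set of a network
#'
#' @param net an \code{ncx_network}.
#' @param class \code{"all"}, \code{"ncRNA"} or \code{"mRNA"}.
#' @return Character vector of node ids.
#' @export
network_nodes <- function(net, class = c("all", "ncRNA", "mRNA")) {
  class <- match.arg(class)
  switch(class,
         all = sort(unique(c(net$edges$ncrna, net$edges$mrna))),
         ncRNA = sort(unique(net$edges$ncrna)),
         mRNA = sort(unique(net$edges$mrna)))
}

# canonical edge keys for set algebra (unordered pair; r ignored)
edge_keys <- function(net) paste(net$edges$ncrna, net$edges$mrna, sep = "\r")

# igraph view of a network; vertices keep their gene class
as_igraph <- function(net) {
  nc <- unique(net$edges$ncrna)
  mr <- unique(net$edges$mrna)
  g <- igraph::graph_from_data_frame(
    net$edges[, c("ncrna", "mrna")], directed = FALSE,
    vertices = data.frame(name = c(nc, mr),
                          class = rep(c("ncRNA", "mRNA"),
                                      c(length(nc), length(mr)))))
  igraph::E(g)$r <- net$edges$r
  g
}

#' Critical Pearson correlation for a given sample size
#'
#' The magnitude r* at which a Pearson correlation computed on
#' \code{n_samples} observations attains p = \code{alpha} under the
#' t-transform t = r * sqrt((n-2)/(1-r^2)) with n-2 degrees of freedom.
#' Inverting for r gives r* = t* / sqrt(n - 2 + t*^2). The threshold shrinks
#' as the sample size grows and tightens as alpha decreases, which is why
#' condition-specific networks (fewer samples) use more stringent cutoffs
#' than the global one.
#'
#' @param n_samples number of observations per correlation (>= 4).
#' @param alpha significance level in (0, 1).
#' @param tails 1 or 2 (default two-sided, the convention matching the
#'   published thresholds).
#' @return The critical magnitude in (0, 1).
#' @examples
#' critical_r(65, 0.0005)  # 0.4198... -> the published -0.42 cutoff
#' critical_r(22, 0.01)    # 0.5368... -> 0.537
#' critical_r(21, 0.01)    # 0.5487... -> 0.549
#' @export
critical_r <- function(n_samples, alpha, tails = 2) {
  if (!is.numeric(n_samples) || length(n_samples) != 1 || n_samples < 4)
    stop("`n_samples` must be a single count >= 4")
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)")
  if (!tails %in% c(1, 2)) stop("`tails` must be 1 or 2")
  df <- n_samples - 2
  tstar <- stats::qt(1 - alpha / tails, df)
  tstar / sqrt(df + tstar^2)
}

#' Pairwise Pearson correlations between ncRNAs and mRNAs
#'
#' Computes the dense ncRNA x mRNA Pearson correlation table over a sample
#' subset. Only inter-class pairs are computed; intra-class correlations
#' never exist in this pipeline. Genes with zero variance within the subset
#' yield undefined correlations: those entries are set to NA, flagged, and a
#' warning names the genes. Results are identical on raw or standardized
#' data (Pearson R is affine-invariant).
#'
#' @param mat an \code{ncx_matrix}.
#' @param sample_subset character vector of sample ids (default all).
#' @return A list of class \code{ncx_cortable}: \code{r} (ncRNA x mRNA
#'   matrix), \code{n_samples}, \code{degenerate_genes}.
#' @export
pairwise_pearson <- function(mat, sample_subset = NULL) {
  stopifnot(inherits(mat, "ncx_matrix"))
  if (is.null(sample_subset)) sample_subset <- colnames(mat$values)
  if (!all(sample_subset %in% colnames(mat$values)))
    stop("unknown sample id(s) in subset")
  if (length(sample_subset) < 3)
    stop("need at least 3 samples to correlate")
  v <- mat$values[, sample_subset, drop = FALSE]
  nc_ids <- rownames(v)[mat$gene_class == "ncRNA"]
  mr_ids <- rownames(v)[mat$gene_class == "mRNA"]
  if (!length(nc_ids) || !length(mr_ids))
    stop("need at least one ncRNA and one mRNA")
  sds <- apply(v, 1, stats::sd)
  degen <- rownames(v)[sds == 0]
  if (length(degen))
    warning("zero-variance gene(s) in subset, correlations flagged NA: ",
            paste(degen, collapse = ", "))
  r <- suppressWarnings(
    stats::cor(t(v[nc_ids, , drop = FALSE]), t(v[mr_ids, , drop = FALSE])))
  r[nc_ids %in% degen, ] <- NA_real_
  r[, mr_ids %in% degen] <- NA_real_
  structure(list(r = r, n_samples = length(sample_subset),
                 degenerate_genes = degen),
            class = "ncx_cortable")
}

#' Threshold a correlation table into a bipartite network
#'
#' Keeps entries strictly beyond the cutoff: \code{r < -r_cut} for the
#' negative network, \code{r > r_cut} for the positive one. Ties at exactly
#' the cutoff are excluded; undefined (NA) entries are dropped.
#'
#' @param table an \code{ncx_cortable} from \code{\link{pairwise_pearson}}.
#' @param r_cut positive cutoff magnitude.
#' @param sign \code{"negative"} (default) or \code{"positive"}.
#' @param condition_label label stored on the resulting network.
#' @return An \code{ncx_network}.
#' @export
threshold_network <- function(table, r_cut, sign = c("negative", "positive"),
                              condition_label = "derived") {
  stopifnot(inherits(table, "ncx_cortable"))
  sign <- match.arg(sign)
  if (!is.numeric(r_cut) || length(r_cut) != 1 || r_cut <= 0)
    stop("`r_cut` must be a positive magnitude")
  hit <- if (sign == "negative") table$r < -r_cut else table$r > r_cut
  hit[is.na(hit)] <- FALSE
  idx <- which(hit, arr.ind = TRUE)
  edges <- data.frame(ncrna = rownames(table$r)[idx[, 1]],
                      mrna = colnames(table$r)[idx[, 2]],
                      r = table$r[idx],
                      stringsAsFactors = FALSE)
  ncx_network(edges, sign = sign, condition_label = condition_label)
}

#' Build a condition-specific (or global) coexpression network
#'
#' Composes \code{\link{pairwise_pearson}} on the condition's samples with
#' \code{\link{threshold_network}} at the significance-derived cutoff
#' \code{critical_r(n_condition, alpha)}.
#'
#' @param mat a preprocessed \code{ncx_matrix}.
#' @param condition \code{"relapse"}, \code{"remission"}, \code{"control"}
#'   or \code{"global"} (all samples).
#' @param alpha significance level for the cutoff.
#' @param sign edge sign to retain (default negative, the assumption that
#'   ncRNAs downregulate their mRNA targets).
#' @return An \code{ncx_network} with the cutoff in attribute \code{r_cut}.
#' @export
build_condition_network <- function(mat, condition, alpha,
                                    sign = c("negative", "positive")) {
  stopifnot(inherits(mat, "ncx_matrix"))
  sign <- match.arg(sign)
  samples <- if (identical(condition, "global")) colnames(mat$values)
             else colnames(mat$values)[mat$condition == condition]
  if (length(samples) < 4)
    stop("condition '", condition, "' has fewer than 4 samples")
  rc <- critical_r(length(samples), alpha)
  tab <- pairwise_pearson(mat, samples)
  net <- threshold_network(tab, rc, sign = sign, condition_label = condition)
  attr(net, "r_cut") <- rc
  attr(net, "n_samples") <- length(samples)
  net
}

#' Write a network as an edge-list TSV (and optionally SIF)
#'
#' TSV columns: source (ncRNA), interaction ("neg"/"pos"), target (mRNA), r.
#' The SIF variant drops the r column for Cytoscape import.
#'
#' @param net an \code{ncx_network}.
#' @param file output TSV path.
#' @param sif_file optional SIF output path.
#' @return Invisibly, \code{file}.
#' @export
write_network_tsv <- function(net, file, sif_file = NULL) {
  stopifnot(inherits(net, "ncx_network"))
  inter <- if (identical(net$sign, "positive")) "pos" else "neg"
  tab <- data.frame(source = net$edges$ncrna, interaction = inter,
                    target = net$edges$mrna, r = net$edges$r,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sif_file))
    utils::write.table(tab[, c("source", "interaction", "target")], sif_file,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  invisible(file)
}

#' Read a network from an edge-list TSV written by write_network_tsv
#'
#' @param file TSV path with columns source, interaction, target, r.
#' @param condition_label label stored on the network.
#' @return An \code{ncx_network}.
#' @export
read_network_tsv <- function(file, condition_label = "derived") {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("source", "interaction", "target", "r") %in% names(tab)))
    stop("malformed network TSV")
  sign <- if (all(tab$interaction == "pos")) "positive" else "negative"
  ncx_network(data.frame(ncrna = tab$source, mrna = tab$target, r = tab$r,
                         stringsAsFactors = FALSE),
              sign = sign, condition_label = condition_label)
}
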