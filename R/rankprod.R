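#' Rank Products differential expression
#'
#' Nonparametric differential-expression test. For each comparison column
#' (a within-patient difference when \code{paired}, otherwise one cross-group
#' sample pairing) genes are ranked by their change score, separately for
#' up-regulation (largest increase ranks 1) and down-regulation (largest
#' decrease ranks 1). A gene's rank product is the geometric mean of its
#' ranks across columns; a gene consistently at the extreme in every column
#' scores 1. Significance is assessed by permutation: ranks are shuffled
#' within each column, the expected number of false positives at each
#' observed rank product is estimated as the mean count of permuted rank
#' products at least as small, and the percentage of false prediction (pfp)
#' is that expectation divided by the gene's position in the ascending
#' rank-product ordering. The permutation null is identical for the two
#' directions (shuffled ranks are direction-free), so one permutation pool
#' serves both.
#'
#' Change scores are differences of (typically z-scored) expression; the
#' rank product is invariant under any monotone transform of the per-column
#' scores. In the unpaired design all group1 x group2 sample pairings are
#' used up to \code{max_pairings}, beyond which a seeded random subset is
#' drawn.
#'
#' @param mat an \code{ncx_matrix} (subset it first to the gene class of
#'   interest).
#' @param comparison \code{"relapse_vs_remission"} or
#'   \code{"remission_vs_controls"}; change = first group minus second.
#' @param paired use within-patient differences (requires a one-to-one
#'   patient match across the two groups; only meaningful for
#'   relapse vs remission).
#' @param n_permutations number of within-column rank shuffles (>= 1;
#'   default 1000).
#' @param pfp_cutoff significance cutoff on pfp (default 0.05).
#' @param seed RNG seed for the permutations (and pairing subsampling).
#' @param max_pairings cap on unpaired comparison columns (default 500).
#' @return A data frame of class \code{ncx_de} with one row per gene and
#'   direction: \code{gene}, \code{direction} ("up"/"down"), \code{RP},
#'   \code{E} (expected false positives), \code{pfp}, \code{rank},
#'   \code{significant}; attributes \code{comparison}, \code{paired},
#'   \code{n_permutations}, \code{pfp_cutoff}.
#' @export
rank_products <- function(mat, comparison = c("relapse_vs_remission",
                                              "remission_vs_controls"),
                          paired = NULL, n_permutations = 1000,
                          pfp_cutoff = 0.05, seed = 1L,
                          max_pairings = 500) {
  stopifnot(inherits(mat, "ncx_matrix"))
  comparison <- match.arg(comparison)
  groups <- strsplit(sub("_vs_", " ", comparison), " ")[[1]]
  groups <- sub("controls", "control", groups)
  if (is.null(paired)) paired <- comparison == "relapse_vs_remission"
  if (n_permutations < 1) stop("`n_permutations` must be >= 1")
  s1 <- colnames(mat$values)[mat$condition == groups[1]]
  s2 <- colnames(mat$values)[mat$condition == groups[2]]
  if (!length(s1) || !length(s2))
    stop("both comparison groups must be non-empty")
  scores <- with_seed(seed, {
    if (paired) {
      p1 <- mat$patient_id[s1]
      p2 <- mat$patient_id[s2]
      if (anyNA(p1) || anyNA(p2) || !setequal(p1, p2) ||
          anyDuplicated(p1) || anyDuplicated(p2))
        stop("paired comparison requires a one-to-one patient match")
      mat$values[, s1, drop = FALSE] -
        mat$values[, s2[match(p1, p2)], drop = FALSE]
    } else {
      pairs <- expand.grid(i = s1, j = s2, stringsAsFactors = FALSE)
      if (nrow(pairs) > max_pairings)
        pairs <- pairs[sample(nrow(pairs), max_pairings), ]
      mat$values[, pairs$i, drop = FALSE] -
        mat$values[, pairs$j, drop = FALSE]
    }
  })
  genes <- rownames(scores)
  ng <- length(genes)
  nc <- ncol(scores)
  # per-column ranks: down-regulation ranks ascending scores first
  rank_down <- apply(scores, 2, rank, ties.method = "average")
  rank_up <- ng + 1 - rank_down
  rp <- function(rk) exp(rowMeans(log(rk)))
  rp_obs <- list(up = rp(rank_up), down = rp(rank_down))
  # one shared permutation pool: shuffled ranks are direction-free
  null_pool <- with_seed(seed + 1L, {
    unlist(lapply(seq_len(n_permutations), function(p) {
      rk <- vapply(seq_len(nc), function(j) sample(ng), integer(ng))
      rp(matrix(rk, nrow = ng))
    }), use.names = FALSE)
  })
  null_sorted <- sort(null_pool)
  out <- do.call(rbind, lapply(c("up", "down"), function(dir) {
    obs <- rp_obs[[dir]]
    ord <- order(obs, genes)
    pos <- integer(ng)
    pos[ord] <- seq_len(ng)
    e <- findInterval(obs, null_sorted) / n_permutations
    pfp <- e / pos
    data.frame(gene = genes, direction = dir, RP = unname(obs),
               E = unname(e), pfp = unname(pfp), rank = pos,
               significant = unname(pfp < pfp_cutoff),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, class = c("ncx_de", "data.frame"),
            comparison = comparison, paired = paired,
            n_permutations = n_permutations, pfp_cutoff = pfp_cutoff)
}

#' Extract significant gene lists from a Rank Products result
#'
#' @param result an \code{ncx_de} from \code{\link{rank_products}}.
#' @return List with elements \code{up}, \code{down} (character vectors of
#'   significant gene ids per direction, deduplicated) and \code{all}
#'   (their union). A gene significant in both directions would violate the
#'   construction and raises an error.
#' @export
de_gene_lists <- function(result) {
  stopifnot(inherits(result, "ncx_de"))
  up <- unique(result$gene[result$direction == "up" & result$significant])
  down <- unique(result$gene[result$direction == "down" & result$significant])
  both <- intersect(up, down)
  if (length(both))
    stop("gene(s) significant in both directions (should be impossible): ",
         paste(both, collapse = ", "))
  list(up = up, down = down, all = union(up, down))
}

#' Write a Rank Products table to TSV
#'
#' @param result an \code{ncx_de}.
#' @param file output path.
#' @return Invisibly, \code{file}.
#' @export
write_de_tsv <- function(result, file) {
  utils::write.table(as.data.frame(result), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
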