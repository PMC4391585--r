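#' Select candidate therapeutic ncRNAs
#'
#' Candidates are the ncRNA nodes of the disease-specific network that are
#' differentially expressed in either comparison (relapse vs remission or
#' remission vs controls): regulators whose altered expression and
#' disease-tied connectivity make them plausible intervention points. Each
#' candidate is annotated with its per-comparison DE membership and its
#' outdegree in the disease-specific network, and rows are sorted by
#' outdegree descending (ties by id).
#'
#' @param disease_net the disease-specific \code{ncx_network}.
#' @param de_relapse,de_remission character vectors of DE ncRNA ids from
#'   the two comparisons (may be empty).
#' @return Data frame of class \code{ncx_candidates} with columns
#'   \code{ncrna}, \code{deg_rel}, \code{deg_rem}, \code{outdegree}.
#' @export
select_candidates <- function(disease_net, de_relapse = character(),
                              de_remission = character()) {
  stopifnot(inherits(disease_net, "ncx_network"))
  net_ncrnas <- network_nodes(disease_net, "ncRNA")
  cand <- intersect(net_ncrnas,
                    union(as.character(de_relapse),
                          as.character(de_remission)))
  outdeg <- table(disease_net$edges$ncrna)
  tab <- data.frame(ncrna = cand,
                    deg_rel = cand %in% de_relapse,
                    deg_rem = cand %in% de_remission,
                    outdegree = as.integer(outdeg[cand]),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$outdegree, tab$ncrna), , drop = FALSE]
  rownames(tab) <- NULL
  stopifnot(all(tab$ncrna %in% net_ncrnas),
            all(tab$deg_rel | tab$deg_rem))
  structure(tab, class = c("ncx_candidates", "data.frame"))
}

#' Flag candidates whose manipulation would be risky
#'
#' A candidate that is both a hub of the global network and a node of the
#' status-independent core sits at the center of the transcriptome's
#' permanent wiring: manipulating it would have effects far beyond the
#' disease-specific subnetwork, so it receives a hard \code{caution} flag.
#' A candidate appearing in only one of those contexts (a control-network
#' hub, or a core node with low connectivity) gets an informational note
#' carrying its control-hub rank and core outdegree, letting the analyst
#' weigh a peripheral core position against the candidate's promise.
#'
#' @param candidates an \code{ncx_candidates} table.
#' @param global_hubs character vector of global-network hub ids.
#' @param control_hubs character vector (ranked, most central first) of
#'   control-network hub ids.
#' @param core_net the status-independent core \code{ncx_network}.
#' @return The candidate table with added columns \code{caution},
#'   \code{caution_reason}.
#' @export
flag_caution <- function(candidates, global_hubs = character(),
                         control_hubs = character(), core_net = NULL) {
  stopifnot(inherits(candidates, "ncx_candidates"))
  core_nodes <- if (is.null(core_net)) character()
                else network_nodes(core_net)
  core_deg <- if (is.null(core_net) || !nrow(core_net$edges)) integer()
              else table(core_net$edges$ncrna)
  n <- nrow(candidates)
  caution <- logical(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    id <- candidates$ncrna[i]
    in_hub <- id %in% global_hubs
    in_core <- id %in% core_nodes
    if (in_hub && in_core) {
      caution[i] <- TRUE
      reason[i] <- "global hub and status-independent core member; manipulation would impact the core transcriptome"
    } else if (in_core || id %in% control_hubs) {
      notes <- character()
      if (in_core) {
        kd <- if (id %in% names(core_deg)) as.integer(core_deg[[id]]) else 0L
        notes <- c(notes, sprintf("core member (outdegree %d)", kd))
      }
      if (id %in% control_hubs)
        notes <- c(notes, sprintf("control-network hub (rank %d)",
                                  match(id, control_hubs)))
      reason[i] <- paste("note:", paste(notes, collapse = "; "))
    }
  }
  candidates$caution <- caution
  candidates$caution_reason <- reason
  candidates
}

#' Write a candidate table to TSV
#'
#' @param candidates an \code{ncx_candidates} table.
#' @param file output path.
#' @return Invisibly, \code{file}.
#' @export
write_candidates_tsv <- function(candidates, file) {
  utils::write.table(as.data.frame(candidates), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}
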