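#' Pipeline run configuration
#'
#' @param input either an \code{ncx_sim_config} (simulate mode) or a named
#'   list with paths \code{matrix_file}, \code{sample_sheet} and optionally
#'   \code{detection_file} (load mode).
#' @param out_dir output directory for all artifacts.
#' @param alpha_global significance level for the global network cutoff
#'   (default 0.0005).
#' @param alpha_condition significance level for the condition-specific
#'   cutoffs (default 0.01).
#' @param hub_percentile combined-centrality hub percentile (default 97.5).
#' @param intensity_threshold optional mRNA intensity filter threshold
#'   (load mode; NULL skips).
#' @param n_permutations,pfp_cutoff Rank Products settings.
#' @param seed integer seed governing every random stage.
#' @return A list of class \code{ncx_run_config}.
#' @export
run_config <- function(input, out_dir, alpha_global = 5e-4,
                       alpha_condition = 0.01, hub_percentile = 97.5,
                       intensity_threshold = NULL, n_permutations = 1000,
                       pfp_cutoff = 0.05, seed = 1L) {
  for (a in c(alpha_global, alpha_condition))
    if (!is.numeric(a) || a <= 0 || a >= 1)
      stop("significance levels must lie in (0, 1)")
  structure(list(input = input, out_dir = out_dir,
                 alpha_global = alpha_global,
                 alpha_condition = alpha_condition,
                 hub_percentile = hub_percentile,
                 intensity_threshold = intensity_threshold,
                 n_permutations = n_permutations, pfp_cutoff = pfp_cutoff,
                 seed = as.integer(seed)),
            class = "ncx_run_config")
}

stage_fail <- function(stage, e) {
  stop(structure(class = c("ncx_stage_error", "error", "condition"),
                 list(message = sprintf("[stage:%s] %s", stage,
                                        conditionMessage(e)),
                      call = NULL, stage = stage)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) stage_fail(stage, e))
}

#' Run the full differential coexpression pipeline
#'
#' Executes, in order: cohort simulation or loading, preprocessing
#' (filters + z-scoring), the global and three condition-specific negative
#' coexpression networks, topology characterization (centralities, hubs,
#' core subnetwork, descriptors), differential network analysis (Venn
#' partitions, status-independent core, disease-specific network,
#' descriptor PCA, distribution correlations), Rank Products on the ncRNAs
#' for both comparisons, and candidate selection with caution flags. Every
#' intermediate artifact is written under \code{config$out_dir} and listed
#' in the returned manifest; the run is a pure function of (input, config,
#' seed).
#'
#' @param config an \code{ncx_run_config}.
#' @return Invisibly, a list with the in-memory results and
#'   \code{manifest} (named vector of written paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ncx_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- c()
  emit <- function(name, path) manifest[[name]] <<- path

  # --- input stage ---------------------------------------------------
  truth <- NULL
  mat <- run_stage("input", {
    if (inherits(config$input, "ncx_sim_config")) {
      cohort <- generate_cohort(config$input)
      paths <- write_cohort(cohort, config$input,
                            file.path(config$out_dir, "cohort"))
      for (nm in names(paths)) emit(paste0("cohort_", nm), paths[[nm]])
      truth <- cohort$truth   # evaluated in this function's frame
      cohort$matrix
    } else {
      read_ncx_matrix(config$input$matrix_file, config$input$sample_sheet,
                      config$input$detection_file)
    }
  })

  # --- preprocess ----------------------------------------------------
  mat <- run_stage("preprocess",
                   preprocess(mat, config$intensity_threshold))
  pp_path <- file.path(config$out_dir, "preprocessed.tsv")
  ss_path <- file.path(config$out_dir, "preprocessed_samples.tsv")
  write_ncx_matrix(mat, pp_path, ss_path)
  emit("preprocessed", pp_path); emit("preprocessed_samples", ss_path)

  # --- networks ------------------------------------------------------
  conditions <- c("global", "relapse", "remission", "control")
  nets <- run_stage("network", {
    stats::setNames(lapply(conditions, function(cond) {
      alpha <- if (cond == "global") config$alpha_global
               else config$alpha_condition
      build_condition_network(mat, cond, alpha)
    }), conditions)
  })
  for (cond in conditions) {
    p <- file.path(config$out_dir, paste0("network_", cond, ".tsv"))
    write_network_tsv(nets[[cond]], p,
                      sif_file = file.path(config$out_dir,
                                           paste0("network_", cond, ".sif")))
    emit(paste0("network_", cond), p)
  }

  # --- topology ------------------------------------------------------
  topo <- run_stage("topology", {
    cents <- lapply(nets, combined_centrality)
    hubs <- lapply(cents, top_central_ncrnas,
                   percentile = config$hub_percentile)
    list(centrality = cents, hubs = hubs,
         core = core_subnetwork(nets$global, hubs$global$node),
         summaries = lapply(nets, descriptors))
  })
  for (cond in conditions) {
    p <- file.path(config$out_dir, paste0("centrality_", cond, ".tsv"))
    utils::write.table(topo$centrality[[cond]], p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(paste0("centrality_", cond), p)
  }
  desc_path <- file.path(config$out_dir, "descriptors.json")
  jsonlite::write_json(lapply(topo$summaries, unclass), desc_path,
                       auto_unbox = TRUE, digits = NA)
  emit("descriptors", desc_path)

  # --- differential networks ----------------------------------------
  diff <- run_stage("diffnet", {
    cn <- nets[c("relapse", "remission", "control")]
    list(edge_venn = edge_intersections(cn[[1]], cn[[2]], cn[[3]]),
         node_venn = node_intersections(cn[[1]], cn[[2]], cn[[3]]),
         core = status_independent_core(cn[[1]], cn[[2]], cn[[3]]),
         disease = disease_specific_network(cn[[1]], cn[[2]], cn[[3]]),
         pca = topology_pca(topo$summaries[c("relapse", "remission",
                                             "control")]),
         dist_cor = distribution_correlations(cn[[1]], cn[[2]], cn[[3]]))
  })
  venn_path <- file.path(config$out_dir, "venn.json")
  jsonlite::write_json(
    list(edges = diff$edge_venn[c("regions", "n_union", "n_triple",
                                  "triple_pct")],
         nodes = diff$node_venn[c("regions", "n_union", "n_triple",
                                  "triple_pct")]),
    venn_path, auto_unbox = TRUE, digits = NA)
  emit("venn", venn_path)
  for (nm in c("core", "disease")) {
    p <- file.path(config$out_dir, paste0("network_", nm, ".tsv"))
    write_network_tsv(diff[[nm]], p)
    emit(paste0("network_", nm), p)
  }

  # --- rank products -------------------------------------------------
  de <- run_stage("rankprod", {
    ncr <- ncx_subset(mat, genes = names(mat$gene_class)[
      mat$gene_class == "ncRNA"])
    list(relapse = rank_products(ncr, "relapse_vs_remission",
                                 n_permutations = config$n_permutations,
                                 pfp_cutoff = config$pfp_cutoff,
                                 seed = config$seed),
         remission = rank_products(ncr, "remission_vs_controls",
                                   n_permutations = config$n_permutations,
                                   pfp_cutoff = config$pfp_cutoff,
                                   seed = config$seed + 1L))
  })
  for (nm in names(de)) {
    p <- file.path(config$out_dir, paste0("rankprod_", nm, ".tsv"))
    write_de_tsv(de[[nm]], p)
    emit(paste0("rankprod_", nm), p)
  }

  # --- candidates ----------------------------------------------------
  cands <- run_stage("candidates", {
    lists_rel <- de_gene_lists(de$relapse)
    lists_rem <- de_gene_lists(de$remission)
    ctab <- select_candidates(diff$disease, lists_rel$all, lists_rem$all)
    control_cent <- topo$centrality$control
    flag_caution(ctab,
                 global_hubs = topo$hubs$global$node,
                 control_hubs = topo$hubs$control$node,
                 core_net = diff$core)
  })
  cand_path <- file.path(config$out_dir, "candidates.tsv")
  write_candidates_tsv(cands, cand_path)
  emit("candidates", cand_path)

  # --- manifest + config echo ---------------------------------------
  cfg_path <- file.path(config$out_dir, "run_config.json")
  cfg_echo <- config
  cfg_echo$input <- if (inherits(config$input, "ncx_sim_config"))
    c(mode = "simulate", unclass(config$input))
    else c(mode = "load", config$input)
  jsonlite::write_json(unclass(cfg_echo), cfg_path, auto_unbox = TRUE,
                       digits = NA)
  emit("run_config", cfg_path)
  man_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(as.list(manifest), man_path, auto_unbox = TRUE)
  emit("manifest", man_path)

  invisible(list(matrix = mat, truth = truth, networks = nets,
                 topology = topo, diffnet = diff, de = de,
                 candidates = cands, manifest = unlist(manifest)))
}
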