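# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulation configuration for a synthetic expression cohort
#'
#' Defines the stated world the generator emulates: a cohort of paired
#' relapse/remission patients plus unpaired healthy controls, a bipartite
#' negative-regulation structure in which a subset of ncRNAs each repress a
#' power-law-distributed number of mRNA targets, condition-specific
#' rewiring of those target sets, and condition mean-shifts injected into a
#' subset of regulators for differential-expression recovery tests.
#'
#' Defaults mirror the motivating study design: 22 paired patients, 21
#' controls, 1113 ncRNAs, 6451 mRNAs. Tests use smaller explicit values.
#'
#' @param n_patients paired patients (each contributes one relapse and one
#'   remission sample).
#' @param n_controls unpaired control samples.
#' @param n_ncrna,n_mrna gene panel sizes.
#' @param n_regulators ncRNAs with planted targets (<= n_ncrna).
#' @param target_exponent exponent of the truncated discrete power law from
#'   which per-regulator target counts are drawn (P(k) proportional to
#'   k^-target_exponent on 1..max_targets).
#' @param max_targets upper truncation of the target-count law
#'   (<= n_mrna).
#' @param effect_beta regulatory coupling strength: a target mRNA equals
#'   -effect_beta times the sum of its regulators' expression plus noise.
#' @param noise_sd standard deviation of the target-mRNA noise term.
#' @param rewire_fraction fraction in [0, 1] of each regulator's targets
#'   replaced, independently per condition, by uniformly drawn non-target
#'   mRNAs.
#' @param n_de_ncrna regulators mean-shifted in relapse samples (altered in
#'   relapse vs remission).
#' @param n_de_remission regulators (disjoint from the relapse set)
#'   mean-shifted in both patient conditions (altered in remission vs
#'   controls).
#' @param de_shift size of the injected mean shift.
#' @param patient_sd sd of the per-patient scalar baseline shift shared by
#'   a patient's relapse and remission samples (within-subject
#'   correlation); controls carry none.
#' @param n_undetectable_ncrna ncRNAs whose detection flags are set FALSE
#'   in every sample (exercises the detection filter); 0 by default.
#' @param seed integer RNG seed; identical configs give byte-identical
#'   output.
#' @return A validated list of class \code{ncx_sim_config}.
#' @export
sim_config <- function(n_patients = 22, n_controls = 21,
                       n_ncrna = 1113, n_mrna = 6451,
                       n_regulators = 100, target_exponent = 2,
                       max_targets = 100, effect_beta = 1,
                       noise_sd = 0.5, rewire_fraction = 0.6,
                       n_de_ncrna = 10, n_de_remission = n_de_ncrna,
                       de_shift = 2, patient_sd = 0.2,
                       n_undetectable_ncrna = 0, seed = 1L) {
  cfg <- list(n_patients = n_patients, n_controls = n_controls,
              n_ncrna = n_ncrna, n_mrna = n_mrna,
              n_regulators = n_regulators,
              target_exponent = target_exponent, max_targets = max_targets,
              effect_beta = effect_beta, noise_sd = noise_sd,
              rewire_fraction = rewire_fraction, n_de_ncrna = n_de_ncrna,
              n_de_remission = n_de_remission, de_shift = de_shift,
              patient_sd = patient_sd,
              n_undetectable_ncrna = n_undetectable_ncrna,
              seed = as.integer(seed))
  counts <- c("n_patients", "n_controls", "n_ncrna", "n_mrna",
              "n_regulators", "max_targets", "n_de_ncrna",
              "n_de_remission", "n_undetectable_ncrna")
  for (f in counts)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] != round(cfg[[f]]))
      stop("`", f, "` must be a non-negative integer")
  if (cfg$n_regulators > cfg$n_ncrna)
    stop("invalid config: n_regulators exceeds n_ncrna")
  if (cfg$max_targets > cfg$n_mrna)
    stop("invalid config: max_targets exceeds n_mrna (requested target counts cannot be satisfied)")
  if (cfg$rewire_fraction < 0 || cfg$rewire_fraction > 1)
    stop("invalid config: rewire_fraction must lie in [0, 1]")
  if (cfg$n_de_ncrna + cfg$n_de_remission > cfg$n_regulators)
    stop("invalid config: DE regulator sets exceed n_regulators")
  if (cfg$n_undetectable_ncrna > cfg$n_ncrna)
    stop("invalid config: n_undetectable_ncrna exceeds n_ncrna")
  if (cfg$noise_sd < 0 || cfg$patient_sd < 0)
    stop("invalid config: standard deviations must be non-negative")
  structure(cfg, class = "ncx_sim_config")
}

sim_gene_ids <- function(cfg) {
  list(ncrna = sprintf("nc%04d", seq_len(cfg$n_ncrna)),
       mrna = sprintf("m%05d", seq_len(cfg$n_mrna)))
}

#' Plant a condition-rewired bipartite regulatory network
#'
#' Each regulator ncRNA receives a target count drawn from a truncated
#' discrete power law with exponent \code{target_exponent} on
#' \code{1..max_targets} (producing the scale-free outdegree distribution
#' observed in real coexpression networks), and a uniformly drawn target
#' set of that size. Then, independently per condition, a fraction
#' \code{rewire_fraction} of each regulator's targets is replaced by
#' uniformly drawn non-target mRNAs: with \code{rewire_fraction = 0} all
#' three condition edge sets are identical; with 1 and a large mRNA panel
#' they barely overlap.
#'
#' @param config an \code{ncx_sim_config}.
#' @return A list of class \code{ncx_groundtruth}:
#'   \code{planted_edges_by_condition} (named list relapse/remission/control
#'   of data frames with columns \code{ncrna}, \code{mrna}),
#'   \code{regulators}, \code{de_ncrna_relapse}, \code{de_ncrna_remission}.
#' @export
plant_regulatory_network <- function(config) {
  stopifnot(inherits(config, "ncx_sim_config"))
  with_seed(config$seed, plant_regulatory_network_impl(config))
}

plant_regulatory_network_impl <- function(cfg) {
  ids <- sim_gene_ids(cfg)
  regs <- ids$ncrna[seq_len(cfg$n_regulators)]
  k_support <- seq_len(cfg$max_targets)
  k_prob <- k_support^(-cfg$target_exponent)
  k <- sample(k_support, cfg$n_regulators, replace = TRUE,
              prob = k_prob / sum(k_prob))
  base_targets <- lapply(k, function(ki) sample(ids$mrna, ki))
  conditions <- c("relapse", "remission", "control")
  edge_sets <- lapply(conditions, function(cond) {
    per_reg <- lapply(seq_along(regs), function(i) {
      tg <- base_targets[[i]]
      n_rw <- round(cfg$rewire_fraction * length(tg))
      if (n_rw > 0) {
        drop_idx <- sample(length(tg), n_rw)
        pool <- setdiff(ids$mrna, tg)
        tg <- c(tg[-drop_idx], sample(pool, n_rw))
      }
      data.frame(ncrna = regs[i], mrna = tg, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, per_reg)
    rownames(df) <- NULL
    df
  })
  names(edge_sets) <- conditions
  de_rel <- regs[seq_len(cfg$n_de_ncrna)]
  de_rem <- regs[cfg$n_de_ncrna + seq_len(cfg$n_de_remission)]
  structure(list(planted_edges_by_condition = edge_sets,
                 regulators = regs,
                 target_counts = stats::setNames(k, regs),
                 de_ncrna_relapse = de_rel,
                 de_ncrna_remission = de_rem),
            class = "ncx_groundtruth")
}

#' Generate a synthetic expression cohort with planted structure
#'
#' Simulates the full cohort under the planted regulatory network:
#' \itemize{
#'   \item ncRNA expression is standard normal per sample, plus a
#'     per-patient scalar baseline shift shared by that patient's relapse
#'     and remission samples (within-subject correlation).
#'   \item A non-target mRNA is standard-normal noise; a target mRNA equals
#'     \code{-effect_beta} times the sum of its regulators' expression in
#'     that sample (using the edge set of the sample's condition) plus
#'     Gaussian noise with sd \code{noise_sd}.
#'   \item The relapse-DE regulators get \code{+de_shift} in relapse
#'     samples; the remission-DE regulators get \code{+de_shift} in both
#'     patient conditions (hence altered in remission vs controls).
#'   \item All genes are flagged detectable unless
#'     \code{n_undetectable_ncrna > 0}.
#' }
#'
#' @param config an \code{ncx_sim_config}.
#' @return A list with elements \code{matrix} (an \code{ncx_matrix}) and
#'   \code{truth} (an \code{ncx_groundtruth}).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "ncx_sim_config"))
  with_seed(config$seed, {
    truth <- plant_regulatory_network_impl(config)
    mat <- generate_cohort_impl(config, truth)
    list(matrix = mat, truth = truth)
  })
}

generate_cohort_impl <- function(cfg, truth) {
  ids <- sim_gene_ids(cfg)
  pat <- sprintf("P%03d", seq_len(cfg$n_patients))
  sample_ids <- c(paste0(pat, "_rel"), paste0(pat, "_rem"),
                  sprintf("C%03d", seq_len(cfg$n_controls)))
  condition <- rep(c("relapse", "remission", "control"),
                   c(cfg$n_patients, cfg$n_patients, cfg$n_controls))
  patient_id <- c(pat, pat, rep(NA_character_, cfg$n_controls))
  ns <- length(sample_ids)

  # ncRNA layer: iid standard normal + patient baseline + DE shifts
  ncv <- matrix(stats::rnorm(cfg$n_ncrna * ns), cfg$n_ncrna, ns,
                dimnames = list(ids$ncrna, sample_ids))
  if (cfg$n_patients > 0 && cfg$patient_sd > 0) {
    shift <- stats::rnorm(cfg$n_patients, 0, cfg$patient_sd)
    for (j in which(!is.na(patient_id)))
      ncv[, j] <- ncv[, j] + shift[match(patient_id[j], pat)]
  }
  if (length(truth$de_ncrna_relapse))
    ncv[truth$de_ncrna_relapse, condition == "relapse"] <-
      ncv[truth$de_ncrna_relapse, condition == "relapse"] + cfg$de_shift
  if (length(truth$de_ncrna_remission))
    ncv[truth$de_ncrna_remission, condition != "control"] <-
      ncv[truth$de_ncrna_remission, condition != "control"] + cfg$de_shift

  # mRNA layer: noise baseline, overwritten for targets per condition
  mrv <- matrix(stats::rnorm(cfg$n_mrna * ns), cfg$n_mrna, ns,
                dimnames = list(ids$mrna, sample_ids))
  for (cond in names(truth$planted_edges_by_condition)) {
    cols <- which(condition == cond)
    if (!length(cols)) next
    ed <- truth$planted_edges_by_condition[[cond]]
    if (!nrow(ed)) next
    tg <- unique(ed$mrna)
    reg_sum <- matrix(0, length(tg), length(cols),
                      dimnames = list(tg, sample_ids[cols]))
    for (i in seq_len(nrow(ed)))
      reg_sum[ed$mrna[i], ] <- reg_sum[ed$mrna[i], ] + ncv[ed$ncrna[i], cols]
    mrv[tg, cols] <- -cfg$effect_beta * reg_sum +
      stats::rnorm(length(tg) * length(cols), 0, cfg$noise_sd)
  }

  values <- rbind(ncv, mrv)
  detectable <- matrix(TRUE, nrow(values), ns, dimnames = dimnames(values))
  if (cfg$n_undetectable_ncrna > 0) {
    # undetectable ncRNAs are drawn from the non-regulator tail
    und <- utils::tail(ids$ncrna, cfg$n_undetectable_ncrna)
    detectable[und, ] <- FALSE
  }
  ncx_matrix(values,
             gene_class = rep(c("ncRNA", "mRNA"),
                              c(cfg$n_ncrna, cfg$n_mrna)),
             condition = condition, patient_id = patient_id,
             detectable = detectable)
}

#' Write a simulated cohort to disk
#'
#' Emits the expression TSV + sample sheet the pipeline reads, the planted
#' ground-truth edge list (columns condition, ncrna, mrna), and a JSON copy
#' of the configuration.
#'
#' @param cohort output of \code{\link{generate_cohort}}.
#' @param config the \code{ncx_sim_config} used.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named vector of the written paths.
#' @export
write_cohort <- function(cohort, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "expression.tsv"),
             samples = file.path(dir, "samples.tsv"),
             detection = file.path(dir, "detection.tsv"),
             truth = file.path(dir, "planted_edges.tsv"),
             config = file.path(dir, "sim_config.json"))
  write_ncx_matrix(cohort$matrix, paths["matrix"], paths["samples"],
                   paths["detection"])
  ed <- do.call(rbind, lapply(names(cohort$truth$planted_edges_by_condition),
    function(cond) cbind(condition = cond,
                         cohort$truth$planted_edges_by_condition[[cond]])))
  utils::write.table(ed, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(unclass(config), paths["config"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
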