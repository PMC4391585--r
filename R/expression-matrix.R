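#' Expression matrix with gene and sample annotations
#'
#' Container for a genes-by-samples expression matrix carrying the metadata
#' the pipeline needs: a gene class (\code{"ncRNA"} or \code{"mRNA"}) per row,
#' a clinical condition (\code{"relapse"}, \code{"remission"} or
#' \code{"control"}) per column, patient pairing ids linking a patient's
#' relapse and remission samples, and per-gene/per-sample detection flags.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row and
#'   column names are the gene and sample identifiers and must be unique.
#' @param gene_class character vector, one of \code{"ncRNA"}/\code{"mRNA"}
#'   per gene.
#' @param condition character vector, one of
#'   \code{"relapse"}/\code{"remission"}/\code{"control"} per sample.
#' @param patient_id character vector per sample; the relapse and remission
#'   samples of one patient share an id, controls carry \code{NA}.
#' @param detectable logical matrix of the same dimension as \code{values}
#'   (vendor detection calls are inputs, not computed here). A single logical
#'   vector per gene is recycled across samples. Default: all \code{TRUE}.
#' @param ncrna_subclass optional character vector per gene
#'   (\code{"miRNA"}, \code{"SNORA"}, \code{"SNORD"}, \code{"sdRNA"},
#'   \code{"other"}); \code{NA} for mRNAs.
#'
#' @return An object of class \code{ncx_matrix}.
#' @export
ncx_matrix <- function(values, gene_class, condition,
                       patient_id = rep(NA_character_, ncol(values)),
                       detectable = NULL, ncrna_subclass = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  gene_class <- as.character(gene_class)
  condition <- as.character(condition)
  if (length(gene_class) != nrow(values))
    stop("`gene_class` length must equal the number of genes")
  if (!all(gene_class %in% c("ncRNA", "mRNA")))
    stop("`gene_class` entries must be 'ncRNA' or 'mRNA'")
  if (length(condition) != ncol(values))
    stop("`condition` length must equal the number of samples")
  if (!all(condition %in% c("relapse", "remission", "control")))
    stop("`condition` entries must be 'relapse', 'remission' or 'control'")
  patient_id <- as.character(patient_id)
  if (length(patient_id) != ncol(values))
    stop("`patient_id` length must equal the number of samples")
  if (any(condition %in% c("relapse", "remission") & is.na(patient_id)))
    stop("every relapse/remission sample needs a patient_id")
  if (is.null(detectable)) {
    detectable <- matrix(TRUE, nrow(values), ncol(values),
                         dimnames = dimnames(values))
  } else if (is.vector(detectable)) {
    detectable <- matrix(as.logical(detectable), nrow(values), ncol(values),
                         dimnames = dimnames(values))
  } else {
    detectable <- as.matrix(detectable)
    if (!identical(dim(detectable), dim(values)))
      stop("`detectable` must match the dimensions of `values`")
    dimnames(detectable) <- dimnames(values)
  }
  if (is.null(ncrna_subclass))
    ncrna_subclass <- rep(NA_character_, nrow(values))
  structure(
    list(values = values,
         gene_class = stats::setNames(gene_class, rownames(values)),
         condition = stats::setNames(condition, colnames(values)),
         patient_id = stats::setNames(patient_id, colnames(values)),
         detectable = detectable,
         ncrna_subclass = stats::setNames(ncrna_subclass, rownames(values))),
    class = "ncx_matrix")
}

#' @export
print.ncx_matrix <- function(x, ...) {
  cat(sprintf(
    "ncx_matrix: %d genes (%d ncRNA, %d mRNA) x %d samples (%s)\n",
    nrow(x$values), sum(x$gene_class == "ncRNA"),
    sum(x$gene_class == "mRNA"), ncol(x$values),
    paste(sprintf("%d %s", table(x$condition), names(table(x$condition))),
          collapse = ", ")))
  invisible(x)
}

#' @export
dim.ncx_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by genes and/or samples
#'
#' @param mat an \code{ncx_matrix}.
#' @param genes,samples character vectors of ids (or logical/integer indices)
#'   to keep; \code{NULL} keeps all.
#' @return The subsetted \code{ncx_matrix}.
#' @export
ncx_subset <- function(mat, genes = NULL, samples = NULL) {
  stopifnot(inherits(mat, "ncx_matrix"))
  g <- if (is.null(genes)) rownames(mat$values) else rownames(mat$values[genes, , drop = FALSE])
  s <- if (is.null(samples)) colnames(mat$values) else colnames(mat$values[, samples, drop = FALSE])
  ncx_matrix(mat$values[g, s, drop = FALSE],
             gene_class = mat$gene_class[g],
             condition = mat$condition[s],
             patient_id = mat$patient_id[s],
             detectable = mat$detectable[g, s, drop = FALSE],
             ncrna_subclass = mat$ncrna_subclass[g])
}

#' Read an expression matrix and its sample sheet from TSV
#'
#' The matrix file has one row per gene: first column the gene id, second the
#' gene class (ncRNA/mRNA), remaining columns the samples. The sample sheet
#' maps \code{sample_id} to \code{condition} and \code{patient_id}. An
#' optional detection file mirrors the matrix layout with TRUE/FALSE entries.
#'
#' @param matrix_file path to the expression TSV.
#' @param sample_sheet path to the sample sheet TSV.
#' @param detection_file optional path to a detection-flag TSV.
#' @return An \code{ncx_matrix}.
#' @export
read_ncx_matrix <- function(matrix_file, sample_sheet, detection_file = NULL) {
  tab <- utils::read.delim(matrix_file, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3 || !all(c("gene_id", "gene_class") %in% names(tab)[1:2]))
    stop("malformed expression matrix: expected columns gene_id, gene_class, <samples...>")
  ss <- utils::read.delim(sample_sheet, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition", "patient_id")
  if (!all(need %in% names(ss)))
    stop("malformed sample sheet: expected columns ", paste(need, collapse = ", "))
  vals <- as.matrix(tab[, -(1:2), drop = FALSE])
  if (!is.numeric(vals)) stop("malformed expression matrix: non-numeric values")
  rownames(vals) <- tab$gene_id
  missing <- setdiff(colnames(vals), ss$sample_id)
  if (length(missing))
    stop("samples absent from sample sheet: ", paste(missing, collapse = ", "))
  ss <- ss[match(colnames(vals), ss$sample_id), ]
  det <- NULL
  if (!is.null(detection_file)) {
    dt <- utils::read.delim(detection_file, check.names = FALSE,
                            stringsAsFactors = FALSE)
    det <- as.matrix(dt[, -(1:2), drop = FALSE]) |> apply(2, as.logical)
    rownames(det) <- dt$gene_id
    det <- det[rownames(vals), colnames(vals), drop = FALSE]
  }
  ncx_matrix(vals, gene_class = tab$gene_class, condition = ss$condition,
             patient_id = ss$patient_id, detectable = det)
}

#' Write an expression matrix and its sample sheet to TSV
#'
#' @param mat an \code{ncx_matrix}.
#' @param matrix_file,sample_sheet output paths.
#' @param detection_file optional path for the detection flags.
#' @return Invisibly, the matrix file path.
#' @export
write_ncx_matrix <- function(mat, matrix_file, sample_sheet,
                             detection_file = NULL) {
  stopifnot(inherits(mat, "ncx_matrix"))
  tab <- data.frame(gene_id = rownames(mat$values),
                    gene_class = unname(mat$gene_class),
                    mat$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, matrix_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ss <- data.frame(sample_id = colnames(mat$values),
                   condition = unname(mat$condition),
                   patient_id = unname(mat$patient_id),
                   stringsAsFactors = FALSE)
  utils::write.table(ss, sample_sheet, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(detection_file)) {
    dt <- data.frame(gene_id = rownames(mat$values),
                     gene_class = unname(mat$gene_class),
                     mat$detectable, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(dt, detection_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(matrix_file)
}
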