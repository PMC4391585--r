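#' Filter mRNAs by 90th-percentile intensity
#'
#' Removes the least informative mRNA probes: an mRNA row is dropped when the
#' chosen per-gene percentile of its intensities across all samples is
#' strictly smaller than \code{threshold}. The threshold is platform-specific
#' (typically the mean intensity of the array's negative control probes) and
#' must be supplied by the user. ncRNA rows pass through untouched.
#'
#' Percentiles use linear interpolation between order statistics
#' (\code{quantile} type 7), the default convention in most software.
#'
#' @param mat an \code{ncx_matrix} on the raw intensity scale.
#' @param threshold intensity cutoff; rows with percentile value
#'   \code{< threshold} are removed (strict).
#' @param percentile percentile in (0, 100); default 90.
#' @return The filtered \code{ncx_matrix}.
#' @export
filter_mrna_by_intensity <- function(mat, threshold, percentile = 90) {
  stopifnot(inherits(mat, "ncx_matrix"))
  if (!is.numeric(percentile) || length(percentile) != 1 ||
      percentile <= 0 || percentile >= 100)
    stop("`percentile` must lie strictly between 0 and 100")
  if (!is.numeric(threshold) || length(threshold) != 1)
    stop("`threshold` must be a single number")
  p90 <- apply(mat$values, 1, stats::quantile, probs = percentile / 100,
               names = FALSE)
  keep <- mat$gene_class != "mRNA" | p90 >= threshold
  ncx_subset(mat, genes = rownames(mat$values)[keep])
}

#' Filter ncRNAs by detection call
#'
#' Removes ncRNA probes not detected in any sample, using the per-gene,
#' per-sample detection flags carried by the matrix (detection calls are
#' vendor output and are taken as input here). An ncRNA is retained when it
#' is detectable in at least one sample; mRNA rows pass through untouched.
#'
#' @param mat an \code{ncx_matrix} with detection flags.
#' @return The filtered \code{ncx_matrix}.
#' @export
filter_ncrna_by_detection <- function(mat) {
  stopifnot(inherits(mat, "ncx_matrix"))
  if (is.null(mat$detectable) || anyNA(mat$detectable))
    stop("detection flags are missing or incomplete")
  any_det <- rowSums(mat$detectable) > 0
  keep <- mat$gene_class != "ncRNA" | any_det
  ncx_subset(mat, genes = rownames(mat$values)[keep])
}

#' Z-score standardize each gene across all samples
#'
#' Centers and scales every gene row to mean 0 and standard deviation 1
#' across all retained samples pooled over conditions (sample sd, n-1
#' denominator). Standardizing per gene before merging platforms or after
#' merging is equivalent, and Pearson correlations are unaffected by the
#' population/sample-sd choice.
#'
#' @param mat an \code{ncx_matrix} with at least two samples.
#' @return The standardized \code{ncx_matrix}.
#' @export
zscore_standardize <- function(mat) {
  stopifnot(inherits(mat, "ncx_matrix"))
  if (ncol(mat$values) < 2) stop("standardization needs at least 2 samples")
  sds <- apply(mat$values, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance gene(s): ",
         paste(rownames(mat$values)[sds == 0], collapse = ", "))
  z <- (mat$values - rowMeans(mat$values)) / sds
  out <- mat
  out$values <- z
  out
}

#' Run the full preprocessing stage
#'
#' Applies the detection filter to ncRNAs, the intensity filter to mRNAs
#' (when a threshold is given), and z-score standardization, in that order.
#' The two filters are mutually order-insensitive.
#'
#' @param mat an \code{ncx_matrix}.
#' @param intensity_threshold mRNA intensity cutoff, or \code{NULL} to skip
#'   the intensity filter (e.g. for simulated cohorts already on the
#'   standardized scale).
#' @param percentile percentile for the intensity filter.
#' @return A filtered, standardized \code{ncx_matrix}.
#' @export
preprocess <- function(mat, intensity_threshold = NULL, percentile = 90) {
  mat <- filter_ncrna_by_detection(mat)
  if (!is.null(intensity_threshold))
    mat <- filter_mrna_by_intensity(mat, intensity_threshold, percentile)
  zscore_standardize(mat)
}
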