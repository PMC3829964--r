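#' Quantile-normalize one dataset of arrays
#'
#' Forces every sample column of a dataset to share the same distribution:
#' the vector of row-wise means of the order statistics (the standard
#' mean-of-order-statistics construction). Ties within a column receive the
#' mean of the normalized values over their tied ranks. The two datasets of
#' the study design are normalized separately; mixing samples from
#' different datasets is an error.
#'
#' @param x an [intensity_matrix()].
#' @param dataset dataset id to select (1 or 2). May be omitted when `x`
#'   already contains a single dataset.
#' @return An [intensity_matrix()] restricted to the dataset's samples,
#'   with normalized values.
#' @export
quantile_normalize <- function(x, dataset = NULL) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (!is.null(dataset)) {
    sel <- x$samples$dataset == dataset
    if (!any(sel)) stop("no samples in dataset ", dataset)
    x <- subset_samples(x, which(sel))
  }
  if (length(unique(x$samples$dataset)) > 1L)
    stop("samples from mixed datasets; normalize each dataset separately")
  if (ncol(x$values) < 2L)
    stop("quantile normalization needs at least 2 samples")
  norm <- limma::normalizeQuantiles(x$values, ties = TRUE)
  dimnames(norm) <- dimnames(x$values)
  intensity_matrix(norm, x$samples)
}

#' Aggregate probe intensities to contig level
#'
#' Pools the oligo probes designed on the same contig by taking their
#' unweighted arithmetic mean per sample (sense and antisense probes of
#' unknown-ORF contigs are averaged together).
#'
#' @param x an [intensity_matrix()].
#' @param probes a `probe_map` data.frame (`probe_id`, `contig_id`, ...).
#' @return A [contig_expression()] on the linear scale.
#' @export
aggregate_probes <- function(x, probes) {
  stopifnot(inherits(x, "intensity_matrix"))
  idx <- match(rownames(x$values), probes$probe_id)
  if (anyNA(idx)) {
    bad <- rownames(x$values)[is.na(idx)]
    stop("probe(s) missing from the probe map: ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) sprintf(" ... (%d total)", length(bad)))
  }
  contig <- probes$contig_id[idx]
  sums <- rowsum(x$values, contig)
  agg <- sums / as.vector(table(contig)[rownames(sums)])
  contig_expression(agg, x$samples, scale = "linear")
}

#' Log-transform a contig expression table
#'
#' Applies `value -> log_base(value + offset)` elementwise. The default
#' (base 2, offset 1) maps the background-subtraction floor at zero
#' intensity to 0 and leaves well-expressed contigs essentially on the
#' log2 scale.
#'
#' @param x a linear-scale [contig_expression()].
#' @param base logarithm base, > 1.
#' @param offset nonnegative value added before taking logs.
#' @return A log-scale [contig_expression()] recording `base` and
#'   `offset`.
#' @export
log_transform <- function(x, base = 2, offset = 1) {
  stopifnot(inherits(x, "contig_expression"))
  if (x$scale != "linear") stop("table is already on the log scale")
  if (base <= 1) stop("log base must exceed 1")
  if (offset < 0) stop("offset must be nonnegative")
  if (any(x$values + offset <= 0))
    stop("value + offset must be positive for all entries")
  contig_expression(log(x$values + offset, base), x$samples,
                    scale = "log", log_base = base, log_offset = offset)
}

#' Per-sample presence/absence calls
#'
#' A contig is called present on an individual array when its aggregated
#' linear intensity is at or above the threshold. The default threshold of
#' 100 reuses the expression cutoff of the differential screens.
#'
#' @param x a linear-scale [contig_expression()].
#' @param threshold positive intensity threshold; present means
#'   `value >= threshold`.
#' @return Logical matrix, contigs x samples.
#' @export
presence_calls <- function(x, threshold = 100) {
  stopifnot(inherits(x, "contig_expression"))
  if (x$scale != "linear")
    stop("presence calls are defined on the linear scale")
  if (threshold <= 0) stop("threshold must be positive")
  x$values >= threshold
}
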