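#' Probe-level intensity matrix with sample annotation
#'
#' Container for background-subtracted, nonnegative probe intensities from
#' single-color arrays, together with the sample sheet that assigns every
#' array to a group (caste or subcaste), a dataset (1 = field castes,
#' 2 = laboratory worker subcastes) and a replicate type.
#'
#' @param values numeric matrix, probes x samples; rownames are probe ids,
#'   colnames are sample ids. Values must be finite and nonnegative.
#' @param samples data.frame with columns `sample_id`, `group`, `dataset`,
#'   `replicate_type` (`"biological"` or `"technical"`), one row per column
#'   of `values`, in the same order.
#' @return An object of class `intensity_matrix`: a list with elements
#'   `values` and `samples`.
#' @export
intensity_matrix <- function(values, samples) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "group", "dataset", "replicate_type")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(samples) != ncol(values))
    stop("sample sheet has ", nrow(samples), " rows but the matrix has ",
         ncol(values), " columns")
  if (is.null(colnames(values))) colnames(values) <- samples$sample_id
  if (!identical(colnames(values), as.character(samples$sample_id)))
    stop("column names of the intensity matrix must match sample_id order")
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample ids")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("probe rownames must be present and unique")
  if (anyNA(values)) stop("missing intensity values are not allowed")
  if (any(values < 0)) stop("negative intensities are not allowed")
  bad <- !samples$replicate_type %in% c("biological", "technical")
  if (any(bad))
    stop("replicate_type must be 'biological' or 'technical'")
  structure(list(values = values, samples = samples),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat("intensity_matrix: ", nrow(x$values), " probes x ",
      ncol(x$values), " samples\n", sep = "")
  tab <- table(x$samples$group, x$samples$dataset)
  cat("samples per group (columns = dataset):\n")
  print(tab)
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' Subset an intensity matrix by samples
#'
#' @param x an `intensity_matrix`.
#' @param samples character vector of sample ids, or logical/integer index
#'   into the sample sheet rows.
#' @return An `intensity_matrix` restricted to the selected samples.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, c("intensity_matrix", "contig_expression")))
  if (is.character(samples)) {
    idx <- match(samples, x$samples$sample_id)
    if (anyNA(idx)) stop("unknown sample id(s): ",
                         paste(samples[is.na(idx)], collapse = ", "))
  } else {
    idx <- seq_len(nrow(x$samples))[samples]
    if (anyNA(idx)) stop("sample index out of range")
  }
  out <- x
  out$values <- x$values[, idx, drop = FALSE]
  out$samples <- x$samples[idx, , drop = FALSE]
  rownames(out$samples) <- NULL
  out
}

#' Contig-level expression table
#'
#' Aggregated expression values per contig and sample; the unit on which all
#' statistics (ANOVA, t-tests, expression factors, presence calls) operate.
#'
#' @param values numeric matrix, contigs x samples; rownames are contig ids.
#' @param samples sample sheet as in [intensity_matrix()].
#' @param scale `"linear"` (fluorescence units) or `"log"`.
#' @param log_base,log_offset the transform parameters when `scale = "log"`,
#'   i.e. values are `log(linear + log_offset, log_base)`.
#' @return An object of class `contig_expression`.
#' @export
contig_expression <- function(values, samples,
                              scale = c("linear", "log"),
                              log_base = NA_real_, log_offset = NA_real_) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (nrow(samples) != ncol(values))
    stop("sample sheet does not match the value matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("contig rownames must be present and unique")
  if (anyNA(values)) stop("missing values are not allowed")
  if (scale == "linear" && any(values < 0))
    stop("negative intensities are not allowed on the linear scale")
  structure(list(values = values, samples = samples, scale = scale,
                 log_base = log_base, log_offset = log_offset),
            class = "contig_expression")
}

#' @export
print.contig_expression <- function(x, ...) {
  cat("contig_expression: ", nrow(x$values), " contigs x ",
      ncol(x$values), " samples (", x$scale, " scale)\n", sep = "")
  if (x$scale == "log")
    cat("log base ", x$log_base, ", offset ", x$log_offset, "\n", sep = "")
  cat("groups: ", paste(unique(x$samples$group), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.contig_expression <- function(x) dim(x$values)

#' Contig ids of a contig-level table
#' @param x a `contig_expression`.
#' @return Character vector of contig ids.
#' @export
contig_ids <- function(x) {
  if (inherits(x, "contig_expression")) return(rownames(x$values))
  if (is.numeric(x) && length(x) == 1L) return(make_contig_ids(x))
  stop("cannot extract contig ids from this object")
}

# canonical contig naming used by the simulator
make_contig_ids <- function(n) sprintf("c%05d", seq_len(n))
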