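#' Write a simulated dataset as TSV files
#'
#' Writes `probe_map.tsv`, `intensities.tsv` (first column `probe_id`,
#' one column per sample), `sample_sheet.tsv` and `truth.tsv` into a
#' directory.
#'
#' @param sim a `sim_result` from [simulate_intensities()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_sim_data <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("probe_map.tsv", "intensities.tsv",
                            "sample_sheet.tsv", "truth.tsv"))
  utils::write.table(sim$probes, paths[1L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_intensities(sim$intensities, paths[2L], paths[3L])
  utils::write.table(sim$truth$spikes, paths[4L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Write an intensity matrix and its sample sheet
#' @param x an [intensity_matrix()].
#' @param values_path,samples_path TSV paths.
#' @return Invisibly, the paths.
#' @export
write_intensities <- function(x, values_path, samples_path) {
  stopifnot(inherits(x, "intensity_matrix"))
  df <- data.frame(probe_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, values_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(values_path, samples_path))
}

#' Read an intensity matrix and sample sheet from TSV
#' @param values_path TSV with first column `probe_id`, one column per
#'   sample.
#' @param samples_path sample sheet TSV (`sample_id`, `group`, `dataset`,
#'   `replicate_type`).
#' @return An [intensity_matrix()].
#' @export
read_intensities <- function(values_path, samples_path) {
  v <- utils::read.delim(values_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(v[, -1L, drop = FALSE])
  rownames(m) <- v[[1L]]
  s <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  intensity_matrix(m, s)
}

#' Read a probe map TSV
#' @param path TSV with columns `probe_id`, `contig_id`, `contig_class`,
#'   `orientation`.
#' @return A `probe_map` data.frame.
#' @export
read_probe_map <- function(path) {
  pm <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("probe_id", "contig_id", "contig_class", "orientation")
  if (!all(req %in% names(pm)))
    stop("probe map must have columns ", paste(req, collapse = ", "))
  class(pm) <- c("probe_map", "data.frame")
  pm
}

#' Read a GO annotation TSV
#' @param path TSV with columns `contig_id`, `term`, `category`, `level`.
#' @return Annotation data.frame.
#' @export
read_go_annotations <- function(path) {
  .check_annotations(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Read a GEO series-matrix text file
#'
#' Minimal reader for the tab-separated series-matrix format: metadata
#' lines prefixed with `!` are skipped; the block between
#' `!series_matrix_table_begin/end` (or, failing that, all unprefixed
#' lines) is parsed with the first column as probe/feature ids.
#'
#' @param path path to an (uncompressed) series-matrix text file.
#' @return Numeric matrix, features x samples.
#' @export
read_series_matrix <- function(path) {
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(beg) == 1L && length(end) == 1L && end > beg + 1L) {
    lines <- lines[(beg + 1L):(end - 1L)]
  } else {
    lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  }
  con <- textConnection(lines)
  on.exit(close(con))
  df <- utils::read.delim(con, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- gsub('^"|"$', "", df[[1L]])
  m
}

#' Write a differential-expression table as TSV
#' @param x a `de_table`.
#' @param path output TSV path.
#' @return Invisibly, the path.
#' @export
write_de_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an EF screen table as TSV
#' @param x an `ef_screen`.
#' @param path output TSV path.
#' @return Invisibly, the path.
#' @export
write_ef_screen <- function(x, path) {
  df <- as.data.frame(x)
  df$comparison <- paste0(attr(x, "group_a"), "_vs_", attr(x, "group_b"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
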