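# Small in-code fixtures shared across test files.

tiny_config <- function(seed = 1L, ...) {
  sim_config(n_contigs = 12L, frac_known_orf = 0.5, n_or_contigs = 2L,
             groups = study_groups(c("large", "tiny")),
             baseline_log2_mean = 8, baseline_log2_sd = 0.5,
             probe_offset_sd = 0.2, replicate_noise_sd = 0.2,
             seed = seed, ...)
}

# Build a contig_expression table directly from a matrix of log-scale
# values; one biological sample per column unless replicate_type given.
log_table <- function(values, groups, replicate_type = NULL,
                      dataset = 1L, log_base = 2) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(replicate_type))
    replicate_type <- rep("biological", length(groups))
  samples <- data.frame(
    sample_id = paste0("s", seq_along(groups)),
    group = groups, dataset = dataset, replicate_type = replicate_type,
    stringsAsFactors = FALSE)
  colnames(values) <- samples$sample_id
  contig_expression(values, samples, scale = "log",
                    log_base = log_base, log_offset = 0)
}

linear_table <- function(values, groups, dataset = 1L) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  samples <- data.frame(
    sample_id = paste0("s", seq_along(groups)),
    group = groups, dataset = dataset,
    replicate_type = rep("biological", length(groups)),
    stringsAsFactors = FALSE)
  colnames(values) <- samples$sample_id
  contig_expression(values, samples, scale = "linear")
}

random_intensity_matrix <- function(n_probes, n_samples, dataset = 1L) {
  m <- matrix(2^rnorm(n_probes * n_samples, 8, 1.5), n_probes, n_samples,
              dimnames = list(sprintf("p%04d", seq_len(n_probes)),
                              sprintf("s%02d", seq_len(n_samples))))
  samples <- data.frame(
    sample_id = colnames(m),
    group = rep(c("a", "b"), length.out = n_samples),
    dataset = dataset,
    replicate_type = "biological", stringsAsFactors = FALSE)
  intensity_matrix(m, samples)
}
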