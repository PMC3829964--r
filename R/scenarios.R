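#' Built-in simulation scenarios
#'
#' Fixed configurations emulating the study's screening and null settings.
#' They are used by the test suite and the reproduction script and are the
#' package's single definition of these conditions.
#'
#' `config_worker_screen()`: 200 OR genes across the worker subcastes
#' (large/tiny, 4 biological replicates each); one gene spiked at
#' 2.1-fold in large workers — the trail-pheromone receptor setting. The
#' within-OR-set baseline spread is 0.2 log2 units: OR genes are each
#' expressed in a small subset of sensory neurons, so whole-antenna
#' intensities within the family occupy a narrow band, and a 0.2–0.3 band
#' is what makes reported candidate EFs of 2–3.4 arithmetically possible
#' at ~2-fold enrichment (see the methods vignette).
#'
#' `config_male_screen()`: 200 OR genes, males vs queens, three genes
#' spiked at 5.5-, 11- and 22.7-fold in males — the sex-pheromone
#' receptor setting.
#'
#' `config_de_null()`: the full five-group study design with no spikes and
#' a transcriptome-wide baseline spread of 1.5 log2 units; used for
#' false-positive calibration of the DE cascade.
#'
#' `config_go_null()`: no spikes, baseline centred at the presence
#' threshold (log2 100) so presence calls vary across arrays; used for
#' the GO chi-square null.
#'
#' `config_de_spike()`: the null design plus one OR contig spiked at
#' 2.3-fold (log2 1.2) in large workers; used for DE power checks.
#'
#' @param seed integer seed.
#' @param n_contigs number of contigs (null scenarios).
#' @return A [sim_config()].
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
config_worker_screen <- function(seed = 1L) {
  ids <- make_contig_ids(200L)
  sim_config(n_contigs = 200L, frac_known_orf = 1, n_or_contigs = 200L,
             groups = study_groups(c("large", "tiny")),
             baseline_log2_mean = 9, baseline_log2_sd = 0.2,
             probe_offset_sd = 0.25, replicate_noise_sd = 0.25,
             spikes = data.frame(contig_id = ids[101L], group = "large",
                                 log2fc = log2(2.1)),
             seed = seed)
}

#' @rdname scenarios
#' @export
config_male_screen <- function(seed = 1L) {
  ids <- make_contig_ids(200L)
  sim_config(n_contigs = 200L, frac_known_orf = 1, n_or_contigs = 200L,
             groups = study_groups(c("queens", "males")),
             baseline_log2_mean = 9, baseline_log2_sd = 0.2,
             probe_offset_sd = 0.25, replicate_noise_sd = 0.25,
             spikes = data.frame(contig_id = ids[c(50L, 100L, 150L)],
                                 group = "males",
                                 log2fc = log2(c(5.5, 11, 22.7))),
             seed = seed)
}

#' @rdname scenarios
#' @export
config_de_null <- function(seed = 1L, n_contigs = 500L) {
  sim_config(n_contigs = n_contigs, frac_known_orf = 0.6,
             n_or_contigs = round(n_contigs / 10),
             groups = study_groups(),
             baseline_log2_mean = 9, baseline_log2_sd = 1.5,
             probe_offset_sd = 0.25, replicate_noise_sd = 0.25,
             seed = seed)
}

#' @rdname scenarios
#' @export
config_go_null <- function(seed = 1L, n_contigs = 300L) {
  sim_config(n_contigs = n_contigs, frac_known_orf = 0.6,
             n_or_contigs = round(n_contigs / 10),
             groups = study_groups(c("large", "tiny")),
             baseline_log2_mean = log2(100), baseline_log2_sd = 1.5,
             probe_offset_sd = 0.25, replicate_noise_sd = 0.25,
             seed = seed)
}

#' @rdname scenarios
#' @export
config_de_spike <- function(seed = 1L, n_contigs = 300L) {
  ids <- make_contig_ids(n_contigs)
  # the spiked contig is an OR contig (5 probes, classes assign OR first)
  sim_config(n_contigs = n_contigs, frac_known_orf = 0.6,
             n_or_contigs = round(n_contigs / 10),
             groups = study_groups(c("large", "tiny")),
             baseline_log2_mean = 9, baseline_log2_sd = 1.5,
             probe_offset_sd = 0.25, replicate_noise_sd = 0.25,
             spikes = data.frame(contig_id = ids[1L], group = "large",
                                 log2fc = 1.2),
             seed = seed)
}
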