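#' Study replicate design
#'
#' The group/replicate layout of the antennal microarray study: dataset 1
#' compares the three castes (queens, males, workers) with four biological
#' replicates each, except workers with three biological replicates and one
#' technical replicate of pooled RNA; dataset 2 compares the worker
#' subcastes (large, tiny) with four biological replicates each.
#'
#' @param groups optional character vector to restrict the design to a
#'   subset of groups (e.g. `c("large", "tiny")`).
#' @return data.frame with columns `group`, `dataset`, `n_biological`,
#'   `n_technical`.
#' @export
study_groups <- function(groups = NULL) {
  g <- data.frame(
    group        = c("queens", "males", "workers", "large", "tiny"),
    dataset      = c(1L, 1L, 1L, 2L, 2L),
    n_biological = c(4L, 4L, 3L, 4L, 4L),
    n_technical  = c(0L, 0L, 1L, 0L, 0L),
    stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    miss <- setdiff(groups, g$group)
    if (length(miss)) stop("unknown group(s): ", paste(miss, collapse = ", "))
    g <- g[g$group %in% groups, , drop = FALSE]
    rownames(g) <- NULL
  }
  g
}

#' Simulation configuration
#'
#' Describes a synthetic probe-level dataset: how many contigs of each class
#' (known ORF, unknown ORF, odorant-receptor contig), the group/replicate
#' design, the log-normal intensity model (baseline, probe offsets,
#' replicate noise, all in log2 units) and group-specific spiked
#' fold-changes that serve as ground truth for recovery tests.
#'
#' The intensity model for a probe p of contig c in sample s of group g is
#' `log2 I = baseline_c + offset_p + spike_{c,g} + noise_{p,s}` with all
#' terms normal; linear intensities are `2^log2 I`, floored at `clip_floor`
#' (the background-subtraction floor). Technical replicates re-draw the
#' noise around their biological source sample with sd
#' `technical_noise_sd` (default half the replicate noise).
#'
#' @param n_contigs total number of contigs.
#' @param frac_known_orf fraction of the non-OR contigs with an identified
#'   ORF (these receive 2 probes; the rest receive 4).
#' @param n_or_contigs number of OR contigs (5 probes each); must not
#'   exceed `n_contigs`.
#' @param groups replicate design as returned by [study_groups()].
#' @param baseline_log2_mean,baseline_log2_sd mean and sd of the per-contig
#'   baseline on the log2 scale.
#' @param probe_offset_sd sd of the per-probe affinity offset (log2 units).
#' @param replicate_noise_sd sd of per-probe, per-sample noise (log2 units).
#' @param technical_noise_sd sd of the technical-replicate re-draw.
#' @param spikes data.frame with columns `contig_id`, `group`, `log2fc`;
#'   each row adds `log2fc` to that contig in that group's samples.
#' @param clip_floor linear intensities below this are set to this value.
#' @param seed integer seed; identical configuration + seed gives
#'   bit-identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_contigs = 500L,
                       frac_known_orf = 0.6,
                       n_or_contigs = round(n_contigs / 10),
                       groups = study_groups(),
                       baseline_log2_mean = 9,
                       baseline_log2_sd = 1.5,
                       probe_offset_sd = 0.25,
                       replicate_noise_sd = 0.25,
                       technical_noise_sd = replicate_noise_sd / 2,
                       spikes = NULL,
                       clip_floor = 0,
                       seed = 1L) {
  n_contigs <- as.integer(n_contigs)
  n_or_contigs <- as.integer(n_or_contigs)
  if (n_contigs < 0L || n_or_contigs < 0L)
    stop("contig counts must be nonnegative")
  if (n_or_contigs > n_contigs)
    stop("n_or_contigs (", n_or_contigs, ") exceeds n_contigs (",
         n_contigs, ")")
  if (frac_known_orf < 0 || frac_known_orf > 1)
    stop("frac_known_orf must lie in [0, 1]")
  if (clip_floor < 0) stop("clip_floor must be nonnegative")
  if (baseline_log2_sd < 0 || probe_offset_sd < 0 ||
      replicate_noise_sd < 0 || technical_noise_sd < 0)
    stop("noise standard deviations must be nonnegative")
  groups <- as.data.frame(groups, stringsAsFactors = FALSE)
  req <- c("group", "dataset", "n_biological", "n_technical")
  if (!all(req %in% names(groups)))
    stop("groups must have columns ", paste(req, collapse = ", "))
  if (anyDuplicated(groups$group)) stop("duplicated group names")
  if (any(groups$n_biological < 1L))
    stop("every group needs at least one biological replicate")

  ids <- make_contig_ids(n_contigs)
  # contig classes: OR contigs first, then known-ORF, then unknown-ORF
  n_non_or <- n_contigs - n_or_contigs
  n_known <- round(frac_known_orf * n_non_or)
  class <- c(rep("or_contig", n_or_contigs),
             rep("known_orf", n_known),
             rep("unknown_orf", n_non_or - n_known))

  if (!is.null(spikes)) {
    spikes <- as.data.frame(spikes, stringsAsFactors = FALSE)
    if (!all(c("contig_id", "group", "log2fc") %in% names(spikes)))
      stop("spikes must have columns contig_id, group, log2fc")
    bad <- setdiff(spikes$contig_id, ids)
    if (length(bad)) stop("spike references unknown contig(s): ",
                          paste(bad, collapse = ", "))
    bad <- setdiff(spikes$group, groups$group)
    if (length(bad)) stop("spike references unknown group(s): ",
                          paste(bad, collapse = ", "))
  } else {
    spikes <- data.frame(contig_id = character(), group = character(),
                         log2fc = numeric(), stringsAsFactors = FALSE)
  }

  structure(list(n_contigs = n_contigs, frac_known_orf = frac_known_orf,
                 n_or_contigs = n_or_contigs, groups = groups,
                 contig_ids = ids, contig_class = class,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 probe_offset_sd = probe_offset_sd,
                 replicate_noise_sd = replicate_noise_sd,
                 technical_noise_sd = technical_noise_sd,
                 spikes = spikes, clip_floor = clip_floor,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: ", x$n_contigs, " contigs (",
      sum(x$contig_class == "or_contig"), " OR, ",
      sum(x$contig_class == "known_orf"), " known-ORF, ",
      sum(x$contig_class == "unknown_orf"), " unknown-ORF), ",
      nrow(x$spikes), " spike(s), seed ", x$seed, "\n", sep = "")
  print(x$groups)
  invisible(x)
}

#' Design oligo probes for a simulated contig set
#'
#' Applies the array's probe multiplicity rules: contigs with an identified
#' ORF get 2 probes (sense), contigs with unknown ORF get 2 additional
#' probes in the opposite reading direction (4 total), and every OR contig
#' gets 5 probes regardless of ORF status.
#'
#' @param config a [sim_config()].
#' @return A `probe_map` data.frame with columns `probe_id`, `contig_id`,
#'   `contig_class`, `orientation`.
#' @export
design_probes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_per <- c(known_orf = 2L, unknown_orf = 4L, or_contig = 5L)
  counts <- n_per[config$contig_class]
  contig <- rep(config$contig_ids, counts)
  class <- rep(config$contig_class, counts)
  k <- sequence(counts)
  # unknown-ORF contigs: probes 3 and 4 target the opposite reading direction
  orientation <- ifelse(class == "unknown_orf" & k > 2L, "antisense", "sense")
  pm <- data.frame(probe_id = paste0(contig, "_p", k),
                   contig_id = contig, contig_class = class,
                   orientation = orientation, stringsAsFactors = FALSE)
  class(pm) <- c("probe_map", "data.frame")
  pm
}

# deterministic per-contig RNG sub-stream so contig values do not depend on
# how many contigs precede them
.contig_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483563)
}

#' Simulate probe-level hybridization intensities
#'
#' Draws intensities under the log-normal model described in
#' [sim_config()]: per-contig baseline, per-probe offsets, group-specific
#' spiked fold-changes and per-probe replicate noise, all on the log2
#' scale; technical replicates are re-drawn around their group's first
#' biological replicate with a smaller sd. The caller's RNG state is left
#' untouched; all randomness derives from `seed` via per-contig
#' sub-streams.
#'
#' @param probes a `probe_map` from [design_probes()] built from `config`.
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return A list of class `sim_result` with elements `intensities`
#'   (an [intensity_matrix()]), `probes`, and `truth` (a list with the
#'   realized `spikes` table and the per-contig true `baseline`).
#' @export
simulate_intensities <- function(probes, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(probes$contig_id %in% config$contig_ids))
    stop("probe map does not match the configuration")
  g <- config$groups
  bio_id <- unlist(lapply(seq_len(nrow(g)), function(i)
    paste0(g$group[i], "_b", seq_len(g$n_biological[i]))))
  bio_group <- rep(g$group, g$n_biological)
  tech_id <- unlist(lapply(seq_len(nrow(g)), function(i)
    if (g$n_technical[i] > 0L)
      paste0(g$group[i], "_t", seq_len(g$n_technical[i])) else character()))
  tech_group <- rep(g$group, g$n_technical)
  samples <- data.frame(
    sample_id = c(bio_id, tech_id),
    group = c(bio_group, tech_group),
    dataset = g$dataset[match(c(bio_group, tech_group), g$group)],
    replicate_type = c(rep("biological", length(bio_id)),
                       rep("technical", length(tech_id))),
    stringsAsFactors = FALSE)
  n_bio <- length(bio_id)
  n_tech <- length(tech_id)
  # technical replicates re-draw noise around the group's first biological
  # sample
  tech_src <- match(paste0(tech_group, "_b1"), bio_id)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))

  spk <- config$spikes
  baseline <- numeric(config$n_contigs)
  names(baseline) <- config$contig_ids
  probes_of <- split(seq_len(nrow(probes)), probes$contig_id)
  log2v <- matrix(NA_real_, nrow(probes), n_bio + n_tech,
                  dimnames = list(probes$probe_id, samples$sample_id))
  for (i in seq_len(config$n_contigs)) {
    cid <- config$contig_ids[i]
    rows <- probes_of[[cid]]
    np <- length(rows)
    set.seed(.contig_seed(seed, i))
    b <- config$baseline_log2_mean + config$baseline_log2_sd * rnorm(1)
    baseline[i] <- b
    off <- config$probe_offset_sd * rnorm(np)
    spike_g <- numeric(n_bio)
    if (nrow(spk)) {
      hit <- spk$contig_id == cid
      if (any(hit))
        spike_g <- vapply(bio_group, function(gg) {
          s <- spk$log2fc[hit & spk$group == gg]
          if (length(s)) sum(s) else 0
        }, numeric(1))
    }
    noise <- matrix(config$replicate_noise_sd * rnorm(np * n_bio), np, n_bio)
    v <- b + off + noise + rep(spike_g, each = np)
    if (n_tech > 0L) {
      tnoise <- matrix(config$technical_noise_sd * rnorm(np * n_tech),
                       np, n_tech)
      v <- cbind(v, v[, tech_src, drop = FALSE] + tnoise)
    }
    log2v[rows, ] <- v
  }
  lin <- 2^log2v
  lin[lin < config$clip_floor] <- config$clip_floor
  res <- list(intensities = intensity_matrix(lin, samples),
              probes = probes,
              truth = list(spikes = spk, baseline = baseline))
  class(res) <- "sim_result"
  res
}

#' @export
print.sim_result <- function(x, ...) {
  cat("sim_result with", nrow(x$probes), "probes;",
      nrow(x$truth$spikes), "spiked contig(s)\n")
  print(x$intensities)
  invisible(x)
}

#' Simulate GO annotations for a contig set
#'
#' Assigns each contig a Poisson-distributed number of GO terms drawn
#' without replacement from a vocabulary; a contig may carry terms from
#' several categories.
#'
#' @param n_contigs number of contigs (ids follow the simulator's naming).
#' @param vocab data.frame with columns `term`, `category`, `level`.
#' @param mean_terms_per_contig Poisson mean of the per-contig term count.
#' @param seed integer seed.
#' @return data.frame with columns `contig_id`, `term`, `category`,
#'   `level`; `(contig_id, term)` pairs are unique.
#' @export
simulate_go_annotations <- function(n_contigs, vocab,
                                    mean_terms_per_contig = 2,
                                    seed = 1L) {
  vocab <- as.data.frame(vocab, stringsAsFactors = FALSE)
  if (nrow(vocab) == 0L) stop("GO vocabulary must be nonempty")
  if (!all(c("term", "category", "level") %in% names(vocab)))
    stop("vocab must have columns term, category, level")
  if (anyDuplicated(vocab$term)) stop("duplicated terms in vocabulary")
  if (mean_terms_per_contig < 0) stop("mean_terms_per_contig must be >= 0")
  ids <- make_contig_ids(n_contigs)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  k <- pmin(stats::rpois(n_contigs, mean_terms_per_contig), nrow(vocab))
  pick <- lapply(k, function(m) if (m > 0L) sample.int(nrow(vocab), m)
                 else integer())
  rows <- unlist(pick)
  out <- data.frame(contig_id = rep(ids, lengths(pick)),
                    term = vocab$term[rows],
                    category = vocab$category[rows],
                    level = vocab$level[rows],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' A small default GO vocabulary for simulations
#'
#' Generic molecular-function (level 3) and biological-process (level 2)
#' terms used to exercise the GO comparison machinery; term names are
#' synthetic placeholders, not curated GO identifiers.
#'
#' @param n_mf,n_bp number of molecular-function and biological-process
#'   terms.
#' @return data.frame with columns `term`, `category`, `level`.
#' @export
default_go_vocab <- function(n_mf = 15L, n_bp = 10L) {
  data.frame(
    term = c(sprintf("MF%02d", seq_len(n_mf)), sprintf("BP%02d", seq_len(n_bp))),
    category = c(rep("molecular function", n_mf),
                 rep("biological process", n_bp)),
    level = c(rep(3L, n_mf), rep(2L, n_bp)),
    stringsAsFactors = FALSE)
}
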