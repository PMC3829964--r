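#' Pipeline configuration
#'
#' Bundles everything needed for an end-to-end run on simulated data: the
#' simulation configuration, the differential-expression thresholds, the
#' EF screening parameters, the log-transform and presence parameters,
#' the EF comparisons (focal group first), and the GO vocabulary.
#' Comparisons are validated against the declared groups before any stage
#' runs.
#'
#' @param sim a [sim_config()].
#' @param thresholds a [de_thresholds()].
#' @param ef_comparisons list of length-2 character vectors
#'   `c(focal, comparison)`; both groups must belong to the same dataset.
#' @param gene_set gene ids for the EF screen; default: all OR contigs of
#'   the simulated design.
#' @param ef_min,band_halfwidth EF screen parameters
#'   (see [candidate_screen()]).
#' @param log_base,log_offset log transform parameters.
#' @param presence_threshold linear intensity threshold for presence
#'   calls.
#' @param go_vocab GO vocabulary for simulated annotations (see
#'   [default_go_vocab()]), or NULL to skip the GO stage.
#' @param mean_terms_per_contig Poisson mean for simulated annotations.
#' @param seed integer seed for the whole run.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = config_de_null(),
                            thresholds = de_thresholds(),
                            ef_comparisons = list(),
                            gene_set = NULL,
                            ef_min = 2, band_halfwidth = 0.5,
                            log_base = 2, log_offset = 1,
                            presence_threshold = 100,
                            go_vocab = default_go_vocab(),
                            mean_terms_per_contig = 2,
                            seed = sim$seed) {
  stopifnot(inherits(sim, "sim_config"), inherits(thresholds, "de_thresholds"))
  for (cmp in ef_comparisons) {
    if (length(cmp) != 2L)
      stop("each EF comparison must name exactly 2 groups")
    bad <- setdiff(cmp, sim$groups$group)
    if (length(bad))
      stop("EF comparison references undeclared group(s): ",
           paste(bad, collapse = ", "))
    ds <- sim$groups$dataset[match(cmp, sim$groups$group)]
    if (length(unique(ds)) != 1L)
      stop("EF comparison mixes datasets: ", paste(cmp, collapse = " vs "))
  }
  if (is.null(gene_set))
    gene_set <- sim$contig_ids[sim$contig_class == "or_contig"]
  bad <- setdiff(gene_set, sim$contig_ids)
  if (length(bad)) stop("gene_set references unknown contig(s): ",
                        paste(bad, collapse = ", "))
  structure(list(sim = sim, thresholds = thresholds,
                 ef_comparisons = ef_comparisons, gene_set = gene_set,
                 ef_min = ef_min, band_halfwidth = band_halfwidth,
                 log_base = log_base, log_offset = log_offset,
                 presence_threshold = presence_threshold,
                 go_vocab = go_vocab,
                 mean_terms_per_contig = mean_terms_per_contig,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on simulated data
#'
#' Executes the stages in order — simulate, per-dataset quantile
#' normalization, probe aggregation, differential expression, EF
#' candidate screens, and the per-term GO chi-square comparison — and
#' returns all stage outputs plus a manifest (config hash, seed, row
#' counts). Reruns with the same configuration and seed reproduce
#' identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param seed integer seed (defaults to the configured seed).
#' @param out_dir optional directory; when given, all stage outputs and
#'   the manifest are written as TSV files.
#' @return list of class `antarray_run` with elements `sim`, `de`
#'   (one `de_table` per dataset), `ef` (one `ef_screen` per
#'   comparison), `go` (one `go_screen` per dataset, if a vocabulary was
#'   configured), `manifest`.
#' @export
run_pipeline <- function(config, seed = config$seed, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sim_cfg <- config$sim
  probes <- design_probes(sim_cfg)
  sim <- simulate_intensities(probes, sim_cfg, seed = seed)

  datasets <- sort(unique(sim_cfg$groups$dataset))
  norm <- lapply(datasets, function(d) quantile_normalize(sim$intensities, d))
  names(norm) <- paste0("dataset", datasets)
  agg <- lapply(norm, aggregate_probes, probes = probes)
  logt <- lapply(agg, log_transform, base = config$log_base,
                 offset = config$log_offset)

  de <- lapply(seq_along(datasets), function(i)
    de_table(agg[[i]], thresholds = config$thresholds,
             log_base = config$log_base, log_offset = config$log_offset))
  names(de) <- names(agg)

  ef <- lapply(config$ef_comparisons, function(cmp) {
    ds <- sim_cfg$groups$dataset[match(cmp[1L], sim_cfg$groups$group)]
    candidate_screen(logt[[paste0("dataset", ds)]], cmp[1L], cmp[2L],
                     config$gene_set, ef_min = config$ef_min,
                     band_halfwidth = config$band_halfwidth)
  })
  names(ef) <- vapply(config$ef_comparisons,
                      function(cmp) paste0(cmp[1L], "_vs_", cmp[2L]),
                      character(1))

  go <- NULL
  annotations <- NULL
  if (!is.null(config$go_vocab)) {
    annotations <- simulate_go_annotations(
      sim_cfg$n_contigs, config$go_vocab,
      mean_terms_per_contig = config$mean_terms_per_contig,
      seed = seed + 1L)
    go <- lapply(seq_along(datasets), function(i) {
      pres <- presence_calls(agg[[i]], config$presence_threshold)
      screen_all_terms(annotations, pres, agg[[i]]$samples,
                       alpha = config$thresholds$alpha)
    })
    names(go) <- names(agg)
  }

  manifest <- list(
    seed = as.integer(seed),
    config_hash = .config_hash(config),
    n_probes = nrow(probes),
    n_contigs = sim_cfg$n_contigs,
    n_samples = ncol(sim$intensities$values),
    n_de_relevant = vapply(de, function(d) sum(d$relevant), integer(1)),
    n_ef_candidates = vapply(ef, function(e) sum(e$candidate), integer(1)),
    n_go_terms = if (is.null(go)) integer() else
      vapply(go, nrow, integer(1)))

  run <- structure(list(sim = sim, de = de, ef = ef, go = go,
                        annotations = annotations, manifest = manifest),
                   class = "antarray_run")
  if (!is.null(out_dir)) .write_run(run, out_dir)
  run
}

# deterministic md5 of the serialized configuration
.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

.write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_sim_data(run$sim, out_dir)
  for (nm in names(run$de))
    write_de_table(run$de[[nm]], file.path(out_dir, paste0("de_", nm, ".tsv")))
  for (nm in names(run$ef))
    write_ef_screen(run$ef[[nm]], file.path(out_dir, paste0("ef_", nm, ".tsv")))
  for (nm in names(run$go))
    utils::write.table(as.data.frame(run$go[[nm]]),
                       file.path(out_dir, paste0("go_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  mf <- run$manifest
  flat <- data.frame(key = c("seed", "config_hash", "n_probes", "n_contigs",
                             "n_samples",
                             paste0("n_de_relevant_", names(mf$n_de_relevant)),
                             paste0("n_ef_candidates_", names(mf$n_ef_candidates)),
                             paste0("n_go_terms_", names(mf$n_go_terms))),
                     value = c(mf$seed, mf$config_hash, mf$n_probes,
                               mf$n_contigs, mf$n_samples,
                               mf$n_de_relevant, mf$n_ef_candidates,
                               mf$n_go_terms),
                     stringsAsFactors = FALSE)
  utils::write.table(flat, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.antarray_run <- function(x, ...) {
  cat("antarray_run (seed ", x$manifest$seed, ", config ",
      substr(x$manifest$config_hash, 1, 8), ")\n", sep = "")
  cat("  probes: ", x$manifest$n_probes, ", contigs: ",
      x$manifest$n_contigs, ", samples: ", x$manifest$n_samples, "\n",
      sep = "")
  for (nm in names(x$de))
    cat("  DE ", nm, ": ", sum(x$de[[nm]]$relevant), " relevant contig(s)\n",
        sep = "")
  for (nm in names(x$ef))
    cat("  EF ", nm, ": ", sum(x$ef[[nm]]$candidate), " candidate(s)\n",
        sep = "")
  if (!is.null(x$go))
    for (nm in names(x$go))
      cat("  GO ", nm, ": ", nrow(x$go[[nm]]), " terms, any p <= alpha: ",
          attr(x$go[[nm]], "any_significant"), "\n", sep = "")
  invisible(x)
}
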