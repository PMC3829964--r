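test_that("probe design follows the 2/4/5 multiplicity rules", {
  cases <- list(
    c(known = 1L, unknown = 0L, or = 0L),
    c(known = 0L, unknown = 1L, or = 0L),
    c(known = 0L, unknown = 0L, or = 1L),
    c(known = 7L, unknown = 5L, or = 3L),
    c(known = 0L, unknown = 0L, or = 10L))
  for (cs in cases) {
    n_non_or <- cs[["known"]] + cs[["unknown"]]
    frac <- if (n_non_or > 0) cs[["known"]] / n_non_or else 0
    cfg <- sim_config(n_contigs = n_non_or + cs[["or"]],
                      frac_known_orf = frac, n_or_contigs = cs[["or"]],
                      groups = study_groups(c("large", "tiny")))
    pm <- design_probes(cfg)
    per_contig <- table(pm$contig_id)
    cls <- cfg$contig_class[match(names(per_contig), cfg$contig_ids)]
    expect_true(all(per_contig[cls == "known_orf"] == 2L))
    expect_true(all(per_contig[cls == "unknown_orf"] == 4L))
    expect_true(all(per_contig[cls == "or_contig"] == 5L))
    expect_identical(nrow(pm),
                     2L * cs[["known"]] + 4L * cs[["unknown"]] + 5L * cs[["or"]])
    expect_false(anyDuplicated(pm$probe_id) > 0)
  }
})

test_that("unknown-ORF contigs get 2 probes per reading direction", {
  cfg <- sim_config(n_contigs = 3L, frac_known_orf = 0, n_or_contigs = 0L,
                    groups = study_groups(c("large", "tiny")))
  pm <- design_probes(cfg)
  tab <- table(pm$contig_id, pm$orientation)
  expect_true(all(tab[, "sense"] == 2L))
  expect_true(all(tab[, "antisense"] == 2L))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_contigs = 3, n_or_contigs = 5),
               "exceeds")
  expect_error(sim_config(n_contigs = -1), "nonnegative")
  expect_error(sim_config(frac_known_orf = 1.2), "0, 1")
  expect_error(sim_config(spikes = data.frame(contig_id = "nope",
                                              group = "large",
                                              log2fc = 1)),
               "unknown contig")
  expect_error(sim_config(groups = study_groups(c("large", "tiny")),
                          spikes = data.frame(contig_id = make_contig_ids(1),
                                              group = "males", log2fc = 1)),
               "unknown group")
})

test_that("zero-noise simulation is exact", {
  base_args <- list(n_contigs = 6L, frac_known_orf = 0.5, n_or_contigs = 1L,
                    groups = study_groups(c("large", "tiny")),
                    baseline_log2_mean = 8, baseline_log2_sd = 0,
                    probe_offset_sd = 0, replicate_noise_sd = 0)
  cfg <- do.call(sim_config, base_args)
  sim <- simulate_intensities(design_probes(cfg), cfg)
  # no spikes: every sample column identical
  expect_true(all(sim$intensities$values == sim$intensities$values[, 1]))

  ids <- make_contig_ids(6L)
  cfg2 <- do.call(sim_config, c(base_args, list(
    spikes = data.frame(contig_id = ids[3], group = "large", log2fc = 1))))
  sim2 <- simulate_intensities(design_probes(cfg2), cfg2)
  v <- sim2$intensities$values
  s <- sim2$intensities$samples
  spiked_probes <- sim2$probes$contig_id == ids[3]
  ratio <- rowMeans(v[spiked_probes, s$group == "large", drop = FALSE]) /
    rowMeans(v[spiked_probes, s$group == "tiny", drop = FALSE])
  expect_equal(ratio, rep(2, sum(spiked_probes)), tolerance = 1e-12,
               ignore_attr = TRUE)
  # unspiked contigs unchanged across groups
  other <- !spiked_probes
  expect_true(all(v[other, ] == v[other, 1]))
})

test_that("per-group fold-changes match the spike under zero noise for any fc", {
  ids <- make_contig_ids(4L)
  for (fc in c(0.5, 1.07, 2.46)) {
    cfg <- sim_config(n_contigs = 4L, frac_known_orf = 1, n_or_contigs = 0L,
                      groups = study_groups(c("queens", "males")),
                      baseline_log2_sd = 0, probe_offset_sd = 0,
                      replicate_noise_sd = 0,
                      spikes = data.frame(contig_id = ids[1], group = "males",
                                          log2fc = fc))
    sim <- simulate_intensities(design_probes(cfg), cfg)
    ag <- aggregate_probes(sim$intensities, sim$probes)
    g <- ag$samples$group
    r <- mean(ag$values[ids[1], g == "males"]) /
      mean(ag$values[ids[1], g == "queens"])
    expect_equal(r, 2^fc, tolerance = 1e-12)
  }
})

test_that("simulation is deterministic in (config, seed) and seed-sensitive", {
  cfg <- tiny_config(seed = 42L)
  pm <- design_probes(cfg)
  a <- simulate_intensities(pm, cfg)
  b <- simulate_intensities(pm, cfg)
  expect_identical(a$intensities$values, b$intensities$values)
  expect_identical(a$truth, b$truth)
  c3 <- simulate_intensities(pm, cfg, seed = 43L)
  expect_false(identical(a$intensities$values, c3$intensities$values))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  r1 <- runif(1)
  set.seed(99)
  invisible(simulate_intensities(design_probes(tiny_config()), tiny_config()))
  r2 <- runif(1)
  expect_identical(r1, r2)
})

test_that("study design replicate structure is reproduced", {
  cfg <- sim_config(n_contigs = 3L, groups = study_groups())
  sim <- simulate_intensities(design_probes(cfg), cfg)
  s <- sim$intensities$samples
  expect_identical(sum(s$group == "workers" & s$replicate_type == "biological"), 3L)
  expect_identical(sum(s$group == "workers" & s$replicate_type == "technical"), 1L)
  expect_identical(sum(s$dataset == 1), 12L)
  expect_identical(sum(s$dataset == 2), 8L)
  # technical replicate tracks its biological source when its own noise is 0
  cfg0 <- sim_config(n_contigs = 3L, groups = study_groups(),
                     technical_noise_sd = 0)
  sim0 <- simulate_intensities(design_probes(cfg0), cfg0)
  v <- sim0$intensities$values
  expect_identical(v[, "workers_t1"], v[, "workers_b1"],
                   ignore_attr = TRUE)
})

test_that("truth covers exactly the configured spikes", {
  ids <- make_contig_ids(5L)
  spikes <- data.frame(contig_id = ids[c(2, 4)], group = c("large", "tiny"),
                       log2fc = c(1, -0.5))
  cfg <- sim_config(n_contigs = 5L, groups = study_groups(c("large", "tiny")),
                    spikes = spikes)
  sim <- simulate_intensities(design_probes(cfg), cfg)
  expect_identical(sim$truth$spikes, cfg$spikes)
  expect_identical(names(sim$truth$baseline), ids)
})

test_that("clip floor replaces sub-floor linear intensities", {
  cfg <- sim_config(n_contigs = 4L, groups = study_groups(c("large", "tiny")),
                    baseline_log2_mean = 1, baseline_log2_sd = 2,
                    clip_floor = 3, seed = 5L)
  sim <- simulate_intensities(design_probes(cfg), cfg)
  expect_true(all(sim$intensities$values >= 3))
})

test_that("GO annotation simulation behaves at the edges", {
  vocab <- default_go_vocab()
  expect_error(simulate_go_annotations(5, vocab[0, ]), "nonempty")
  none <- simulate_go_annotations(5, vocab, mean_terms_per_contig = 0)
  expect_identical(nrow(none), 0L)
  a <- simulate_go_annotations(20, vocab, 2, seed = 7)
  b <- simulate_go_annotations(20, vocab, 2, seed = 7)
  expect_identical(a, b)
  expect_false(anyDuplicated(a[, c("contig_id", "term")]) > 0)
  # saturation: single term, huge rate -> every contig carries it
  one <- data.frame(term = "T1", category = "molecular function", level = 3)
  sat <- simulate_go_annotations(30, one, mean_terms_per_contig = 50, seed = 1)
  expect_identical(sort(unique(sat$contig_id)), make_contig_ids(30))
})
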