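---
title: "Methods: caste-specific antennal expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: caste-specific antennal expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antarray)
```

# The analysis problem

Ant castes with a pheromone-processing macroglomerulus in the antennal
lobe (large workers: one; males: three) are expected to express the
corresponding odorant-receptor (OR) genes at high levels, enriched
relative to castes without that structure. The package analyses
single-color microarray intensities measured on probes designed per
assembled transcriptome contig, across two separately hybridized
datasets: dataset 1 compares the castes (queens, males, workers; four
replicates each, the workers as three biological replicates plus one
technical replicate of pooled RNA), dataset 2 the worker subcastes
(large, tiny; four biological replicates each).

Three statistical instruments operate on the aggregated contig table:

1. a per-contig differential-expression cascade (ANOVA or t-test, FDR
   correction, post-hoc grouping, expression and fold gates);
2. the expression factor, a within-gene-set z-score used to screen OR
   genes for candidate pheromone receptors; and
3. a per-GO-term chi-square comparison of presence/absence composition
   across groups.

# Array processing

**Quantile normalization** is applied to each dataset separately (the two
datasets were hybridized and scanned as separate experiments, so their
intensity distributions are not comparable a priori, and normalizing them
jointly would partially absorb genuine caste/subcaste signal into the
reference distribution). The implementation delegates to
`limma::normalizeQuantiles`, i.e. the mean-of-order-statistics
construction: every column is mapped onto the vector of row-wise means of
the order statistics. Ties within a column receive the mean of the
normalized values over their tied ranks. The procedure is idempotent (to
floating precision) and equivariant under sample permutation; both
properties are asserted in the test suite on random matrices.

**Probe aggregation** pools a contig's probes — 2 for contigs with an
identified ORF, 4 for unknown-ORF contigs (2 per reading direction), 5
for OR contigs — by their unweighted arithmetic mean per sample. Sense
and antisense probes of unknown-ORF contigs are averaged together; the
analysis reports contig-level values only, and strand-aware filtering
would require sequence-level information outside this package's scope.

**Log transform.** All tests and the EF operate on
`log2(intensity + 1)`. The base is a convention: the grey band of ±0.5
(below) and the 2-fold relevance threshold are mutually consistent on a
log2 scale (a 2-fold change is 1.0 log2 units, comfortably outside the
band; on a log10 scale a 2.1-fold change would fall inside a ±0.5 band,
which contradicts how the band is used). The +1 offset maps the
background-subtraction floor at zero intensity to 0 and perturbs
well-expressed contigs (intensities ≥ 100) by less than 0.015 log2
units.

**Presence calls** are per individual array: present ⇔ aggregated linear
intensity ≥ 100, reusing the expression cutoff of the DE cascade. The
original feature-extraction software's own detection flags are not
reproducible from intensity tables alone; an intensity threshold is the
transparent surrogate, and the threshold is exposed as a parameter.

# Differential expression

Per contig, group means are computed on the **linear** scale and the
hypothesis tests run on the **log** scale. The log-normal noise model
makes log-scale residuals approximately normal with comparable variance
across groups, which is the regime where the fixed-effects F and pooled-t
assumptions hold; the biological relevance thresholds (absolute intensity
100, 2-fold ratio) are quoted on the linear scale and are therefore
applied to linear means.

The cascade, in order:

* **expressed**: max linear group mean ≥ `min_mean_intensity`
  (default 100, intensity units). The maximum — not the grand mean — is
  used so that a gene expressed in only one caste is kept.
* **test**: one-way ANOVA for 3 groups, classical pooled-variance
  two-sided t-test for 2 groups (a Welch correction is deliberately not
  used; the pooled test is the stated method and matches the balanced
  4-replicate design). Degenerate inputs are defined away from NaN:
  all-identical values give F = 0 (or t = 0), p = 1; zero within-group
  variance with distinct means gives p = 0 and, for the t-test, a
  `degenerate` flag.
* **Benjamini–Hochberg** step-up adjustment across all *expressed*
  contigs of the dataset (excluded contigs are not tested and do not
  enter the correction).
* **SNK post-hoc** letter groupings for ANOVA-significant contigs
  (adjusted p ≤ alpha), using the log-scale group means and the ANOVA
  mean-square error. Computing the post-hoc only after a significant
  omnibus test is the standard gating; the harmonic mean of group sizes
  is used when sizes are unbalanced (the 3+1 worker group is balanced at
  n = 4 because the technical replicate is included as an observation,
  consistent with it being listed among the four replicates).
* **relevant**: expressed ∧ adjusted p ≤ alpha (default 0.05) ∧ max
  pairwise ratio of linear group means ≥ `min_fold` (default 2).

`heatmap_matrix()` emits the log-transformed group means with
non-relevant contigs masked as missing — the "white boxes" convention of
expression heatmaps.

The SNK step-down compares, for stretch length r = k … 2, the range of
every stretch of r adjacent ordered means against
`qtukey(1 − alpha, r, df) * sqrt(MSE / n_h)`; a stretch that fails to
reach the critical value is declared homogeneous and never subdivided.
Homogeneous subsets may overlap and are reported as letter groupings.
The test suite verifies the whole step-down against an independent
re-derivation whose critical decisions come from a studentized-range CDF
computed by double Gauss–Legendre integration (160 × 220 nodes), and
checks that for k = 2 the accept/reject decision coincides with the
pooled t-test at the same alpha. A nonpositive MSE is rejected as an
error; the MSE → 0 limit (every group its own subset) is exercised at
tiny positive MSE.

# The expression-factor screen

For a gene set G (all OR genes and OR-gene fragments) within one group,
let LTI be the log-transformed intensity averaged over the group's
**biological** replicates (the technical replicate is a re-measurement,
not an independent sample, so it is excluded here; in the DE cascade it
participates like any array). Then

```
EF(g) = (LTI_g − mean(LTI over G)) / sd(LTI over G)
```

with the sample standard deviation (n − 1). The alternative reading of
the normalizer as a standard error of the mean is rejected: dividing by
SD/√|G| with |G| in the hundreds would inflate all EFs by an order of
magnitude, incompatible with candidate EFs in the 2–3.4 range at the
reported fold-changes. By construction the EF vector over G has mean 0
and sd 1 (asserted to 1e-10), and it is invariant under affine rescaling
of the LTIs.

A **candidate** must satisfy two gates: `EF ≥ ef_min` (default 2.0 —
high absolute expression within the family) and
`log_fold ≥ band_halfwidth` (default 0.5 log2 units) versus the
comparison group. Log-fold differences inside ±0.5 are treated as
biologically irrelevant; the gate is one-sided because a candidate
pheromone receptor must be *enriched* in the macroglomerulus-bearing
group, while the symmetric band is still reported for plotting. Output
is ranked by EF descending, ties broken by log-fold then gene id, making
the ordering reproducible.

`percentile_rank()` places one gene within a reference class (e.g. a
receptor subfamily) as the percentage of reference genes with strictly
lower LTI; ties count one half, and the gene itself is excluded from its
reference set so that "above all others" reads 100%.

# GO presence/absence comparison

For each GO term independently, the 2 × k table of
(present-and-annotated, present-and-not-annotated) × group is tested
with Pearson's chi-square, no continuity correction and no correction
across terms — each term is reported on its own. A contig is
group-present when present on ≥ 50% of the group's arrays (majority
rule; the per-array calls must be aggregated somehow and the majority is
the least informative-assumption choice; the fraction is a parameter).
Expected counts below 5 are flagged, never auto-corrected. Groups with
zero present contigs make the test undefined and are skipped with a
flag.

Two caveats are deliberate. First, the observation unit is the contig:
the same contig can be present in several groups, so the k columns are
not independent samples, and the test is conservative in exactly the
situations where presence is driven by overall abundance rather than
group. The test suite therefore checks calibration (type-I error ≈
alpha) on tables whose groups *are* sampled independently, and checks
only the one-sided bound (false-positive fraction ≤ alpha + 2·SE) on
full pipeline simulations. Second, GO levels are taken from the input
annotation table as produced by upstream annotation software;
`go_levels_from_edges()` offers a shortest-path-from-root definition
when only an ontology edge list is available.

# The synthetic-data generator

The generator is the package's stand-in for the deposited arrays and
defines the conditions under which every statistical property is tested.
On the log2 scale, a probe value is

```
baseline(contig) + offset(probe) + spike(contig, group) + noise(probe, sample)
```

with all terms Gaussian, exponentiated to linear intensities and floored
at `clip_floor` (default 0: background subtraction reports nonnegative
values). Choices worth stating:

* **Log-normal model** — all downstream statistics run on log-scale
  values, and fluorescence intensities are classically right-skewed with
  multiplicative noise.
* **Noise is drawn per probe × sample**, so pooling a contig's 2/4/5
  probes reduces contig-level noise by √(number of probes), as
  hybridization-level replication should.
* **Technical replicates** re-draw noise around their group's first
  biological sample with half the replicate sd — a re-hybridization of
  the same RNA pool shares the biological draw and adds smaller
  technical variation.
* **Determinism** — every contig draws from its own deterministic
  sub-stream of the seed, so outputs are bit-identical for identical
  (configuration, seed) and stable under contig reordering; the caller's
  RNG state is left untouched.
* **Defaults** — baseline mean 9 log2 units (≈ 500 intensity units,
  comfortably above the expression cutoff), transcriptome-wide baseline
  sd 1.5 log2 units (the dynamic range of quantile-normalized arrays),
  probe offset sd 0.25, replicate noise sd 0.25 log2 units.

The **screening scenarios** (`config_worker_screen()`,
`config_male_screen()`) use a *within-OR-set* baseline sd of 0.2 log2
units instead. This is a calibration from the screen's own arithmetic,
fixed before any testing: a candidate with EF ≈ 3.4 at a 1.07 log2-unit
caste enrichment requires the OR-set LTI spread to be ≈ 0.3 log2 units
if the enrichment alone carries the elevation, and less when the
candidate also sits above the family baseline; biologically, OR genes
are each expressed in a small subpopulation of antennal neurons, so
whole-antenna intensities within the family occupy a narrow band rather
than the full transcriptome's range. The null scenarios
(`config_de_null()`, `config_go_null()`) keep the wide transcriptome
spread; the GO null centres baselines at the presence threshold
(log2 100) so presence calls actually vary between arrays.

What the generator does **not** model: dye chemistry, spatial array
artifacts, probe sequence effects (GC content, cross-hybridization),
correlated expression between contigs, and heavy-tailed outliers.
Passing recovery and calibration tests therefore demonstrates the
correctness and power of the statistical machinery under the declared
noise model, not performance guarantees on real hybridizations.

# Problem sizes and tolerances

The test suite runs the screening scenarios at 200 OR genes with 100
simulation seeds each (recovery thresholds 90% for the 2.1-fold worker
spike, 95% for the three 5.5–22.7-fold male spikes), the null
calibrations at 500 (DE) and 300 (GO) contigs over 50 seeds, BH
equivalence on 1000 random vectors of length up to 200, SNK-vs-oracle
agreement on 200 random instances with k ≤ 5 and df ≤ 30, and quantile
normalization invariants on 100 random matrices. Equality tolerances:
exact (bitwise) for BH against the step-up definition; 1e-10 for EF
standardization; 1e-12 relative for normalization idempotence.
`scripts/acceptance.R` re-runs the same scenarios from a user-supplied
seed and writes the resulting quantities as JSON.

# Known limitations

* Quantile normalization slightly attenuates spiked fold-changes (a true
  2.1-fold spike is realized at ≈ 1.9–2.0), as it must when one group's
  distribution is shifted by signal; thresholds sitting exactly at a
  true fold-change are therefore crossed stochastically.
* The plain ANOVA/t-test cascade has limited power at four replicates;
  no empirical-Bayes variance moderation is applied because the plain
  tests are the method being implemented.
* The per-term chi-square inherits the shared-contig dependence
  discussed above and is best read, as in the source analyses, as a
  coarse screen for compositional differences.
* Linear-mean ratios (not back-transformed log-mean ratios) implement
  the fold thresholds; with log-normal noise the two differ by a small
  Jensen term.
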