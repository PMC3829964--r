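Package: antarray
Title: Caste-Specific Antennal Expression Analysis for Single-Color Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential expression analysis of antennal transcriptomes across
    ant castes and worker subcastes on single-color microarray intensity data.
    Provides per-dataset quantile normalization, probe-to-contig aggregation,
    ANOVA and t-test screens with Benjamini-Hochberg correction and
    Student-Newman-Keuls post-hoc grouping, an expression-factor (z-score)
    screen for candidate pheromone receptors among odorant-receptor genes,
    per-GO-term presence/absence chi-square comparisons, and a synthetic-data
    generator that emulates the probe design and replicate structure of the
    study arrays with known spiked fold-changes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    limma,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
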