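Package: votuecol
Title: Community Ecology of Viral Operational Taxonomic Units from
    Metagenomic Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the post-identification ecology of prokaryotic DNA
    viruses in metagenomes: greedy clustering of viral contigs into viral
    operational taxonomic units (vOTUs) at 95% average nucleotide identity
    and 80% aligned fraction, coverage-based abundance normalization per
    metagenome gigabase, compositional (centered log-ratio) transformation
    and Aitchison beta-diversity, permutation statistics (PERMANOVA,
    environmental vector fitting, Mantel tests), Bray-Curtis distance decay
    partitioned into balanced-variation and abundance-gradient components,
    occupancy-based dynamic classes, annotation-driven group contrasts
    (hosts, replicative strategy, auxiliary viral genes), and a seeded
    synthetic-data generator that plants recoverable two-ecosystem and
    time-series structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    pheatmap,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
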