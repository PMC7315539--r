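Package: dielSync
Title: Cross-Species Diurnal Expression Rhythms, Co-Clustering and Promoter Motif Enrichment
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects diurnally rhythmic genes in 72-hour expression time
    courses with a nonparametric Kendall-tau test against cosine reference
    waveforms, filters syntenic ortholog groups for day-to-day
    reproducibility, co-clusters 0-1 scaled expression profiles across
    species by K-means with Pearson correlation distance under a
    syntenic-pair permutation criterion, and discovers enriched promoter
    k-mers by combining per-species Fisher exact tests with a
    Cochran-Mantel-Haenszel test under a permutation-based false discovery
    rate. Includes a synthetic multi-species data generator with planted
    phases and cis-elements so every stage can be validated against known
    ground truth, plus an end-to-end seeded pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    tools,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Transcriptomics, TimeCourse, Clustering, MotifDiscovery,
    SystemsBiology
RoxygenNote: 7.3.3
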