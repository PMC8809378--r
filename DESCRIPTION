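Package: otufit
Title: Reference-Based and De Novo OTU Clustering by MCC Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Clusters amplicon sequences into operational taxonomic units
    (OTUs) by iteratively maximizing the Matthews correlation coefficient
    (MCC) over a sparse pairwise-similarity graph, following the OptiClust
    de novo algorithm and its reference-based extension OptiFit.  Query
    sequences can be fitted to existing reference OTUs in open or closed
    mode, datasets can be split into reference and query fractions by
    simple, abundance-weighted or similarity-weighted sampling, and OTU
    quality is scored with exact confusion-matrix accounting over all
    sequence pairs.  Readers and writers are provided for FASTA, sparse
    column and PHYLIP-style distance formats, and mothur-style list files,
    together with planted-partition simulators and exhaustive brute-force
    optima for validation on small instances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
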