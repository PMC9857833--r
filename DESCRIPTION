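Package: edbsa
Title: Bulked Segregant RNA-Seq Association Mapping with the
    Euclidean-Distance Statistic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping quantitative trait loci from pooled
    RNA-seq of extreme-phenotype bulks (BSR-seq). Implements variant
    filtering for two-bulk designs, the per-locus Euclidean distance (ED)
    between bulk base-frequency vectors with a power transform, profile
    smoothing by transcript or sliding window, a median + k*SD association
    threshold, candidate-region extraction and gene annotation, FPKM
    expression classification of candidate genes, seed-ratio phenotyping
    with extreme-bulk selection, and a half-sib population and pooled
    sequencing simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
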