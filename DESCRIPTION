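Package: unitigphaser
Title: Chromosome Clustering and Haplotype Phasing of Assembly-Graph
    Unitigs from Strand-Seq Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phases diploid genome assembly graphs with single-cell
    strand sequencing (Strand-seq) evidence. Per-library Watson/Crick
    alignment counts on assembly-graph unitigs are turned into
    strand-state-frequency vectors, which are clustered by chromosome
    with a batched agglomerative absolute-cosine-similarity strategy,
    corrected for misoriented unitigs by signed-cosine hierarchical
    clustering, and resolved into per-cluster phase geometry
    (cluster and phase vectors from an uncentered principal component
    analysis of the chromosome plane). Haplotype-informative reads are
    pooled into per-unitig haplotype marker counts ready for
    graph-threading tools, with an internal fallback haplotype caller.
    A synthetic Strand-seq generator with planted chromosome,
    haplotype, orientation and noise structure makes the whole engine
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
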