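Package: magsom
Title: Tetranucleotide Self-Organizing-Map Binning and Sulfide-Oxidation
    Energetics for Metagenomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recovering genome bins from assembled metagenomes of
    sulfidic-cave microbial biofilms and for assessing the energetics of the
    sulfide-oxidation reactions those communities catalyse. Contigs are
    profiled by windowed tetranucleotide frequency, embedded on a toroidal
    emergent self-organizing map, and segmented into genome bins by U-matrix
    thresholding; bins are curated by per-scaffold taxonomic majority vote and
    GC/coverage filtering, and summarised with assembly statistics and
    single-copy marker completeness. Best-hit tables are filtered with
    e-value, bit-score and query-coverage thresholds and functional-gene
    abundance is normalized to gene length and library size. A stoichiometry
    balancer and Gibbs free-energy calculator evaluate pH-corrected reaction
    energies for aerobic and nitrate-coupled sulfide oxidation. A seedable
    synthetic community generator supplies multi-genome test data with ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    GenomicRanges,
    S4Vectors,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    mclust,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    rtracklayer,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
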