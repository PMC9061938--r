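Package: prophinder
Title: Prophage Detection in Bacterial Genomes by Density Clustering and
    Keyword Window Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates prophage regions in annotated bacterial genomes by
    combining two detectors: single-linkage density clustering of
    phage-homologous genes along each contig (a one-dimensional DBSCAN
    reduction) and a sliding window scan of gene product annotations for
    phage-related keywords. Overlapping candidate clusters from the two
    arms are merged, attL/attR direct repeats are searched in the gene
    flanks around integrase anchors, and each region is assigned a phage
    taxonomy by majority vote over its homology hits. Includes parsers
    for GenBank flat files, FASTA and tabular protein-alignment output,
    a deterministic synthetic-genome generator with implanted prophage
    cassettes for offline testing, result writers (TSV, GFF3, FASTA,
    HTML) and a parameter-tuning harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    GenomicRanges,
    igraph,
    rtracklayer,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
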