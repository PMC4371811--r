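Package: LSUpipe
Title: Fungal LSU (28S rDNA) Amplicon Community Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for fungal large-subunit (28S rDNA)
    amplicon metabarcoding: primer-aware qualification, trimming and
    quality-aware merging of Illumina paired-end reads; curation of an
    LSU reference set with seven-rank taxonomic lineages; nearest-neighbor
    taxonomy assignment with lineage-consensus resolution and domain
    splitting; per-sample OTU construction (dereplication, singleton
    removal, greedy 97 percent clustering, reference-based chimera
    filtering, read re-assignment); and phylogenetic community comparison
    (rarefaction, neighbor-joining trees over OTU representatives, weighted
    and unweighted UniFrac, principal coordinates analysis, taxonomy
    composition summaries). A synthetic-data module simulates reference
    databases and tuber- and soil-like communities with realistic read
    lengths, quality decay, sequencing error and chimeras, so the whole
    pipeline can be exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    ape,
    phangorn
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
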