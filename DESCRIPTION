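Package: coretax
Title: Metatranscriptome Read Partitioning and Core/Taxon-Specific
    Transcript Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the analysis of mixed-community RNA sequencing
    (metatranscriptome) libraries: quality control of pyrosequencing
    reads (3' quality trimming, length, mean-quality, ambiguity and
    DUST low-complexity filters, artificial-replicate removal),
    partitioning of reads into SSU rRNA, LSU rRNA and putative mRNA
    fractions from tabular homology searches with bit-score
    arbitration, closed-reference OTU assignment with
    mapping-efficiency curves and taxon abundance tables,
    classification of mRNA reads into core, non-core-shared,
    taxon-specific, minor-group and novel transcripts from their
    homolog distribution across taxon-specific protein databases, and
    downstream community and functional statistics (Bray-Curtis
    dissimilarity, normalized taxon-specific abundance, key-function
    expression profiles, Yates-corrected chi-square tests for
    differentially represented functional subsystems).  A fully
    seeded synthetic-data generator emulates every input with known
    ground truth so the whole chain can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
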