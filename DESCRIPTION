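Package: plastidSV
Title: Quadripartite Plastome Structure, SSC Switching and Structural
    Variant Analysis from Long Reads
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the quadripartite structure of plant
    chloroplast genomes (plastomes) and the structural dynamics it permits.
    Detects the inverted-repeat pair and partitions a circular plastome into
    LSC, IR1, SSC and IR2; constructs the SSC-forward and SSC-reverse
    orientation haplotypes that coexist within an individual; classifies
    junction-spanning long reads to quantify SSC switching with a Wilson
    confidence interval on the orientation mixture; screens assemblies by the
    conserved rice IR1-SSC junction signatures and flags chimeric assemblies;
    applies the inverted-repeat gain and loss rearrangements of the
    asymmetric-recombination model; detects short tandem repeat loci and calls
    their copy-number variation from spanning reads; and simulates
    quadripartite genomes, mixed-orientation molecule pools and error-bearing
    long reads with recorded provenance so that every stage can be tested
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Genetics, SequenceMatching, Alignment, StructuralVariation
RoxygenNote: 7.3.3
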