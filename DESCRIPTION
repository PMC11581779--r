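Package: ssrscape
Title: Comparative Microsatellite Landscapes, Genic Context and Rates of
    Repeat-Abundance Evolution
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-wide mining of simple sequence repeats (SSRs,
    microsatellites) with perfect, imperfect and compound repeat calls;
    canonical motif classes under cyclic rotation and reverse complement
    (501 classes for motif sizes 1-6); localization of repeat loci to
    genic regions (CDS, exon, intron, intergenic) from GFF3 annotation;
    normalized landscape statistics (relative abundance in loci/Mbp and
    relative density in bp/Mbp of valid non-N sequence, GC content,
    ranked-density score matrices) and correlations with genome size;
    Brownian-motion models of repeat-abundance evolution on a
    time-calibrated phylogeny, including a multirate penalized-likelihood
    fit with per-branch rates; hypergeometric over-representation tests
    for annotation terms of repeat-bearing coding sequences; and a
    synthetic-genome generator with planted repeats and ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    phytools,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
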