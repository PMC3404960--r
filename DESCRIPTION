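Package: ssrmite
Title: In Silico SSR and MITE Polymorphism Discovery with F2 Linkage
    and QTL Mapping
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for developing codominant and dominant DNA markers
    from enriched genomic libraries of two inbred lines, and for using
    them in F2 genetics. Detects perfect microsatellite (SSR) tracts and
    canonicalizes their motifs, clusters reads from the two lines by
    flanking-sequence identity, classifies loci as polymorphic,
    monomorphic or line-specific (including miniature inverted-repeat
    transposable element, MITE, insertion sites), and designs PCR primer
    pairs on the flanks with a nearest-neighbor melting-temperature
    model. Downstream, it builds F2 linkage maps (EM recombination
    fractions, LOD grouping, SARF ordering, Haldane distances), runs
    Haley-Knott interval mapping with permutation thresholds, and
    screens multi-locus genotype combinations for epistatic traits. A
    seeded simulator generates reads, F2 populations and phenotypes with
    known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
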