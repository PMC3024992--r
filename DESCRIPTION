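Package: mhctyper
Title: Genotyping of Complex Multilocus MHC Amplicon Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Read-to-genotype workflow for ultra-complex multilocus MHC
    class IIB amplicon sequencing. Provides tag-based demultiplexing with
    estimation of the tag misassignment rate, a replication-based allele
    filter ("2-PCRs-3-copies-in-each"), PCR-chimera classification driven by
    the maximum per-amplicon frequency (MPAF) with data-derived and
    proportionally scaled thresholds, homopolymer-indel artifact flagging,
    pseudogene versus expressed-allele classification, per-individual
    genotyping with conservative allele counts and minimum locus-number
    estimation, Nei-Gojobori dN/dS with the Z-test of selection, Tamura-Nei
    distances with neighbor-joining trees, and a ground-truth amplicon read
    simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
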