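Package: panelforge
Title: Design and Validation Toolkit for SNP Genotyping Arrays
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing the marker content of high-density SNP
    genotyping arrays from a candidate variant set, in the style of the
    barley 50k Illumina Infinium iSelect platform. Implements two-stage
    marker selection with per-gene caps and recombination-aware,
    genetic-map-proportional allocation across chromosome zones;
    Infinium-style manifest construction with IUPAC polymorphism
    encoding; alignment-based redundancy detection against legacy marker
    sets; best-hit placement of legacy markers on a genome assembly with
    allele-based validation; single-effect variant annotation from gene
    models; and post-genotyping quality-control metrics (call agreement,
    polymorphism rate, transition/transversion ratio, conversion
    statistics, and genetic-versus-physical order concordance). A
    deterministic simulator generates genomes, gene models, candidate
    variants, legacy markers, and paired call sets with planted ground
    truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    data.table,
    methods,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
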