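Package: usnp
Title: Universal SNP Nomenclature, Cross-Database Mapping and Flanking-Sequence Localization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for a position-based universal nomenclature for single
    nucleotide polymorphisms of the form HG<build>.<chromosome>:<locus>:<alleles>.
    Provides a strict parser, formatter and validator for the nomenclature,
    translation to and from genomic-level HGVS names via user-supplied
    accession maps, a local cross-reference snapshot store that resolves
    dbSNP/JSNP/HapMap/GWAS identifiers by genomic position, a mismatch-tolerant
    gapless aligner that places flanking sequences with a marked variant site
    on a reference genome and projects the site to a genomic coordinate, a
    synthetic fixture generator (random genomes, planted SNPs, simulated
    flanking reads, cross-reference snapshots), and a command-line interface
    mirroring the name-generator, name-mapper and aligner utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    tools,
    utils,
    withr
Suggests:
    Rsamtools,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
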