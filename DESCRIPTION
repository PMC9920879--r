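Package: proteodrift
Title: Long-Read Proteogenomic Databases and Proteoform Identifiability
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building custom protein search databases from
    long-read transcript isoform catalogs and for analysing how database
    composition changes proteoform identifiability in bottom-up proteomics.
    Translates transcript models (GTF + genome FASTA) into proteoform
    databases with splice-aware ORF selection, gene-level start
    harmonization and premature-termination-codon / nonsense-mediated-decay
    feature annotation; removes exact-sequence redundancy and merges
    catalogs into hybrid databases with base-accession precedence; performs
    in silico tryptic digestion, peptide-to-proteoform indexing, uniqueness
    classification and cross-database uniqueness-drift analysis; infers
    identified protein families, unambiguous proteoforms and greedy
    parsimony groups from post-FDR peptide evidence; and generates fully
    seeded synthetic genomes, isoform catalogs, peptide evidence and
    differential-expression tables with recorded ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
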