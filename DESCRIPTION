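Package: radsexr
Title: Sex-Linked SNP Marker Discovery from RAD Sequencing in Dioecious Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A de novo pipeline for discovering sex-linked single nucleotide
    polymorphism markers from restriction site-associated DNA (RAD) sequencing
    of a full-sib family in a dioecious species. Starting from barcoded
    single-end reads, the pipeline demultiplexes by inline multiplex
    identifier, clusters 82-nt RAD reads into tag stacks within individuals,
    matches stacks across individuals into catalog loci, calls genotypes,
    filters to loci polymorphic between the parents, screens for SNPs that
    co-segregate perfectly with sex, and infers the heterogametic system
    (ZW versus XY). A companion simulator generates EcoRI RAD libraries from
    a ZW (or XY) cross with planted sex-linked and autosomal variants and a
    genotype truth table, so the full pipeline is testable without external
    data. Summary accounting (coverage depth, sequence coverage, SNP density)
    mirrors the standard reduced-representation bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
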