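Package: CommunityPrimers
Title: Taxon-Specific PCR Primer Design for Defined Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs PCR primer pairs that selectively amplify single members
    (microbe-specific) or user-defined groups of members (group-specific) of a
    defined microbial community, starting from per-genome coding-sequence
    (CDS) FASTA files. An internal k-mer-seeded banded Smith-Waterman engine
    (or an external MMseqs2-compatible hit table) performs the all-vs-all CDS
    homology screen; genes whose only surviving alignment is their self-hit
    are unique marker candidates, genes shared by every intended target and
    absent elsewhere are group marker candidates. Primer pairs are enumerated
    under product-size, melting-temperature, GC and dimer constraints with a
    nearest-neighbor thermodynamic model (SantaLucia 1998 unified parameters,
    Owczarzy 2008 divalent salt correction) and ranked by a Primer3-style
    penalty. Also provides genomic copy-number arithmetic for equal-copy
    pooling and droplet-digital-PCR absolute-to-relative abundance
    conversion, and a deterministic synthetic-community generator with
    planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    IRanges,
    data.table
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
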